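#' Gradient samples along two baseline lines
#'
#' Samples the response gradient along the two straight lines used by the
#' independence test: `s2` held at a constant low value while `s1` sweeps
#' its range, and `s1` held low while `s2` sweeps.  At low companion input
#' the integration is in its linear regime, so these baselines characterize
#' the subunit derivatives individually; from them the gradient angle at any
#' interior rectangle corner can be predicted (see [predict_angle()]).
#'
#' @param surface A [fit_surface()] result, or a model /
#'   [response_adapter()] (gradients then via central differences).
#' @param s2_low,s1_low Baseline coordinates; default 5% into each range.
#' @param n Samples per line.
#' @return List with data frames `line1` (varying `s1` at `s2 = s2_low`) and
#'   `line2` (varying `s2` at `s1 = s1_low`), each with columns `s1`, `s2`,
#'   `d1`, `d2`, `tan_alpha` where `tan_alpha = d2/d1` is the tangent of the
#'   angle between the `s1` axis and the gradient.
#' @export
gradients_on_lines <- function(surface, s2_low = NULL, s1_low = NULL, n = 65L) {
  rg <- input_ranges(surface)
  if (is.null(s1_low)) s1_low <- rg[1, 1] + 0.05 * diff(rg[1, ])
  if (is.null(s2_low)) s2_low <- rg[2, 1] + 0.05 * diff(rg[2, ])
  if (s1_low < rg[1, 1] || s1_low > rg[1, 2] ||
      s2_low < rg[2, 1] || s2_low > rg[2, 2])
    stop("baseline lines lie outside the input rectangle", call. = FALSE)
  x <- seq(rg[1, 1], rg[1, 2], length.out = n)
  y <- seq(rg[2, 1], rg[2, 2], length.out = n)
  line1 <- gradient_samples(surface, x, rep(s2_low, n))
  line2 <- gradient_samples(surface, rep(s1_low, n), y)
  list(line1 = line1, line2 = line2, s1_low = s1_low, s2_low = s2_low)
}

input_ranges <- function(x) {
  if (inherits(x, "response_surface")) rbind(range(x$s1), range(x$s2))
  else x$ranges
}

# gradient (and angle tangent) of a surface or callable model, pairwise;
# floor = 0 disables the degeneracy error (the caller maps flat gradients,
# e.g. on a capped plateau, to the sentinel error value instead)
gradient_samples <- function(x, s1, s2, floor = 1e-10) {
  if (inherits(x, "response_surface")) {
    d1 <- predict(x, s1 = s1, s2 = s2, deriv = c(1L, 0L))
    d2 <- predict(x, s1 = s1, s2 = s2, deriv = c(0L, 1L))
  } else {
    rg <- input_ranges(x)
    h1 <- 1e-5 * diff(rg[1, ]); h2 <- 1e-5 * diff(rg[2, ])
    p1 <- pmin(s1 + h1, rg[1, 2]); m1 <- pmax(s1 - h1, rg[1, 1])
    p2 <- pmin(s2 + h2, rg[2, 2]); m2 <- pmax(s2 - h2, rg[2, 1])
    d1 <- (predict(x, s1 = p1, s2 = s2) - predict(x, s1 = m1, s2 = s2)) / (p1 - m1)
    d2 <- (predict(x, s1 = s1, s2 = p2) - predict(x, s1 = s1, s2 = m2)) / (p2 - m2)
  }
  if (floor > 0 && any(sqrt(d1^2 + d2^2) < floor))
    stop("degenerate gradient: magnitude below the floor on a baseline line",
         call. = FALSE)
  data.frame(s1 = s1, s2 = s2, d1 = d1, d2 = d2, tan_alpha = d2 / d1)
}

#' Predict a gradient angle from three rectangle corners
#'
#' For a feedforward two-layer response the tangent of the gradient angle
#' factorizes into a ratio of the two subunit derivatives, so for any axis
#' aligned rectangle with corners `A`, `B`, `C`, `D` (where `A` and `B`
#' share `s1`, `C` and `D` share `s1`, `B` and `C` share `s2`, `A` and `D`
#' share `s2`) the identity
#' `tan(aD) = tan(aA) * tan(aC) / tan(aB)`
#' holds exactly — the output non-linearity cancels from the ratio.  Any
#' discrepancy between the predicted and the measured angle at `D` therefore
#' signals a failure of subunit independence at that input combination.
#'
#' @param alpha_A,alpha_B,alpha_C Angles (radians) at corners `A`, `B`, `C`.
#' @return Predicted angle at corner `D` (radians).
#' @examples
#' predict_angle(pi / 4, pi / 4, pi / 4)
#' @export
predict_angle <- function(alpha_A, alpha_B, alpha_C) {
  tB <- tan(alpha_B)
  if (any(abs(tB) < 1e-300) || any(!is.finite(tB)))
    stop("tangent at corner B vanishes or is undefined", call. = FALSE)
  atan(tan(alpha_A) * tan(alpha_C) / tB)
}

#' Input-regime map of subunit-independence errors
#'
#' For each interior grid point `D = (s1, s2)` the gradient angle is
#' predicted from the two baseline lines (corners `A = (s1_low, s2)`,
#' `B = (s1_low, s2_low)`, `C = (s1, s2_low)`) and compared with the
#' measured angle; the reported error is
#' `|log2(tan(alpha_pred)) - log2(tan(alpha_act))|`.  The map is identically
#' zero (up to interpolation accuracy) exactly when the response is
#' separable into `f1(s1) + f2(s2)` before the output non-linearity on the
#' tested grid, and is invariant under any strictly monotone re-mapping of
#' the response since the output stage cancels in the tangent ratio.
#' High-error regions localize the input combinations where feedback (or
#' other cross-subunit coupling) acts.
#'
#' @param surface A [fit_surface()] result or a model / adapter.
#' @param resolution Interior grid resolution per axis.
#' @param s2_low,s1_low Baseline coordinates (default 5% into each range).
#' @param sentinel Error value reported where a tangent underflows or turns
#'   non-positive (degenerate angle).
#' @return An object of class `"independence_map"`: list with `s1`, `s2`
#'   (interior grids), `error` (matrix), `max_error`, `mean_error` and the
#'   baselines.
#' @export
independence_error_map <- function(surface, resolution = 32L,
                                   s2_low = NULL, s1_low = NULL,
                                   sentinel = 64) {
  rg <- input_ranges(surface)
  if (is.null(s1_low)) s1_low <- rg[1, 1] + 0.05 * diff(rg[1, ])
  if (is.null(s2_low)) s2_low <- rg[2, 1] + 0.05 * diff(rg[2, ])
  xs <- seq(rg[1, 1], rg[1, 2], length.out = resolution + 2L)[-c(1L, resolution + 2L)]
  ys <- seq(rg[2, 1], rg[2, 2], length.out = resolution + 2L)[-c(1L, resolution + 2L)]
  tan_B <- gradient_samples(surface, s1_low, s2_low)$tan_alpha
  tan_A <- gradient_samples(surface, rep(s1_low, length(ys)), ys)$tan_alpha
  tan_C <- gradient_samples(surface, xs, rep(s2_low, length(xs)))$tan_alpha
  err <- matrix(NA_real_, length(xs), length(ys))
  for (i in seq_along(xs)) {
    # interior gradients may legitimately vanish (capped plateau): those
    # points get the sentinel rather than aborting the whole map
    gd <- gradient_samples(surface, rep(xs[i], length(ys)), ys, floor = 0)
    tan_D <- gd$tan_alpha
    tan_pred <- tan_A * tan_C[i] / tan_B
    bad <- !is.finite(tan_D) | tan_D <= 1e-12 | tan_pred <= 1e-12 |
      sqrt(gd$d1^2 + gd$d2^2) < 1e-10
    tan_D[bad] <- 1e-12
    e <- abs(log2(pmax(tan_pred, 1e-12)) - log2(pmax(tan_D, 1e-12)))
    e[bad] <- sentinel
    err[i, ] <- e
  }
  structure(list(s1 = xs, s2 = ys, error = err,
                 max_error = max(err), mean_error = mean(err),
                 s1_low = s1_low, s2_low = s2_low, sentinel = sentinel),
            class = "independence_map")
}

#' @export
print.independence_map <- function(x, ...) {
  cat(sprintf(paste0("Subunit-independence error map: %d x %d interior grid, ",
                     "max %.3g, mean %.3g\n"),
              length(x$s1), length(x$s2), x$max_error, x$mean_error))
  invisible(x)
}

#' @export
plot.independence_map <- function(x, ...) {
  graphics::image(x$s1, x$s2, x$error, xlab = "s1", ylab = "s2",
                  col = grDevices::hcl.colors(64, "inferno", rev = TRUE), ...)
  invisible(x)
}
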
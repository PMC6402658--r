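#' Fit a smooth response surface to gridded samples
#'
#' Builds a bicubic interpolant of a two-input response function
#' `r(s1, s2)` from samples on a rectangular grid, as a tensor product of
#' one-dimensional cubic splines: each `s2` grid row is interpolated along
#' `s1`, and the row values at a query point are interpolated along `s2`.
#' With `smoothing = 0` (the default) the interpolant passes exactly through
#' the samples; a positive `smoothing` first runs a smoothing spline
#' (`stats::smooth.spline` with `spar = smoothing`) along both grid
#' directions, for noisy measured surfaces.
#'
#' Partial derivatives of the interpolant are available analytically through
#' [predict.response_surface()], which the level-set extraction and the
#' gradient-angle independence test rely on.  The framework assumes the
#' response gradient exists and is non-zero over the whole input regime; the
#' surface is flagged degenerate when the finite-difference gradient
#' magnitude on the grid falls below `grad_floor`.
#'
#' @param samples Either a data frame with columns `s1`, `s2`, `r` covering a
#'   full rectangular grid, or a list with components `s1`, `s2` (strictly
#'   increasing axis vectors) and `r` (matrix, `length(s1)` rows).
#' @param smoothing Smoothing parameter in `[0, 1]`; 0 = exact interpolation.
#' @param cap Optional response cap (spike-threshold emulation); recorded on
#'   the surface and respected by [select_triplet()].
#' @param grad_floor Gradient-magnitude floor below which the surface is
#'   flagged degenerate.
#' @return An object of class `"response_surface"` with fields `s1`, `s2`
#'   (axes), `r` (matrix), `r_range`, `cap`, `degenerate`.
#' @examples
#' g <- expand.grid(s1 = seq(0, 1, length.out = 8), s2 = seq(0, 1, length.out = 8))
#' g$r <- g$s1 + g$s2
#' surf <- fit_surface(g)
#' predict(surf, s1 = 0.35, s2 = 0.62)
#' @export
fit_surface <- function(samples, smoothing = 0, cap = NULL, grad_floor = 1e-8) {
  gr <- as_surface_grid(samples)
  s1 <- gr$s1; s2 <- gr$s2; r <- gr$r
  if (length(s1) < 4L || length(s2) < 4L)
    stop("surface grid must have at least 4 nodes per axis", call. = FALSE)
  if (any(!is.finite(r))) stop("response matrix contains non-finite values", call. = FALSE)
  if (smoothing < 0 || smoothing > 1)
    stop("'smoothing' must be in [0, 1]", call. = FALSE)
  if (smoothing > 0) {
    for (j in seq_along(s2))
      r[, j] <- stats::predict(stats::smooth.spline(s1, r[, j], spar = smoothing), s1)$y
    for (i in seq_along(s1))
      r[i, ] <- stats::predict(stats::smooth.spline(s2, r[i, ], spar = smoothing), s2)$y
  }
  # per-s2-row splines along s1; built once, reused for every evaluation
  col_splines <- lapply(seq_along(s2), function(j)
    stats::splinefun(s1, r[, j], method = "fmm"))
  # degenerate if both finite-difference partials vanish somewhere below the
  # cap (the capped plateau is excluded: the framework's non-zero-gradient
  # assumption applies to the sub-threshold regime only)
  d1 <- apply(r, 2, function(col) diff(col) / diff(s1))
  d2 <- t(apply(r, 1, function(row) diff(row) / diff(s2)))
  g1 <- abs(d1); g2 <- abs(d2)
  n1 <- length(s1); n2 <- length(s2)
  gmag <- sqrt(g1[pmin(seq_len(n1 - 1), n1 - 1), seq_len(n2 - 1), drop = FALSE]^2 +
               g2[seq_len(n1 - 1), pmin(seq_len(n2 - 1), n2 - 1), drop = FALSE]^2)
  sub_cap <- if (is.null(cap)) TRUE else
    (r[-n1, -n2, drop = FALSE] < cap - 1e-12)
  degenerate <- any(gmag[sub_cap] < grad_floor)
  structure(list(s1 = s1, s2 = s2, r = r, col_splines = col_splines,
                 r_range = range(r), cap = cap, smoothing = smoothing,
                 degenerate = degenerate, grad_floor = grad_floor),
            class = "response_surface")
}

# normalize grid-table or list input to axes + matrix; errors are format errors
as_surface_grid <- function(samples) {
  if (inherits(samples, "response_surface"))
    return(samples[c("s1", "s2", "r")])
  if (is.list(samples) && !is.data.frame(samples) &&
      all(c("s1", "s2", "r") %in% names(samples)) && is.matrix(samples$r)) {
    s1 <- as.numeric(samples$s1); s2 <- as.numeric(samples$s2)
    if (any(diff(s1) <= 0) || any(diff(s2) <= 0))
      stop("axis grids must be strictly increasing", call. = FALSE)
    if (!all(dim(samples$r) == c(length(s1), length(s2))))
      stop("response matrix shape does not match the axes", call. = FALSE)
    return(list(s1 = s1, s2 = s2, r = samples$r))
  }
  df <- as.data.frame(samples)
  if (!all(c("s1", "s2", "r") %in% names(df)))
    stop("surface table must have columns s1, s2, r", call. = FALSE)
  s1 <- sort(unique(df$s1)); s2 <- sort(unique(df$s2))
  if (length(s1) < 2L || length(s2) < 2L)
    stop("surface grid is degenerate: need at least 2 distinct values per axis",
         call. = FALSE)
  if (nrow(df) != length(s1) * length(s2))
    stop("surface table is not a complete rectangular grid", call. = FALSE)
  r <- matrix(NA_real_, length(s1), length(s2))
  i <- match(df$s1, s1); j <- match(df$s2, s2)
  if (anyDuplicated(cbind(i, j)))
    stop("duplicated grid nodes in surface table", call. = FALSE)
  r[cbind(i, j)] <- df$r
  list(s1 = s1, s2 = s2, r = r)
}

# values (and s1-derivatives) of all row splines at scalar x
surface_column <- function(surface, x, deriv1 = 0L) {
  vapply(surface$col_splines, function(f) f(x, deriv = deriv1), 0)
}

# evaluator in s2 at fixed s1 = x, as a splinefun over the s2 axis
surface_column_fun <- function(surface, x, deriv1 = 0L) {
  stats::splinefun(surface$s2, surface_column(surface, x, deriv1), method = "fmm")
}

#' Evaluate a response surface and its partial derivatives
#'
#' @param object A [fit_surface()] result.
#' @param newdata Data frame with columns `s1`, `s2` of query points, or pass
#'   `s1`, `s2` directly (recycled pairwise).
#' @param s1,s2 Query coordinates.
#' @param deriv Length-2 integer vector of partial-derivative orders
#'   `c(d_s1, d_s2)`; `c(0, 0)` for values, `c(1, 0)` / `c(0, 1)` for the
#'   gradient components.
#' @param ... Unused.
#' @return Numeric vector of interpolated values or derivatives.
#' @export
predict.response_surface <- function(object, newdata = NULL, s1 = NULL, s2 = NULL,
                                     deriv = c(0L, 0L), ...) {
  if (!is.null(newdata)) { s1 <- newdata$s1; s2 <- newdata$s2 }
  n <- max(length(s1), length(s2))
  s1 <- rep_len(as.numeric(s1), n); s2 <- rep_len(as.numeric(s2), n)
  rg1 <- range(object$s1); rg2 <- range(object$s2)
  if (any(s1 < rg1[1] - 1e-9) || any(s1 > rg1[2] + 1e-9) ||
      any(s2 < rg2[1] - 1e-9) || any(s2 > rg2[2] + 1e-9))
    stop("query point outside the surface grid", call. = FALSE)
  out <- numeric(n)
  for (x in unique(s1)) {
    sel <- which(s1 == x)
    cf <- surface_column_fun(object, x, deriv1 = deriv[1])
    out[sel] <- cf(s2[sel], deriv = deriv[2])
  }
  out
}

#' Gradient of the response surface
#'
#' Convenience wrapper returning both partial derivatives of the interpolant.
#'
#' @param surface A [fit_surface()] result.
#' @param s1,s2 Query coordinates (recycled pairwise).
#' @return Data frame with columns `s1`, `s2`, `d1` (= dr/ds1), `d2`
#'   (= dr/ds2).
#' @export
surface_gradient <- function(surface, s1, s2) {
  data.frame(s1 = s1, s2 = s2,
             d1 = predict(surface, s1 = s1, s2 = s2, deriv = c(1L, 0L)),
             d2 = predict(surface, s1 = s1, s2 = s2, deriv = c(0L, 1L)))
}

#' @export
print.response_surface <- function(x, ...) {
  cat(sprintf("Response surface: %d x %d grid, s1 in [%g, %g], s2 in [%g, %g]\n",
              length(x$s1), length(x$s2), min(x$s1), max(x$s1),
              min(x$s2), max(x$s2)))
  cat(sprintf("  response range [%g, %g]%s%s\n", x$r_range[1], x$r_range[2],
              if (!is.null(x$cap)) sprintf(", cap %g", x$cap) else "",
              if (x$degenerate) ", DEGENERATE gradient" else ""))
  invisible(x)
}

#' @export
plot.response_surface <- function(x, levels = NULL, ...) {
  graphics::image(x$s1, x$s2, x$r, xlab = "s1", ylab = "s2",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  graphics::contour(x$s1, x$s2, x$r, add = TRUE,
                    levels = levels %||% pretty(x$r_range, 8))
  invisible(x)
}
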
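#' Fit a point-neuron baseline to two training curves
#'
#' Fits the classical point-neuron abstraction `r = f3(w1*s1 + w2*s2)` to the
#' two training iso-response curves: since the weighted input sum
#' `u = w1*s1 + w2*s2` must be constant on each curve, the non-negative
#' weights (and the free level `u_L`) are chosen by least squares so that `u`
#' deviates minimally from `u_L` on `L` and from `u_H = u_L + 1` on `H` —
#' minimizing the squared error between predicted and observed responses on
#' the training curves up to the output stage, in the same drive gauge as the
#' two-layer reconstruction (`u_H - u_L = 1`).  Weights are only determined
#' up to a joint rescaling absorbed into `f3`; the gauge fixes that scale.
#'
#' When a test curve is supplied, the report includes the normalized drive
#' variance [error_sigma_m2()] of the point-neuron prediction on it.
#'
#' @param L,H Training [iso_curve()]s.
#' @param T_curve Optional test [iso_curve()] for the error report.
#' @param nonneg If `TRUE` (default) constrain the weights to be
#'   non-negative via non-negative least squares.
#' @return An object of class `"point_neuron_fit"`: weights `w1`, `w2`,
#'   drive levels `u_L`, `u_H`, training residual, and (if `T_curve` given)
#'   `sigma_m2` on the test curve.
#' @examples
#' s1 <- seq(0, 1, length.out = 21)
#' L <- iso_curve(s1, (1 - s1) / 2, level = 1)
#' H <- iso_curve(s1, (2 - s1) / 2, level = 2)
#' coef(fit_point_neuron(L, H))
#' @export
fit_point_neuron <- function(L, H, T_curve = NULL, nonneg = TRUE) {
  stopifnot(inherits(L, "iso_curve"), inherits(H, "iso_curve"))
  if (nrow(L$points) < 2L || nrow(H$points) < 2L)
    stop("degenerate training curve: need at least 2 points each", call. = FALSE)
  A <- rbind(cbind(L$points, -1, 1), cbind(H$points, -1, 1))
  b <- c(rep(0, nrow(L$points)), rep(1, nrow(H$points)))
  if (nonneg) {
    sol <- pracma::lsqnonneg(A, b)$x
  } else {
    sol <- qr.coef(qr(A), b)
  }
  w1 <- sol[1]; w2 <- sol[2]; u_L <- sol[3] - sol[4]
  resid <- sqrt(mean((A %*% sol - b)^2))
  sigma_m2 <- NULL
  if (!is.null(T_curve)) {
    u_T <- w1 * T_curve$points[, 1] + w2 * T_curve$points[, 2]
    sigma_m2 <- error_sigma_m2(u_T, m_L = u_L, m_H = u_L + 1)
  }
  structure(list(w1 = unname(w1), w2 = unname(w2),
                 u_L = unname(u_L), u_H = unname(u_L) + 1,
                 residual = resid, sigma_m2 = sigma_m2),
            class = "point_neuron_fit")
}

#' @export
print.point_neuron_fit <- function(x, ...) {
  cat(sprintf("Point-neuron fit: w1 = %.6g, w2 = %.6g (gauge u_H - u_L = 1)\n",
              x$w1, x$w2))
  cat(sprintf("  training residual %.3g", x$residual))
  if (!is.null(x$sigma_m2))
    cat(sprintf("; test-curve drive variance %.3g", x$sigma_m2))
  cat("\n")
  invisible(x)
}

#' @export
coef.point_neuron_fit <- function(object, ...) {
  c(w1 = object$w1, w2 = object$w2)
}
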
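#' Normalized error measures on the test iso-response curve
#'
#' Three dimensionless error measures quantify how well an identified model
#' explains the held-out test curve `T`:
#' \describe{
#'   \item{`error_sigma_r2()`}{variance of the predicted responses over the
#'     `K` observed test-curve points, normalized by the squared response gap
#'     of the training curves:
#'     `(1/K) * sum((r_bar - r_k)^2) / (r_H - r_L)^2`.  Requires a
#'     reconstructed output non-linearity; used for feedforward models.}
#'   \item{`error_sigma_m2()`}{the same variance measure applied to the
#'     summed subunit drive `m = f1_hat(s1) + f2_hat(s2)` on the test points,
#'     normalized by `(m_H - m_L)^2`.  This is the measure used for feedback
#'     models, where the output non-linearity is not identifiable.}
#'   \item{`error_mse_r()`}{mean squared deviation of the predicted responses
#'     from the observed test-curve response `r_T`, normalized by
#'     `(r_H - r_L)^2`; unlike the variance measures it penalizes a constant
#'     prediction bias.  The affine reconstruction gauge is the only free
#'     parameter of the prediction and is fixed upstream when `f3` is
#'     reconstructed.}
#' }
#' A model is conventionally judged adequate when the relevant error is below
#' the 4% decision threshold (see [two_layer_threshold()]).
#'
#' @param r_pred Predicted responses at the observed test-curve points.
#' @param r_L,r_H Response levels of the training curves (`r_H != r_L`).
#' @param m_pred Predicted drive values at the observed test-curve points.
#' @param m_L,m_H Drive levels of the training curves (`m_H != m_L`).
#' @param r_T Observed response level of the test curve.
#' @return A non-negative dimensionless fraction.
#' @examples
#' error_sigma_r2(c(0.9, 1.0, 1.1), r_L = 0, r_H = 1)  # 0.02/3
#' @export
error_sigma_r2 <- function(r_pred, r_L, r_H) {
  if (r_H == r_L) stop("r_H equals r_L: normalization undefined", call. = FALSE)
  r_pred <- as.numeric(r_pred)
  mean((mean(r_pred) - r_pred)^2) / (r_H - r_L)^2
}

#' @rdname error_sigma_r2
#' @export
error_sigma_m2 <- function(m_pred, m_L, m_H) {
  if (m_H == m_L) stop("m_H equals m_L: normalization undefined", call. = FALSE)
  m_pred <- as.numeric(m_pred)
  mean((mean(m_pred) - m_pred)^2) / (m_H - m_L)^2
}

#' @rdname error_sigma_r2
#' @export
error_mse_r <- function(r_pred, r_T, r_L, r_H) {
  if (r_H == r_L) stop("r_H equals r_L: normalization undefined", call. = FALSE)
  r_pred <- as.numeric(r_pred)
  mean((r_T - r_pred)^2) / (r_H - r_L)^2
}

#' Decision threshold for two-layer adequacy
#'
#' The conventional classification "two-layer model adequate" uses a
#' normalized test error below 4%.  Exposed as a function so pipelines can
#' share one configurable constant.
#'
#' @param value New threshold; omit to query the default.
#' @return The threshold as a fraction (default 0.04).
#' @export
two_layer_threshold <- function(value = 0.04) value

#' Best affine alignment of a reconstructed function to a reference
#'
#' Subunit non-linearities are identifiable only up to an affine map
#' (absorbed into the output stage), so reconstructions are compared to
#' ground truth after fitting the best `a * f_hat + b` in the least-squares
#' sense.  Returns the maximum absolute deviation after alignment, the
#' standard accuracy measure of the synthetic benchmarks.
#'
#' @param f_hat A [subunit_fn()] (reconstruction).
#' @param f_true A [subunit_fn()] or plain function (ground truth).
#' @param xs Evaluation points; default 201 points over the overlap of the
#'   two domains.
#' @param normalize If `TRUE` (default) the deviation is expressed relative
#'   to the range of the true values over `xs`, making it comparable across
#'   gauge scales.
#' @return List with `max_abs_error`, the fitted coefficients `a`, `b`, and
#'   the evaluation grid.
#' @export
affine_alignment_error <- function(f_hat, f_true, xs = NULL, normalize = TRUE) {
  stopifnot(inherits(f_hat, "subunit_fn"))
  if (inherits(f_true, "subunit_fn")) {
    dom <- c(max(f_hat$domain[1], f_true$domain[1]),
             min(f_hat$domain[2], f_true$domain[2]))
    tf <- function(x) eval_subunit(f_true, x)
  } else {
    dom <- f_hat$domain
    tf <- f_true
  }
  if (is.null(xs)) xs <- seq(dom[1], dom[2], length.out = 201L)
  yh <- eval_subunit(f_hat, xs)
  yt <- tf(xs)
  fit <- stats::lm.fit(cbind(1, yh), yt)
  b <- fit$coefficients[1]; a <- fit$coefficients[2]
  err <- max(abs(a * yh + b - yt))
  if (normalize) err <- err / diff(range(yt))
  list(max_abs_error = unname(err), a = unname(a), b = unname(b), xs = xs)
}
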
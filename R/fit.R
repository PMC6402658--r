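#' Identify a two-layer subunit model from iso-response curves
#'
#' The main fitting entry point of the package.  Starting from a response
#' surface (or directly from measured curves), it
#' \enumerate{
#'   \item selects a curve triplet — two training curves `L`, `H` and a test
#'     curve `T` just below the usable response top ([select_triplet()]);
#'   \item fits the point-neuron baseline ([fit_point_neuron()]);
#'   \item reconstructs the subunit non-linearities `f1_hat`, `f2_hat` from
#'     `L` and `H`, by monotone basis expansion (default) or by the stairway
#'     construction ([reconstruct_basis()], [reconstruct_stairway()]);
#'   \item predicts the test curve and computes the normalized test errors
#'     (drive variance `sigma_m2`; and, when a surface is available so the
#'     output non-linearity can be reconstructed along the diagonal, the
#'     response variance `sigma_r2` and the optimized normalized MSE);
#'   \item classifies the fit against the 4% decision threshold and, when
#'     requested (or when the feedforward fit is inadequate with
#'     `feedback = "auto"`), searches for additive and/or multiplicative
#'     output feedback ([identify_feedback()]).
#' }
#'
#' @param x A `"response_surface"`, a `"curve_triplet"`, a grid table
#'   (data frame with `s1`, `s2`, `r`), or a model object
#'   (`"two_layer_model"`, `"point_neuron_model"`, `"response_adapter"`)
#'   which is then sampled on `grid` first.
#' @param fractions Level fractions for the triplet, see [select_triplet()].
#' @param method Reconstruction method, `"basis"` (default) or `"stairway"`.
#' @param knots Knots per subunit for the basis method.
#' @param n_points Samples per extracted curve.
#' @param stairway_n Stairway size for the stairway method.
#' @param feedback `"none"` (default), `"auto"` (search only if the
#'   feedforward fit fails the threshold), or a mode passed to
#'   [identify_feedback()]: `"additive"`, `"multiplicative"`, `"both"`.
#' @param fb_grid Optional [feedback_grid()] search configuration.
#' @param threshold Decision threshold on the normalized test error.
#' @param grid Sampling grid size when `x` is a model object.
#' @param smoothing Surface smoothing parameter, see [fit_surface()].
#' @return An object of class `"two_layer_fit"`; see
#'   [print.two_layer_fit()], [coef.two_layer_fit()],
#'   [predict.two_layer_fit()], [residuals.two_layer_fit()],
#'   [plot.two_layer_fit()].
#' @examples
#' m <- two_layer_model(subunit_fn("power", exponent = 2), subunit_fn("linear"))
#' fit <- fit_two_layer(m, grid = c(32, 32))
#' fit
#' @export
fit_two_layer <- function(x, fractions = c(0.3, 0.6, 0.95),
                          method = c("basis", "stairway"),
                          knots = 21L, n_points = 101L, stairway_n = 11L,
                          feedback = c("none", "auto", "additive",
                                       "multiplicative", "both"),
                          fb_grid = NULL,
                          threshold = two_layer_threshold(),
                          grid = c(64L, 64L), smoothing = 0) {
  method <- match.arg(method)
  feedback <- match.arg(feedback)
  cl <- match.call()

  surface <- NULL
  if (inherits(x, "curve_triplet")) {
    triplet <- x
  } else {
    if (inherits(x, c("two_layer_model", "point_neuron_model",
                      "response_adapter"))) {
      samples <- sample_surface(x, grid = grid)
      surface <- fit_surface(samples, smoothing = smoothing, cap = x$cap)
    } else if (inherits(x, "response_surface")) {
      surface <- x
    } else {
      surface <- fit_surface(x, smoothing = smoothing)
    }
    triplet <- select_triplet(surface, fractions = fractions,
                              n_points = n_points)
  }
  L <- triplet$L; H <- triplet$H; T_curve <- triplet$T

  point_fit <- fit_point_neuron(L, H, T_curve = T_curve)

  rec <- if (method == "basis") {
    reconstruct_basis(L, H, knots = knots)
  } else {
    reconstruct_stairway(L, H, build_stairway(L, H, n = stairway_n))
  }

  # test-curve points inside the covered rectangle (no extrapolation)
  tp <- T_curve$points
  in_cov <- tp[, 1] >= rec$f1_hat$domain[1] - 1e-12 &
            tp[, 1] <= rec$f1_hat$domain[2] + 1e-12 &
            tp[, 2] >= rec$f2_hat$domain[1] - 1e-12 &
            tp[, 2] <= rec$f2_hat$domain[2] + 1e-12
  tp <- tp[in_cov, , drop = FALSE]
  if (nrow(tp) < 3L)
    stop("test curve barely overlaps the training coverage", call. = FALSE)
  m_T <- drive(rec, tp[, 1], tp[, 2])
  sigma_m2 <- error_sigma_m2(m_T, m_L = rec$m_L, m_H = rec$m_H)

  anchor <- tp[which.min(abs(m_T - stats::median(m_T))), ]
  predicted_T <- tryCatch(predict_test_curve(rec, anchor, n_points = n_points),
                          error = function(e) NULL)

  f3_hat <- NULL; sigma_r2 <- NULL; mse_r <- NULL
  if (!is.null(surface)) {
    dg <- seq(max(min(surface$s1), min(surface$s2)),
              min(max(surface$s1), max(surface$s2)), length.out = n_points)
    diag_tab <- data.frame(s = dg, r = predict(surface, s1 = dg, s2 = dg))
    f3_hat <- tryCatch(reconstruct_f3(rec, diag_tab), error = function(e) NULL)
    if (!is.null(f3_hat)) {
      m_cl <- pmin(pmax(m_T, f3_hat$domain[1]), f3_hat$domain[2])
      r_pred <- eval_subunit(f3_hat, m_cl)
      sigma_r2 <- error_sigma_r2(r_pred, r_L = triplet$levels["L"],
                                 r_H = triplet$levels["H"])
      mse_r <- error_mse_r(r_pred, r_T = triplet$levels["T"],
                           r_L = triplet$levels["L"],
                           r_H = triplet$levels["H"])
    }
  }

  fb_fit <- NULL
  want_fb <- feedback %in% c("additive", "multiplicative", "both") ||
    (feedback == "auto" && sigma_m2 >= threshold)
  if (want_fb) {
    mode <- if (feedback %in% c("none", "auto")) "additive" else feedback
    fb_fit <- identify_feedback(triplet, mode = mode, grid = fb_grid,
                                knots = knots)
  }

  decision <- if (sigma_m2 < threshold) {
    "feedforward two-layer adequate"
  } else if (!is.null(fb_fit) && fb_fit$sigma_m2 < threshold) {
    switch(fb_fit$mode,
           additive = "additive feedback required",
           multiplicative = "multiplicative feedback required",
           both = "additive and multiplicative feedback required")
  } else {
    "two-layer model inadequate"
  }

  structure(list(call = cl, surface = surface, triplet = triplet,
                 point_fit = point_fit, reconstruction = rec,
                 m_T = m_T, K = length(m_T),
                 sigma_m2 = sigma_m2, sigma_r2 = sigma_r2, mse_r = mse_r,
                 f3_hat = f3_hat, predicted_T = predicted_T,
                 feedback = fb_fit,
                 threshold = threshold, decision = decision),
            class = "two_layer_fit")
}

#' @describeIn fit_two_layer Compact display of the fitted object.
#' @param ... Unused.
#' @export
print.two_layer_fit <- function(x, ...) {
  cat("Two-layer model identification from iso-response curves\n")
  cat(sprintf("  training levels: r_L = %.6g, r_H = %.6g; test level r_T = %.6g\n",
              x$triplet$levels["L"], x$triplet$levels["H"],
              x$triplet$levels["T"]))
  cat(sprintf("  reconstruction: %s method, %d test points in coverage\n",
              x$reconstruction$method, x$K))
  cat(sprintf("  test errors: sigma_m2 = %.4g", x$sigma_m2))
  if (!is.null(x$sigma_r2)) cat(sprintf(", sigma_r2 = %.4g", x$sigma_r2))
  if (!is.null(x$mse_r)) cat(sprintf(", MSE = %.4g", x$mse_r))
  cat("\n")
  if (!is.null(x$point_fit$sigma_m2))
    cat(sprintf("  point-neuron baseline: sigma_m2 = %.4g\n",
                x$point_fit$sigma_m2))
  if (!is.null(x$feedback))
    cat(sprintf("  feedback search (%s): best sigma_m2 = %.4g\n",
                x$feedback$mode, x$feedback$sigma_m2))
  cat(sprintf("  decision (threshold %.3g): %s\n", x$threshold, x$decision))
  invisible(x)
}

#' @export
summary.two_layer_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.two_layer_fit")
}

#' @export
print.summary.two_layer_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nGauge: ", f$reconstruction$gauge$anchor, "; ",
      f$reconstruction$gauge$scale, "\n", sep = "")
  cat("Point-neuron weights: w1 =", format(f$point_fit$w1, digits = 6),
      ", w2 =", format(f$point_fit$w2, digits = 6), "\n")
  if (!is.null(f$feedback)) {
    cat("\nFeedback deltas (H, then T, relative to L):\n")
    print(f$feedback$deltas_H); print(f$feedback$deltas_T)
  }
  invisible(x)
}

#' @describeIn fit_two_layer Reconstructed subunit-function samples: a data
#'   frame with columns `subunit` (`"f1"`/`"f2"`), `s` (knot/node position)
#'   and `value` (gauge units).
#' @param object A `"two_layer_fit"`.
#' @export
coef.two_layer_fit <- function(object, ...) {
  rec <- object$reconstruction
  tab <- function(f, nm) data.frame(subunit = nm, s = f$params$s,
                                    value = f$params$f)
  rbind(tab(rec$f1_hat, "f1"), tab(rec$f2_hat, "f2"))
}

#' @describeIn fit_two_layer Predict the summed subunit drive `m` (gauge
#'   units) or, when the output stage was reconstructed, the response at new
#'   stimulus pairs inside the covered rectangle.
#' @param newdata Data frame with columns `s1`, `s2`.
#' @param type `"drive"` for `m` (default), `"response"` for `f3_hat(m)`.
#' @export
predict.two_layer_fit <- function(object, newdata,
                                  type = c("drive", "response"), ...) {
  type <- match.arg(type)
  m <- drive(object$reconstruction, newdata$s1, newdata$s2)
  if (type == "drive") return(m)
  if (is.null(object$f3_hat))
    stop("output non-linearity was not reconstructed; no response prediction",
         call. = FALSE)
  eval_subunit(object$f3_hat,
               pmin(pmax(m, object$f3_hat$domain[1]), object$f3_hat$domain[2]))
}

#' @describeIn fit_two_layer Centered drive deviations on the test curve —
#'   the residuals whose normalized variance is `sigma_m2`.
#' @export
residuals.two_layer_fit <- function(object, ...) {
  object$m_T - mean(object$m_T)
}

#' @describeIn fit_two_layer Two-panel diagnostic plot: the curve triplet
#'   with the predicted test curve, and the reconstructed subunit functions.
#' @export
plot.two_layer_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  plot(x$triplet, main = "iso-response curves")
  if (!is.null(x$predicted_T))
    graphics::lines(x$predicted_T$points, col = "red", lty = 3, lwd = 2)
  cf <- coef(x)
  graphics::plot(NA, xlim = range(cf$s), ylim = range(cf$value),
                 xlab = "s (normalized)", ylab = "f (gauge units)",
                 main = "reconstructed subunits")
  for (nm in c("f1", "f2")) {
    sel <- cf$subunit == nm
    graphics::lines(cf$s[sel], cf$value[sel],
                    col = if (nm == "f1") "darkred" else "navy")
  }
  graphics::legend("topleft", legend = c("f1", "f2"),
                   col = c("darkred", "navy"), lty = 1, bty = "n")
  invisible(x)
}
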
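#' Feedback deltas between response levels
#'
#' Only differences of additive feedback and ratios of multiplicative
#' feedback between two response levels are identifiable from iso-response
#' curves, because any constant part can be absorbed into the subunit
#' functions.  A `feedback_deltas` object stores, for one non-reference
#' curve, the additive differences (stimulus units) and multiplicative
#' ratios (dimensionless, positive) of both subunits relative to the
#' reference curve `L`, whose deltas are the identity `(0, 0, 1, 1)`.
#'
#' @param add1,add2 Additive deltas for subunit 1 and 2.
#' @param mult1,mult2 Multiplicative deltas (must be positive).
#' @return An object of class `"feedback_deltas"`.
#' @export
feedback_deltas <- function(add1 = 0, add2 = 0, mult1 = 1, mult2 = 1) {
  if (mult1 <= 0 || mult2 <= 0)
    stop("multiplicative deltas must be positive", call. = FALSE)
  structure(list(add1 = add1, add2 = add2, mult1 = mult1, mult2 = mult2),
            class = "feedback_deltas")
}

#' @export
print.feedback_deltas <- function(x, ...) {
  cat(sprintf("Feedback deltas: add = (%.4g, %.4g), mult = (%.4g, %.4g)\n",
              x$add1, x$add2, x$mult1, x$mult2))
  invisible(x)
}

is_identity_deltas <- function(d, tol = 1e-12) {
  abs(d$add1) <= tol && abs(d$add2) <= tol &&
    abs(d$mult1 - 1) <= tol && abs(d$mult2 - 1) <= tol
}

# pointwise affine image of curve points under the deltas:
# (s1, s2) -> (mult1*s1 + add1, mult2*s2 + add2)
transform_points <- function(points, deltas) {
  cbind(s1 = deltas$mult1 * points[, 1] + deltas$add1,
        s2 = deltas$mult2 * points[, 2] + deltas$add2)
}

#' Transform a feedback-model curve into a feedback-free curve
#'
#' An iso-response curve of a two-layer model with feedback differs from the
#' corresponding curve of the hypothetical feedback-free model with the same
#' subunit non-linearities by a per-axis affine map: since feedback is
#' constant along the curve, each point maps as
#' `(s1, s2) -> (dm1*s1 + da1, dm2*s2 + da2)`, i.e. the feedback-free curve
#' is `H(x) = dm2 * H_fb((x - da1)/dm1) + da2`.  Identity deltas return the
#' input curve unchanged.
#'
#' @param curve An [iso_curve()] measured on the feedback model.
#' @param deltas A [feedback_deltas()] object.
#' @param domain Optional rectangle (2x2 matrix, rows = inputs); if supplied,
#'   transformed points leaving it are an error.
#' @return A new [iso_curve()] (re-validated: strictly decreasing,
#'   invertible), carrying the same response level.
#' @export
transform_curve <- function(curve, deltas, domain = NULL) {
  stopifnot(inherits(curve, "iso_curve"), inherits(deltas, "feedback_deltas"))
  pts <- transform_points(curve$points, deltas)
  if (!is.null(domain)) {
    domain <- matrix(as.numeric(domain), 2, 2)
    if (any(pts[, 1] < domain[1, 1] - 1e-9) || any(pts[, 1] > domain[1, 2] + 1e-9) ||
        any(pts[, 2] < domain[2, 1] - 1e-9) || any(pts[, 2] > domain[2, 2] + 1e-9))
      stop("transformed curve exits the declared domain rectangle", call. = FALSE)
  }
  if (any(diff(pts[, 1]) <= 0) || any(diff(pts[, 2]) >= 0))
    stop("transformed curve lost monotonicity", call. = FALSE)
  iso_curve(pts[, 1], pts[, 2], level = curve$level)
}

#' Search-grid configuration for feedback identification
#'
#' Declares the brute-force grids over feedback deltas.  The defaults cover
#' additive strengths up to 20% of the normalized input range in steps of
#' 1%, and multiplicative ratios 0.8-1.25 in steps of 0.01 — comfortably
#' spanning the strengths reported for tuft dendrites (additive feedback up
#' to about 10% of the input range; multiplicative ratios concentrated near
#' 1 with a secondary mode near 1.1).
#'
#' @param additive Numeric vector of candidate additive deltas.
#' @param multiplicative Numeric vector of candidate multiplicative deltas.
#' @param positive_only Restrict additive deltas to non-negative values.
#' @param tie_subunits If `TRUE` (default), one delta per curve is applied
#'   to both subunits, giving the two-dimensional strength-on-H versus
#'   strength-on-T error surface; `FALSE` searches per-subunit deltas (four
#'   parameters), which is slower and can trade off degenerately.
#' @param coarse Integer subsampling factor for the coarse search pass
#'   (every `coarse`-th grid value); the final errors always come from an
#'   exhaustive fine grid at the declared step around the coarse optimum.
#' @return An object of class `"feedback_grid"`.
#' @export
feedback_grid <- function(additive = seq(-0.2, 0.2, by = 0.01),
                          multiplicative = seq(0.8, 1.25, by = 0.01),
                          positive_only = FALSE,
                          tie_subunits = TRUE,
                          coarse = 5L) {
  additive <- round(as.numeric(additive), 10)
  multiplicative <- round(as.numeric(multiplicative), 10)
  if (positive_only) additive <- additive[additive >= 0]
  if (length(additive) == 0L || length(multiplicative) == 0L)
    stop("empty feedback search grid", call. = FALSE)
  if (any(multiplicative <= 0))
    stop("multiplicative grid values must be positive", call. = FALSE)
  structure(list(additive = additive, multiplicative = multiplicative,
                 positive_only = positive_only,
                 tie_subunits = isTRUE(tie_subunits),
                 coarse = as.integer(coarse)),
            class = "feedback_grid")
}

# subsample a grid for the coarse pass, always keeping the identity value
coarse_values <- function(values, coarse, identity) {
  idx <- unique(c(seq(1L, length(values), by = max(1L, coarse)), length(values)))
  v <- values[idx]
  id_near <- values[which.min(abs(values - identity))]
  sort(unique(c(v, id_near)))
}

# fine window: all declared grid values within one coarse step of the center
fine_values <- function(values, center, coarse) {
  step <- if (length(values) > 1L) min(diff(values)) else 0
  halfw <- step * max(1L, coarse)
  values[values >= center - halfw - 1e-12 & values <= center + halfw + 1e-12]
}

#' Identify additive and multiplicative feedback from a curve triplet
#'
#' Brute-force identification of output feedback: candidate feedback deltas
#' for the curves `H` and `T` (relative to the reference curve `L`) are
#' enumerated on declared grids; for each `H`-combination the curve is
#' transformed to its hypothetical feedback-free counterpart
#' ([transform_curve()]) and the subunit non-linearities are reconstructed
#' from `L` and the transformed `H`; for each `T`-combination the
#' transformed test curve is scored by the normalized drive variance
#' ([error_sigma_m2()]).  Combinations whose transformed test curve is
#' shorter than half of either training curve (within the covered input
#' region) are discarded as infeasible.  `H`- and `T`-deltas are optimized
#' jointly; a coarse pass on a subsampled grid localizes the optimum, the
#' reported result comes from the exhaustive fine grid at the declared step
#' around it.
#'
#' Modes: `"additive"` varies the additive deltas of both subunits (ratios
#' fixed at 1); `"multiplicative"` varies the ratios (additive fixed at 0);
#' `"both"` alternates the two searches and keeps the additive-only solution
#' unless the multiplicative extension improves the error by more than
#' `tol_improve` (purely additive feedback is preferred on ties).
#'
#' @param triplet A [select_triplet()] result (curves measured on the
#'   possibly-feedback system).
#' @param mode `"additive"`, `"multiplicative"` or `"both"`.
#' @param grid A [feedback_grid()]; defaults per mode.
#' @param knots Knots for the basis reconstruction.
#' @param tol_improve Relative improvement required before the
#'   multiplicative extension is kept in mode `"both"`.
#' @return An object of class `"feedback_fit"`: best `deltas_H`,
#'   `deltas_T`, the achieved `sigma_m2`, the reconstruction at the optimum,
#'   the evaluated fine `error_grid` (data frame), and diagnostics
#'   (`n_feasible`, `n_discarded`).
#' @export
identify_feedback <- function(triplet, mode = c("additive", "multiplicative",
                                                "both"),
                              grid = NULL, knots = 21L, tol_improve = 0.1) {
  stopifnot(inherits(triplet, "curve_triplet"))
  mode <- match.arg(mode)
  if (is.null(grid)) grid <- feedback_grid()
  stopifnot(inherits(grid, "feedback_grid"))

  if (mode == "both") {
    fit_add <- identify_feedback(triplet, "additive", grid, knots)
    grid_m <- grid
    fit_mult <- search_feedback(triplet, "multiplicative", grid_m, knots,
                                base_H = fit_add$deltas_H,
                                base_T = fit_add$deltas_T)
    keep_mult <- fit_mult$sigma_m2 < (1 - tol_improve) * fit_add$sigma_m2
    out <- if (keep_mult) fit_mult else fit_add
    out$mode <- "both"
    out$additive_only <- fit_add[c("deltas_H", "deltas_T", "sigma_m2")]
    return(out)
  }
  search_feedback(triplet, mode, grid, knots)
}

search_feedback <- function(triplet, mode, grid, knots,
                            base_H = feedback_deltas(),
                            base_T = feedback_deltas()) {
  L <- triplet$L; H <- triplet$H; T_curve <- triplet$T
  rect <- triplet$ranges %||%
    rbind(range(L$points[, 1], H$points[, 1], T_curve$points[, 1]),
          range(L$points[, 2], H$points[, 2], T_curve$points[, 2]))
  # polyline length of the portion of a point set inside the rectangle
  rect_len <- function(pts) {
    ok <- pts[, 1] >= rect[1, 1] - 1e-12 & pts[, 1] <= rect[1, 2] + 1e-12 &
          pts[, 2] >= rect[2, 1] - 1e-12 & pts[, 2] <= rect[2, 2] + 1e-12
    pv <- pts[ok, , drop = FALSE]
    if (nrow(pv) < 2L) 0 else sum(sqrt(diff(pv[, 1])^2 + diff(pv[, 2])^2))
  }
  values <- if (mode == "additive") grid$additive else grid$multiplicative
  identity_v <- if (mode == "additive") 0 else 1

  make_deltas <- function(v1, v2, base) {
    if (mode == "additive") feedback_deltas(add1 = v1, add2 = v2,
                                            mult1 = base$mult1, mult2 = base$mult2)
    else feedback_deltas(add1 = base$add1, add2 = base$add2,
                         mult1 = v1, mult2 = v2)
  }

  eval_pass <- function(vals_H, vals_T) {
    combos_H <- if (grid$tie_subunits) data.frame(h1 = vals_H, h2 = vals_H)
                else expand.grid(h1 = vals_H, h2 = vals_H)
    combos_T <- if (grid$tie_subunits) data.frame(t1 = vals_T, t2 = vals_T)
                else expand.grid(t1 = vals_T, t2 = vals_T)
    best <- list(err = Inf)
    rows <- vector("list", nrow(combos_H))
    n_feasible <- 0L; n_discarded <- 0L
    for (i in seq_len(nrow(combos_H))) {
      dH <- make_deltas(combos_H$h1[i], combos_H$h2[i], base_H)
      Ht <- tryCatch(transform_curve(H, dH), error = function(e) NULL)
      rec <- if (!is.null(Ht))
        tryCatch(reconstruct_basis(L, Ht, knots = knots),
                 error = function(e) NULL)
      errs <- rep(NA_real_, nrow(combos_T))
      if (!is.null(rec)) {
        # the usable (in-coverage) part of the transformed test curve must be
        # at least half as long as the shorter training curve, measured
        # inside the sampled input rectangle; shorter slivers score an
        # artificially small variance and are discarded as infeasible
        min_len <- 0.5 * min(rect_len(L$points), rect_len(Ht$points))
        for (j in seq_len(nrow(combos_T))) {
          dT <- make_deltas(combos_T$t1[j], combos_T$t2[j], base_T)
          pts <- transform_points(T_curve$points, dT)
          in_cov <- pts[, 1] >= rec$f1_hat$domain[1] - 1e-12 &
                    pts[, 1] <= rec$f1_hat$domain[2] + 1e-12 &
                    pts[, 2] >= rec$f2_hat$domain[1] - 1e-12 &
                    pts[, 2] <= rec$f2_hat$domain[2] + 1e-12
          pv <- pts[in_cov, , drop = FALSE]
          if (nrow(pv) < 3L || rect_len(pv) < min_len) {
            n_discarded <- n_discarded + 1L; next
          }
          m <- drive(rec, pv[, 1], pv[, 2])
          err <- error_sigma_m2(m, m_L = rec$m_L, m_H = rec$m_H)
          errs[j] <- err
          n_feasible <- n_feasible + 1L
          if (err < best$err) {
            best <- list(err = err, dH = dH, dT = dT, rec = rec,
                         K = nrow(pv))
          }
        }
      }
      rows[[i]] <- cbind(combos_H[i, , drop = FALSE][rep(1, nrow(combos_T)), ],
                         combos_T, sigma_m2 = errs)
    }
    list(best = best, grid = do.call(rbind, rows),
         n_feasible = n_feasible, n_discarded = n_discarded)
  }

  if (grid$tie_subunits) {
    # one delta per curve: the full grid is small enough to enumerate
    # exhaustively, which is robust to narrow optima and side valleys
    pass <- eval_pass(values, values)
    if (!is.finite(pass$best$err))
      stop("no feasible feedback combination on the search grid", call. = FALSE)
    return(structure(list(mode = mode,
                          deltas_H = pass$best$dH, deltas_T = pass$best$dT,
                          sigma_m2 = pass$best$err, K = pass$best$K,
                          reconstruction = pass$best$rec,
                          error_grid = pass$grid, grid = grid,
                          n_feasible = pass$n_feasible,
                          n_discarded = pass$n_discarded),
                     class = "feedback_fit"))
  }

  coarse_v <- coarse_values(values, grid$coarse, identity_v)
  pass1 <- eval_pass(coarse_v, coarse_v)
  if (!is.finite(pass1$best$err))
    stop("no feasible feedback combination on the search grid", call. = FALSE)
  b <- pass1$best
  centers <- if (mode == "additive")
    c(b$dH$add1, b$dH$add2, b$dT$add1, b$dT$add2)
  else
    c(b$dH$mult1, b$dH$mult2, b$dT$mult1, b$dT$mult2)
  fine_H1 <- fine_values(values, centers[1], grid$coarse)
  fine_H2 <- fine_values(values, centers[2], grid$coarse)
  fine_T1 <- fine_values(values, centers[3], grid$coarse)
  fine_T2 <- fine_values(values, centers[4], grid$coarse)
  # joint fine pass (exhaustive at the declared step within the window)
  pass2 <- eval_pass(sort(unique(c(fine_H1, fine_H2))),
                     sort(unique(c(fine_T1, fine_T2))))
  best <- if (pass2$best$err <= pass1$best$err) pass2$best else pass1$best
  used_grid <- if (pass2$best$err <= pass1$best$err) pass2$grid else pass1$grid

  structure(list(mode = mode,
                 deltas_H = best$dH, deltas_T = best$dT,
                 sigma_m2 = best$err, K = best$K,
                 reconstruction = best$rec,
                 error_grid = used_grid,
                 grid = grid,
                 n_feasible = pass1$n_feasible + pass2$n_feasible,
                 n_discarded = pass1$n_discarded + pass2$n_discarded),
            class = "feedback_fit")
}

#' @export
print.feedback_fit <- function(x, ...) {
  cat(sprintf("Feedback identification (%s mode): best sigma_m2 = %.4g\n",
              x$mode, x$sigma_m2))
  cat("  H vs L: "); print(x$deltas_H)
  cat("  T vs L: "); print(x$deltas_T)
  cat(sprintf("  %d feasible / %d discarded grid combinations\n",
              x$n_feasible, x$n_discarded))
  invisible(x)
}

#' Summarize identified feedback strengths
#'
#' Expresses additive feedback deltas as a percentage of the normalized
#' input range and multiplicative deltas as ratios, the units in which
#' feedback strengths are conventionally reported; optionally adds the
#' average separation of the training curves (as % of the stimulus range)
#' for comparison, since a shift is only meaningful relative to how far
#' apart the training curves sit.
#'
#' @param deltas A [feedback_deltas()] object (or `"feedback_fit"`; then
#'   both the `H` and `T` deltas are summarized).
#' @param input_range Length-2 normalized input interval (default `c(0, 1)`).
#' @param triplet Optional [select_triplet()] result used to report the mean
#'   training-curve separation.
#' @return A data frame with one row per delta and columns `curve`,
#'   `subunit`, `kind`, `value`, `unit`.
#' @export
summarize_feedback <- function(deltas, input_range = c(0, 1), triplet = NULL) {
  span <- diff(as.numeric(input_range))
  if (span <= 0) stop("'input_range' must be increasing", call. = FALSE)
  one <- function(d, curve) {
    data.frame(curve = curve,
               subunit = c(1L, 2L, 1L, 2L),
               kind = c("additive", "additive",
                        "multiplicative", "multiplicative"),
               value = c(100 * d$add1 / span, 100 * d$add2 / span,
                         d$mult1, d$mult2),
               unit = c("% of input range", "% of input range",
                        "ratio", "ratio"))
  }
  out <- if (inherits(deltas, "feedback_fit")) {
    rbind(one(deltas$deltas_H, "H"), one(deltas$deltas_T, "T"))
  } else {
    one(deltas, "H")
  }
  if (!is.null(triplet)) {
    sep <- mean(abs(triplet$H$points[, 2] -
                      curve_s2(triplet$L,
                               pmin(pmax(triplet$H$points[, 1],
                                         triplet$L$s1_range[1]),
                                    triplet$L$s1_range[2]))))
    attr(out, "training_separation_pct") <- 100 * sep / span
  }
  out
}
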
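#' Construct an iso-response curve from sampled points
#'
#' An iso-response curve is the set of stimulus pairs `(s1, s2)` that evoke
#' the same response `level`; for a monotone response surface it is a
#' strictly decreasing, hence invertible, function of either coordinate.  The
#' curve is stored with both parametrizations, `s2 = C(s1)` and
#' `s1 = C^-1(s2)`, as monotone (Hyman-filtered) cubic splines over the
#' sampled points, plus its Euclidean arc length in normalized input
#' coordinates.
#'
#' Use this constructor directly for curves measured externally (e.g. in a
#' closed-loop experiment); curves from a fitted surface come from
#' [extract_iso_curve()].
#'
#' @param s1,s2 Sampled curve coordinates; `s1` strictly increasing, `s2`
#'   strictly decreasing.
#' @param level The shared response value of all points (response units).
#' @return An object of class `"iso_curve"` with fields `level`, `points`
#'   (two-column matrix), `s1_range`, `s2_range`, `arclength`, and the two
#'   parametrizations.
#' @examples
#' s1 <- seq(0, 1, length.out = 21)
#' cv <- iso_curve(s1, 1 - s1, level = 1)
#' curve_s2(cv, 0.25)
#' @export
iso_curve <- function(s1, s2, level) {
  s1 <- as.numeric(s1); s2 <- as.numeric(s2)
  if (length(s1) != length(s2) || length(s1) < 3L)
    stop("an iso-response curve needs at least 3 matched points", call. = FALSE)
  o <- order(s1); s1 <- s1[o]; s2 <- s2[o]
  if (any(diff(s1) <= 0))
    stop("curve s1 coordinates must be strictly increasing", call. = FALSE)
  if (any(diff(s2) >= 0))
    stop("curve must be strictly decreasing: s2 must fall as s1 grows",
         call. = FALSE)
  fwd <- stats::splinefun(s1, s2, method = "hyman")
  inv <- stats::splinefun(rev(s2), rev(s1), method = "hyman")
  structure(list(level = as.numeric(level),
                 points = cbind(s1 = s1, s2 = s2),
                 s1_range = range(s1), s2_range = range(s2),
                 forward = fwd, inverse = inv,
                 arclength = polyline_length(fwd, range(s1))),
            class = "iso_curve")
}

# arc length of s2 = C(s1) by dense polyline refinement
polyline_length <- function(fwd, s1_range, n = 2001L) {
  x <- seq(s1_range[1], s1_range[2], length.out = n)
  y <- fwd(x)
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

#' Evaluate the two parametrizations of an iso-response curve
#'
#' `curve_s2()` returns `s2 = C(s1)`; `curve_s1()` returns the inverse
#' `s1 = C^-1(s2)`.  Queries outside the curve's valid interval are domain
#' errors.
#'
#' @param curve An [iso_curve()].
#' @param s1,s2 Query coordinates.
#' @param tol Domain tolerance.
#' @return Numeric vector of matched coordinates.
#' @export
curve_s2 <- function(curve, s1, tol = 1e-9) {
  stopifnot(inherits(curve, "iso_curve"))
  if (any(s1 < curve$s1_range[1] - tol) || any(s1 > curve$s1_range[2] + tol))
    stop("s1 outside the curve's valid interval", call. = FALSE)
  curve$forward(pmin(pmax(s1, curve$s1_range[1]), curve$s1_range[2]))
}

#' @rdname curve_s2
#' @export
curve_s1 <- function(curve, s2, tol = 1e-9) {
  stopifnot(inherits(curve, "iso_curve"))
  if (any(s2 < curve$s2_range[1] - tol) || any(s2 > curve$s2_range[2] + tol))
    stop("s2 outside the curve's valid interval", call. = FALSE)
  curve$inverse(pmin(pmax(s2, curve$s2_range[1]), curve$s2_range[2]))
}

#' @export
print.iso_curve <- function(x, ...) {
  cat(sprintf(paste0("Iso-response curve at level %.6g: %d points, ",
                     "s1 in [%.4g, %.4g], arc length %.4g\n"),
              x$level, nrow(x$points), x$s1_range[1], x$s1_range[2],
              x$arclength))
  invisible(x)
}

#' @export
plot.iso_curve <- function(x, add = FALSE, ...) {
  if (add) graphics::lines(x$points, ...)
  else graphics::plot(x$points, type = "l", xlab = "s1", ylab = "s2", ...)
  invisible(x)
}

#' Extract an iso-response curve from a fitted surface
#'
#' Finds the level set `r(s1, s2) = level` of the surface interpolant.  The
#' attainable `s1` interval is bracketed first (the level must be reachable
#' within the `s2` grid range at each sampled `s1`), then each of `n_points`
#' columns is solved by one-dimensional root finding on the interpolant.
#'
#' @param surface A [fit_surface()] result.
#' @param level Response level, strictly inside the surface's response range.
#' @param n_points Number of curve samples.
#' @param tol Maximum allowed deviation `|r(s1, s2) - level|` at the returned
#'   points.
#' @return An [iso_curve()].
#' @export
extract_iso_curve <- function(surface, level, n_points = 101L, tol = 1e-8) {
  stopifnot(inherits(surface, "response_surface"))
  rr <- surface$r_range
  if (level <= rr[1] || level >= rr[2])
    stop(sprintf("level %g outside the surface's open response range (%g, %g)",
                 level, rr[1], rr[2]), call. = FALSE)
  if (surface$degenerate)
    stop("surface is flagged degenerate: gradient falls below the floor",
         call. = FALSE)
  s1g <- surface$s1; s2g <- surface$s2
  lo2 <- min(s2g); hi2 <- max(s2g)
  top <- function(x) predict(surface, s1 = x, s2 = hi2) - level
  bot <- function(x) predict(surface, s1 = x, s2 = lo2) - level
  # attainability at column x (monotone surface): r(x, lo2) <= level <= r(x, hi2)
  a <- min(s1g); b <- max(s1g)
  if (top(b) < 0 || bot(a) > 0)
    stop("level set is empty on the sampled grid", call. = FALSE)
  s1_lo <- if (top(a) >= 0) a else stats::uniroot(top, c(a, b), tol = 1e-13)$root
  s1_hi <- if (bot(b) <= 0) b else stats::uniroot(bot, c(a, b), tol = 1e-13)$root
  if (s1_hi <= s1_lo)
    stop("level set has no extent along s1; extraction failed", call. = FALSE)
  xs <- seq(s1_lo, s1_hi, length.out = n_points)
  ys <- numeric(n_points)
  for (k in seq_len(n_points)) {
    cf <- surface_column_fun(surface, xs[k])
    g <- function(y) cf(y) - level
    glo <- g(lo2); ghi <- g(hi2)
    if (glo > tol || ghi < -tol) {
      # level exits the box at a bracket endpoint (numerical margin)
      ys[k] <- if (abs(glo) <= abs(ghi)) lo2 else hi2
    } else if (glo >= 0) {
      ys[k] <- lo2
    } else if (ghi <= 0) {
      ys[k] <- hi2
    } else {
      col_vals <- surface_column(surface, xs[k]) - level
      if (sum(sign(col_vals[-1]) * sign(col_vals[-length(col_vals)]) < 0) > 1L)
        stop(paste0("multiple roots in a grid column: the monotone-gradient ",
                    "assumption is violated"), call. = FALSE)
      ys[k] <- stats::uniroot(g, c(lo2, hi2), tol = 1e-13)$root
    }
  }
  resid <- abs(predict(surface, s1 = xs, s2 = ys) - level)
  if (max(resid) > tol)
    stop(sprintf("extraction residual %g exceeds tolerance %g",
                 max(resid), tol), call. = FALSE)
  if (any(diff(ys) >= 0))
    stop("extracted level set is not strictly decreasing in s1", call. = FALSE)
  iso_curve(xs, ys, level)
}

#' Select training and test iso-response curves
#'
#' Chooses the curve triplet used throughout the identification: two training
#' curves `L` and `H` at a low and a high response level, and a test curve
#' `T` just below the usable top of the response range (the spike-threshold
#' cap when the surface carries one).  Levels are placed at the given
#' fractions of the usable range `[min r, cap)`.  The test curve must be at
#' least half as long (Euclidean arc length) as the shorter training curve;
#' if the requested `T` level violates this, the level is lowered in steps of
#' 1% of the usable range until the constraint holds, and the adjustment is
#' reported via the `"adjusted"` attribute and a message.
#'
#' @param surface A [fit_surface()] result.
#' @param fractions Strictly increasing fractions in (0, 1) for the `L`, `H`
#'   and `T` levels.
#' @param n_points Samples per extracted curve.
#' @param tol Extraction tolerance, see [extract_iso_curve()].
#' @return An object of class `"curve_triplet"`: list with `L`, `H`, `T`
#'   ([iso_curve()]s) and `levels`.
#' @export
select_triplet <- function(surface, fractions = c(0.3, 0.6, 0.95),
                           n_points = 101L, tol = 1e-8) {
  stopifnot(inherits(surface, "response_surface"))
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3L || any(fractions <= 0) || any(fractions >= 1) ||
      any(diff(fractions) <= 0))
    stop("'fractions' must be three strictly increasing values in (0, 1)",
         call. = FALSE)
  r_lo <- surface$r_range[1]
  r_top <- min(surface$r_range[2], surface$cap %||% Inf)
  span <- r_top - r_lo
  if (span <= 0) stop("usable response range is empty", call. = FALSE)
  lv <- r_lo + fractions * span
  L <- extract_iso_curve(surface, lv[1], n_points, tol)
  H <- extract_iso_curve(surface, lv[2], n_points, tol)
  min_len <- 0.5 * min(L$arclength, H$arclength)
  lvT <- lv[3]
  adjusted <- FALSE
  repeat {
    T_curve <- extract_iso_curve(surface, lvT, n_points, tol)
    if (T_curve$arclength >= min_len) break
    lvT <- lvT - 0.01 * span
    adjusted <- TRUE
    if (lvT <= lv[2])
      stop(paste0("no test level above H satisfies the half-length ",
                  "constraint"), call. = FALSE)
  }
  if (adjusted)
    message(sprintf("test level lowered from %.6g to %.6g to satisfy the half-length constraint",
                    lv[3], lvT))
  structure(list(L = L, H = H, T = T_curve,
                 levels = c(L = lv[1], H = lv[2], T = lvT),
                 ranges = rbind(range(surface$s1), range(surface$s2))),
            class = "curve_triplet",
            adjusted = adjusted)
}

#' @export
print.curve_triplet <- function(x, ...) {
  cat("Iso-response curve triplet:\n")
  cat("  L: "); print(x$L)
  cat("  H: "); print(x$H)
  cat("  T: "); print(x$T)
  invisible(x)
}

#' @export
plot.curve_triplet <- function(x, ...) {
  rngx <- range(x$L$points[, 1], x$H$points[, 1], x$T$points[, 1])
  rngy <- range(x$L$points[, 2], x$H$points[, 2], x$T$points[, 2])
  graphics::plot(NA, xlim = rngx, ylim = rngy, xlab = "s1", ylab = "s2", ...)
  graphics::lines(x$L$points, col = "goldenrod")
  graphics::lines(x$H$points, col = "purple")
  graphics::lines(x$T$points, col = "black", lty = 2)
  graphics::legend("topright", legend = c("L", "H", "T"), lty = c(1, 1, 2),
                   col = c("goldenrod", "purple", "black"), bty = "n")
  invisible(x)
}
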
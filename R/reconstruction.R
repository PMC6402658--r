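#' Build a stairway between two iso-response curves
#'
#' The stairway is the alternating point construction that pins the subunit
#' non-linearities at discrete nodes: starting from `(s1, H(s1))` on the
#' upper training curve, it drops vertically to the lower curve
#' (`s2' = L(s1)`) and steps horizontally back to the upper curve
#' (`s1' = H^-1(s2')`), producing an odd number `n` of points that lie on the
#' two curves in alternating order.  Between consecutive nodes the summed
#' subunit drive changes by exactly the (constant) gap between the two
#' curves' drive levels, which is what [reconstruct_stairway()] exploits.
#'
#' @param L,H [iso_curve()]s; `H` must lie above `L` (higher level).
#' @param start_s1 Starting abscissa; defaults to the left end of the curves'
#'   common `s1` interval.
#' @param n Odd number of stairway points (>= 3).
#' @return An object of class `"stairway"`: list with `s1_nodes`, `s2_nodes`
#'   (each of length `(n + 1) / 2`), the alternating `points` matrix, and a
#'   `truncated` flag set when the stairway exited the curves' valid
#'   intervals before reaching `n` points.
#' @examples
#' # curves of the surface r = s1^2 + s2 at levels 0.5 and 1
#' s1 <- seq(0, 1, length.out = 41)
#' L <- iso_curve(s1[s1 <= sqrt(0.5)], 0.5 - s1[s1 <= sqrt(0.5)]^2, 0.5)
#' H <- iso_curve(s1, 1 - s1^2, 1)
#' build_stairway(L, H, start_s1 = 0, n = 5)
#' @export
build_stairway <- function(L, H, start_s1 = NULL, n = 11L) {
  stopifnot(inherits(L, "iso_curve"), inherits(H, "iso_curve"))
  n <- as.integer(n)
  if (n < 3L || n %% 2L == 0L)
    stop("'n' must be an odd integer >= 3", call. = FALSE)
  common <- c(max(L$s1_range[1], H$s1_range[1]),
              min(L$s1_range[2], H$s1_range[2]))
  if (common[1] >= common[2])
    stop("curves have no common s1 interval", call. = FALSE)
  if (is.null(start_s1)) start_s1 <- common[1]
  if (start_s1 < common[1] - 1e-9 || start_s1 > common[2] + 1e-9)
    stop("'start_s1' outside the curves' common s1 interval", call. = FALSE)
  start_s1 <- min(max(start_s1, common[1]), common[2])
  n_nodes <- (n + 1L) / 2L
  s1n <- numeric(n_nodes); s2n <- numeric(n_nodes)
  s1n[1] <- start_s1
  s2n[1] <- curve_s2(H, start_s1)
  truncated <- FALSE
  k <- 1L
  while (k < n_nodes) {
    # drop to L at the current abscissa
    if (s1n[k] > L$s1_range[2] + 1e-8) { truncated <- TRUE; break }
    nxt_s2 <- curve_s2(L, min(s1n[k], L$s1_range[2]))
    # step back to H at that ordinate
    if (nxt_s2 < H$s2_range[1] - 1e-8) { truncated <- TRUE; break }
    nxt_s1 <- curve_s1(H, max(nxt_s2, H$s2_range[1]))
    k <- k + 1L
    s2n[k] <- nxt_s2
    s1n[k] <- nxt_s1
  }
  if (k == 1L)
    stop("stairway exited the valid intervals immediately", call. = FALSE)
  if (truncated) { s1n <- s1n[seq_len(k)]; s2n <- s2n[seq_len(k)] }
  n_nodes <- length(s1n)
  pts <- matrix(NA_real_, 2L * n_nodes - 1L, 2,
                dimnames = list(NULL, c("s1", "s2")))
  pts[seq(1L, 2L * n_nodes - 1L, by = 2L), ] <- cbind(s1n, s2n)
  if (n_nodes > 1L)
    pts[seq(2L, 2L * n_nodes - 2L, by = 2L), ] <- cbind(s1n[-n_nodes], s2n[-1L])
  structure(list(s1_nodes = s1n, s2_nodes = s2n, points = pts,
                 truncated = truncated, n = 2L * n_nodes - 1L),
            class = "stairway")
}

#' @export
print.stairway <- function(x, ...) {
  cat(sprintf("Stairway with %d points (%d nodes per axis)%s\n",
              x$n, length(x$s1_nodes),
              if (x$truncated) ", truncated at curve boundary" else ""))
  invisible(x)
}

#' Reconstruct subunit non-linearities from a stairway
#'
#' On each training curve the summed subunit drive `m = f1(s1) + f2(s2)` is
#' constant; stepping along the stairway therefore increments `f1` at the
#' `s1` nodes, and decrements `f2` at the `s2` nodes, by exactly the drive
#' gap between the two curves.  The reconstruction is unique up to an affine
#' transformation that can be absorbed into the output non-linearity; the
#' gauge fixed here anchors both functions to 0 at the left edge of their
#' covered intervals and normalizes the drive gap `m_H - m_L` to 1 (so each
#' stairway rung is one gauge unit).
#'
#' @param L,H Training [iso_curve()]s (as used to build the stairway).
#' @param stairway A [build_stairway()] result.
#' @return An object of class `"subunit_reconstruction"`: sampled `f1_hat`,
#'   `f2_hat` ([subunit_fn()] tables), drive levels `m_L`, `m_H`, the gauge
#'   description, and the fit residual (0 by construction here).
#' @export
reconstruct_stairway <- function(L, H, stairway) {
  stopifnot(inherits(stairway, "stairway"))
  s1n <- stairway$s1_nodes
  s2n <- stairway$s2_nodes
  K <- length(s1n)
  if (K < 2L)
    stop("stairway too short to constrain the subunit functions", call. = FALSE)
  # guard against vanishing curve derivatives (flat parametrization would
  # collapse consecutive nodes)
  if (any(diff(s1n) <= 1e-12) || any(diff(s2n) >= -1e-12))
    stop("vanishing curve derivative: consecutive stairway nodes collapse",
         call. = FALSE)
  f1_vals <- (seq_len(K) - 1)                 # 0, 1, ..., K-1 at s1 nodes
  f2_vals <- (K - seq_len(K))                 # K-1, ..., 0 at decreasing s2
  f1_hat <- subunit_table(s1n, f1_vals)
  f2_hat <- subunit_table(rev(s2n), rev(f2_vals))
  new_reconstruction(f1_hat, f2_hat, m_L = K - 2, m_H = K - 1,
                     method = "stairway", residual = 0)
}

new_reconstruction <- function(f1_hat, f2_hat, m_L, m_H, method, residual,
                               basis = NULL) {
  structure(list(f1_hat = f1_hat, f2_hat = f2_hat,
                 m_L = m_L, m_H = m_H,
                 gauge = list(anchor = "f = 0 at left edge of coverage",
                              scale = "m_H - m_L = 1"),
                 method = method, residual = residual, basis = basis),
            class = "subunit_reconstruction")
}

#' @export
print.subunit_reconstruction <- function(x, ...) {
  cat(sprintf("Subunit reconstruction (%s method)\n", x$method))
  cat("  f1_hat: "); print(x$f1_hat)
  cat("  f2_hat: "); print(x$f2_hat)
  cat(sprintf("  drive levels: m_L = %.6g, m_H = %.6g (gauge: gap = 1)\n",
              x$m_L, x$m_H))
  cat(sprintf("  fit residual: %.3g\n", x$residual))
  invisible(x)
}

#' Reconstruct subunit non-linearities by basis expansion
#'
#' For arbitrary curve samples that need not form a stairway, the subunit
#' non-linearities are expanded in a monotone piecewise-linear basis on a
#' uniform knot grid per subunit: each function is parametrized by its
#' non-negative increments between knots, which makes monotonicity a simple
#' sign constraint and keeps the fit linear in the parameters.  The
#' increments (plus the free drive level of the lower curve) are found by
#' non-negative least squares on the requirement that the summed drive
#' `m = f1(s1) + f2(s2)` is constant on each training curve, under the gauge
#' `f1 = f2 = 0` at the left edge of coverage and `m_H - m_L = 1`.
#'
#' Two curves determine the subunit functions exactly only at stairway
#' nodes; between the orbits of the stairway step map there remains a smooth
#' near-null family of equivalent solutions.  A small roughness penalty
#' (`lambda` times the squared third differences of the knot values, which
#' vanishes for quadratic functions) selects the smoothest member of that
#' family without visibly biasing the genuinely constrained shape.
#'
#' @param L,H Training [iso_curve()]s.
#' @param knots Number of knots per subunit (default 21).
#' @param lambda Roughness-penalty weight (default 1; 0 disables it).
#' @return A `"subunit_reconstruction"` (see [reconstruct_stairway()]), with
#'   `residual` the root-mean-square deviation of `m` from constancy over
#'   all constraint points.
#' @export
reconstruct_basis <- function(L, H, knots = 21L, lambda = 1) {
  stopifnot(inherits(L, "iso_curve"), inherits(H, "iso_curve"))
  knots <- as.integer(knots)
  if (knots < 3L) stop("'knots' must be at least 3", call. = FALSE)
  pts_L <- L$points; pts_H <- H$points
  s1_cov <- range(pts_L[, 1], pts_H[, 1])
  s2_cov <- range(pts_L[, 2], pts_H[, 2])
  t1 <- seq(s1_cov[1], s1_cov[2], length.out = knots)
  t2 <- seq(s2_cov[1], s2_cov[2], length.out = knots)
  n_con <- nrow(pts_L) + nrow(pts_H)
  n_par <- 2L * (knots - 1L) + 2L
  if (n_par > n_con)
    stop(sprintf(paste0("underdetermined basis system: %d parameters but only ",
                        "%d constraint points"), n_par, n_con), call. = FALSE)
  A_L <- cbind(ramp_design(pts_L[, 1], t1), ramp_design(pts_L[, 2], t2), -1, 1)
  A_H <- cbind(ramp_design(pts_H[, 1], t1), ramp_design(pts_H[, 2], t2), -1, 1)
  A <- rbind(A_L, A_H)
  b <- c(rep(0, nrow(pts_L)), rep(1, nrow(pts_H)))
  k1 <- knots - 1L
  Afit <- A; bfit <- b
  if (lambda > 0 && k1 >= 3L) {
    D <- diff(diag(k1), differences = 2L)  # 3rd differences of knot values
    z <- matrix(0, nrow(D), k1)
    P <- sqrt(lambda) * rbind(cbind(D, z, 0, 0), cbind(z, D, 0, 0))
    Afit <- rbind(A, P); bfit <- c(b, rep(0, nrow(P)))
  }
  sol <- pracma::lsqnonneg(Afit, bfit)
  theta <- sol$x
  d1 <- theta[seq_len(k1)]
  d2 <- theta[k1 + seq_len(k1)]
  m_L <- theta[2L * k1 + 1L] - theta[2L * k1 + 2L]
  f1_hat <- subunit_table(t1, cumsum(c(0, d1)))
  f2_hat <- subunit_table(t2, cumsum(c(0, d2)))
  resid <- sqrt(mean((A %*% theta - b)^2))
  new_reconstruction(f1_hat, f2_hat, m_L = m_L, m_H = m_L + 1,
                     method = "basis", residual = resid,
                     basis = list(knots1 = t1, knots2 = t2))
}

# integrated-hat ("ramp") design matrix: column j is the increment of a
# monotone piecewise-linear function over knot interval j, evaluated at x
ramp_design <- function(x, knots) {
  k <- length(knots) - 1L
  out <- matrix(0, length(x), k)
  for (j in seq_len(k)) {
    out[, j] <- pmin(pmax((x - knots[j]) / (knots[j + 1] - knots[j]), 0), 1)
  }
  out
}

#' Summed subunit drive of a reconstruction
#'
#' Evaluates `m(s1, s2) = f1_hat(s1) + f2_hat(s2)` at stimulus pairs, in the
#' reconstruction's gauge.  Points outside the covered rectangle are domain
#' errors (the identification never extrapolates).
#'
#' @param result A `"subunit_reconstruction"`.
#' @param s1,s2 Stimulus coordinates (recycled pairwise).
#' @return Numeric drive values.
#' @export
drive <- function(result, s1, s2) {
  stopifnot(inherits(result, "subunit_reconstruction"))
  eval_subunit(result$f1_hat, s1) + eval_subunit(result$f2_hat, s2)
}

#' Predict an iso-response curve from reconstructed subunits
#'
#' Given reconstructed subunit non-linearities and one anchor point on an
#' observed test curve, predicts the full level set
#' `{f1_hat(s1) + f2_hat(s2) = m(anchor)}` restricted to the input range
#' covered by the training curves.  For data generated by a feedforward
#' two-layer model the prediction coincides with the observed test curve;
#' any systematic deviation indicates a violation of the model class.
#'
#' @param result A `"subunit_reconstruction"`.
#' @param anchor Length-2 numeric `(s1, s2)`, a point on the observed test
#'   curve, inside the covered rectangle.
#' @param n_points Number of prediction samples.
#' @return An [iso_curve()] whose `level` is the anchored drive value
#'   `m(anchor)` (gauge units, not response units).
#' @export
predict_test_curve <- function(result, anchor, n_points = 101L) {
  stopifnot(inherits(result, "subunit_reconstruction"), length(anchor) == 2L)
  f1 <- result$f1_hat; f2 <- result$f2_hat
  m_star <- drive(result, anchor[1], anchor[2])
  # s1 values whose required f2 value is attainable inside coverage
  f2_lo <- eval_subunit(f2, f2$domain[1]); f2_hi <- eval_subunit(f2, f2$domain[2])
  g <- function(x) m_star - eval_subunit(f1, x)   # required f2 value at s1 = x
  a <- f1$domain[1]; b <- f1$domain[2]
  lo_ok <- function(x) g(x) <= f2_hi; hi_ok <- function(x) g(x) >= f2_lo
  x_lo <- if (lo_ok(a)) a else stats::uniroot(function(x) g(x) - f2_hi,
                                              c(a, b), tol = 1e-13)$root
  x_hi <- if (hi_ok(b)) b else stats::uniroot(function(x) g(x) - f2_lo,
                                              c(a, b), tol = 1e-13)$root
  if (x_hi <= x_lo)
    stop("predicted level set has no extent inside the covered domain",
         call. = FALSE)
  xs <- seq(x_lo, x_hi, length.out = n_points)
  ys <- vapply(xs, function(x) invert_monotone(f2, g(x)), 0)
  keep <- c(TRUE, diff(ys) < -1e-12)  # drop stalls from flat f segments
  if (sum(keep) < 3L)
    stop("predicted level set degenerate (flat subunit function)", call. = FALSE)
  iso_curve(xs[keep], ys[keep], level = m_star)
}

# invert a monotone non-decreasing subunit_fn at value v (leftmost preimage)
invert_monotone <- function(f, v, tol = 1e-12) {
  lo <- f$domain[1]; hi <- f$domain[2]
  flo <- eval_subunit(f, lo); fhi <- eval_subunit(f, hi)
  if (v <= flo + tol) return(lo)
  if (v >= fhi - tol) return(hi)
  stats::uniroot(function(x) eval_subunit(f, x) - v, c(lo, hi), tol = tol)$root
}

#' Reconstruct the output non-linearity along the diagonal
#'
#' Once the subunit non-linearities are identified (up to the affine gauge),
#' the output non-linearity `f3` of a feedforward model follows from
#' responses along any line that sweeps the drive range, canonically the
#' diagonal `s1 = s2`: each measured `(s, r(s, s))` pair yields a point
#' `(m_hat(s, s), r)` on the graph of `f3`.  The pairs must be monotone —
#' decreasing diagonal responses violate the model and are an error — and are
#' interpolated by a monotone cubic spline.
#'
#' @param result A `"subunit_reconstruction"`.
#' @param diagonal Data frame with columns `s` and `r` (responses at
#'   `s1 = s2 = s`), or columns `s1`, `s2`, `r` for a general monotone path.
#' @param tol Monotonicity tolerance on the paired responses.
#' @return A [subunit_fn()] (`"table"` family, monotone cubic interpolation)
#'   mapping gauge drive `m` to response `r`.
#' @export
reconstruct_f3 <- function(result, diagonal, tol = 1e-9) {
  stopifnot(inherits(result, "subunit_reconstruction"))
  df <- as.data.frame(diagonal)
  if (!is.null(df$s) && is.null(df$s1)) { df$s1 <- df$s; df$s2 <- df$s }
  if (!all(c("s1", "s2", "r") %in% names(df)))
    stop("diagonal table must have columns (s, r) or (s1, s2, r)", call. = FALSE)
  # keep points inside the reconstruction's coverage
  in_cov <- df$s1 >= result$f1_hat$domain[1] - 1e-12 &
            df$s1 <= result$f1_hat$domain[2] + 1e-12 &
            df$s2 >= result$f2_hat$domain[1] - 1e-12 &
            df$s2 <= result$f2_hat$domain[2] + 1e-12
  df <- df[in_cov, , drop = FALSE]
  if (nrow(df) < 4L)
    stop("too few diagonal samples inside the covered domain", call. = FALSE)
  m <- drive(result, df$s1, df$s2)
  o <- order(m)
  m <- m[o]; r <- df$r[o]
  if (any(diff(r) < -tol))
    stop("diagonal responses are not monotone in the drive: cannot reconstruct f3",
         call. = FALSE)
  keep <- c(TRUE, diff(m) > 1e-12)
  m <- m[keep]; r <- r[keep]
  r <- cummax(r)  # clip within-tolerance monotonicity violations
  keep <- c(TRUE, diff(r) > 1e-12)  # hyman interpolation needs strict increase
  m <- m[keep]; r <- r[keep]
  subunit_fn("table", s = m, f = r, interp = "hyman", domain = range(m))
}
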
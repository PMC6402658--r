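#' Two-layer subunit model
#'
#' Constructs a cascade model of dendritic integration with two input
#' branches: each stimulus strength `s1`, `s2` passes through its branch's
#' subunit non-linearity (`f1`, `f2`), the subunit outputs are summed, and the
#' sum is passed through a strictly increasing output non-linearity `f3`, so
#' that the feedforward response is `r = f3(f1(s1) + f2(s2))`.
#'
#' Optionally the model carries output feedback: the response modulates the
#' effective input of each subunit multiplicatively and/or additively, and the
#' response is then defined implicitly by
#' `r = f3(f1(g1m(r)*s1 + g1a(r)) + f2(g2m(r)*s2 + g2a(r)))`,
#' solved per stimulus pair by [eval_feedback()].
#'
#' @param f1,f2 [subunit_fn()] objects, non-decreasing on their domains.
#' @param f3 A strictly increasing [subunit_fn()] for the output stage; its
#'   domain must cover the attainable range of `f1 + f2`. Defaults to the
#'   identity on that range.
#' @param feedback `NULL` for a purely feedforward model, otherwise a list
#'   with (any of the) components `g1_add`, `g2_add`, `g1_mult`, `g2_mult`,
#'   each a [feedback_fn()] of matching kind; missing components default to
#'   identity feedback (0 additive, 1 multiplicative).
#' @param ranges 2x2 numeric matrix (rows = subunits) giving the input
#'   rectangle in normalized stimulus units; defaults to `[0,1] x [0,1]`.
#' @param cap Optional response cap emulating the spike threshold: responses
#'   are reported as `pmin(r, cap)` by the sampling helpers, and test curves
#'   are always chosen strictly below it.
#' @return An object of class `"two_layer_model"`.
#' @seealso [point_neuron_model()], [eval_feedforward()], [eval_feedback()],
#'   [predict.two_layer_model()]
#' @examples
#' m <- two_layer_model(subunit_fn("power", exponent = 2), subunit_fn("linear"))
#' eval_feedforward(m, 0.5, 0.25)
#' @export
two_layer_model <- function(f1, f2, f3 = NULL, feedback = NULL,
                            ranges = rbind(c(0, 1), c(0, 1)), cap = NULL) {
  stopifnot(inherits(f1, "subunit_fn"), inherits(f2, "subunit_fn"))
  ranges <- matrix(as.numeric(ranges), 2, 2)
  if (any(ranges[, 2] <= ranges[, 1]))
    stop("input ranges must be increasing intervals", call. = FALSE)
  if (ranges[1, 1] < f1$domain[1] - 1e-12 || ranges[1, 2] > f1$domain[2] + 1e-12 ||
      ranges[2, 1] < f2$domain[1] - 1e-12 || ranges[2, 2] > f2$domain[2] + 1e-12)
    stop("input ranges must lie inside the subunit domains", call. = FALSE)
  m_range <- c(eval_subunit(f1, f1$domain[1]) + eval_subunit(f2, f2$domain[1]),
               eval_subunit(f1, f1$domain[2]) + eval_subunit(f2, f2$domain[2]))
  if (is.null(f3)) {
    f3 <- subunit_fn("linear", gain = 1, offset = 0,
                     domain = m_range + c(-1, 1))
  }
  stopifnot(inherits(f3, "subunit_fn"))
  fb <- NULL
  if (!is.null(feedback)) {
    fb <- list(
      g1_add  = feedback$g1_add  %||% feedback_fn("additive", "none"),
      g2_add  = feedback$g2_add  %||% feedback_fn("additive", "none"),
      g1_mult = feedback$g1_mult %||% feedback_fn("multiplicative", "none"),
      g2_mult = feedback$g2_mult %||% feedback_fn("multiplicative", "none")
    )
    ok <- vapply(fb, inherits, TRUE, what = "feedback_fn")
    if (!all(ok)) stop("feedback components must be feedback_fn objects", call. = FALSE)
    if (fb$g1_add$kind != "additive" || fb$g2_add$kind != "additive" ||
        fb$g1_mult$kind != "multiplicative" || fb$g2_mult$kind != "multiplicative")
      stop("feedback component kinds do not match their slots", call. = FALSE)
    if (all(vapply(fb, is_identity_feedback, TRUE))) fb <- NULL
  }
  structure(list(f1 = f1, f2 = f2, f3 = f3, feedback = fb,
                 ranges = ranges, cap = cap),
            class = "two_layer_model")
}

#' Point-neuron model
#'
#' The classical single-compartment abstraction: stimuli are summed linearly
#' with non-negative weights and passed through one output non-linearity,
#' `r = f3(w1*s1 + w2*s2)`.  Its iso-response curves are straight lines of
#' slope `-w1/w2`.
#'
#' @param w1,w2 Non-negative summation weights.
#' @param f3 Output non-linearity ([subunit_fn()]); defaults to the identity.
#' @param ranges Input rectangle as in [two_layer_model()].
#' @param cap Optional response cap.
#' @return An object of class `"point_neuron_model"`.
#' @examples
#' pn <- point_neuron_model(1, 3, subunit_fn("power", exponent = 2))
#' eval_point_neuron(pn, 0.2, 0.1)
#' @export
point_neuron_model <- function(w1, w2, f3 = NULL,
                               ranges = rbind(c(0, 1), c(0, 1)), cap = NULL) {
  if (w1 < 0 || w2 < 0) stop("weights must be non-negative", call. = FALSE)
  ranges <- matrix(as.numeric(ranges), 2, 2)
  u_max <- w1 * max(abs(ranges[1, ])) + w2 * max(abs(ranges[2, ]))
  if (is.null(f3)) f3 <- subunit_fn("linear", domain = c(-u_max - 1, u_max + 1))
  stopifnot(inherits(f3, "subunit_fn"))
  structure(list(w1 = w1, w2 = w2, f3 = f3, ranges = ranges, cap = cap),
            class = "point_neuron_model")
}

#' @export
print.two_layer_model <- function(x, ...) {
  cat("Two-layer subunit model",
      if (is.null(x$feedback)) "(feedforward)\n" else "(with output feedback)\n")
  cat("  f1: "); print(x$f1)
  cat("  f2: "); print(x$f2)
  cat("  f3: "); print(x$f3)
  if (!is.null(x$feedback)) {
    for (nm in names(x$feedback)) {
      if (!is_identity_feedback(x$feedback[[nm]])) {
        cat("  ", nm, ": ", sep = ""); print(x$feedback[[nm]])
      }
    }
  }
  cat(sprintf("  input rectangle: [%g, %g] x [%g, %g]\n",
              x$ranges[1, 1], x$ranges[1, 2], x$ranges[2, 1], x$ranges[2, 2]))
  invisible(x)
}

#' @export
print.point_neuron_model <- function(x, ...) {
  cat(sprintf("Point-neuron model: r = f3(%g*s1 + %g*s2)\n", x$w1, x$w2))
  cat("  f3: "); print(x$f3)
  invisible(x)
}

check_in_rectangle <- function(model, s1, s2, tol = 1e-9) {
  rg <- model$ranges
  if (any(s1 < rg[1, 1] - tol) || any(s1 > rg[1, 2] + tol) ||
      any(s2 < rg[2, 1] - tol) || any(s2 > rg[2, 2] + tol))
    stop("stimulus pair outside the model's input rectangle", call. = FALSE)
  invisible(TRUE)
}

#' Evaluate a feedforward two-layer model
#'
#' Computes `r = f3(f1(s1) + f2(s2))` for a model without feedback (or with
#' all-identity feedback).  Deterministic and strictly increasing in each
#' argument whenever `f1`, `f2`, `f3` are strictly increasing.
#'
#' @param model A [two_layer_model()] without feedback.
#' @param s1,s2 Stimulus strengths (vectors are recycled to equal length).
#' @return Numeric response vector.
#' @export
eval_feedforward <- function(model, s1, s2) {
  stopifnot(inherits(model, "two_layer_model"))
  if (!is.null(model$feedback))
    stop("model has feedback; use eval_feedback()", call. = FALSE)
  n <- max(length(s1), length(s2))
  s1 <- rep_len(as.numeric(s1), n); s2 <- rep_len(as.numeric(s2), n)
  check_in_rectangle(model, s1, s2)
  eval_subunit(model$f3, eval_subunit(model$f1, s1) + eval_subunit(model$f2, s2))
}

#' Evaluate a two-layer model with output feedback
#'
#' Solves the implicit response equation
#' `r = f3(f1(g1m(r)*s1 + g1a(r)) + f2(g2m(r)*s2 + g2a(r)))`
#' per stimulus pair.  A damped fixed-point iteration (damping 0.5) is run on
#' all points simultaneously; points that fail to converge fall back to
#' bracketed root finding on the scalar residual.  If root scanning brackets
#' several fixed points the smallest is returned and flagged, matching the
#' assumption of a unique sub-threshold response.
#'
#' @param model A [two_layer_model()] with feedback.
#' @param s1,s2 Stimulus strengths (recycled to equal length).
#' @param tol Convergence tolerance on the residual `|r - f3(...)|`.
#' @param max_iter Maximum damped-iteration count before the bisection
#'   fallback.
#' @param check_multiplicity If `TRUE`, scan the response interval for
#'   additional fixed points (slower); any multiplicity is reported through
#'   the `"multiplicity"` attribute.
#' @return Numeric response vector with attributes `"residual"` (max absolute
#'   residual) and `"multiplicity"` (logical, any point with several fixed
#'   points detected).
#' @export
eval_feedback <- function(model, s1, s2, tol = 1e-10, max_iter = 1000L,
                          check_multiplicity = FALSE) {
  stopifnot(inherits(model, "two_layer_model"))
  fb <- model$feedback
  if (is.null(fb)) {
    r <- eval_feedforward(model, s1, s2)
    attr(r, "residual") <- 0; attr(r, "multiplicity") <- FALSE
    return(r)
  }
  n <- max(length(s1), length(s2))
  s1 <- rep_len(as.numeric(s1), n); s2 <- rep_len(as.numeric(s2), n)
  check_in_rectangle(model, s1, s2)

  rhs <- function(r, i = seq_len(n)) {
    x1 <- fb$g1_mult$fun(r) * s1[i] + fb$g1_add$fun(r)
    x2 <- fb$g2_mult$fun(r) * s2[i] + fb$g2_add$fun(r)
    eval_subunit(model$f3,
                 eval_subunit(model$f1, x1) + eval_subunit(model$f2, x2))
  }

  # start from the feedback-free response
  r <- eval_subunit(model$f3,
                    eval_subunit(model$f1, s1) + eval_subunit(model$f2, s2))
  lambda <- 0.5
  converged <- rep(FALSE, n)
  for (it in seq_len(max_iter)) {
    fr <- rhs(r)
    delta <- fr - r
    converged <- abs(delta) <= tol
    if (all(converged)) break
    r <- r + lambda * delta
  }
  multiplicity <- FALSE
  if (!all(converged)) {
    # bracketing/bisection fallback on the residual phi(r) = rhs(r) - r
    r_lo <- eval_subunit(model$f3, model$f3$domain[1])
    r_hi <- eval_subunit(model$f3, model$f3$domain[2])
    for (i in which(!converged)) {
      phi <- function(rr) rhs(rr, i) - rr
      roots <- scan_fixed_points(phi, r_lo, r_hi, n_scan = 400L, tol = tol)
      if (length(roots) == 0L)
        stop(sprintf(paste0("implicit response equation did not converge at ",
                            "(s1=%g, s2=%g); residual %g"),
                     s1[i], s2[i], abs(phi(r[i]))), call. = FALSE)
      if (length(roots) > 1L) multiplicity <- TRUE
      r[i] <- min(roots)
    }
  }
  if (check_multiplicity) {
    r_lo <- eval_subunit(model$f3, model$f3$domain[1])
    r_hi <- eval_subunit(model$f3, model$f3$domain[2])
    for (i in seq_len(n)) {
      phi <- function(rr) rhs(rr, i) - rr
      roots <- scan_fixed_points(phi, r_lo, r_hi, n_scan = 400L, tol = tol)
      if (length(roots) > 1L) multiplicity <- TRUE
      if (length(roots) >= 1L && min(roots) < r[i] - 10 * tol) r[i] <- min(roots)
    }
  }
  resid <- max(abs(rhs(r) - r))
  if (resid > 10 * tol)
    stop(sprintf("implicit response equation residual %g exceeds tolerance", resid),
         call. = FALSE)
  attr(r, "residual") <- resid
  attr(r, "multiplicity") <- multiplicity
  r
}

# locate sign changes of phi on [lo, hi] and polish with uniroot
scan_fixed_points <- function(phi, lo, hi, n_scan = 400L, tol = 1e-10) {
  grid <- seq(lo, hi, length.out = n_scan)
  vals <- vapply(grid, phi, 0)
  roots <- numeric(0)
  zero_hits <- grid[abs(vals) <= tol]
  sgn <- sign(vals)
  idx <- which(sgn[-1] * sgn[-n_scan] < 0)
  for (k in idx) {
    rt <- stats::uniroot(phi, c(grid[k], grid[k + 1]), tol = tol / 10)$root
    roots <- c(roots, rt)
  }
  roots <- sort(unique(c(roots, zero_hits)))
  if (length(roots) > 1L) roots <- roots[c(TRUE, diff(roots) > 100 * tol)]
  roots
}

#' Evaluate a point-neuron model
#'
#' @param model A [point_neuron_model()].
#' @param s1,s2 Stimulus strengths (recycled to equal length).
#' @return Numeric response vector `f3(w1*s1 + w2*s2)`.
#' @export
eval_point_neuron <- function(model, s1, s2) {
  stopifnot(inherits(model, "point_neuron_model"))
  n <- max(length(s1), length(s2))
  s1 <- rep_len(as.numeric(s1), n); s2 <- rep_len(as.numeric(s2), n)
  check_in_rectangle(model, s1, s2)
  eval_subunit(model$f3, model$w1 * s1 + model$w2 * s2)
}

#' Predict responses from a subunit model
#'
#' Dispatches to the appropriate evaluator: feedforward composition,
#' implicit feedback solution, or weighted point-neuron summation.
#'
#' @param object A `"two_layer_model"` or `"point_neuron_model"`.
#' @param newdata Data frame with columns `s1` and `s2`; alternatively pass
#'   `s1` and `s2` directly.
#' @param s1,s2 Stimulus vectors, used when `newdata` is missing.
#' @param ... Passed to [eval_feedback()] for feedback models.
#' @return Numeric response vector.
#' @export
predict.two_layer_model <- function(object, newdata = NULL, s1 = NULL, s2 = NULL, ...) {
  if (!is.null(newdata)) { s1 <- newdata$s1; s2 <- newdata$s2 }
  if (is.null(s1) || is.null(s2)) stop("supply 'newdata' or 's1' and 's2'", call. = FALSE)
  if (is.null(object$feedback)) eval_feedforward(object, s1, s2)
  else eval_feedback(object, s1, s2, ...)
}

#' @rdname predict.two_layer_model
#' @export
predict.point_neuron_model <- function(object, newdata = NULL, s1 = NULL, s2 = NULL, ...) {
  if (!is.null(newdata)) { s1 <- newdata$s1; s2 <- newdata$s2 }
  if (is.null(s1) || is.null(s2)) stop("supply 'newdata' or 's1' and 's2'", call. = FALSE)
  eval_point_neuron(object, s1, s2)
}

#' Wrap an arbitrary response function as a model adapter
#'
#' The identification pipeline only needs a deterministic callable
#' `(s1, s2) -> r` plus its input rectangle; this adapter lets external
#' simulators (or closed-loop experimental rigs) plug into the same code path
#' as the built-in model classes.
#'
#' @param fun Vectorized function of two numeric vectors returning responses.
#' @param ranges Input rectangle (2x2 matrix, rows = inputs).
#' @param cap Optional response cap (spike threshold emulation).
#' @return An object of class `"response_adapter"` usable with
#'   [sample_surface()].
#' @examples
#' ad <- response_adapter(function(s1, s2) s1 + 2 * s2)
#' @export
response_adapter <- function(fun, ranges = rbind(c(0, 1), c(0, 1)), cap = NULL) {
  stopifnot(is.function(fun))
  ranges <- matrix(as.numeric(ranges), 2, 2)
  structure(list(fun = fun, ranges = ranges, cap = cap),
            class = "response_adapter")
}

#' @rdname predict.two_layer_model
#' @export
predict.response_adapter <- function(object, newdata = NULL, s1 = NULL, s2 = NULL, ...) {
  if (!is.null(newdata)) { s1 <- newdata$s1; s2 <- newdata$s2 }
  n <- max(length(s1), length(s2))
  s1 <- rep_len(as.numeric(s1), n); s2 <- rep_len(as.numeric(s2), n)
  check_in_rectangle(object, s1, s2)
  object$fun(s1, s2)
}
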
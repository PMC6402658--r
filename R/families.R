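#' Scalar subunit and output non-linearities
#'
#' `subunit_fn()` constructs a monotone scalar input-output function, used both
#' for the first-layer subunit non-linearities (the per-branch functions
#' `f1`, `f2`) and for the final output non-linearity `f3` of a two-layer
#' cascade model.  Stimulus strengths are dimensionless, normalized to the
#' input range of a branch, so all parametric families are defined on
#' normalized coordinates.
#'
#' Available families:
#' \describe{
#'   \item{`"linear"`}{`f(s) = gain * s + offset`; defined on all reals.}
#'   \item{`"power"`}{`f(s) = gain * s^exponent`; supralinear for
#'     `exponent > 1`, sublinear (e.g. square root) for `exponent < 1`;
#'     defined on `s >= 0`.}
#'   \item{`"sigmoid"`}{`f(s) = onset_gain * s + amplitude *
#'     (plogis((s - center)/width) - plogis(-center/width))`; a small linear
#'     onset followed by a rapid saturating rise, the shape class typical of
#'     NMDA-dominated dendritic branches; defined on all reals and strictly
#'     increasing whenever `onset_gain > 0` or `amplitude > 0`.}
#'   \item{`"saturating"`}{`f(s) = gain * s / (half + s)`; Michaelis-Menten
#'     style saturation, typically used for the output non-linearity;
#'     defined on `s > -half`.}
#'   \item{`"table"`}{a strictly ordered sample table `(s, f)` with either
#'     linear or monotone cubic (`"hyman"`) interpolation; defined on the
#'     sampled interval only.}
#' }
#'
#' Evaluation outside the declared domain is an error: the identification
#' framework never extrapolates subunit functions.
#'
#' @param family Character; one of `"linear"`, `"power"`, `"sigmoid"`,
#'   `"saturating"`, `"table"`.
#' @param s,f Sample table for the `"table"` family: strictly increasing
#'   abscissae and non-decreasing values.
#' @param interp Interpolation rule for the `"table"` family: `"linear"` or
#'   monotone cubic `"hyman"`.
#' @param ... Remaining family parameters, see Details.
#' @param domain Numeric length-2; closed evaluation interval. Defaults to the
#'   family's natural domain intersected with `c(0, 1)` for bounded families,
#'   otherwise `c(0, 1)`.
#' @return An object of class `"subunit_fn"`: a list with elements `family`,
#'   `params`, `domain` and an evaluator; call it through
#'   [eval_subunit()] or convert with `as.function()`.
#' @examples
#' f <- subunit_fn("power", gain = 1, exponent = 2)
#' eval_subunit(f, c(0, 0.5, 1))
#' @export
subunit_fn <- function(family = c("linear", "power", "sigmoid", "saturating", "table"),
                       s = NULL, f = NULL, interp = "linear",
                       ..., domain = NULL) {
  family <- match.arg(family)
  params <- list(...)
  if (family == "table") params <- c(params, list(s = s, f = f, interp = interp))
  p <- function(name, default = NULL) {
    if (!is.null(params[[name]])) params[[name]] else default
  }
  natural <- c(-Inf, Inf)
  core <- switch(family,
    linear = {
      gain <- p("gain", 1); offset <- p("offset", 0)
      stopifnot(is.finite(gain), is.finite(offset))
      function(s) gain * s + offset
    },
    power = {
      gain <- p("gain", 1); exponent <- p("exponent", 2)
      if (exponent <= 0) stop("'exponent' must be positive", call. = FALSE)
      natural <- c(0, Inf)
      function(s) gain * s^exponent
    },
    sigmoid = {
      onset_gain <- p("onset_gain", 0.25)
      amplitude  <- p("amplitude", 1)
      center     <- p("center", 0.5)
      width      <- p("width", 0.1)
      if (width <= 0) stop("'width' must be positive", call. = FALSE)
      if (onset_gain < 0 || amplitude < 0)
        stop("'onset_gain' and 'amplitude' must be non-negative", call. = FALSE)
      if (onset_gain == 0 && amplitude == 0)
        stop("sigmoid family needs a positive 'onset_gain' or 'amplitude'", call. = FALSE)
      base <- stats::plogis(-center / width)
      function(s) onset_gain * s + amplitude * (stats::plogis((s - center) / width) - base)
    },
    saturating = {
      gain <- p("gain", 1); half <- p("half", 0.5)
      if (half <= 0) stop("'half' must be positive", call. = FALSE)
      natural <- c(-half + 1e-12, Inf)
      function(s) gain * s / (half + s)
    },
    table = {
      s <- p("s"); v <- p("f")
      if (is.null(s) || is.null(v) || length(s) != length(v) || length(s) < 2L)
        stop("table family needs matching 's' and 'f' vectors of length >= 2", call. = FALSE)
      if (any(!is.finite(s)) || any(!is.finite(v)))
        stop("table family values must be finite", call. = FALSE)
      o <- order(s); s <- s[o]; v <- v[o]
      if (any(diff(s) <= 0)) stop("table 's' values must be strictly ordered", call. = FALSE)
      if (any(diff(v) < -1e-12)) stop("table 'f' values must be non-decreasing", call. = FALSE)
      natural <- range(s)
      interp <- p("interp", "linear")
      if (identical(interp, "hyman")) {
        stats::splinefun(s, v, method = "hyman")
      } else {
        function(x) stats::approx(s, v, xout = x, rule = 1)$y
      }
    }
  )
  # 'natural' may have been narrowed inside the switch branch environment
  natural <- environment(core)$natural %||% natural
  if (is.null(domain)) {
    domain <- c(max(0, natural[1]), if (is.finite(natural[2])) natural[2] else 1)
  }
  domain <- as.numeric(domain)
  if (length(domain) != 2L || !all(is.finite(domain)) || domain[1] >= domain[2])
    stop("'domain' must be a finite, increasing length-2 interval", call. = FALSE)
  if (domain[1] < natural[1] - 1e-12 || domain[2] > natural[2] + 1e-12)
    stop("'domain' exceeds the family's natural domain", call. = FALSE)
  structure(
    list(family = family, params = params, domain = domain, fun = core),
    class = "subunit_fn"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a subunit non-linearity
#'
#' @param f A [subunit_fn()] object.
#' @param s Numeric vector of (normalized) stimulus strengths.
#' @param tol Domain tolerance; inputs within `tol` of the domain edge are
#'   clamped onto it, anything further outside is a domain error.
#' @return Numeric vector `f(s)`.
#' @export
eval_subunit <- function(f, s, tol = 1e-9) {
  stopifnot(inherits(f, "subunit_fn"))
  s <- as.numeric(s)
  if (any(!is.finite(s))) stop("non-finite stimulus value", call. = FALSE)
  lo <- f$domain[1]; hi <- f$domain[2]
  if (any(s < lo - tol) || any(s > hi + tol)) {
    stop(sprintf("stimulus outside the function domain [%g, %g]", lo, hi),
         call. = FALSE)
  }
  f$fun(pmin(pmax(s, lo), hi))
}

#' @export
as.function.subunit_fn <- function(x, ...) function(s) eval_subunit(x, s)

#' @export
print.subunit_fn <- function(x, ...) {
  ps <- x$params[!vapply(x$params, is.null, TRUE)]
  ps <- ps[!(names(ps) %in% c("s", "f"))]
  cat(sprintf("<subunit_fn: %s on [%g, %g]%s>\n", x$family,
              x$domain[1], x$domain[2],
              if (length(ps)) paste0("; ", paste(names(ps), unlist(ps),
                                                 sep = "=", collapse = ", "))
              else ""))
  invisible(x)
}

#' Build a sampled, monotone subunit function from node values
#'
#' Internal helper used by the reconstruction routines: wraps ordered node
#' samples as a `"table"`-family [subunit_fn()].
#' @noRd
subunit_table <- function(s, f, interp = "linear") {
  subunit_fn("table", s = s, f = f, interp = interp)
}

#' Output feedback functions
#'
#' Constructs a feedback function `g(r)` mapping the model output `r` back to
#' a modulation of a subunit's effective input: additive feedback is added to
#' the stimulus (stimulus units), multiplicative feedback scales it
#' (dimensionless, strictly positive).  Feedback is stored relative to a
#' reference response level, i.e. an additive function is 0 and a
#' multiplicative function 1 at low responses, because only differences
#' (additive) and ratios (multiplicative) of feedback between response levels
#' are identifiable from iso-response curves.
#'
#' Families:
#' \describe{
#'   \item{`"none"`}{identity feedback: constantly 0 (additive) or 1
#'     (multiplicative).}
#'   \item{`"step"`}{a step located at the response level `onset`, smoothed by
#'     a logistic ramp of width `width` (response units) so the implicit
#'     response equation stays well-posed: additive
#'     `g(r) = amplitude * plogis((r - onset)/width)`; multiplicative
#'     `g(r) = 1 + (ratio - 1) * plogis((r - onset)/width)`.}
#' }
#'
#' @param kind `"additive"` or `"multiplicative"`.
#' @param family `"none"` or `"step"`.
#' @param onset Response level at which the step is centred.
#' @param amplitude Step height for additive feedback (stimulus units; may be
#'   negative for suppressive feedback).
#' @param ratio Asymptotic multiplicative factor (must be positive).
#' @param width Ramp width in response units.
#' @return An object of class `"feedback_fn"` with fields `kind`, `family`,
#'   `params` and an evaluator `fun(r)`.
#' @examples
#' g <- feedback_fn("additive", "step", onset = 0.5, amplitude = 0.1, width = 0.01)
#' g$fun(c(0.2, 0.8))
#' @export
feedback_fn <- function(kind = c("additive", "multiplicative"),
                        family = c("none", "step"),
                        onset = NULL, amplitude = NULL, ratio = NULL,
                        width = NULL) {
  kind <- match.arg(kind)
  family <- match.arg(family)
  if (family == "none") {
    fun <- if (kind == "additive") function(r) rep(0, length(r))
           else function(r) rep(1, length(r))
    params <- list()
  } else {
    if (is.null(onset) || is.null(width) || width <= 0)
      stop("step feedback needs 'onset' and a positive 'width'", call. = FALSE)
    if (kind == "additive") {
      if (is.null(amplitude)) stop("additive step feedback needs 'amplitude'", call. = FALSE)
      fun <- function(r) amplitude * stats::plogis((r - onset) / width)
      params <- list(onset = onset, amplitude = amplitude, width = width)
    } else {
      if (is.null(ratio) || ratio <= 0)
        stop("multiplicative step feedback needs a positive 'ratio'", call. = FALSE)
      fun <- function(r) 1 + (ratio - 1) * stats::plogis((r - onset) / width)
      params <- list(onset = onset, ratio = ratio, width = width)
    }
  }
  structure(list(kind = kind, family = family, params = params, fun = fun),
            class = "feedback_fn")
}

#' @export
print.feedback_fn <- function(x, ...) {
  cat(sprintf("<feedback_fn: %s, %s%s>\n", x$kind, x$family,
              if (length(x$params))
                paste0("; ", paste(names(x$params), unlist(x$params),
                                   sep = "=", collapse = ", "))
              else ""))
  invisible(x)
}

is_identity_feedback <- function(g) {
  is.null(g) || (inherits(g, "feedback_fn") && g$family == "none")
}
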
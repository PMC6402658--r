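#' Declare a synthetic ground-truth scenario
#'
#' A scenario spec fully determines a benchmark model and the surface
#' sampled from it (same spec and seed give bit-identical surfaces), and
#' carries its ground truth alongside, so validation code never has to
#' infer labels from the pipeline under test.
#'
#' @param name Scenario name.
#' @param kind `"point"`, `"feedforward"` or `"feedback"`.
#' @param f1,f2 [subunit_fn()]s (ignored for `kind = "point"`).
#' @param f3 Output [subunit_fn()] or `NULL` for identity.
#' @param w Length-2 weights for point-neuron scenarios.
#' @param feedback For `kind = "feedback"`: list with `kind`
#'   (`"additive"`/`"multiplicative"`), `onset` (response level),
#'   `amplitude` (additive, stimulus units) or `ratio` (multiplicative),
#'   optional `width` (response units; default 5% of the response range) and
#'   `subunits` (which subunits receive feedback, default `c(1, 2)`).
#'   Supplying feedback with any other kind is a spec error.
#' @param grid Default sampling resolution per axis.
#' @param noise Additive Gaussian response noise SD (default 0).
#' @param seed RNG seed for the noisy sampling path.
#' @param cap Optional response cap (spike-threshold emulation).
#' @param fractions Default triplet level fractions for this scenario.
#' @param ranges Input rectangle.
#' @return An object of class `"scenario_spec"` with a `truth` field
#'   (`separable`, `feedback_kind`, `amplitude`/`ratio`, `onset`).
#' @export
scenario_spec <- function(name, kind = c("feedforward", "feedback", "point"),
                          f1 = NULL, f2 = NULL, f3 = NULL, w = c(1, 1),
                          feedback = NULL, grid = 64L, noise = 0,
                          seed = 1L, cap = NULL,
                          fractions = c(0.3, 0.6, 0.95),
                          ranges = rbind(c(0, 1), c(0, 1))) {
  kind <- match.arg(kind)
  if (!is.null(feedback) && kind != "feedback")
    stop(sprintf("feedback supplied for a '%s' scenario", kind), call. = FALSE)
  if (kind == "feedback" && is.null(feedback))
    stop("a feedback scenario needs a 'feedback' spec", call. = FALSE)
  truth <- list(separable = kind != "feedback",
                feedback_kind = feedback$kind %||% "none",
                amplitude = feedback$amplitude %||% NA_real_,
                ratio = feedback$ratio %||% NA_real_,
                onset = feedback$onset %||% NA_real_)
  structure(list(name = name, kind = kind, f1 = f1, f2 = f2, f3 = f3,
                 w = w, feedback = feedback, grid = grid, noise = noise,
                 seed = seed, cap = cap, fractions = fractions,
                 ranges = ranges, truth = truth),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario '%s': %s model, %dx%d grid, noise %g, seed %d\n",
              x$name, x$kind, x$grid, x$grid, x$noise, x$seed))
  if (x$kind == "feedback")
    cat(sprintf("  feedback: %s, onset %.3g, %s\n", x$truth$feedback_kind,
                x$truth$onset,
                if (x$truth$feedback_kind == "additive")
                  sprintf("amplitude %.3g", x$truth$amplitude)
                else sprintf("ratio %.3g", x$truth$ratio)))
  invisible(x)
}

#' Instantiate the ground-truth model of a scenario
#'
#' @param spec A [scenario_spec()].
#' @return A [two_layer_model()] or [point_neuron_model()] honoring all
#'   spec fields.
#' @export
make_model <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$kind == "point") {
    return(point_neuron_model(spec$w[1], spec$w[2], spec$f3,
                              ranges = spec$ranges, cap = spec$cap))
  }
  if (is.null(spec$f1) || is.null(spec$f2))
    stop("two-layer scenarios need 'f1' and 'f2'", call. = FALSE)
  fb <- NULL
  if (spec$kind == "feedback") {
    fs <- spec$feedback
    subunits <- fs$subunits %||% c(1, 2)
    # the step is smoothed by a ramp, by default 5% of the feedforward
    # response range: narrow enough to act as a step between response
    # levels, wide enough that the feedback loop stays contractive (a hard
    # step makes the implicit response equation multi-valued)
    ff <- two_layer_model(spec$f1, spec$f2, spec$f3, ranges = spec$ranges)
    rr <- range(eval_feedforward(ff,
                                 rep(spec$ranges[1, ], 2),
                                 rep(spec$ranges[2, ], each = 2)))
    width <- fs$width %||% (0.05 * diff(rr))
    g <- function() {
      if (fs$kind == "additive")
        feedback_fn("additive", "step", onset = fs$onset,
                    amplitude = fs$amplitude, width = width)
      else
        feedback_fn("multiplicative", "step", onset = fs$onset,
                    ratio = fs$ratio, width = width)
    }
    fb <- list()
    for (i in subunits) {
      slot <- if (fs$kind == "additive") sprintf("g%d_add", i)
              else sprintf("g%d_mult", i)
      fb[[slot]] <- g()
    }
  }
  two_layer_model(spec$f1, spec$f2, spec$f3, feedback = fb,
                  ranges = spec$ranges, cap = spec$cap)
}

#' Sample a response surface from a model
#'
#' Evaluates a model (or adapter) on a regular grid over its input
#' rectangle, optionally adds Gaussian response noise, and applies the
#' response cap (values above the cap are reported as the cap, emulating the
#' cutoff at the spike threshold).  With `noise = 0` the table is fully
#' deterministic; with noise, the caller's RNG state is left untouched.
#'
#' @param model A `"two_layer_model"`, `"point_neuron_model"` or
#'   [response_adapter()].
#' @param grid Length-1 or -2 integer grid resolution (default 64 per axis,
#'   minimum 4).
#' @param noise Gaussian noise standard deviation (response units).
#' @param seed Seed used for the noise draw.
#' @param cap Response cap; defaults to the model's own.
#' @return Data frame with columns `s1`, `s2`, `r` (row-major in `s1` then
#'   `s2`), with the grid axes as attributes.
#' @export
sample_surface <- function(model, grid = c(64L, 64L), noise = 0, seed = 1L,
                           cap = NULL) {
  grid <- rep_len(as.integer(grid), 2L)
  if (any(grid < 4L)) stop("grid must be at least 4 per axis", call. = FALSE)
  rg <- input_ranges(model)
  s1 <- seq(rg[1, 1], rg[1, 2], length.out = grid[1])
  s2 <- seq(rg[2, 1], rg[2, 2], length.out = grid[2])
  gr <- expand.grid(s1 = s1, s2 = s2, KEEP.OUT.ATTRS = FALSE)
  r <- predict(model, newdata = gr)
  r <- as.numeric(r)
  if (noise > 0) {
    r <- r + with_local_seed(seed, stats::rnorm(length(r), sd = noise))
  }
  cap <- cap %||% model$cap
  if (!is.null(cap)) r <- pmin(r, cap)
  out <- data.frame(s1 = gr$s1, s2 = gr$s2, r = r)
  out <- out[order(out$s1, out$s2), ]
  rownames(out) <- NULL
  attr(out, "axes") <- list(s1 = s1, s2 = s2)
  attr(out, "cap") <- cap
  out
}

# run code with a temporary seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Run a full scenario: model, samples, fitted surface
#'
#' Convenience wrapper: instantiates the scenario's model, samples its grid
#' and fits the interpolating surface (with the scenario's cap).
#'
#' @param spec A [scenario_spec()].
#' @param grid Optional grid override.
#' @return List with `model`, `samples`, `surface`, `spec`.
#' @export
realize_scenario <- function(spec, grid = NULL) {
  model <- make_model(spec)
  samples <- sample_surface(model, grid = grid %||% spec$grid,
                            noise = spec$noise, seed = spec$seed)
  surface <- fit_surface(samples,
                         smoothing = if (spec$noise > 0) 0.6 else 0,
                         cap = attr(samples, "cap"))
  list(model = model, samples = samples, surface = surface, spec = spec)
}

#' Canonical synthetic benchmark scenarios
#'
#' The named ground-truth scenario set used to validate every stage of the
#' identification pipeline on artificial data:
#' \describe{
#'   \item{`ff_supralinear`}{feedforward model with two supralinear
#'     (sigmoid-saturating) subunits and a saturating output stage — the
#'     canonical positive case for the feedforward identification.}
#'   \item{`ff_asymmetric`}{feedforward with one supralinear and one linear
#'     subunit; also serves as the null probe for wrongly assumed feedback.}
#'   \item{`ff_sublinear`}{feedforward with a sublinear (saturating)
#'     subunit.}
#'   \item{`ff_null_probe`}{feedforward model sampled under the same study
#'     conditions (cap, training levels) as the feedback scenarios; used to
#'     probe that wrongly assumed feedback is rejected.}
#'   \item{`fb_step_additive`}{two-layer model with positive step-shaped
#'     additive feedback (amplitude 8% of the input range) switching on
#'     between the default L and H training levels.}
#'   \item{`fb_step_multiplicative`}{same construction with multiplicative
#'     step feedback of ratio 1.1.}
#'   \item{`point_linear`}{point-neuron model with weights (1, 2) and a
#'     saturating output stage.}
#' }
#' All scenarios are deterministic (noise 0, fixed seeds); the feedback
#' onset levels sit between the default training levels so that the
#' low-response regime remains feedback-free.
#'
#' @return Named list of [scenario_spec()]s.
#' @export
make_paper_scenarios <- function() {
  sig <- function(og, amp, ctr, wd)
    subunit_fn("sigmoid", onset_gain = og, amplitude = amp, center = ctr,
               width = wd, domain = c(-0.6, 1.9))
  # supralinear pair: linear onsets with steep saturating rises around
  # mid-range, the shape class of NMDA-dominated branches
  f1_supra <- sig(0.4, 0.9, 0.55, 0.10)
  f2_supra <- sig(0.35, 0.75, 0.45, 0.09)
  pow3 <- function() subunit_fn("power", exponent = 1.3, domain = c(0, 8))
  sat3 <- function() subunit_fn("saturating", gain = 3, half = 4,
                                domain = c(-2, 8))
  # feedback scenarios: spike-threshold cap at 70% of the attainable
  # feedforward range (so the test curve crosses the steep mid-range),
  # step onset at 75% of the usable (sub-cap) span -- between the H and T
  # levels -- and training levels close together (their curve separation is
  # then about 14% of the stimulus range)
  ff_base <- two_layer_model(f1_supra, f2_supra)
  rr <- range(eval_feedforward(ff_base, c(0, 1, 0, 1), c(0, 0, 1, 1)))
  cap_fb <- rr[1] + 0.70 * diff(rr)
  onset_fb <- rr[1] + 0.75 * 0.70 * diff(rr)
  ramp_fb <- 0.05 * diff(rr)
  fr_fb <- c(0.55, 0.65, 0.95)
  specs <- list(
    scenario_spec("ff_supralinear", "feedforward",
                  f1 = f1_supra, f2 = f2_supra,
                  f3 = pow3(), seed = 101L),
    scenario_spec("ff_asymmetric", "feedforward",
                  f1 = sig(0.6, 0.6, 0.5, 0.12),
                  f2 = subunit_fn("linear", gain = 0.9, domain = c(-0.6, 1.9)),
                  f3 = sat3(), seed = 102L),
    scenario_spec("ff_sublinear", "feedforward",
                  f1 = subunit_fn("saturating", gain = 2, half = 0.8,
                                  domain = c(0, 1.9)),
                  f2 = subunit_fn("linear", gain = 1, domain = c(-0.6, 1.9)),
                  f3 = NULL, seed = 103L),
    scenario_spec("ff_null_probe", "feedforward",
                  f1 = f1_supra, f2 = f2_supra, f3 = NULL,
                  cap = cap_fb, fractions = fr_fb, seed = 107L),
    scenario_spec("fb_step_additive", "feedback",
                  f1 = f1_supra, f2 = f2_supra, f3 = NULL,
                  feedback = list(kind = "additive", onset = onset_fb,
                                  amplitude = 0.09, width = ramp_fb),
                  cap = cap_fb, fractions = fr_fb, grid = 128L,
                  seed = 104L),
    scenario_spec("fb_step_multiplicative", "feedback",
                  f1 = f1_supra, f2 = f2_supra, f3 = NULL,
                  feedback = list(kind = "multiplicative", onset = onset_fb,
                                  ratio = 1.2, width = ramp_fb),
                  cap = cap_fb, fractions = fr_fb, grid = 128L,
                  seed = 105L),
    scenario_spec("point_linear", "point", w = c(1, 2), f3 = pow3(),
                  seed = 106L)
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}
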
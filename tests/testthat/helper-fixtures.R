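# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# realized benchmark scenario (model + samples + fitted surface)
get_realized <- function(name) {
  key <- paste0("rz_", name)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- realize_scenario(make_paper_scenarios()[[name]])
  }
  .fixtures[[key]]
}

# curve triplet for a scenario, at the scenario's own level fractions
get_triplet <- function(name) {
  key <- paste0("tri_", name)
  if (is.null(.fixtures[[key]])) {
    rz <- get_realized(name)
    .fixtures[[key]] <- suppressMessages(
      select_triplet(rz$surface, fractions = rz$spec$fractions))
  }
  .fixtures[[key]]
}

# full feedforward fit for a scenario
get_fit <- function(name) {
  key <- paste0("fit_", name)
  if (is.null(.fixtures[[key]])) {
    rz <- get_realized(name)
    .fixtures[[key]] <- suppressMessages(
      fit_two_layer(rz$surface, fractions = rz$spec$fractions,
                    feedback = "none"))
  }
  .fixtures[[key]]
}

# feedback identification for a scenario and mode
get_feedback <- function(name, mode) {
  key <- paste0("fb_", name, "_", mode)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- identify_feedback(get_triplet(name), mode = mode)
  }
  .fixtures[[key]]
}

# exact identifiable feedback deltas of a scenario at the extracted levels:
# differences (additive) or ratios (multiplicative) of the generator's
# feedback function between each curve's level and the reference level L
true_deltas <- function(name) {
  rz <- get_realized(name)
  tri <- get_triplet(name)
  fbk <- rz$spec$truth$feedback_kind
  slot <- if (fbk == "additive") "g1_add" else "g1_mult"
  g <- rz$model$feedback[[slot]]$fun
  lv <- tri$levels
  if (fbk == "additive") {
    c(H = unname(g(lv["H"]) - g(lv["L"])), T = unname(g(lv["T"]) - g(lv["L"])))
  } else {
    c(H = unname(g(lv["H"]) / g(lv["L"])), T = unname(g(lv["T"]) / g(lv["L"])))
  }
}

# uncapped separable surface (identity output stage) over the benchmark's
# supralinear subunit pair, plus its raw sample table
get_separable <- function() {
  if (is.null(.fixtures$separable)) {
    sp <- make_paper_scenarios()$ff_null_probe
    m <- two_layer_model(sp$f1, sp$f2)
    sam <- sample_surface(m, grid = 64)
    .fixtures$separable <- list(model = m, samples = sam,
                                surface = fit_surface(sam))
  }
  .fixtures$separable
}

# iso-response curve built from an analytic parametrization s2 = fun(s1)
analytic_curve <- function(fun, s1_range, level, n = 401L) {
  s1 <- seq(s1_range[1], s1_range[2], length.out = n)
  iso_curve(s1, fun(s1), level = level)
}

# the r = s1^2 + s2 test surface on [0,1]^2
quad_surface <- function(grid = 64L) {
  if (is.null(.fixtures$quad)) {
    m <- two_layer_model(subunit_fn("power", exponent = 2),
                         subunit_fn("linear"))
    .fixtures$quad <- fit_surface(sample_surface(m, grid = grid))
  }
  .fixtures$quad
}
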
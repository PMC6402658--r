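# Model classes: subunit families, feedforward/feedback/point evaluation.

test_that("subunit families are monotone and respect their domains", {
  fams <- list(
    subunit_fn("linear", gain = 2),
    subunit_fn("power", gain = 1.5, exponent = 2),
    subunit_fn("power", exponent = 0.5),
    subunit_fn("sigmoid", onset_gain = 0.3, amplitude = 1, center = 0.5,
               width = 0.1),
    subunit_fn("saturating", gain = 2, half = 0.7),
    subunit_fn("table", s = c(0, 0.3, 0.7, 1), f = c(0, 0.2, 0.8, 1))
  )
  s <- seq(0, 1, length.out = 101)
  for (f in fams) {
    v <- eval_subunit(f, s)
    expect_true(all(diff(v) >= 0), info = f$family)
    expect_error(eval_subunit(f, f$domain[2] + 0.5), "domain")
  }
  expect_error(subunit_fn("table", s = c(0, 0.5, 0.5), f = c(0, 1, 2)),
               "strictly ordered")
  expect_error(subunit_fn("table", s = c(0, 0.5, 1), f = c(0, 1, 0.5)),
               "non-decreasing")
})

test_that("feedforward evaluation composes the cascade", {
  id <- subunit_fn("linear", domain = c(-1, 2))
  m_id <- two_layer_model(id, id)
  expect_equal(eval_feedforward(m_id, 0.3, 0.2), 0.5)
  # zero-anchored subunits give a zero response at the origin
  m0 <- two_layer_model(subunit_fn("power", exponent = 2),
                        subunit_fn("sigmoid", onset_gain = 0.5,
                                   amplitude = 0, center = 0.5, width = 0.1))
  expect_equal(eval_feedforward(m0, 0, 0), 0)
  # hand-evaluated composition: f1 = s^2, f2 = 2s, f3 = m/(1 + m)
  sat <- subunit_fn("saturating", gain = 1, half = 1, domain = c(0, 4))
  m <- two_layer_model(subunit_fn("power", exponent = 2),
                       subunit_fn("linear", gain = 2), sat)
  expect_equal(eval_feedforward(m, 0.5, 0.25), 0.75 / 1.75, tolerance = 1e-12)
  expect_error(eval_feedforward(m, 1.5, 0), "rectangle")
})

test_that("feedforward response increases along both axes", {
  rz <- get_realized("ff_supralinear")
  s <- seq(0, 1, length.out = 21)
  for (fixed in c(0.2, 0.7)) {
    expect_true(all(diff(eval_feedforward(rz$model, s, fixed)) > 0))
    expect_true(all(diff(eval_feedforward(rz$model, fixed, s)) > 0))
  }
})

test_that("identity feedback reduces exactly to the feedforward model", {
  id <- subunit_fn("linear", domain = c(-2, 3))
  fb <- list(g1_add = feedback_fn("additive", "none"),
             g2_mult = feedback_fn("multiplicative", "none"))
  m <- two_layer_model(subunit_fn("power", exponent = 2), id,
                       feedback = fb)
  # all-identity feedback is normalized away at construction
  expect_null(m$feedback)
  set.seed(7)
  s1 <- runif(20); s2 <- runif(20)
  expect_equal(as.numeric(predict(m, s1 = s1, s2 = s2)),
               eval_subunit(m$f3, s1^2 + s2))
})

test_that("linear additive feedback reaches its closed-form fixed point", {
  id <- subunit_fn("linear", domain = c(-10, 10))
  lin_fb <- function() {
    structure(list(kind = "additive", family = "custom",
                   params = list(slope = 0.25),
                   fun = function(r) 0.25 * r),
              class = "feedback_fn")
  }
  m <- two_layer_model(id, id, id,
                       feedback = list(g1_add = lin_fb(), g2_add = lin_fb()))
  # r = s1 + s2 + 0.5 r  =>  r = (s1 + s2) / 0.5
  r <- eval_feedback(m, 0.25, 0.25)
  expect_equal(as.numeric(r), 1, tolerance = 1e-9)
  expect_lt(attr(r, "residual"), 1e-9)
})

test_that("step-feedback responses agree with a bisection oracle", {
  rz <- get_realized("fb_step_additive")
  m <- rz$model
  set.seed(11)
  s1 <- runif(15); s2 <- runif(15)
  r_solver <- eval_feedback(m, s1, s2, tol = 1e-12)
  g1 <- m$feedback$g1_add$fun; g2 <- m$feedback$g2_add$fun
  oracle <- vapply(seq_along(s1), function(i) {
    phi <- function(r) {
      eval_subunit(m$f3,
                   eval_subunit(m$f1, s1[i] + g1(r)) +
                   eval_subunit(m$f2, s2[i] + g2(r))) - r
    }
    uniroot(phi, c(0, 10), tol = 1e-12)$root
  }, 0)
  expect_equal(as.numeric(r_solver), oracle, tolerance = 1e-8)
  # returned responses satisfy the implicit equation
  resid <- abs(eval_subunit(m$f3,
                            eval_subunit(m$f1, s1 + g1(r_solver)) +
                            eval_subunit(m$f2, s2 + g2(r_solver))) - r_solver)
  expect_lt(max(resid), 1e-9)
})

test_that("point-neuron evaluation is a weighted sum through f3", {
  id <- subunit_fn("linear", domain = c(-1, 5))
  pn <- point_neuron_model(1, 1, id)
  expect_equal(eval_point_neuron(pn, 0.4, 0.1), 0.5)
  # degenerate weight: output independent of s2
  pn0 <- point_neuron_model(2, 0, id)
  expect_equal(eval_point_neuron(pn0, 0.3, seq(0, 1, 0.25)),
               rep(0.6, 5))
  sq <- subunit_fn("power", exponent = 2, domain = c(0, 5))
  pn2 <- point_neuron_model(1, 3, sq)
  expect_equal(eval_point_neuron(pn2, 0.2, 0.1), 0.25)
  expect_error(point_neuron_model(-1, 1), "non-negative")
})

test_that("model JSON round trip is byte-stable and value-preserving", {
  rz <- get_realized("fb_step_additive")
  p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".json")
  write_model_json(rz$model, p1)
  m2 <- read_model_json(p1)
  write_model_json(m2, p2)
  expect_identical(readLines(p1), readLines(p2))
  set.seed(3)
  s1 <- runif(10); s2 <- runif(10)
  expect_equal(as.numeric(predict(m2, s1 = s1, s2 = s2)),
               as.numeric(predict(rz$model, s1 = s1, s2 = s2)),
               tolerance = 1e-10)
  # point-neuron round trip
  pn <- point_neuron_model(1, 2, subunit_fn("power", exponent = 1.3,
                                            domain = c(0, 8)))
  p3 <- tempfile(fileext = ".json")
  write_model_json(pn, p3)
  pn2 <- read_model_json(p3)
  expect_equal(eval_point_neuron(pn2, 0.4, 0.3),
               eval_point_neuron(pn, 0.4, 0.3))
})
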
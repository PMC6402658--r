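# Feedback-delta transforms, brute-force identification, summaries.

test_that("curve transforms follow the per-axis affine map", {
  line <- analytic_curve(function(x) 1 - x, c(0, 1), 1.0, n = 101)
  # identity deltas return the curve unchanged
  t0 <- transform_curve(line, feedback_deltas())
  expect_equal(t0$points, line$points, tolerance = 1e-12)
  # pure shifts: s2 = 1 + a + b - s1
  a <- 0.07; b <- -0.03
  ts <- transform_curve(line, feedback_deltas(add1 = a, add2 = b))
  expect_equal(curve_s2(ts, ts$points[, 1]),
               1 + a + b - ts$points[, 1], tolerance = 1e-10)
  # pure scaling against a direct substitution oracle
  k <- 1.15
  tk <- transform_curve(line, feedback_deltas(mult1 = k, mult2 = k))
  xs <- tk$points[, 1]
  expect_equal(curve_s2(tk, xs), k * (1 - xs / k), tolerance = 1e-10)
  # declared domain rectangle is enforced
  expect_error(transform_curve(line, feedback_deltas(add1 = 0.5),
                               domain = rbind(c(0, 1), c(0, 1))),
               "domain")
})

test_that("null data recovers identity deltas in every mode", {
  for (mode in c("additive", "multiplicative")) {
    fb <- get_feedback("ff_null_probe", mode)
    if (mode == "additive") {
      expect_equal(fb$deltas_H$add1, 0)
      expect_equal(fb$deltas_T$add1, 0)
    } else {
      expect_equal(fb$deltas_H$mult1, 1)
      expect_equal(fb$deltas_T$mult1, 1)
    }
    expect_lt(fb$sigma_m2, 1e-4)
  }
})

test_that("wrongly assumed feedback strength increases the error", {
  # on feedforward data the error grows monotonically with the assumed
  # (tied) additive strength away from zero
  fb <- get_feedback("ff_null_probe", "additive")
  eg <- fb$error_grid
  sym <- eg[abs(eg$h1 - eg$t1) < 1e-9 & !is.na(eg$sigma_m2), ]
  e0 <- sym$sigma_m2[abs(sym$h1) < 1e-9]
  for (d in c(0.05, -0.05, 0.1, 0.15)) {
    ed <- sym$sigma_m2[abs(sym$h1 - d) < 1e-9]
    if (length(ed)) expect_gt(ed, 20 * e0)
  }
})

test_that("step additive feedback is recovered within one grid step", {
  fb <- get_feedback("fb_step_additive", "additive")
  truth <- true_deltas("fb_step_additive")
  expect_lt(abs(fb$deltas_H$add1 - truth["H"]), 0.01 + 1e-9)
  expect_lt(abs(fb$deltas_T$add1 - truth["T"]), 0.01 + 1e-9)
  expect_lt(fb$sigma_m2, 0.04)
  # the delta is positive: curves moved closer together
  expect_gt(fb$deltas_T$add1, 0)
})

test_that("step multiplicative feedback is recovered within one grid step", {
  fb <- get_feedback("fb_step_multiplicative", "multiplicative")
  truth <- true_deltas("fb_step_multiplicative")
  expect_lt(abs(fb$deltas_H$mult1 - truth["H"]), 0.01 + 1e-9)
  expect_lt(abs(fb$deltas_T$mult1 - truth["T"]), 0.01 + 1e-9)
  expect_lt(fb$sigma_m2, 0.04)
})

test_that("the wrong feedback kind leaves a clearly larger residual", {
  right_m <- get_feedback("fb_step_multiplicative", "multiplicative")$sigma_m2
  wrong_m <- get_feedback("fb_step_multiplicative", "additive")$sigma_m2
  expect_gt(wrong_m, 10 * right_m)
  right_a <- get_feedback("fb_step_additive", "additive")$sigma_m2
  wrong_a <- get_feedback("fb_step_additive", "multiplicative")$sigma_m2
  expect_gt(wrong_a, 5 * right_a)
})

test_that("enlarging the search grid never increases the minimal error", {
  tri <- get_triplet("ff_null_probe")
  small <- identify_feedback(tri, "additive",
                             grid = feedback_grid(additive = seq(-0.05, 0.05,
                                                                 0.01)))
  big <- get_feedback("ff_null_probe", "additive")
  expect_lte(big$sigma_m2, small$sigma_m2 + 1e-12)
})

test_that("positive-only grids and argument errors behave", {
  g <- feedback_grid(positive_only = TRUE)
  expect_true(all(g$additive >= 0))
  expect_error(feedback_grid(additive = numeric(0)), "empty")
  expect_error(feedback_grid(multiplicative = c(-1, 1)), "positive")
})

test_that("feedback strengths are summarized in input-range units", {
  s <- summarize_feedback(feedback_deltas(add1 = 0.1, add2 = 0.1))
  expect_equal(s$value[s$kind == "additive"], c(10, 10))
  s0 <- summarize_feedback(feedback_deltas())
  expect_equal(s0$value, c(0, 0, 1, 1))
  s2 <- summarize_feedback(feedback_deltas(add1 = 0.05),
                           input_range = c(0, 0.5))
  expect_equal(s2$value[1], 10)
  # training-curve separation context
  tri <- get_triplet("fb_step_additive")
  s3 <- summarize_feedback(feedback_deltas(), triplet = tri)
  expect_true(attr(s3, "training_separation_pct") > 5 &&
              attr(s3, "training_separation_pct") < 30)
})

test_that("per-subunit (untied) search still recovers the null on a small grid", {
  tri <- get_triplet("ff_null_probe")
  fb <- identify_feedback(tri, "additive",
                          grid = feedback_grid(additive = seq(-0.02, 0.02,
                                                              0.01),
                                               tie_subunits = FALSE,
                                               coarse = 2L))
  expect_equal(fb$deltas_H$add1, 0)
  expect_equal(fb$deltas_H$add2, 0)
  expect_equal(fb$deltas_T$add1, 0)
  expect_lt(fb$sigma_m2, 1e-4)
})

test_that("combined mode keeps additive deltas for additive-feedback data", {
  fb <- identify_feedback(get_triplet("fb_step_additive"), "both")
  truth <- true_deltas("fb_step_additive")
  expect_identical(fb$mode, "both")
  expect_lt(abs(fb$deltas_T$add1 - truth["T"]), 0.01 + 1e-9)
  expect_lt(fb$sigma_m2, 0.04)
  expect_false(is.null(fb$additive_only))
})
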
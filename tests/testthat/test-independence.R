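# Gradient-angle test of subunit independence.

test_that("baseline-line gradients match analytic derivatives", {
  g <- expand.grid(s1 = seq(0, 1, length.out = 16),
                   s2 = seq(0, 1, length.out = 16))
  g$r <- g$s1 + 2 * g$s2
  plane <- fit_surface(g)
  gl <- gradients_on_lines(plane)
  expect_lt(max(abs(gl$line1$d1 - 1)), 1e-8)
  expect_lt(max(abs(gl$line1$d2 - 2)), 1e-8)
  expect_lt(max(abs(gl$line2$tan_alpha - 2)), 1e-8)

  gl2 <- gradients_on_lines(quad_surface(), s2_low = 0.1)
  expect_lt(max(abs(gl2$line1$d1 - 2 * gl2$line1$s1)), 1e-6)
  expect_lt(max(abs(gl2$line1$d2 - 1)), 1e-6)

  flat <- expand.grid(s1 = seq(0, 1, length.out = 8),
                      s2 = seq(0, 1, length.out = 8))
  flat$r <- rep(2, nrow(flat))
  expect_error(gradients_on_lines(fit_surface(flat)), "degenerate")
})

test_that("the rectangle angle identity predicts the fourth corner", {
  expect_equal(predict_angle(pi / 4, pi / 4, pi / 4), pi / 4)
  expect_equal(predict_angle(atan(1), atan(2), atan(4)), atan(2),
               tolerance = 1e-12)
  expect_error(predict_angle(pi / 4, 0, pi / 4), "vanishes")
})

test_that("the angle identity is exact on separable surfaces", {
  # additive surface: exact through the interpolant
  im0 <- independence_error_map(get_separable()$surface, resolution = 32)
  expect_lt(im0$max_error, 1e-6)
  # random separable rectangles, straight from a model via finite differences
  m <- get_realized("ff_supralinear")$model
  set.seed(5)
  pts <- matrix(runif(40, 0.05, 0.95), ncol = 4)
  for (k in seq_len(nrow(pts))) {
    a <- pts[k, 1]; c <- pts[k, 2]; ylo <- pts[k, 3]; yhi <- pts[k, 4]
    tanat <- function(x, y)
      gradient_samples(m, x, y)$tan_alpha
    aD <- atan(tanat(c, yhi))
    aD_pred <- predict_angle(atan(tanat(a, yhi)), atan(tanat(a, ylo)),
                             atan(tanat(c, ylo)))
    expect_equal(aD, aD_pred, tolerance = 1e-6)
  }
})

test_that("a point-neuron surface has constant angles and a zero map", {
  pn <- point_neuron_model(1, 2)   # identity output stage
  imp <- independence_error_map(fit_surface(sample_surface(pn, grid = 32)),
                                resolution = 16)
  expect_lt(imp$max_error, 1e-8)
})

test_that("the error map is invariant under monotone response re-mapping", {
  sep <- get_separable()
  im0 <- independence_error_map(sep$surface, resolution = 16)
  sam <- sep$samples
  sam$r <- sam$r^3 + 2 * sam$r          # strictly increasing remap
  imr <- independence_error_map(fit_surface(sam), resolution = 16)
  expect_lt(max(abs(imr$error - im0$error)), 1e-4)
})

test_that("feedback creates failures only above the onset response", {
  rz <- get_realized("fb_step_additive")
  surf <- rz$surface
  im <- independence_error_map(surf, resolution = 24)
  r_at <- outer(im$s1, im$s2, function(x, y) predict(surf, s1 = x, s2 = y))
  onset <- rz$spec$feedback$onset
  ramp <- rz$spec$feedback$width
  high <- im$error > 0.05
  expect_true(any(high))
  # every failure sits where the response reached the feedback ramp
  expect_true(all(r_at[high] > onset - 3 * ramp))
  # the low-response regime stays separable
  low <- r_at < onset - 4 * ramp
  expect_lt(max(im$error[low]), 0.05)
})
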
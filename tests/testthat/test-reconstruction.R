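# Stairway and basis identification, test-curve prediction, error measures,
# point-neuron baseline, output-stage reconstruction.

test_that("stairways alternate between the two curves as constructed", {
  # curves of r = s1^2 + s2 at levels 0.5 and 1.0
  L <- analytic_curve(function(x) 0.5 - x^2, c(0, sqrt(0.5)), 0.5)
  H <- analytic_curve(function(x) 1.0 - x^2, c(0, 1), 1.0)
  st <- build_stairway(L, H, start_s1 = 0, n = 5)
  expect_equal(st$s1_nodes, c(0, sqrt(0.5), 1), tolerance = 1e-6)
  expect_equal(st$s2_nodes, c(1, 0.5, 0), tolerance = 1e-6)
  expect_false(st$truncated)
  # parallel lines: equidistant s1 nodes
  Ll <- analytic_curve(function(x) 0.5 - x, c(0, 0.5), 0.5)
  Hl <- analytic_curve(function(x) 1.0 - x, c(0, 1), 1.0)
  stl <- build_stairway(Ll, Hl, start_s1 = 0, n = 5)
  expect_equal(stl$s1_nodes, c(0, 0.5, 1), tolerance = 1e-9)
  expect_error(build_stairway(Ll, Hl, start_s1 = 0.9, n = 5), "interval")
})

test_that("stairway reconstruction pins subunit values up to an affine map", {
  L <- analytic_curve(function(x) 0.5 - x^2, c(0, sqrt(0.5)), 0.5)
  H <- analytic_curve(function(x) 1.0 - x^2, c(0, 1), 1.0)
  rec <- reconstruct_stairway(L, H, build_stairway(L, H, start_s1 = 0, n = 5))
  f1_nodes <- rec$f1_hat$params$f
  expect_equal(diff(f1_nodes), c(1, 1))           # one gauge unit per rung
  expect_equal(rec$m_H - rec$m_L, 1)
  # truth f1 = s^2 at the nodes, up to the affine gauge: increments of the
  # truth are equal too (0.5, 0.5), so the gauge map is exact
  truth <- rec$f1_hat$params$s^2
  fit <- lm(truth ~ f1_nodes)
  expect_lt(max(abs(fitted(fit) - truth)), 1e-6)
  # linear ground truth stays linear in the nodes
  Ll <- analytic_curve(function(x) 0.5 - x, c(0, 0.5), 0.5)
  Hl <- analytic_curve(function(x) 1.0 - x, c(0, 1), 1.0)
  recl <- reconstruct_stairway(Ll, Hl,
                               build_stairway(Ll, Hl, start_s1 = 0, n = 7))
  expect_lt(max(abs(diff(recl$f1_hat$params$s) -
                    diff(recl$f1_hat$params$s)[1])), 1e-9)
})

test_that("sublinear subunits are recovered at stairway nodes", {
  # m = s1 + sqrt(s2): curves s2 = (m0 - s1)^2
  L <- analytic_curve(function(x) (1.0 - x)^2, c(0, 1 - 1e-9), 1.0, n = 801)
  H <- analytic_curve(function(x) (1.3 - x)^2, c(0.3 + 1e-9, 1), 1.3, n = 801)
  st <- build_stairway(L, H, n = 9)
  rec <- reconstruct_stairway(L, H, st)
  truth <- sqrt(rec$f2_hat$params$s)
  fit <- lm(truth ~ rec$f2_hat$params$f)
  expect_lt(max(abs(fitted(fit) - truth)), 1e-6)
})

test_that("basis reconstruction matches known subunits after gauge fit", {
  # identity model: lines; the fit is exact
  Ll <- analytic_curve(function(x) 0.5 - x, c(0, 0.5), 0.5, n = 101)
  Hl <- analytic_curve(function(x) 1.0 - x, c(0, 1), 1.0, n = 101)
  recl <- reconstruct_basis(Ll, Hl)
  expect_lt(recl$residual, 1e-10)
  expect_lt(affine_alignment_error(recl$f1_hat, function(x) x)$max_abs_error,
            1e-6)
  # quadratic/linear model through the full extraction pipeline
  tri <- suppressMessages(select_triplet(quad_surface()))
  rec <- reconstruct_basis(tri$L, tri$H)
  expect_lt(affine_alignment_error(rec$f1_hat,
                                   function(x) x^2)$max_abs_error, 1e-3)
  expect_lt(affine_alignment_error(rec$f2_hat,
                                   function(x) x)$max_abs_error, 1e-3)
  # an underdetermined basis is refused
  expect_error(reconstruct_basis(analytic_curve(function(x) 0.5 - x,
                                                c(0, 0.5), 0.5, n = 10),
                                 analytic_curve(function(x) 1 - x,
                                                c(0, 1), 1.0, n = 10),
                                 knots = 100),
               "underdetermined")
})

test_that("basis and stairway reconstructions agree on stairway nodes", {
  Ll <- analytic_curve(function(x) 0.5 - x, c(0, 0.5), 0.5, n = 101)
  Hl <- analytic_curve(function(x) 1.0 - x, c(0, 1), 1.0, n = 101)
  st <- build_stairway(Ll, Hl, n = 5)
  rec_s <- reconstruct_stairway(Ll, Hl, st)
  rec_b <- reconstruct_basis(Ll, Hl)
  vb <- eval_subunit(rec_b$f1_hat, st$s1_nodes)
  vs <- rec_s$f1_hat$params$f
  fit <- lm(vb ~ vs)
  expect_lt(max(abs(fitted(fit) - vb)), 1e-6)
})

test_that("the drive refuses extrapolation outside coverage", {
  tri <- suppressMessages(select_triplet(quad_surface()))
  rec <- reconstruct_basis(tri$L, tri$H)
  expect_error(drive(rec, rec$f1_hat$domain[2] + 0.5, 0.2), "domain")
})

test_that("predicted test curves match observation iff the model is two-layer", {
  # feedforward data: predicted and observed test curves coincide
  fitq <- suppressMessages(fit_two_layer(quad_surface(), feedback = "none"))
  obsq <- fitq$triplet$T; predq <- fitq$predicted_T
  xq <- seq(max(obsq$s1_range[1], predq$s1_range[1]) + 1e-6,
            min(obsq$s1_range[2], predq$s1_range[2]) - 1e-6,
            length.out = 51)
  expect_lt(max(abs(curve_s2(predq, xq) - curve_s2(obsq, xq))), 1e-3)
  fit <- get_fit("ff_supralinear")
  obs <- fit$triplet$T; pred <- fit$predicted_T
  xs <- seq(max(obs$s1_range[1], pred$s1_range[1]) + 1e-6,
            min(obs$s1_range[2], pred$s1_range[2]) - 1e-6,
            length.out = 51)
  expect_lt(max(abs(curve_s2(pred, xs) - curve_s2(obs, xs))), 1e-2)
  # linear model: the predicted curve is a straight line of slope -w1/w2
  pfit <- get_fit("point_linear")
  pp <- pfit$predicted_T$points
  slopes <- diff(pp[, 2]) / diff(pp[, 1])
  expect_equal(slopes, rep(-0.5, length(slopes)), tolerance = 1e-3)
  # feedback data: prediction and observation diverge visibly
  ffit <- get_fit("fb_step_additive")
  obs2 <- ffit$triplet$T; pred2 <- ffit$predicted_T
  xs2 <- seq(max(obs2$s1_range[1], pred2$s1_range[1]) + 1e-6,
             min(obs2$s1_range[2], pred2$s1_range[2]) - 1e-6,
             length.out = 51)
  expect_gt(max(abs(curve_s2(pred2, xs2) - curve_s2(obs2, xs2))), 1e-4)
})

test_that("normalized error measures reproduce hand-computed values", {
  expect_equal(error_sigma_r2(c(0.9, 1.0, 1.1), r_L = 0, r_H = 1), 0.02 / 3)
  # variance is invariant under a constant offset
  expect_equal(error_sigma_r2(c(0.9, 1.0, 1.1) + 5, 0, 1), 0.02 / 3)
  expect_equal(error_sigma_r2(rep(0.7, 10), 0, 1), 0)
  expect_equal(error_sigma_m2(c(0.98, 1.0, 1.02), 0, 1), 0.0008 / 3)
  expect_equal(error_mse_r(c(0.9, 1.0, 1.1), r_T = 1.0, 0, 1), 0.02 / 3)
  # the MSE, unlike the variance, sees a constant bias
  expect_equal(error_mse_r(rep(1.1, 5), r_T = 1.0, 0, 1), 0.01)
  expect_equal(error_sigma_r2(rep(1.1, 5), 0, 1), 0)
  expect_error(error_sigma_r2(1:3, 1, 1), "normalization")
})

test_that("the point-neuron baseline recovers linear weights", {
  pfit <- get_fit("point_linear")
  pn <- pfit$point_fit
  expect_equal(pn$w2 / pn$w1, 2, tolerance = 1e-6)
  expect_lt(pn$sigma_m2, 1e-8)
  # supralinear data: the point neuron does worse than the two-layer model
  sfit <- get_fit("ff_supralinear")
  expect_gt(sfit$point_fit$sigma_m2, sfit$sigma_m2)
})

test_that("the output stage is recovered along the diagonal", {
  # nonlinear f3: predicted responses on the diagonal match the truth
  fit <- get_fit("ff_supralinear")
  expect_false(is.null(fit$f3_hat))
  surf <- get_realized("ff_supralinear")$surface
  dg <- seq(0.05, 0.95, length.out = 41)
  r_true <- predict(surf, s1 = dg, s2 = dg)
  r_pred <- predict(fit, data.frame(s1 = dg, s2 = dg), type = "response")
  expect_lt(max(abs(r_pred - r_true)) / diff(range(r_true)), 1e-3)
  # identity f3: the recovered map is affine in the drive
  fit0 <- get_fit("ff_sublinear")
  tab <- fit0$f3_hat$params
  aff <- lm(tab$f ~ tab$s)
  expect_lt(max(abs(fitted(aff) - tab$f)) / diff(range(tab$f)), 5e-3)
  # decreasing diagonal responses violate monotonicity
  rec <- fit$reconstruction
  bad <- data.frame(s = seq(0.1, 0.9, length.out = 20),
                    r = seq(1, 0.5, length.out = 20))
  expect_error(reconstruct_f3(rec, bad), "monotone")
})

test_that("sigma_m2 of the full pipeline is tiny on feedforward data", {
  fit <- get_fit("ff_supralinear")
  expect_lt(fit$sigma_m2, 1e-4)
  expect_identical(fit$decision, "feedforward two-layer adequate")
  # residuals method returns centered drive deviations
  expect_equal(mean(residuals(fit)), 0, tolerance = 1e-12)
  expect_equal(error_sigma_m2(residuals(fit) + 1, 0, 1), fit$sigma_m2)
})
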
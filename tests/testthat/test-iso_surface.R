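# Surface fitting, level-set extraction and triplet selection.

test_that("the interpolant reproduces smooth surfaces off-grid", {
  g <- expand.grid(s1 = seq(0, 1, length.out = 8),
                   s2 = seq(0, 1, length.out = 8))
  g$r <- g$s1 + g$s2
  surf <- fit_surface(g)
  set.seed(1)
  xs <- runif(50); ys <- runif(50)
  expect_lt(max(abs(predict(surf, s1 = xs, s2 = ys) - (xs + ys))), 1e-6)

  surf2 <- quad_surface()
  set.seed(2)
  xs <- runif(1000); ys <- runif(1000)
  expect_lt(max(abs(predict(surf2, s1 = xs, s2 = ys) - (xs^2 + ys))), 1e-6)
})

test_that("malformed grids are rejected with format errors", {
  row <- data.frame(s1 = seq(0, 1, 0.1), s2 = 0, r = seq(0, 1, 0.1))
  expect_error(fit_surface(row), "degenerate")
  g <- expand.grid(s1 = 0:7 / 7, s2 = 0:7 / 7)
  g$r <- g$s1 + g$s2
  expect_error(fit_surface(g[-5, ]), "rectangular")
  g$r[3] <- NaN
  expect_error(fit_surface(g), "finite")
})

test_that("analytic partial derivatives match the generating surface", {
  surf <- quad_surface()
  xs <- seq(0.1, 0.9, 0.1)
  gr <- surface_gradient(surf, xs, rev(xs))
  expect_equal(gr$d1, 2 * xs, tolerance = 1e-5)
  expect_equal(gr$d2, rep(1, length(xs)), tolerance = 1e-6)
})

test_that("level sets of simple surfaces are extracted exactly", {
  g <- expand.grid(s1 = seq(0, 1, length.out = 16),
                   s2 = seq(0, 1, length.out = 16))
  g$r <- g$s1 + g$s2
  plane <- fit_surface(g)
  cv <- extract_iso_curve(plane, 1.0)
  expect_equal(curve_s2(cv, 0.25), 0.75, tolerance = 1e-8)
  expect_lt(max(abs(cv$points[, 1] + cv$points[, 2] - 1)), 1e-8)

  cv2 <- extract_iso_curve(quad_surface(), 0.5)
  expect_equal(curve_s2(cv2, 0.5), 0.25, tolerance = 1e-6)
  # round trip through the generating model
  expect_lt(max(abs(cv2$points[, 1]^2 + cv2$points[, 2] - 0.5)), 1e-3)

  expect_error(extract_iso_curve(plane, 5), "outside")
})

test_that("degenerate (flat) surfaces are flagged and refused", {
  g <- expand.grid(s1 = seq(0, 1, length.out = 8),
                   s2 = seq(0, 1, length.out = 8))
  g$r <- rep(1, nrow(g))
  flat <- fit_surface(g)
  expect_true(flat$degenerate)
  expect_error(extract_iso_curve(flat, 1), "range|degenerate")
})

test_that("curve parametrizations are mutually consistent", {
  tri <- get_triplet("ff_supralinear")
  for (cv in list(tri$L, tri$H, tri$T)) {
    s1 <- seq(cv$s1_range[1], cv$s1_range[2], length.out = 41)
    back <- curve_s1(cv, curve_s2(cv, s1))
    expect_lt(max(abs(back - s1)), 1e-4)
    # arc length computed from either parametrization agrees to 0.1%
    s2 <- seq(cv$s2_range[1], cv$s2_range[2], length.out = 2001)
    x <- cv$inverse(s2)
    len_inv <- sum(sqrt(diff(x)^2 + diff(s2)^2))
    expect_lt(abs(len_inv - cv$arclength) / cv$arclength, 1e-3)
  }
})

test_that("higher-level curves lie above lower ones and extraction repeats", {
  tri <- get_triplet("ff_supralinear")
  shared <- c(max(tri$L$s1_range[1], tri$H$s1_range[1]),
              min(tri$L$s1_range[2], tri$H$s1_range[2]))
  xs <- seq(shared[1], shared[2], length.out = 33)
  expect_true(all(curve_s2(tri$H, xs) > curve_s2(tri$L, xs)))
  surf <- get_realized("ff_supralinear")$surface
  again <- extract_iso_curve(surf, tri$levels["H"])
  expect_equal(again$points, tri$H$points, tolerance = 1e-10)
})

test_that("triplet selection places levels and honors the length rule", {
  g <- expand.grid(s1 = seq(0, 1, length.out = 16),
                   s2 = seq(0, 1, length.out = 16))
  g$r <- g$s1 + g$s2
  plane <- fit_surface(g)
  tri <- select_triplet(plane, fractions = c(0.2, 0.35, 0.5))
  expect_equal(unname(tri$levels), 2 * c(0.2, 0.35, 0.5), tolerance = 1e-9)
  # parallel lines of slope -1 at the requested levels
  for (cv in list(tri$L, tri$H, tri$T))
    expect_lt(max(abs(rowSums(cv$points) - cv$level)), 1e-8)
  expect_error(select_triplet(plane, fractions = c(0.6, 0.3, 0.95)),
               "increasing")
  # strongly curved surface: top-level curve too short, level gets lowered
  expect_message(
    tri2 <- select_triplet(quad_surface(), fractions = c(0.3, 0.6, 0.95)),
    "lowered")
  expect_true(isTRUE(attr(tri2, "adjusted")))
  expect_gte(tri2$T$arclength,
             0.5 * min(tri2$L$arclength, tri2$H$arclength))
  expect_lt(tri2$levels["T"], 0.95 * 2)
})

test_that("capped surfaces restrict usable levels to below the cap", {
  rz <- get_realized("fb_step_additive")
  surf <- rz$surface
  expect_false(surf$degenerate)
  tri <- get_triplet("fb_step_additive")
  expect_lt(tri$levels["T"], surf$cap)
})
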
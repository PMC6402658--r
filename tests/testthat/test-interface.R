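# File formats, adapters, pipeline orchestration, CLI.

test_that("surface CSV round trips byte-identically", {
  sam <- sample_surface(make_model(make_paper_scenarios()$ff_sublinear),
                        grid = 8)
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_surface_csv(sam, p1)
  back <- read_surface_csv(p1)
  write_surface_csv(back, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_lt(max(abs(back$r - sam$r)), 1e-10)
})

test_that("malformed surface CSVs fail with located errors", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("s1,s2", "0,0", "0,1"), p)
  expect_error(read_surface_csv(p), "missing column.*r")
  writeLines(c("s1,s2,r", "0,0,1", "0,1"), p)
  expect_error(read_surface_csv(p), "line 3")
})

test_that("curve JSON preserves the level and every point", {
  cv <- analytic_curve(function(x) 1 - x^2, c(0, 1), 0.75, n = 31)
  p <- tempfile(fileext = ".json")
  write_curve_json(cv, p)
  back <- read_curve_json(p)
  expect_identical(back$level, cv$level)
  expect_identical(back$points, cv$points)
})

test_that("response adapters plug external callables into the pipeline", {
  ad <- response_adapter(function(s1, s2) (s1 + s2)^1.5)
  sam <- sample_surface(ad, grid = 32)
  fit <- suppressMessages(fit_two_layer(fit_surface(sam), feedback = "none"))
  expect_lt(fit$sigma_m2, 1e-5)
  expect_identical(fit$decision, "feedforward two-layer adequate")
})

test_that("the pipeline labels a feedforward scenario and writes reports", {
  out <- tempfile("pipe_ff_")
  res <- run_pipeline(list(scenario = "ff_supralinear", outdir = out,
                           feedback = "auto", independence = 12),
                      quiet = TRUE)
  expect_identical(res$summary$decision, "feedforward two-layer adequate")
  for (f in c("surface.csv", "curve_L.json", "curve_H.json", "curve_T.json",
              "reconstruction.json", "independence_map.csv", "summary.json"))
    expect_true(file.exists(file.path(out, f)), info = f)
  rep <- jsonlite::read_json(file.path(out, "reconstruction.json"),
                             simplifyVector = TRUE)
  expect_lt(rep$errors$sigma_m2, 0.04)
  # feedback report is not written when the search was not needed
  expect_false(file.exists(file.path(out, "feedback.json")))
})

test_that("the pipeline escalates to feedback on additive-feedback data", {
  out <- tempfile("pipe_fb_")
  res <- run_pipeline(list(scenario = "fb_step_additive", outdir = out,
                           feedback = "auto", independence = 0),
                      quiet = TRUE)
  expect_identical(res$summary$decision, "additive feedback required")
  fbrep <- jsonlite::read_json(file.path(out, "feedback.json"),
                               simplifyVector = TRUE)
  expect_lt(fbrep$sigma_m2, 0.04)
  expect_gt(fbrep$deltas_T$add1, 0.04)   # positive shift, several % of range
})

test_that("bad configurations fail cleanly before any computation", {
  out <- tempfile("pipe_bad_")
  expect_error(run_pipeline(list(surface = "does/not/exist.csv",
                                 outdir = out), quiet = TRUE),
               "does not exist")
  expect_error(run_pipeline(list(outdir = out), quiet = TRUE), "one of")
  expect_error(run_pipeline(list(scenario = "nope", outdir = out),
                            quiet = TRUE), "unknown scenario")
  expect_false(dir.exists(out))
})

test_that("the command-line front end synthesizes scenario bundles", {
  cli <- file.path(find.package("isoresponse"), "exec", "isoresponse")
  expect_true(file.exists(cli))
  out <- tempfile("cli_")
  status <- system2("Rscript",
                    c(cli, "synth", "--scenario", "ff_sublinear",
                      "--out", out, "--grid", "16", "--quiet"),
                    stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(out, "surface.csv")))
  expect_true(file.exists(file.path(out, "model.json")))
  truth <- jsonlite::read_json(file.path(out, "truth.json"),
                               simplifyVector = TRUE)
  expect_true(truth$separable)
})
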
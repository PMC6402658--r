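#' Run the full identification pipeline from a configuration
#'
#' Executes the complete analysis end to end: load or synthesize the
#' response surface, select the curve triplet, fit the point-neuron
#' baseline, reconstruct the subunit non-linearities and validate them on
#' the test curve, search for output feedback when the feedforward fit is
#' inadequate, compute the subunit-independence error map, and write all
#' machine-readable reports (surface CSV, curve JSONs, reconstruction
#' report, feedback report, independence map CSV, summary JSON) into the
#' output directory.  Every stage is logged to `stderr` unless `quiet`.
#'
#' @param config A named list, or a path to a YAML/JSON configuration file,
#'   with fields (all optional unless noted):
#'   \describe{
#'     \item{`scenario`}{name of a [make_paper_scenarios()] scenario, or}
#'     \item{`surface`}{path to a surface CSV, or}
#'     \item{`model`}{path to a model JSON (required: one of the three).}
#'     \item{`grid`}{sampling resolution for model inputs (default 64).}
#'     \item{`fractions`}{triplet level fractions (default 0.3, 0.6, 0.95).}
#'     \item{`knots`}{basis knots (default 21).}
#'     \item{`feedback`}{feedback search mode (default `"auto"`).}
#'     \item{`threshold`}{decision threshold (default 0.04).}
#'     \item{`independence`}{resolution of the error map (default 32; 0
#'       disables it).}
#'     \item{`outdir`}{output directory (required).}
#'     \item{`seed`}{seed forwarded to noisy sampling (default 1).}
#'   }
#' @param quiet Suppress progress logging.
#' @return Invisibly, a list with the fitted objects and the summary
#'   (also written as `summary.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(sprintf("configuration file '%s' does not exist", config),
           call. = FALSE)
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  log_msg <- function(...) if (!quiet) message(sprintf(...))
  outdir <- config$outdir %||% stop("config needs an 'outdir'", call. = FALSE)

  # resolve the input before creating any output
  src <- NULL
  if (!is.null(config$scenario)) {
    specs <- make_paper_scenarios()
    if (!config$scenario %in% names(specs))
      stop(sprintf("unknown scenario '%s'; available: %s", config$scenario,
                   paste(names(specs), collapse = ", ")), call. = FALSE)
    src <- list(kind = "scenario", spec = specs[[config$scenario]])
  } else if (!is.null(config$model)) {
    if (!file.exists(config$model))
      stop(sprintf("model file '%s' does not exist", config$model),
           call. = FALSE)
    src <- list(kind = "model", model = read_model_json(config$model))
  } else if (!is.null(config$surface)) {
    if (!file.exists(config$surface))
      stop(sprintf("surface file '%s' does not exist", config$surface),
           call. = FALSE)
    src <- list(kind = "surface", samples = read_surface_csv(config$surface))
  } else {
    stop("config needs one of 'scenario', 'model' or 'surface'", call. = FALSE)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  grid <- config$grid %||% 64L
  log_msg("stage 1/5: building the response surface")
  if (src$kind == "scenario") {
    rz <- realize_scenario(src$spec, grid = grid)
    surface <- rz$surface
    write_model_json(rz$model, file.path(outdir, "model.json"))
  } else if (src$kind == "model") {
    samples <- sample_surface(src$model, grid = grid,
                              seed = config$seed %||% 1L)
    surface <- fit_surface(samples, cap = attr(samples, "cap"))
  } else {
    surface <- fit_surface(src$samples,
                           smoothing = config$smoothing %||% 0)
  }
  write_surface_csv(surface, file.path(outdir, "surface.csv"))

  log_msg("stage 2/5: triplet selection and point-neuron baseline")
  fractions <- config$fractions %||%
    (if (src$kind == "scenario") src$spec$fractions else c(0.3, 0.6, 0.95))
  threshold <- config$threshold %||% two_layer_threshold()
  log_msg("stage 3/5: two-layer reconstruction and validation")
  fit <- fit_two_layer(surface, fractions = fractions,
                       knots = config$knots %||% 21L,
                       feedback = config$feedback %||% "auto",
                       threshold = threshold)
  for (nm in c("L", "H", "T"))
    write_curve_json(fit$triplet[[nm]],
                     file.path(outdir, sprintf("curve_%s.json", nm)))
  report <- list(
    gauge = fit$reconstruction$gauge,
    f1_hat = list(s = fit$reconstruction$f1_hat$params$s,
                  f = fit$reconstruction$f1_hat$params$f),
    f2_hat = list(s = fit$reconstruction$f2_hat$params$s,
                  f = fit$reconstruction$f2_hat$params$f),
    errors = list(sigma_m2 = fit$sigma_m2, sigma_r2 = fit$sigma_r2,
                  mse_r = fit$mse_r, K = fit$K),
    point_neuron = list(w1 = fit$point_fit$w1, w2 = fit$point_fit$w2,
                        sigma_m2 = fit$point_fit$sigma_m2),
    threshold = threshold,
    decision = fit$decision)
  jsonlite::write_json(drop_nulls(report),
                       file.path(outdir, "reconstruction.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (!is.null(fit$feedback)) {
    log_msg("stage 4/5: feedback identification (%s mode)",
            fit$feedback$mode)
    fb <- fit$feedback
    fb_report <- list(mode = fb$mode,
                      grid = list(additive = fb$grid$additive,
                                  multiplicative = fb$grid$multiplicative),
                      deltas_H = unclass(fb$deltas_H),
                      deltas_T = unclass(fb$deltas_T),
                      sigma_m2 = fb$sigma_m2,
                      n_feasible = fb$n_feasible,
                      n_discarded = fb$n_discarded)
    jsonlite::write_json(fb_report, file.path(outdir, "feedback.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    log_msg("stage 4/5: feedback search not required")
  }

  imap <- NULL
  ind_res <- config$independence %||% 32L
  if (ind_res > 0) {
    log_msg("stage 5/5: subunit-independence error map (%dx%d)",
            ind_res, ind_res)
    imap <- independence_error_map(surface, resolution = ind_res)
    utils::write.csv(
      data.frame(s1 = rep(imap$s1, times = length(imap$s2)),
                 s2 = rep(imap$s2, each = length(imap$s1)),
                 err = as.vector(imap$error)),
      file.path(outdir, "independence_map.csv"), row.names = FALSE)
  } else {
    log_msg("stage 5/5: independence map disabled")
  }

  summary <- list(decision = fit$decision,
                  sigma_m2 = fit$sigma_m2,
                  sigma_r2 = fit$sigma_r2,
                  point_neuron_sigma_m2 = fit$point_fit$sigma_m2,
                  feedback_sigma_m2 = if (!is.null(fit$feedback))
                    fit$feedback$sigma_m2 else NULL,
                  independence_max_error = if (!is.null(imap))
                    imap$max_error else NULL,
                  threshold = threshold)
  jsonlite::write_json(drop_nulls(summary),
                       file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("done: %s", fit$decision)
  invisible(list(fit = fit, surface = surface, independence = imap,
                 summary = summary))
}
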
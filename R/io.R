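#' Read and write response-surface grid tables
#'
#' Surfaces are exchanged as CSV with header `s1,s2,r`, one row per grid
#' node, ordered row-major in `s1` then `s2`, values at 12 significant
#' digits (below every tolerance used by the pipeline).  Reading validates
#' the header, rectangularity and finiteness, reporting the offending line
#' on malformed input; the round trip write-read-write is byte stable.
#'
#' @param x Data frame with columns `s1`, `s2`, `r` (e.g. from
#'   [sample_surface()]) or a `"response_surface"`.
#' @param path File path.
#' @return `read_surface_csv()` returns the grid data frame;
#'   `write_surface_csv()` returns `path` invisibly.
#' @export
write_surface_csv <- function(x, path) {
  if (inherits(x, "response_surface")) {
    x <- data.frame(s1 = rep(x$s1, times = length(x$s2)),
                    s2 = rep(x$s2, each = length(x$s1)),
                    r = as.vector(x$r))
    x <- x[order(x$s1, x$s2), ]
  }
  stopifnot(all(c("s1", "s2", "r") %in% names(x)))
  lines <- c("s1,s2,r",
             sprintf("%s,%s,%s",
                     formatC(x$s1, digits = 12, format = "g"),
                     formatC(x$s2, digits = 12, format = "g"),
                     formatC(x$r, digits = 12, format = "g")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_surface_csv
#' @export
read_surface_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("surface CSV is empty", call. = FALSE)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  missing_cols <- setdiff(c("s1", "s2", "r"), header)
  if (length(missing_cols))
    stop(sprintf("surface CSV header is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  parts <- strsplit(lines[-1], ",", fixed = TRUE)
  bad <- which(lengths(parts) != length(header))
  if (length(bad))
    stop(sprintf("ragged row at line %d of %s", bad[1] + 1L, path),
         call. = FALSE)
  mat <- matrix(as.numeric(unlist(parts)), ncol = length(header),
                byrow = TRUE, dimnames = list(NULL, header))
  if (any(!is.finite(mat))) {
    bad <- which(!stats::complete.cases(mat) | rowSums(!is.finite(mat)) > 0)[1]
    stop(sprintf("non-numeric value at line %d of %s", bad + 1L, path),
         call. = FALSE)
  }
  as.data.frame(mat)[, c("s1", "s2", "r")]
}

#' Read and write model descriptions as JSON
#'
#' Models are serialized with family tags and parameters for the subunit
#' functions, the output stage and any feedback, in a fixed canonical key
#' order so that save-load-save round trips are byte stable.
#'
#' @param model A `"two_layer_model"` or `"point_neuron_model"`.
#' @param path File path.
#' @return `read_model_json()` returns the reconstructed model;
#'   `write_model_json()` returns `path` invisibly.
#' @export
write_model_json <- function(model, path) {
  obj <- if (inherits(model, "point_neuron_model")) {
    list(type = "point_neuron",
         w = c(model$w1, model$w2),
         f3 = fn_to_list(model$f3),
         ranges = as.vector(model$ranges),
         cap = model$cap)
  } else if (inherits(model, "two_layer_model")) {
    list(type = "two_layer",
         f1 = fn_to_list(model$f1),
         f2 = fn_to_list(model$f2),
         f3 = fn_to_list(model$f3),
         feedback = if (is.null(model$feedback)) NULL
                    else lapply(model$feedback, fb_to_list),
         ranges = as.vector(model$ranges),
         cap = model$cap)
  } else stop("unsupported model class", call. = FALSE)
  jsonlite::write_json(drop_nulls(obj), path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

fn_to_list <- function(f) {
  ps <- f$params[!vapply(f$params, is.null, TRUE)]
  c(list(family = f$family), ps[order(names(ps))], list(domain = f$domain))
}

fb_to_list <- function(g) {
  ps <- g$params
  if (length(ps)) ps <- ps[order(names(ps))]
  c(list(kind = g$kind, family = g$family), ps)
}

drop_nulls <- function(x) x[!vapply(x, is.null, TRUE)]

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ranges <- matrix(obj$ranges, 2, 2)
  cap <- obj$cap
  fn_from <- function(l) {
    if (is.null(l)) return(NULL)
    args <- l[setdiff(names(l), c("family", "domain"))]
    do.call(subunit_fn, c(list(family = l$family), args,
                          list(domain = unlist(l$domain))))
  }
  if (identical(obj$type, "point_neuron")) {
    return(point_neuron_model(obj$w[1], obj$w[2], fn_from(obj$f3),
                              ranges = ranges, cap = cap))
  }
  fb <- NULL
  if (!is.null(obj$feedback)) {
    fb <- lapply(obj$feedback, function(l)
      do.call(feedback_fn, c(list(kind = l$kind, family = l$family),
                             l[setdiff(names(l), c("kind", "family"))])))
  }
  two_layer_model(fn_from(obj$f1), fn_from(obj$f2), fn_from(obj$f3),
                  feedback = fb, ranges = ranges, cap = cap)
}

#' Read and write iso-response curves as JSON
#'
#' Curves are stored as `{level, points: [[s1, s2], ...], arclength}` with
#' full stored precision; the read-write round trip preserves the level and
#' every point exactly.
#'
#' @param curve An [iso_curve()].
#' @param path File path.
#' @return `read_curve_json()` returns the [iso_curve()];
#'   `write_curve_json()` returns `path` invisibly.
#' @export
write_curve_json <- function(curve, path) {
  stopifnot(inherits(curve, "iso_curve"))
  obj <- list(level = curve$level,
              points = unname(apply(curve$points, 1, as.numeric,
                                    simplify = FALSE)),
              arclength = curve$arclength)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_curve_json
#' @export
read_curve_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pts <- obj$points
  if (is.list(pts)) pts <- do.call(rbind, pts)
  iso_curve(pts[, 1], pts[, 2], level = obj$level)
}
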
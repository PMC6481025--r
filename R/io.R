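#' Read and write vessel images
#'
#' 8-bit TIFF (lossless, the acquisition format) and PNG rasters are
#' supported; anything else, including 16-bit input, raises a format error.
#' RGB images are accepted and kept as three channels — downstream processing
#' uses the green channel.
#'
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @param site,eye optional metadata attached to the returned object.
#' @return `read_image()`: a [vessel_image()].
#' @export
read_image <- function(path, site = NA_character_, eye = NA_character_) {
  if (!file.exists(path)) stop("no such image file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, as.is = TRUE)
    if (max(px) > 255)
      stop("unsupported bit depth in ", path,
           ": only 8-bit images are supported")
  } else if (ext == "png") {
    px <- png::readPNG(path, info = TRUE)
    info <- attr(px, "info")
    if (!is.null(info$bit.depth) && info$bit.depth != 8L)
      stop("unsupported bit depth in ", path,
           ": only 8-bit images are supported (got ", info$bit.depth,
           "-bit)")
    px <- round(px * 255)
  } else {
    stop("unsupported image format '", ext, "': use 8-bit TIFF or PNG")
  }
  if (length(dim(px)) == 3L) {
    if (dim(px)[3L] == 4L) px <- px[, , 1:3]  # drop alpha
    if (dim(px)[3L] == 1L) px <- px[, , 1L]
  }
  vessel_image(px, site = site, eye = eye)
}

#' @rdname read_image
#' @param img a [vessel_image()].
#' @return `write_image()`: the path, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "vessel_image"))
  ext <- tolower(tools::file_ext(path))
  px <- img$pixels / 255
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(px, path, bits.per.sample = 8L, compression = "none")
  } else if (ext == "png") {
    png::writePNG(px, path)
  } else {
    stop("unsupported image format '", ext, "': use TIFF or PNG")
  }
  invisible(path)
}

#' Read and write centerline trace files
#'
#' Traces are stored as CSV with columns `segment_id, point_index, x, y`
#' (pixel units, 0-based, y down), full float precision, one row per point.
#' On reading, rows are ordered by `point_index` within each segment
#' (shuffled files are re-sorted deterministically); duplicate
#' `(segment_id, point_index)` pairs and segments with fewer than 3 points
#' are rejected.
#'
#' @param path CSV file path.
#' @return `read_traces()`: a named list of [polyline][as_polyline]s, one
#'   per `segment_id` (in first-appearance order).
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("no such trace file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("segment_id", "point_index", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trace file is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df[c("segment_id", "point_index")]))
    stop("duplicate (segment_id, point_index) in ", path)
  ids <- unique(df$segment_id)
  out <- lapply(ids, function(id) {
    seg <- df[df$segment_id == id, , drop = FALSE]
    if (nrow(seg) < 3L)
      stop("segment '", id, "' has fewer than 3 points")
    seg <- seg[order(seg$point_index), , drop = FALSE]
    as_polyline(cbind(seg$x, seg$y))
  })
  names(out) <- ids
  out
}

#' @rdname read_traces
#' @param traces a named list of polylines (or a single polyline), or the
#'   trace list of a [gen_cohort()] result.
#' @return `write_traces()`: the path, invisibly.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "vessel_cohort")) traces <- traces$traces
  if (inherits(traces, "polyline")) traces <- list(segment = traces)
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    id <- if (is.list(tr)) tr$segment_id else
      (names(traces)[i] %||% as.character(i))
    if (is.null(id) || !nzchar(id)) id <- as.character(i)
    pl <- poly_mat(as_polyline(if (is.list(tr)) tr$polyline else tr))
    data.frame(segment_id = id, point_index = seq_len(nrow(pl)) - 1L,
               x = pl[, 1L], y = pl[, 2L], stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read/write a segment-level metrics table
#'
#' Flat CSV with one row per traced segment:
#' `subject_id, group, sex, age, eye, site, segment_id, arc_length_px,
#' soam, pad, i2e` (provenance columns may be empty for anonymous traces).
#'
#' @param metrics a metrics data frame ([tortuosity_table()]), optionally
#'   already merged with subject columns.
#' @param path CSV file path.
#' @return the path (write) or the data frame (read).
#' @export
write_metrics <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  if (!file.exists(path)) stop("no such metrics file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "eye", "site", "segment_id", "soam", "pad", "i2e")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metrics file is missing columns: ", paste(miss, collapse = ", "))
  df
}

#' Pipeline configuration
#'
#' A single serializable bundle of every tunable in the pipeline, writable
#' to and readable from a YAML file. Unknown keys in a config file are
#' rejected rather than silently ignored.
#'
#' @param rng_seed integer seed for the whole run.
#' @param out_dir output directory for pipeline artifacts.
#' @param metric a [metric_config()] or a named list overriding its
#'   defaults.
#' @param tracing a [tracing_config()] or overrides.
#' @param stats a [stats_config()] or overrides.
#' @param cohort a [cohort_params()] or overrides (simulation stage).
#' @param trace_images if `TRUE`, the pipeline rasterizes every simulated
#'   centerline and re-traces it semi-automatically before measuring;
#'   the default measures the simulated centerlines directly.
#' @param log_level `"info"` or `"quiet"`.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(rng_seed = 1, out_dir = tempfile("ocutort_run_"),
                            metric = metric_config(),
                            tracing = tracing_config(),
                            stats = stats_config(),
                            cohort = cohort_params(),
                            trace_images = FALSE,
                            log_level = c("info", "quiet")) {
  as_cfg <- function(x, ctor, cls) {
    if (inherits(x, cls)) return(x)
    if (is.list(x)) return(do.call(ctor, x))
    stop("cannot interpret configuration block for ", cls)
  }
  structure(list(rng_seed = rng_seed, out_dir = out_dir,
                 metric = as_cfg(metric, metric_config, "metric_config"),
                 tracing = as_cfg(tracing, tracing_config, "tracing_config"),
                 stats = as_cfg(stats, stats_config, "stats_config"),
                 cohort = as_cfg(cohort, cohort_params, "cohort_params"),
                 trace_images = isTRUE(trace_images),
                 log_level = match.arg(log_level)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- lapply(config, function(x) if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config` (for `write_config`).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("rng_seed", "out_dir", "metric", "tracing", "stats", "cohort",
             "trace_images", "log_level")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  if (!is.null(raw$cohort)) {
    # YAML reads named vectors back as lists; restore the shapes
    # cohort_params expects
    for (f in c("segments_per_site", "effect_multiplier"))
      if (!is.null(raw$cohort[[f]])) raw$cohort[[f]] <- unlist(raw$cohort[[f]])
    if (!is.null(raw$cohort$sites)) raw$cohort$sites <- unlist(raw$cohort$sites)
    if (!is.null(raw$cohort$age_range))
      raw$cohort$age_range <- unlist(raw$cohort$age_range)
  }
  do.call(pipeline_config, raw)
}

#' Serialize a study report
#'
#' `write_report()` writes the full report as JSON (timestamps deliberately
#' excluded so identical runs produce identical bytes);
#' `report_to_csv()` writes the flat table of all tests (rank tests and
#' regressions) as CSV.
#'
#' @param report a `study_report` from [run_study()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "study_report"))
  payload <- list(demographics = report$demographics,
                  tests = report$tests, regressions = report$regressions,
                  skipped = report$skipped,
                  config = unclass(report$config))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
report_to_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}

log_info <- function(config, fmt, ...) {
  if (identical(config$log_level, "info"))
    message(sprintf(paste0("[ocutort] ", fmt), ...))
}

#' Run the pipeline end to end
#'
#' Simulates a cohort, (optionally) rasterizes and re-traces every segment,
#' computes the tortuosity metrics, runs the case-control analysis, and
#' writes all artifacts (`subjects.csv`, `traces.csv`, `metrics.csv`,
#' `report.json`, `tests.csv`) under `config$out_dir`. Every stage is
#' logged with counts; any stage failure aborts with a stage-named error.
#' Deterministic given `config$rng_seed`.
#'
#' @param config a [pipeline_config()].
#' @param metrics_path,subjects_path optional pre-existing inputs: when both
#'   are given the simulate/trace/measure stages are skipped and only the
#'   comparison stage runs.
#' @return the [run_study()] report, invisibly, with an
#'   `artifacts` attribute naming the files written.
#' @export
run_pipeline <- function(config = pipeline_config(), metrics_path = NULL,
                         subjects_path = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  if (is.null(metrics_path) != is.null(subjects_path) &&
      !is.null(metrics_path))
    stop("compare-only mode needs both metrics_path and subjects_path")
  if (!is.null(subjects_path) && is.null(metrics_path))
    stop("compare-only mode needs both metrics_path and subjects_path")
  if (is.null(metrics_path)) {
    cp <- config$cohort
    cp$rng_seed <- config$rng_seed
    co <- stage("simulate", gen_cohort(cp))
    log_info(config, "simulate: %d subjects, %d traces",
             nrow(co$subjects), length(co$traces))
    traces <- co$traces
    if (config$trace_images) {
      traces <- stage("trace", lapply(seq_along(traces), function(i) {
        tr <- traces[[i]]
        pl0 <- poly_mat(tr$polyline)
        mar <- 16
        pl <- sweep(pl0, 2L, c(mar - min(pl0[, 1L]), mar - min(pl0[, 2L])),
                    "+")
        rp <- raster_params(image_size = c(ceiling(diff(range(pl[, 2L]))) +
                                             2L * mar,
                                           ceiling(diff(range(pl[, 1L]))) +
                                             2L * mar))
        img <- rasterize_vessel(as_polyline(pl), rp)
        n <- nrow(pl)
        sd <- pl[c(1L, ceiling(n / 2), n), , drop = FALSE]
        traced <- trace_segment(img, sd, config$tracing)
        tr$polyline <- traced
        tr
      }))
      log_info(config, "trace: re-traced %d rasterized segments",
               length(traces))
    }
    mt <- stage("metrics", tortuosity_table(traces, config$metric))
    mt <- merge(mt, co$subjects, by = "subject_id", sort = FALSE)
    subjects <- co$subjects
    write_traces(traces, file.path(config$out_dir, "traces.csv"))
    utils::write.csv(subjects, file.path(config$out_dir, "subjects.csv"),
                     row.names = FALSE)
    log_info(config, "metrics: %d segments measured", nrow(mt))
  } else {
    mt <- stage("metrics", read_metrics(metrics_path))
    subjects <- stage("subjects", read_subjects(subjects_path))
    log_info(config, "loaded %d metric rows, %d subjects", nrow(mt),
             nrow(subjects))
  }
  write_metrics(mt, file.path(config$out_dir, "metrics.csv"))
  report <- stage("compare", run_study(mt, subjects, config$stats))
  if (!is.null(report$skipped))
    for (i in seq_len(nrow(report$skipped)))
      log_info(config, "skipped %s/%s/%s: %s", report$skipped$comparison[i],
               report$skipped$site[i], report$skipped$metric[i],
               report$skipped$reason[i])
  write_report(report, file.path(config$out_dir, "report.json"))
  report_to_csv(report, file.path(config$out_dir, "tests.csv"))
  log_info(config, "report written to %s", config$out_dir)
  attr(report, "artifacts") <- file.path(config$out_dir,
                                         c("subjects.csv", "traces.csv",
                                           "metrics.csv", "report.json",
                                           "tests.csv"))
  invisible(report)
}
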
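## Workbench module: end-to-end orchestration, configuration and run
## manifests.

#' Pipeline configuration
#'
#' Collects per-stage configurations and I/O settings for [run_pipeline()].
#' Configs round-trip through JSON via [read_pipeline_config()] /
#' [write_pipeline_config()].
#'
#' @param seed master seed; propagated to every stochastic stage.
#' @param synth a [trace_spec()] to simulate input traces, or `NULL` when
#'   `traces` are supplied directly.
#' @param traces data.frame `(track_id, frame, conc)` in nM (already
#'   calibrated), or `NULL` to simulate from `synth`.
#' @param detection a [detection_config()].
#' @param fit a [fit_config()].
#' @param volume_fL cytosol volume for molecule counts.
#' @param calib_error_rel,bleach_error_rel systematic error components.
#' @param knockdown optional list with `expr` (cells x timepoints matrix of
#'   corrected relative expression, rows named by track_id), `times_h`, and
#'   optionally `r2_threshold`, `n_groups`; enables the dose-response stage.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, synth = NULL, traces = NULL,
                            detection = detection_config(),
                            fit = fit_config(), volume_fL = 5000,
                            calib_error_rel = 0.08, bleach_error_rel = 0.05,
                            knockdown = NULL, out_dir = NULL) {
  assert_that(!is.null(synth) || !is.null(traces),
              "config needs either synthetic spec or input traces")
  structure(list(seed = as.integer(seed), synth = synth, traces = traces,
                 detection = detection, fit = fit, volume_fL = volume_fL,
                 calib_error_rel = calib_error_rel,
                 bleach_error_rel = bleach_error_rel,
                 knockdown = knockdown, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes (simulate) -> detect -> fit-release -> (group/IC50) and returns
#' all intermediates plus a run manifest. With `out_dir` set, writes
#' `traces.csv`, `events.csv`, `releases.csv`, `manifest.json` (and
#' `groups.csv`, `ic50.csv` when the knockdown stage runs). Identical
#' config + seed give identical bundles.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result`: `traces`, `truth` (when
#'   simulated), `events`, `releases`, `groups`, `ic50`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  if (!is.null(config$synth)) {
    spec <- config$synth
    spec$seed <- config$seed
    ens <- gen_trace_ensemble(spec)
    traces <- ens$traces
    truth <- ens$truth
  } else {
    traces <- config$traces
    assert_that(all(c("track_id", "frame", "conc") %in% names(traces)),
                "traces must have track_id, frame, conc columns")
  }

  events <- detect_events_table(traces, config$detection)
  releases <- fit_release_table(traces, events, config$fit,
                                config$volume_fL, config$calib_error_rel,
                                config$bleach_error_rel)

  groups <- NULL
  ic50 <- NULL
  if (!is.null(config$knockdown)) {
    kd <- config$knockdown
    first_ev <- releases[!duplicated(releases$track_id) &
                           releases$converged, ]
    cells <- data.frame(track_id = first_ev$track_id,
                        peak_conc = first_ev$peak_conc,
                        r_squared = first_ev$r_squared)
    cells <- cells[as.character(cells$track_id) %in% rownames(kd$expr), ]
    if (nrow(cells) >= (kd$n_groups %||% 5L)) {
      groups <- group_by_magnitude(
        cells, expr = kd$expr, times_h = kd$times_h,
        r2_threshold = kd$r2_threshold %||% 0.3,
        n_groups = kd$n_groups %||% 5L)
      doses <- cells$peak_conc
      expr <- kd$expr[as.character(cells$track_id), , drop = FALSE]
      ic50 <- ic50_timecourse(doses, expr, kd$times_h,
                              n_boot = kd$n_boot %||% 200L,
                              seed = config$seed)
    }
  }

  manifest <- list(
    package = "cytorelease",
    version = as.character(utils::packageVersion("cytorelease")),
    seed = config$seed,
    config_hash = config_hash(jsonlite::toJSON(
      config[c("seed", "volume_fL", "calib_error_rel", "bleach_error_rel")],
      auto_unbox = TRUE)),
    n_traces = length(unique(traces$track_id)),
    n_events = nrow(events),
    timestamp = NA # deliberately unset: manifests must be reproducible
  )

  result <- structure(list(traces = traces, truth = truth, events = events,
                           releases = releases, groups = groups,
                           ic50 = ic50, manifest = manifest),
                      class = "pipeline_result")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(traces, file.path(config$out_dir, "traces.csv"),
              row.names = FALSE)
    write.csv(events, file.path(config$out_dir, "events.csv"),
              row.names = FALSE)
    write.csv(releases, file.path(config$out_dir, "releases.csv"),
              row.names = FALSE)
    if (!is.null(ic50)) {
      write.csv(ic50, file.path(config$out_dir, "ic50.csv"),
                row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  result
}

#' Read / write a pipeline configuration as JSON
#'
#' Serializes the scalar stage parameters (not in-memory traces or
#' expression matrices, which travel as CSV) so a run can be reproduced from
#' a config file plus its input files.
#'
#' @param path JSON file path.
#' @param config a [pipeline_config()] (write).
#' @return for `read_pipeline_config`, a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  synth <- if (!is.null(raw$synth)) do.call(trace_spec, raw$synth) else NULL
  det <- if (!is.null(raw$detection)) {
    do.call(detection_config, raw$detection)
  } else {
    detection_config()
  }
  fit <- if (!is.null(raw$fit)) do.call(fit_config, raw$fit) else fit_config()
  traces <- if (!is.null(raw$traces_csv)) read.csv(raw$traces_csv) else NULL
  pipeline_config(seed = raw$seed %||% 1L, synth = synth, traces = traces,
                  detection = det, fit = fit,
                  volume_fL = raw$volume_fL %||% 5000,
                  calib_error_rel = raw$calib_error_rel %||% 0.08,
                  bleach_error_rel = raw$bleach_error_rel %||% 0.05,
                  out_dir = raw$out_dir)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  raw <- list(
    seed = config$seed,
    synth = if (!is.null(config$synth)) unclass(config$synth),
    detection = unclass(config$detection),
    fit = unclass(config$fit),
    volume_fL = config$volume_fL,
    calib_error_rel = config$calib_error_rel,
    bleach_error_rel = config$bleach_error_rel,
    out_dir = config$out_dir
  )
  jsonlite::write_json(raw[!vapply(raw, is.null, logical(1))], path,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "pipeline_result: %d traces, %d events, %d release fits\n",
    x$manifest$n_traces, x$manifest$n_events,
    sum(x$releases$converged %||% logical(0))))
  invisible(x)
}
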
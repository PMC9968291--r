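## Event-detection module: sudden cytosolic siRNA signal shifts in per-cell
## traces, plus sensitivity/specificity scoring against ground truth.

#' Detection configuration
#'
#' Parameters of the release-event calling rule: frame `t` is called when
#' the (median-filtered) value at `t` and the `persistence` following values
#' all exceed the larger of (i) the mean of the previous `mean_lookback`
#' frames plus `sd_multiplier` times the SD of the previous `sd_lookback`
#' frames, and (ii) the same mean plus `fixed_offset`.
#'
#' @param median_window moving-median window applied to the trace before
#'   analysis (odd, default 5).
#' @param mean_lookback frames averaged for the local baseline (3).
#' @param sd_lookback frames used for the local SD (10, excluding the shift
#'   frame itself).
#' @param sd_multiplier SD multiplier (3).
#' @param fixed_offset fixed minimum shift in the units of the trace
#'   (default 0.15 nM-equivalent; the original value was tuned empirically
#'   and not published).
#' @param persistence frames after the shift that must also exceed the
#'   threshold (5, i.e. the shifted value plus the five following).
#' @return list of class `detection_config`.
#' @export
detection_config <- function(median_window = 5L, mean_lookback = 3L,
                             sd_lookback = 10L, sd_multiplier = 3,
                             fixed_offset = 0.15, persistence = 5L) {
  assert_that(median_window >= 1 && mean_lookback >= 1 && sd_lookback >= 1,
              "window lengths must be >= 1")
  assert_that(sd_multiplier > 0, "sd_multiplier must be positive")
  assert_that(fixed_offset >= 0, "fixed_offset must be non-negative")
  structure(list(median_window = as.integer(median_window),
                 mean_lookback = as.integer(mean_lookback),
                 sd_lookback = as.integer(sd_lookback),
                 sd_multiplier = sd_multiplier,
                 fixed_offset = fixed_offset,
                 persistence = as.integer(persistence)),
            class = "detection_config")
}

#' Centered moving median with shrinking edge windows
#'
#' @param x numeric vector.
#' @param window odd window length; 1 is the identity.
#' @return filtered vector, same length; at the edges the window is
#'   truncated to the available frames.
#' @export
median_filter <- function(x, window = 5L) {
  if (length(x) == 0) return(x)
  assert_that(window >= 1, "window must be >= 1")
  assert_that(window %% 2 == 1, "window must be odd")
  if (window == 1) return(x)
  h <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    median(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Detect cytosolic release events in a single trace
#'
#' Applies a `median_window`-frame moving median, then scans frames with at
#' least `sd_lookback` frames of history. A frame `t` is called when the
#' filtered values at `t, ..., t + persistence` are all strictly larger than
#' `max(mean3 + sd_multiplier * sd10, mean3 + fixed_offset)` where `mean3`
#' and `sd10` are computed over the `mean_lookback` and `sd_lookback` frames
#' immediately preceding `t` (exact ties do not trigger). After a call,
#' scanning resumes at `t + persistence + 1`, so multiple events per trace
#' are supported.
#'
#' @param trace numeric vector (background-corrected siRNA signal, any
#'   consistent units; `fixed_offset` must be in the same units).
#' @param config a [detection_config()].
#' @return integer vector of called frames (possibly empty). Traces shorter
#'   than `sd_lookback + persistence + 1` give no calls with a warning.
#' @export
detect_events <- function(trace, config = detection_config()) {
  n <- length(trace)
  if (n < config$sd_lookback + config$persistence + 1L) {
    warning("trace too short for event detection; no calls made")
    return(integer(0))
  }
  f <- median_filter(trace, config$median_window)
  calls <- integer(0)
  t <- config$sd_lookback + 1L
  last <- n - config$persistence
  while (t <= last) {
    m <- mean(f[(t - config$mean_lookback):(t - 1L)])
    s <- sd(f[(t - config$sd_lookback):(t - 1L)])
    thr <- max(m + config$sd_multiplier * s, m + config$fixed_offset)
    if (all(f[t:(t + config$persistence)] > thr)) {
      calls <- c(calls, t)
      t <- t + config$persistence + 1L
    } else {
      t <- t + 1L
    }
  }
  calls
}

#' Detect events across a table of traces
#'
#' @param traces data.frame `(track_id, frame, conc)` (or a column named by
#'   `value_col`), one trace per `track_id`, frames consecutive.
#' @param config a [detection_config()].
#' @param value_col column holding the signal (default `"conc"`).
#' @return data.frame `(track_id, frame, qc_status)` of calls, with
#'   `qc_status = "auto"`.
#' @export
detect_events_table <- function(traces, config = detection_config(),
                                value_col = "conc") {
  out <- lapply(split(traces, traces$track_id), function(d) {
    d <- d[order(d$frame), ]
    calls <- detect_events(d[[value_col]], config)
    if (length(calls) == 0) return(NULL)
    data.frame(track_id = d$track_id[1], frame = d$frame[calls],
               qc_status = "auto")
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(track_id = integer(), frame = integer(),
                      qc_status = character())
  }
  rownames(out) <- NULL
  out
}

#' Score detection calls against ground-truth event times
#'
#' Per cell, the evaluation mirrors the benchmarking protocol against an
#' independent membrane-damage (galectin) reporter: each cell is assessed up
#' to its first event. A cell with a true event counts as TP if any
#' surviving call lies within `match_window` frames of the first truth
#' frame, FN if it has no surviving call, and FP if its calls all miss the
#' window. A cell without a true event counts as FP if it has a surviving
#' call and TN otherwise. Calls with `qc_status == "rejected"` (manual QC)
#' are discarded before scoring, so a rejected false positive becomes a TN.
#'
#' @param calls data.frame `(track_id, frame[, qc_status])`.
#' @param truth data.frame `(track_id, frame)` of true first-event times;
#'   only the earliest truth per cell is used.
#' @param cell_ids all evaluated cells (cells absent from both tables are
#'   true negatives).
#' @param match_window frames of tolerance on either side (default 5).
#' @return list of class `detection_performance`: `tp, fp, tn, fn,
#'   sensitivity, specificity` (the rates are `NA` when undefined).
#' @export
evaluate_detection <- function(calls, truth, cell_ids, match_window = 5L) {
  if (!"qc_status" %in% names(calls)) {
    calls$qc_status <- rep("auto", nrow(calls))
  }
  calls <- calls[calls$qc_status != "rejected", , drop = FALSE]
  tp <- fp <- tn <- fn <- 0L
  for (id in cell_ids) {
    tr <- truth$frame[truth$track_id == id]
    cl <- calls$frame[calls$track_id == id]
    has_truth <- length(tr) > 0
    if (has_truth) tr1 <- min(tr)
    if (has_truth && length(cl) > 0) {
      if (any(abs(cl - tr1) <= match_window)) tp <- tp + 1L else fp <- fp + 1L
    } else if (has_truth) {
      fn <- fn + 1L
    } else if (length(cl) > 0) {
      fp <- fp + 1L
    } else {
      tn <- tn + 1L
    }
  }
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    match_window = as.integer(match_window)
  ), class = "detection_performance")
}

#' @export
print.detection_performance <- function(x, ...) {
  cat(sprintf(
    "detection: TP %d FP %d TN %d FN %d | sensitivity %.3f specificity %.3f\n",
    x$tp, x$fp, x$tn, x$fn, x$sensitivity, x$specificity))
  invisible(x)
}
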
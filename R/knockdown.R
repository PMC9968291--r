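## Knockdown module: correct and align single-cell reporter traces,
## stratify by release magnitude, and estimate per-timepoint IC50s.

#' Knockdown analysis configuration
#'
#' @param frame_interval minutes between frames (default 5).
#' @param min_controls minimum no-event control cells per well for the
#'   bleaching correction; fewer triggers a hard warning and skips the
#'   correction.
#' @param apoptosis_mask_frames frames masked before a detected cell death
#'   (default 20).
#' @param late_entry_frame cells first seen after this frame are excluded
#'   (default 3; guards against cells with prior undetected releases).
#' @param low_egfp_threshold cells whose initial reporter intensity is below
#'   this are excluded; `NULL` disables. The original threshold was a fixed
#'   empirical value; a sensible default is 3x the background SD of the
#'   reporter channel.
#' @param mitosis_window frames on either side of a detected mitosis over
#'   which the mitosis correction factor is applied.
#' @return list of class `knockdown_config`.
#' @export
knockdown_config <- function(frame_interval = 5, min_controls = 5L,
                             apoptosis_mask_frames = 20L,
                             late_entry_frame = 3L,
                             low_egfp_threshold = NULL,
                             mitosis_window = 3L) {
  structure(list(frame_interval = frame_interval,
                 min_controls = as.integer(min_controls),
                 apoptosis_mask_frames = as.integer(apoptosis_mask_frames),
                 late_entry_frame = as.integer(late_entry_frame),
                 low_egfp_threshold = low_egfp_threshold,
                 mitosis_window = as.integer(mitosis_window)),
            class = "knockdown_config")
}

#' Correct, align and normalize single-cell reporter traces
#'
#' For each cell with a detected release event:
#' \enumerate{
#'   \item divide its reporter trace by the mean trajectory of same-well
#'     control cells (cells without any detected event, each normalized to
#'     its own first frame) — this removes photobleaching, drift and
#'     well-level confounders including undetected low-level release;
#'   \item optionally apply a multiplicative mitosis correction factor
#'     within `mitosis_window` frames of each annotated mitosis;
#'   \item mask frames after a second detected event, and frames from
#'     `apoptosis_mask_frames` before an annotated death onward;
#'   \item shift time so the first event sits at t = 0 and normalize to the
#'     value at t = 0 (so every corrected trace equals 1 there by
#'     construction);
#'   \item drop cells that entered the field after `late_entry_frame` or
#'     start below `low_egfp_threshold`.
#' }
#'
#' @param traces data.frame `(track_id, frame, egfp)`.
#' @param events data.frame `(track_id, frame)` of detected releases (a cell
#'   may appear several times; the first is the alignment event).
#' @param apoptosis optional data.frame `(track_id, frame)` of death frames.
#' @param mitosis optional data.frame `(track_id, frame)`; combined with
#'   `mitosis_factor` (a function of signed frame offset returning the
#'   multiplicative correction, estimated from control-siRNA experiments).
#' @param mitosis_factor function(offset_frames) -> factor; default NULL.
#' @param config a [knockdown_config()].
#' @return data.frame of class `corrected_traces`:
#'   `(track_id, time_min, rel_expr)`; masked frames are dropped.
#' @export
correct_expression <- function(traces, events, apoptosis = NULL,
                               mitosis = NULL, mitosis_factor = NULL,
                               config = knockdown_config()) {
  ids <- unique(traces$track_id)
  event_ids <- unique(events$track_id)
  control_ids <- setdiff(ids, event_ids)

  ## mean normalized control trajectory per frame
  ctrl <- NULL
  if (length(control_ids) >= config$min_controls) {
    ctrl_mat <- lapply(control_ids, function(id) {
      d <- traces[traces$track_id == id, ]
      d <- d[order(d$frame), ]
      v <- d$egfp / d$egfp[1]
      setNames(v, d$frame)
    })
    all_frames <- sort(unique(traces$frame))
    ctrl <- vapply(as.character(all_frames), function(f) {
      vals <- vapply(ctrl_mat, function(v) {
        if (f %in% names(v)) v[[f]] else NA_real_
      }, numeric(1))
      mean(vals, na.rm = TRUE)
    }, numeric(1))
  } else {
    warning(sprintf(
      "only %d control cells (< %d): bleaching correction skipped",
      length(control_ids), config$min_controls))
  }

  out <- list()
  for (id in event_ids) {
    d <- traces[traces$track_id == id, ]
    d <- d[order(d$frame), ]
    if (nrow(d) == 0) next
    ## exclusions
    if (min(d$frame) > config$late_entry_frame) next
    if (!is.null(config$low_egfp_threshold) &&
        d$egfp[1] < config$low_egfp_threshold) next

    ev <- sort(events$frame[events$track_id == id])
    e1 <- ev[1]
    v <- d$egfp
    if (!is.null(ctrl)) {
      cf <- ctrl[as.character(d$frame)]
      cf[!is.finite(cf) | abs(cf) < 1e-8] <- NA
      v <- v / cf
    }
    if (!is.null(mitosis) && !is.null(mitosis_factor)) {
      mf <- mitosis$frame[mitosis$track_id == id]
      for (m in mf) {
        off <- d$frame - m
        w <- abs(off) <= config$mitosis_window
        v[w] <- v[w] / mitosis_factor(off[w])
      }
    }
    keep <- rep(TRUE, nrow(d))
    if (length(ev) >= 2) keep[d$frame > ev[2]] <- FALSE
    if (!is.null(apoptosis)) {
      af <- apoptosis$frame[apoptosis$track_id == id]
      if (length(af) > 0) {
        keep[d$frame >= min(af) - config$apoptosis_mask_frames] <- FALSE
      }
    }
    at0 <- which(d$frame == e1)
    if (length(at0) != 1 || !is.finite(v[at0]) || v[at0] == 0) next
    rel <- v / v[at0]
    sel <- keep & is.finite(rel)
    if (!any(sel)) next
    out[[length(out) + 1L]] <- data.frame(
      track_id = id,
      time_min = (d$frame[sel] - e1) * config$frame_interval,
      rel_expr = rel[sel]
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(track_id = integer(), time_min = numeric(),
                      rel_expr = numeric())
  }
  class(res) <- c("corrected_traces", "data.frame")
  res
}

#' Stratify cells into dose groups by release magnitude
#'
#' Cells passing the R-squared confidence filter are sorted by model-based
#' peak concentration and split into `n_groups` equal-sized (+/- 1) groups.
#' Per group: median and IQR of peak concentration, mean R-squared, and
#' (when expression curves are supplied) the mean relative-expression curve
#' with a pointwise t-based confidence band.
#'
#' @param cells data.frame with columns `track_id`, `peak_conc`,
#'   `r_squared`.
#' @param expr optional matrix of relative expression (rows named by
#'   `track_id`, columns = timepoints).
#' @param times_h timepoints (h) for `expr` columns.
#' @param r2_threshold minimum model R-squared (default 0.3, the
#'   low-confidence exclusion; 0.75 restricts to highly reliable
#'   quantifications).
#' @param n_groups number of groups (default 5, quintiles).
#' @param ci_level level of the per-timepoint confidence band (default 0.8).
#' @return object of class `quantile_groups`: list `groups` (per group:
#'   `track_ids, median_conc, iqr_conc, mean_r2, n`, and with `expr`:
#'   `mean_curve, ci_lo, ci_hi, expr`), plus `times_h`, `r2_threshold`.
#' @export
group_by_magnitude <- function(cells, expr = NULL, times_h = NULL,
                               r2_threshold = 0.3, n_groups = 5L,
                               ci_level = 0.8) {
  keep <- cells[!is.na(cells$r_squared) & cells$r_squared >= r2_threshold, ]
  assert_that(nrow(keep) >= n_groups,
              "fewer cells than groups after R^2 filtering")
  keep <- keep[order(keep$peak_conc), ]
  bins <- quantile_bins(nrow(keep), n_groups)

  groups <- lapply(seq_len(n_groups), function(g) {
    sub <- keep[bins == g, ]
    out <- list(
      track_ids = sub$track_id,
      median_conc = median(sub$peak_conc),
      iqr_conc = unname(quantile(sub$peak_conc, c(0.25, 0.75))),
      mean_r2 = mean(sub$r_squared),
      n = nrow(sub)
    )
    if (!is.null(expr)) {
      e <- expr[as.character(sub$track_id), , drop = FALSE]
      ci <- curve_ci(e, ci_level)
      out$expr <- e
      out$mean_curve <- ci$mean
      out$ci_lo <- ci$lo
      out$ci_hi <- ci$hi
    }
    out
  })
  structure(list(groups = groups, times_h = times_h,
                 r2_threshold = r2_threshold, ci_level = ci_level),
            class = "quantile_groups")
}

#' Per-timepoint 4PL IC50 timecourse
#'
#' At each requested timepoint, fits a 4PL of single-cell relative
#' expression against log dose (model-based peak concentration) and reports
#' relative and absolute IC50 with bootstrap confidence intervals.
#' Timepoints with fewer than `min_cells` cells are skipped with a warning.
#'
#' @param doses per-cell dose vector (nM), aligned with `expr` rows.
#' @param expr matrix cells x timepoints of relative expression.
#' @param times_h timepoints (h) of the columns.
#' @param timepoints which times to evaluate (default all columns).
#' @param min_cells minimum cells per timepoint (default 20).
#' @param n_boot bootstrap replicates.
#' @param ci_level confidence level (default 0.8, as used for the IC50
#'   timecourse band).
#' @param seed integer seed.
#' @return data.frame: `time_h, n, ic50_relative, rel_lo, rel_hi,
#'   ic50_absolute, abs_lo, abs_hi, bottom, hillslope`.
#' @export
ic50_timecourse <- function(doses, expr, times_h, timepoints = times_h,
                            min_cells = 20L, n_boot = 200L, ci_level = 0.8,
                            seed = 1L) {
  rows <- list()
  for (tp in timepoints) {
    j <- which.min(abs(times_h - tp))
    y <- expr[, j]
    ok <- is.finite(y) & is.finite(doses) & doses > 0
    if (sum(ok) < min_cells) {
      warning(sprintf("timepoint %g h skipped: only %d cells", tp, sum(ok)))
      next
    }
    fit <- fit_4pl(doses[ok], y[ok], n_boot = n_boot, ci_level = ci_level,
                   seed = seed)
    ci_rel <- fit$ci_relative %||% c(NA_real_, NA_real_)
    ci_abs <- fit$ci_absolute %||% c(NA_real_, NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      time_h = tp, n = sum(ok),
      ic50_relative = fit$ic50_relative,
      rel_lo = ci_rel[1], rel_hi = ci_rel[2],
      ic50_absolute = fit$ic50_absolute,
      abs_lo = ci_abs[1], abs_hi = ci_abs[2],
      bottom = fit$bottom, hillslope = fit$hillslope
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(time_h = numeric(), n = integer(),
                      ic50_relative = numeric(), rel_lo = numeric(),
                      rel_hi = numeric(), ic50_absolute = numeric(),
                      abs_lo = numeric(), abs_hi = numeric(),
                      bottom = numeric(), hillslope = numeric())
  }
  out
}

#' @export
print.quantile_groups <- function(x, ...) {
  cat(sprintf("quantile_groups: %d groups (R^2 >= %g)\n",
              length(x$groups), x$r2_threshold))
  for (i in seq_along(x$groups)) {
    g <- x$groups[[i]]
    cat(sprintf("  group %d: n = %d, median %.3g nM (IQR %.3g-%.3g), mean R^2 %.2f\n",
                i, g$n, g$median_conc, g$iqr_conc[1], g$iqr_conc[2],
                g$mean_r2))
  }
  invisible(x)
}
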
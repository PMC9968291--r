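make_well <- function(n_ctrl = 8, n_frames = 160, bleach = 0.002,
                      kd_curve = NULL, event_frame = 20, seed = 1) {
  # control cells share the well bleaching; one event cell optionally
  # carries a knockdown curve aligned at event_frame
  set.seed(seed)
  bl <- (1 - bleach)^(seq_len(n_frames) - 1)
  rows <- list()
  for (i in seq_len(n_ctrl)) {
    rows[[i]] <- data.frame(track_id = i, frame = seq_len(n_frames),
                            egfp = 100 * bl)
  }
  kd <- rep(1, n_frames)
  if (!is.null(kd_curve)) {
    idx <- event_frame:n_frames
    kd[idx] <- kd_curve[seq_along(idx)]
  }
  rows[[n_ctrl + 1]] <- data.frame(track_id = n_ctrl + 1,
                                   frame = seq_len(n_frames),
                                   egfp = 100 * bl * kd)
  do.call(rbind, rows)
}

test_that("bleach-matched event cells correct to a flat unit trace", {
  traces <- make_well()
  events <- data.frame(track_id = 9, frame = 20)
  ct <- correct_expression(traces, events)
  expect_equal(unique(ct$track_id), 9)
  expect_equal(ct$rel_expr[ct$time_min == 0], 1) # exact by construction
  expect_equal(ct$rel_expr, rep(1, nrow(ct)), tolerance = 1e-9)
})

test_that("a synthetic 50% knockdown at 10 h survives bleaching correction", {
  m <- kinetic_model()
  dose <- kinetic_ic50(m, 10)
  n_frames <- 160
  times_h <- (0:(n_frames - 20)) * 5 / 60
  kd_curve <- predict_knockdown(m, dose, times_h)[1, ]
  traces <- make_well(kd_curve = kd_curve)
  ct <- correct_expression(traces, data.frame(track_id = 9, frame = 20))
  at10 <- ct$rel_expr[ct$time_min == 600]
  expect_equal(at10, 0.5, tolerance = 0.02)
})

test_that("masking rules drop the right frames and cells", {
  traces <- make_well()
  events <- data.frame(track_id = 9, frame = 20)
  # apoptosis at frame 100: values masked from frame 80 onward
  ct <- correct_expression(traces, events,
                           apoptosis = data.frame(track_id = 9, frame = 100))
  expect_lt(max(ct$time_min), (80 - 20) * 5)
  # second event at frame 60: nothing after it
  ev2 <- rbind(events, data.frame(track_id = 9, frame = 60))
  ct2 <- correct_expression(traces, ev2)
  expect_lte(max(ct2$time_min), (60 - 20) * 5)
  # masked traces are shorter than unmasked ones (knockdown-duration bias)
  ct_full <- correct_expression(traces, events)
  expect_lt(max(ct2$time_min), max(ct_full$time_min))
  # late entry: cell first seen at frame 5 is excluded
  tr_late <- traces[!(traces$track_id == 9 & traces$frame < 5), ]
  expect_equal(nrow(correct_expression(tr_late, events)), 0)
  # low-eGFP exclusion
  cfg <- knockdown_config(low_egfp_threshold = 1000)
  expect_equal(nrow(correct_expression(traces, events, config = cfg)), 0)
})

test_that("too few controls triggers a hard warning and skips correction", {
  traces <- make_well(n_ctrl = 2)
  expect_warning(
    ct <- correct_expression(traces, data.frame(track_id = 3, frame = 20)),
    "control")
  expect_equal(ct$rel_expr[ct$time_min == 0], 1)
})

test_that("magnitude quantiles split cells as ranked groups", {
  cells <- data.frame(track_id = 1:100, peak_conc = 1:100,
                      r_squared = 1)
  g <- group_by_magnitude(cells, n_groups = 5)
  expect_equal(vapply(g$groups, function(x) x$n, numeric(1)), rep(20, 5))
  expect_equal(vapply(g$groups, function(x) x$median_conc, numeric(1)),
               c(10.5, 30.5, 50.5, 70.5, 90.5))
  # R^2 threshold removes exactly the sub-threshold cells
  cells$r_squared <- seq(0, 0.99, length.out = 100)
  g2 <- group_by_magnitude(cells, r2_threshold = 0.3)
  kept <- unlist(lapply(g2$groups, function(x) x$track_ids))
  expect_setequal(kept, cells$track_id[cells$r_squared >= 0.3])
  expect_error(group_by_magnitude(cells[1:3, ], n_groups = 5), "fewer")
})

test_that("4PL fits recover generating parameters and the IC50 geometry", {
  set.seed(6)
  d <- 10^runif(150, -2, 2)
  y0 <- cytorelease:::fourpl_curve(log10(d), 1, 0, -1, 0) # IC50 = 1 nM
  f <- fit_4pl(d, y0)
  expect_equal(f$ic50_relative, 1, tolerance = 1e-3)
  expect_equal(f$ic50_absolute, 1, tolerance = 1e-3) # bottom 0: equal
  expect_equal(f$bottom, 0, tolerance = 1e-4)
  # bottom 0.3: absolute IC50 sits where the curve crosses 0.5 exactly
  y3 <- cytorelease:::fourpl_curve(log10(d), 1, 0.3, -1, 0)
  f3 <- fit_4pl(d, y3)
  expect_equal(f3$bottom, 0.3, tolerance = 1e-3)
  pred_at_abs <- cytorelease:::fourpl_curve(log10(f3$ic50_absolute), 1,
                                            f3$bottom, f3$hillslope,
                                            log10(f3$ic50_relative))
  expect_equal(pred_at_abs, 0.5, tolerance = 1e-6)
  # for a decreasing curve with bottom 0.3 the midpoint response is 0.65,
  # so the 0.5 crossing lies at a higher dose than the relative IC50
  expect_gt(f3$ic50_absolute, f3$ic50_relative)
  expect_equal(f3$ic50_absolute, 2.5 * f3$ic50_relative, tolerance = 1e-3)
  # dose -> infinity approaches the fitted bottom
  expect_equal(cytorelease:::fourpl_curve(8, 1, f3$bottom, f3$hillslope,
                                          log10(f3$ic50_relative)),
               f3$bottom, tolerance = 1e-4)
  # bottom above 0.5: no absolute IC50
  y7 <- cytorelease:::fourpl_curve(log10(d), 1, 0.7, -1, 0)
  f7 <- fit_4pl(d, y7)
  expect_true(is.na(f7$ic50_absolute))
  # flat data: degenerate flag
  expect_warning(fd <- fit_4pl(d, rep(1, length(d))), "degenerate")
  expect_true(fd$degenerate)
})

test_that("shared-hillslope fits constrain all curves to one slope", {
  set.seed(8)
  d <- 10^seq(-2, 2, length.out = 30)
  y1 <- cytorelease:::fourpl_curve(log10(d), 1, 0, -1.2, log10(0.3))
  y2 <- cytorelease:::fourpl_curve(log10(d), 1, 0.1, -1.2, log10(2))
  fits <- fit_4pl_shared(list(d, d), list(y1, y2))
  expect_equal(fits[[1]]$hillslope, fits[[2]]$hillslope)
  expect_equal(fits[[1]]$ic50_relative, 0.3, tolerance = 0.02)
  expect_equal(fits[[2]]$ic50_relative, 2, tolerance = 0.05)
})

test_that("time-invariant responses give a constant IC50 timecourse", {
  set.seed(10)
  d <- 10^runif(80, -1.5, 1.5)
  y <- cytorelease:::fourpl_curve(log10(d), 1, 0.05, -1, 0)
  expr <- cbind(y, y, y)
  out <- ic50_timecourse(d, expr, times_h = c(2, 6, 10), n_boot = 0)
  expect_equal(nrow(out), 3)
  expect_equal(diff(range(out$ic50_relative)), 0, tolerance = 1e-9)
  expect_warning(
    ic50_timecourse(d[1:5], expr[1:5, 1, drop = FALSE], times_h = 2,
                    n_boot = 0), "skipped")
})

test_that("the kinetic model meets its structural invariants", {
  m <- kinetic_model()
  # protein decay closed form: half-life 48 min -> ln 2 / 0.8 per h
  expect_equal(m$delta_p, log(2) / 0.8)
  # dose 0: relative expression identically 1
  expect_equal(unname(predict_knockdown(m, 0, seq(0, 20, 1))[1, ]),
               rep(1, 21))
  # monotone dose response: deeper nadir and longer knockdown at higher dose
  tt <- seq(0, 20, 0.25)
  p <- predict_knockdown(m, c(0.5, 5), tt)
  expect_lte(min(p[2, ]), min(p[1, ]))
  below <- function(r) sum(r < 0.8)
  expect_gte(below(p[2, ]), below(p[1, ]))
  expect_error(kinetic_model(delta_m = -1), "non-negative")
})

test_that("kinetic parameters are recovered from simulated quantiles", {
  m <- kinetic_model(K = 1)
  set.seed(12)
  doses <- exp(runif(500, log(0.05), log(30)))
  kd <- gen_knockdown_dataset(m, doses, times_h = seq(0, 14, 0.5),
                              noise_sd = 0.12, seed = 12)
  rownames(kd$expr) <- kd$cells$track_id
  cells <- data.frame(track_id = kd$cells$track_id, peak_conc = doses,
                      r_squared = 1)
  g <- group_by_magnitude(cells, expr = kd$expr, times_h = kd$times_h)
  kf <- fit_kinetic_model(g)
  expect_equal(kf$model$K, 1, tolerance = 0.2)
  expect_equal(kf$ic50, kinetic_ic50(m), tolerance = 0.1 * kinetic_ic50(m))
})
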
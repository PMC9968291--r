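test_that("median filter suppresses spikes and respects its edge contract", {
  expect_equal(median_filter(rep(3, 10)), rep(3, 10))
  expect_equal(median_filter(c(0, 0, 0, 10, 0, 0, 0))[4], 0) # spike killed
  x <- rnorm(20)
  expect_equal(median_filter(x, 1), x)
  expect_identical(median_filter(numeric(0)), numeric(0))
  expect_error(median_filter(x, 4), "odd")
  # shrinking edge window: first value is median of first 3 (window 5)
  y <- c(5, 1, 2, 9, 9, 9)
  expect_equal(median_filter(y, 5)[1], median(y[1:3]))
})

test_that("the detection rule fires on persistent shifts only", {
  cfg <- detection_config()
  # flat zero-noise: no events (fixed offset blocks the zero-SD case)
  expect_identical(detect_events(rep(0, 40), cfg), integer(0))
  # clear step with enough persistence: one call at the step frame
  set.seed(2)
  base <- rnorm(40, sd = 0.05)
  tr <- base
  tr[20:40] <- tr[20:40] + 10 * 0.05 * 10 # 10x the trailing SD, lasting
  calls <- detect_events(tr, cfg)
  expect_equal(length(calls), 1)
  expect_true(abs(calls - 20) <= 2)
  # same step persisting only 3 frames: persistence condition fails
  tr3 <- base
  tr3[20:22] <- tr3[20:22] + 5
  expect_identical(detect_events(tr3, cfg), integer(0))
  # too-short trace: warning, no calls
  expect_warning(out <- detect_events(rep(0, 10), cfg), "short")
  expect_identical(out, integer(0))
})

test_that("multiple events in one trace are called after the refractory gap", {
  tr <- rep(0, 60)
  tr[20:60] <- 2
  tr[40:60] <- 6
  calls <- detect_events(tr, detection_config())
  expect_equal(length(calls), 2)
  expect_true(abs(calls[1] - 20) <= 2 && abs(calls[2] - 40) <= 2)
})

test_that("the optimized detector equals the literal nested-loop oracle", {
  cfg <- detection_config()
  set.seed(77)
  for (i in 1:150) {
    tr <- random_trace()
    expect_identical(detect_events(tr, cfg), oracle_detect(tr, cfg))
  }
})

test_that("raising the fixed offset never increases the number of calls", {
  set.seed(5)
  traces <- replicate(40, random_trace(), simplify = FALSE)
  offs <- c(0, 0.1, 0.3, 1, 5)
  counts <- vapply(offs, function(o) {
    cfg <- detection_config(fixed_offset = o)
    sum(vapply(traces, function(tr) length(detect_events(tr, cfg)),
               numeric(1)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detection performance counts follow the per-cell protocol", {
  # exact-frame match: TP; no negatives so specificity is NA-safe
  p <- evaluate_detection(data.frame(track_id = 1, frame = 20),
                          data.frame(track_id = 1, frame = 20), 1)
  expect_equal(p$tp, 1)
  expect_equal(p$sensitivity, 1)
  expect_true(is.na(p$specificity))
  # 14 cells with truth, 13 matched calls -> sensitivity 13/14
  truth <- data.frame(track_id = 1:14, frame = 30)
  calls <- data.frame(track_id = 1:13, frame = 30 + (-2:10)[1:13])
  calls <- calls[abs(calls$frame - 30) <= 5, ]
  calls <- rbind(calls, data.frame(track_id = setdiff(1:13, calls$track_id),
                                   frame = 28))
  p2 <- evaluate_detection(calls, truth, 1:14)
  expect_equal(p2$tp, 13)
  expect_equal(p2$fn, 1)
  expect_equal(p2$sensitivity, 13 / 14, tolerance = 1e-12)
  # no truths, no calls, 10 cells -> specificity 1
  p3 <- evaluate_detection(data.frame(track_id = integer(),
                                      frame = integer()),
                           data.frame(track_id = integer(),
                                      frame = integer()), 1:10)
  expect_equal(p3$tn, 10)
  expect_equal(p3$specificity, 1)
  # rejected-QC false positive is reclassified as true negative
  p4 <- evaluate_detection(
    data.frame(track_id = 1, frame = 15, qc_status = "rejected"),
    data.frame(track_id = integer(), frame = integer()), 1)
  expect_equal(p4$tn, 1)
  expect_equal(p4$fp, 0)
})

test_that("sensitivity on realistic synthetic ensembles exceeds 0.9", {
  spec <- trace_spec(n_cells = 120, n_frames = 80, event_rate = 0.4,
                     magnitude_range = c(1, 40), seed = 88)
  ens <- gen_trace_ensemble(spec)
  calls <- detect_events_table(ens$traces)
  first_truth <- ens$truth$events[!duplicated(ens$truth$events$track_id), ]
  perf <- evaluate_detection(calls, first_truth, seq_len(spec$n_cells))
  expect_gt(perf$sensitivity, 0.9)
  expect_gt(perf$specificity, 0.8)
})
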
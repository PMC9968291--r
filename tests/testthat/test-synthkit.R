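test_that("trace ensemble honours the no-event and determinism contracts", {
  spec0 <- trace_spec(n_cells = 8, n_frames = 30, event_rate = 0,
                      noise_sd = 0.1, seed = 4)
  ens <- gen_trace_ensemble(spec0)
  expect_equal(nrow(ens$truth$events), 0)
  expect_true(all(abs(ens$truth$clean) < 1e-12)) # baseline 0, no events
  expect_lt(max(abs(ens$traces$conc)), 0.1 * 6)  # noise only

  spec <- trace_spec(n_cells = 10, n_frames = 40, event_rate = 1, seed = 9)
  a <- gen_trace_ensemble(spec)
  b <- gen_trace_ensemble(spec)
  expect_identical(a$traces, b$traces)
  expect_identical(a$truth$events, b$truth$events)
  c <- gen_trace_ensemble(trace_spec(n_cells = 10, n_frames = 40,
                                     event_rate = 1, seed = 10))
  expect_false(identical(a$traces$conc, c$traces$conc))
})

test_that("spec invariants are enforced", {
  expect_error(trace_spec(n_frames = 10), "n_frames")
  expect_error(trace_spec(magnitude_range = c(-1, 5)), "positive")
  expect_error(trace_spec(bleach_rate = 1), "bleach")
})

test_that("release magnitudes are log-uniform with the closed-form median", {
  # median of log-uniform on [1, 40] is sqrt(40) ~ 6.325; the sample median
  # of n draws has SD ~ 1/(2 f(m) sqrt(n)) with f(m) = 1/(m log 40)
  spec <- trace_spec(n_cells = 900, n_frames = 40, event_rate = 2, seed = 21)
  ens <- gen_trace_ensemble(spec)
  mags <- ens$truth$events$magnitude
  expect_gt(length(mags), 1500)
  mc_sd <- sqrt(40) * log(40) / (2 * sqrt(length(mags)))
  expect_lt(abs(median(mags) - sqrt(40)), 4 * mc_sd)
  expect_true(all(mags >= 1 & mags <= 40))
})

test_that("injected events are conserved in the noiseless ground truth", {
  spec <- trace_spec(n_cells = 60, n_frames = 60, event_rate = 0.8,
                     baseline = 0.2, seed = 31)
  ens <- gen_trace_ensemble(spec)
  ev <- ens$truth$events
  one_event <- names(which(table(ev$track_id) == 1))
  expect_gte(length(one_event), 3)
  for (id in as.integer(one_event)) {
    e <- ev[ev$track_id == id, ]
    step <- ens$truth$clean[id, e$frame] - ens$truth$clean[id, e$frame - 1]
    expect_equal(step, e$magnitude, tolerance = 1e-10)
  }
})

test_that("event traces from gen_event_trace follow the stated model", {
  set.seed(1)
  tr <- gen_event_trace(30, 10, 5, decay_rate = 0.1, noise_sd = 0)
  expect_equal(tr[1:9], rep(0, 9))
  expect_equal(tr[10], 5)
  expect_equal(tr[20], 5 * exp(-0.1 * 10))
  expect_error(gen_event_trace(30, 10, -1), "positive")
})

test_that("rendered scenes apply the vignette field by construction", {
  sp <- scene_spec(vignette_min = 0.8, seed = 2)
  vig <- cytorelease:::vignette_field(sp$image_size, 0.8)
  ctr <- (sp$image_size + 1) / 2
  expect_equal(vig[round(ctr), round(ctr)], 1, tolerance = 1e-3)
  expect_equal(vig[1, 1], 0.8)
  expect_equal(vig[1, sp$image_size], 0.8)
})

test_that("rendered frames reproduce trace concentrations under truth masks", {
  ts <- trace_spec(n_cells = 4, n_frames = 20, event_rate = 3,
                   magnitude_range = c(5, 40), seed = 5)
  ens <- gen_trace_ensemble(ts)
  sc <- gen_image_sequence(scene_spec(seed = 5), ens$truth)
  cal <- build_reference(gen_reference_stack(scene_spec(seed = 5)))
  for (i in 1:4) {
    cyto <- sc$truth$cell == i & sc$truth$nucleus == 0 &
      sc$truth$lipoplex_z1 == 0 & sc$truth$lipoplex_z2 == 0
    pos <- c(sc$truth$cells$y[i], sc$truth$cells$x[i])
    meas <- vapply(seq_along(sc$frames), function(f) {
      median(sc$frames[[f]]$z1$sirna[cyto])
    }, numeric(1))
    conc <- to_concentration(meas, pos, cal)
    expect_equal(conc, unname(ens$truth$clean[i, ]), tolerance = 0.05)
  }
  # event step visible at the right frame
  ev <- ens$truth$events[1, ]
  cyto <- sc$truth$cell == ev$track_id & sc$truth$nucleus == 0
  before <- median(sc$frames[[ev$frame - 1]]$z1$sirna[cyto])
  at <- median(sc$frames[[ev$frame]]$z1$sirna[cyto])
  pos <- c(sc$truth$cells$y[ev$track_id], sc$truth$cells$x[ev$track_id])
  dstep <- to_concentration(at, pos, cal) - to_concentration(before, pos, cal)
  expect_equal(dstep, ev$magnitude, tolerance = 0.1 * ev$magnitude)
})

test_that("scene/trace consistency and geometry invariants are checked", {
  ens <- gen_trace_ensemble(trace_spec(n_cells = 3, n_frames = 20, seed = 1))
  expect_error(gen_image_sequence(scene_spec(seed = 1), ens$truth,
                                  frames = 25), "frames")
  expect_error(scene_spec(vignette_min = 0), "vignette")
  expect_error(scene_spec(psf_sigma_outfocus = 0.5), "psf")
  expect_error(scene_spec(nucleus_radius = 12, cell_radius = 11), "radius")
})

test_that("knockdown datasets follow the generating ODE", {
  m <- kinetic_model()
  kd <- gen_knockdown_dataset(m, c(0, 0.5, 5), times_h = seq(0, 12, 1),
                              noise_sd = 0, seed = 3)
  # dose 0: identically 1 (up to the lognormal noise, disabled here)
  expect_equal(unname(kd$expr[1, ]), rep(1, 13))
  # monotone in dose at every timepoint
  expect_true(all(kd$truth$clean[3, ] <= kd$truth$clean[2, ] + 1e-9))
  # dose = model's 10 h absolute IC50 gives expression 0.5 at 10 h
  ic <- kinetic_ic50(m, t_star = 10)
  at10 <- predict_knockdown(m, ic, 10)[1, 1]
  expect_equal(at10, 0.5, tolerance = 1e-3)
  expect_error(gen_knockdown_dataset(m, c(-1, 2)), "non-negative")
})
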
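test_that("segmentation recovers truth nuclei and tracks static cells", {
  ens <- gen_trace_ensemble(trace_spec(n_cells = 4, n_frames = 20,
                                       event_rate = 0, seed = 3))
  sc <- gen_image_sequence(scene_spec(seed = 3), ens$truth, frames = 1:10)
  seg <- segment_and_track(sc)
  expect_equal(length(unique(seg$tracks$track_id)), 4)
  # every track spans all 10 frames (static cells, noiseless render)
  lens <- table(seg$tracks$track_id)
  expect_true(all(lens == 10))
  # per-cell nucleus IoU vs ground truth above 0.8
  labs <- seg$masks[[1]]$nucleus
  for (i in 1:4) {
    tru <- sc$truth$nucleus == i
    ovl <- vapply(seq_len(max(labs)), function(l) sum(labs == l & tru),
                  numeric(1))
    s <- labs == which.max(ovl)
    expect_gt(sum(s & tru) / sum(s | tru), 0.8)
  }
})

test_that("a cell leaving the field terminates its track", {
  n <- 48
  mk_frame <- function(with_cell) {
    nuc <- matrix(0, n, n)
    eg <- matrix(0, n, n)
    if (with_cell) {
      nuc[disk(n, 24, 24, 5)] <- 100
      eg[disk(n, 24, 24, 12)] <- 50
    }
    list(z1 = list(sirna = matrix(0, n, n), egfp = eg, nuclear = nuc),
         z2 = list(sirna = matrix(0, n, n)))
  }
  sc <- structure(list(frames = c(rep(list(mk_frame(TRUE)), 6),
                                  rep(list(mk_frame(FALSE)), 4))),
                  class = "scene")
  seg <- segment_and_track(sc)
  expect_equal(unique(seg$tracks$track_id), 1)
  expect_equal(max(seg$tracks$frame), 6)
})

test_that("lipoplex masking covers out-of-focus light and clips at borders", {
  n <- 40
  z1 <- matrix(0, n, n)
  z2 <- matrix(0, n, n)
  z2[20, 20] <- 100                       # bright blob only in z2
  m <- mask_lipoplexes(z1, z2, threshold = 50, margin_px = 3)
  expect_true(m[20, 20])
  expect_true(m[23, 20])                  # dilated into z1 footprint
  expect_false(m[30, 30])
  # blank frames: empty mask
  expect_false(any(mask_lipoplexes(matrix(0, n, n), matrix(0, n, n), 50)))
  # border blob: clipped, no error
  z1b <- matrix(0, n, n)
  z1b[1, 1] <- 100
  mb <- mask_lipoplexes(z1b, matrix(0, n, n), 50, margin_px = 3)
  expect_true(mb[1, 1] && mb[1, 4])
  expect_equal(dim(mb), c(n, n))
})

test_that("measured medians are background-corrected and blob-immune", {
  n <- 40
  sc <- flat_scene(n, n_frames = 2)
  # one cell: nucleus disk + cell disk; uniform cytosol value 7, bg 2
  nuc <- matrix(0, n, n); nuc[disk(n, 20, 20, 4)] <- 100
  eg <- matrix(0, n, n); eg[disk(n, 20, 20, 10)] <- 50
  sir <- matrix(2, n, n); sir[disk(n, 20, 20, 10) & !disk(n, 20, 20, 4)] <- 9
  for (f in 1:2) {
    sc$frames[[f]]$z1$nuclear <- nuc
    sc$frames[[f]]$z1$egfp <- eg
    sc$frames[[f]]$z1$sirna <- sir
  }
  # add a saturating blob inside the cell in frame 2
  sir2 <- sir; sir2[disk(n, 24, 20, 1.5)] <- 1e4
  sc$frames[[2]]$z1$sirna <- sir2
  seg <- segment_and_track(sc)
  tt <- measure_traces(sc, seg, imgproc_config(lipoplex_threshold = 100))
  expect_equal(tt$median_sirna_cyto, c(7, 7), tolerance = 1e-10)
  expect_equal(tt$background_sirna, c(2, 2))
  # background invariance: adding a constant to every pixel changes nothing
  sc2 <- sc
  for (f in 1:2) sc2$frames[[f]]$z1$sirna <- sc2$frames[[f]]$z1$sirna + 13
  tt2 <- measure_traces(sc2, segment_and_track(sc2),
                        imgproc_config(lipoplex_threshold = 113))
  expect_equal(tt2$median_sirna_cyto, tt$median_sirna_cyto, tolerance = 1e-10)
})

test_that("fully masked cells are recorded as missing and flagged", {
  n <- 40
  sc <- flat_scene(n, n_frames = 1)
  nuc <- matrix(0, n, n); nuc[disk(n, 20, 20, 4)] <- 100
  eg <- matrix(0, n, n); eg[disk(n, 20, 20, 8)] <- 50
  sir <- matrix(0, n, n); sir[disk(n, 20, 20, 9)] <- 500 # whole cell "blob"
  sc$frames[[1]]$z1$nuclear <- nuc
  sc$frames[[1]]$z1$egfp <- eg
  sc$frames[[1]]$z1$sirna <- sir
  seg <- segment_and_track(sc)
  tt <- measure_traces(sc, seg, imgproc_config(lipoplex_threshold = 100,
                                               lipoplex_margin_px = 5))
  expect_true(all(is.na(tt$median_sirna_cyto)))
  expect_true(all(tt$flag_empty_mask))
})

test_that("lipoplex diameters follow the equal-area circle formula", {
  # single particle of area pi um^2 -> diameter 2 um
  n <- 60
  img <- matrix(0, n, n)
  img[disk(n, 30, 30, sqrt(pi / pi) / 0.1)] <- 100 # radius 1 um at 0.1 um/px
  d <- lipoplex_diameters(img, 50, 0.1)
  expect_equal(length(d), 1)
  expect_equal(d, 2, tolerance = 0.05) # pixelated disk
  # 79 px at 0.1 um/px: area 0.79 um^2 -> d ~ 1.003 um (hand arithmetic)
  img2 <- matrix(0, n, n)
  img2[seq_len(79)] <- 100
  expect_equal(lipoplex_diameters(img2, 50, 0.1),
               2 * sqrt(79 * 0.01 / pi), tolerance = 1e-12)
  expect_identical(lipoplex_diameters(matrix(0, 5, 5), 1, 0.1), numeric(0))
})

test_that("cytosol volume subtracts nuclear from cell volume", {
  expect_equal(cytosol_volume(rep(100, 10), rep(20, 5), dz = 1), 900)
  expect_equal(cytosol_volume(rep(50, 4), rep(50, 4), dz = 2), 0)
  expect_error(cytosol_volume(rep(10, 3), rep(20, 3), dz = 1), "exceeds")
  expect_error(cytosol_volume(rep(10, 3), rep(1, 3), dz = 0), "dz")
  # the synthetic default geometry sits near the typical 5000 fL cytosol:
  # a ~12 um tall cell column with an ~8 um tall nucleus
  sp <- scene_spec()
  v <- cytosol_volume(rep(pi * sp$cell_radius^2, 12),
                      rep(pi * sp$nucleus_radius^2, 8), dz = 1)
  expect_gt(v, 3800)
  expect_lt(v, 5900)
})
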
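## Image-processing module: two-plane stacks -> per-cell background-corrected
## median-intensity traces, plus the geometric utilities (lipoplex diameters,
## cytosol volume).

#' Configuration for segmentation, tracking and measurement
#'
#' @param denoise_sigma Gaussian blur SD (pixels) applied to the nuclear and
#'   eGFP channels before thresholding. Denoising is a pluggable standard
#'   step used only for segmentation; measurements are always taken on raw
#'   images.
#' @param min_nucleus_px discard nucleus candidates smaller than this.
#' @param max_displacement maximum centroid displacement (pixels) linked
#'   between consecutive frames; `NULL` = 2x the median nucleus radius.
#' @param lipoplex_threshold intensity above which siRNA-channel pixels are
#'   treated as lipoplex particles; `NULL` = 99.9th percentile of the
#'   first-frame siRNA channel.
#' @param lipoplex_margin_px dilation margin applied to the particle
#'   footprint before exclusion (default 3).
#' @return list of class `imgproc_config`.
#' @export
imgproc_config <- function(denoise_sigma = 1, min_nucleus_px = 20,
                           max_displacement = NULL,
                           lipoplex_threshold = NULL,
                           lipoplex_margin_px = 3) {
  structure(list(denoise_sigma = denoise_sigma,
                 min_nucleus_px = min_nucleus_px,
                 max_displacement = max_displacement,
                 lipoplex_threshold = lipoplex_threshold,
                 lipoplex_margin_px = lipoplex_margin_px),
            class = "imgproc_config")
}

#' Segment nuclei and cells and track them across frames
#'
#' Per frame: the nuclear channel is denoised and Otsu-thresholded; connected
#' components above `min_nucleus_px` become nuclei. Cells are grown from the
#' nucleus seeds into the Otsu-foreground of the denoised eGFP channel
#' (seeded region growing standing in for a seeded watershed). Nuclei are
#' linked across frames by greedy nearest-centroid matching within
#' `max_displacement`; unmatched detections start new tracks, unmatched
#' tracks terminate.
#'
#' @param scene a `scene` from [gen_image_sequence()] or any list with the
#'   same `frames` layout.
#' @param config an [imgproc_config()].
#' @return list with `masks` (per frame: `nucleus`, `cell` label matrices,
#'   labels = per-frame segment ids) and `tracks` data.frame
#'   `(track_id, frame, label, x, y, area)`.
#' @export
segment_and_track <- function(scene, config = imgproc_config()) {
  frames <- scene$frames
  n_frames <- length(frames)
  masks <- vector("list", n_frames)
  track_rows <- list()
  active <- data.frame(track_id = integer(), x = numeric(), y = numeric())
  next_id <- 1L

  for (f in seq_len(n_frames)) {
    fr <- frames[[f]]
    nuc_img <- gaussian_blur(fr$z1$nuclear, config$denoise_sigma)
    thr <- otsu_threshold(nuc_img)
    nuc_bin <- nuc_img > thr
    nuc_lab <- label_components(nuc_bin)
    cents <- label_centroids(nuc_lab)
    keep <- cents$label[cents$area >= config$min_nucleus_px]
    nuc_lab[!(nuc_lab %in% keep)] <- 0L
    cents <- cents[cents$label %in% keep, , drop = FALSE]

    egfp_img <- gaussian_blur(fr$z1$egfp, config$denoise_sigma)
    cell_fg <- egfp_img > otsu_threshold(egfp_img)
    cell_fg <- cell_fg | nuc_lab > 0
    cell_lab <- grow_labels(nuc_lab, cell_fg)

    masks[[f]] <- list(nucleus = nuc_lab, cell = cell_lab)

    if (nrow(cents) == 0) {
      active <- active[0, ]
      next
    }
    med_r <- median(sqrt(cents$area / pi))
    max_disp <- config$max_displacement %||% (2 * med_r)

    assigned <- rep(NA_integer_, nrow(cents))
    if (nrow(active) > 0) {
      ## greedy matching: smallest distances first
      d <- outer(seq_len(nrow(active)), seq_len(nrow(cents)),
                 function(i, j) sqrt((active$x[i] - cents$x[j])^2 +
                                     (active$y[i] - cents$y[j])^2))
      repeat {
        if (all(!is.finite(d)) || min(d, na.rm = TRUE) > max_disp) break
        k <- arrayInd(which.min(d), dim(d))
        assigned[k[2]] <- active$track_id[k[1]]
        d[k[1], ] <- Inf
        d[, k[2]] <- Inf
      }
    }
    new <- which(is.na(assigned))
    if (length(new) > 0) {
      assigned[new] <- seq.int(next_id, length.out = length(new))
      next_id <- next_id + length(new)
    }
    track_rows[[f]] <- data.frame(
      track_id = assigned, frame = f, label = cents$label,
      x = cents$x, y = cents$y, area = cents$area
    )
    active <- data.frame(track_id = assigned, x = cents$x, y = cents$y)
  }

  tracks <- do.call(rbind, track_rows)
  if (is.null(tracks)) {
    tracks <- data.frame(track_id = integer(), frame = integer(),
                         label = integer(), x = numeric(), y = numeric(),
                         area = numeric())
  }
  list(masks = masks, tracks = tracks[order(tracks$track_id, tracks$frame), ])
}

#' Lipoplex exclusion mask from a two-plane frame pair
#'
#' Pixels above `threshold` in either z-plane of the siRNA channel are
#' particles; the union footprint, dilated by `margin_px`, is the exclusion
#' mask applied to z1 measurements. This removes both in-focus puncta and
#' the halo of out-of-focus light from particles in the other plane.
#'
#' @param z1,z2 siRNA-channel matrices of the two planes.
#' @param threshold particle intensity threshold (must sit above typical
#'   cytosolic signal).
#' @param margin_px dilation radius in pixels.
#' @return logical exclusion matrix (TRUE = excluded).
#' @export
mask_lipoplexes <- function(z1, z2, threshold, margin_px = 3) {
  stopifnot(all(dim(z1) == dim(z2)))
  fg <- (z1 > threshold) | (z2 > threshold)
  if (!any(fg)) return(fg)
  dilate_mask(fg, margin_px)
}

#' Measure background-corrected per-cell median-intensity traces
#'
#' Per cell and frame, medians of raw pixel intensities are taken in three
#' masks: the full cell mask minus lipoplexes (siRNA, used for event
#' detection), the cytosol mask (cell minus nucleus minus lipoplexes; siRNA
#' quantification), and the nucleus mask (eGFP; robust to knockdown-driven
#' loss of cell-boundary signal). The per-frame background is the median of
#' all pixels outside every object (cells, nuclei, lipoplexes) and is
#' subtracted. A cell whose mask is empty after exclusions gets `NA` and a
#' flag.
#'
#' @param scene a `scene` (see [gen_image_sequence()]).
#' @param seg output of [segment_and_track()].
#' @param config an [imgproc_config()]; its lipoplex threshold/margin are
#'   used to build per-frame exclusion masks via [mask_lipoplexes()].
#' @return data.frame of class `trace_table` with columns `track_id, frame,
#'   median_sirna_cell, median_sirna_cyto, median_egfp_nucleus,
#'   background_sirna, background_egfp, flag_empty_mask`.
#' @export
measure_traces <- function(scene, seg, config = imgproc_config()) {
  frames <- scene$frames
  thr <- config$lipoplex_threshold %||%
    as.numeric(quantile(frames[[1]]$z1$sirna, 0.999))
  rows <- list()
  for (f in seq_len(length(frames))) {
    fr <- frames[[f]]
    m <- seg$masks[[f]]
    lip <- mask_lipoplexes(fr$z1$sirna, fr$z2$sirna, thr,
                           config$lipoplex_margin_px)
    free <- m$cell == 0 & m$nucleus == 0 & !lip
    bg_sirna <- median(fr$z1$sirna[free])
    bg_egfp <- median(fr$z1$egfp[free])
    tr <- seg$tracks[seg$tracks$frame == f, , drop = FALSE]
    if (nrow(tr) == 0) next
    for (i in seq_len(nrow(tr))) {
      lab <- tr$label[i]
      cell_px <- m$cell == lab & !lip
      cyto_px <- cell_px & m$nucleus == 0
      nuc_px <- m$nucleus == lab
      med_cell <- if (any(cell_px)) median(fr$z1$sirna[cell_px]) else NA_real_
      med_cyto <- if (any(cyto_px)) median(fr$z1$sirna[cyto_px]) else NA_real_
      med_nuc <- if (any(nuc_px)) median(fr$z1$egfp[nuc_px]) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        track_id = tr$track_id[i], frame = f,
        median_sirna_cell = med_cell - bg_sirna,
        median_sirna_cyto = med_cyto - bg_sirna,
        median_egfp_nucleus = med_nuc - bg_egfp,
        background_sirna = bg_sirna, background_egfp = bg_egfp,
        flag_empty_mask = !any(cyto_px)
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(track_id = integer(), frame = integer(),
                      median_sirna_cell = numeric(),
                      median_sirna_cyto = numeric(),
                      median_egfp_nucleus = numeric(),
                      background_sirna = numeric(),
                      background_egfp = numeric(),
                      flag_empty_mask = logical())
  }
  class(out) <- c("trace_table", "data.frame")
  out
}

#' Equivalent-circle diameters of lipoplex particles
#'
#' Particles are connected components above `threshold`; each diameter
#' assumes the measured pixel area is that of a circle:
#' `d = 2 * sqrt(area / pi)` with `area = n_px * pixel_size^2`.
#'
#' @param image intensity matrix.
#' @param threshold particle threshold.
#' @param pixel_size micrometres per pixel (> 0).
#' @return numeric vector of diameters in micrometres (empty if none).
#' @export
lipoplex_diameters <- function(image, threshold, pixel_size) {
  assert_that(pixel_size > 0, "pixel_size must be positive")
  lab <- label_components(image > threshold)
  if (max(lab) == 0) return(numeric(0))
  areas <- as.numeric(table(lab[lab > 0])) * pixel_size^2
  2 * sqrt(areas / pi)
}

#' Cytosol volume from per-plane areas
#'
#' `V = dz * (sum(cell areas) - sum(nucleus areas))`, with areas in square
#' micrometres and `dz` in micrometres; 1 um^3 = 1 fL.
#'
#' @param cell_areas,nucleus_areas per-plane areas (um^2). The nucleus may
#'   appear in fewer planes than the cell; each stack is summed over its own
#'   planes.
#' @param dz plane spacing (um, > 0).
#' @return cytosol volume in femtolitres.
#' @export
cytosol_volume <- function(cell_areas, nucleus_areas, dz) {
  assert_that(dz > 0, "dz must be positive")
  v <- dz * (sum(cell_areas) - sum(nucleus_areas))
  assert_that(v >= 0, "nucleus volume exceeds cell volume")
  v
}
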
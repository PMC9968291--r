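## Synthetic-data module: trace ensembles, two-plane image scenes and
## knockdown datasets with full ground truth. All generators are
## deterministic given their seed.

#' Specification for a synthetic single-cell siRNA trace ensemble
#'
#' Describes an ensemble of background-corrected cytosolic siRNA traces (in
#' nM) with burst-like release events. A release event is rendered as an
#' instantaneous concentration step (cytoplasmic dispersion completes in
#' ~20 s, far below the 5-min frame interval) followed by exponential decay
#' of the cytosolic signal as the siRNA redistributes into foci.
#'
#' @param n_cells number of cells (tracks).
#' @param n_frames number of frames (>= 20).
#' @param frame_interval minutes between frames (default 5, the acquisition
#'   interval used for long-term imaging).
#' @param event_rate expected release events per cell per hour.
#' @param magnitude_range lower/upper bound (nM) of the log-uniform release
#'   magnitude distribution. Default `c(1, 40)` spans the >1 order of
#'   magnitude observed between low and high dose quintiles.
#' @param decay_rate exponential post-release decay constant, per frame.
#' @param noise_sd additive Gaussian frame noise, nM-equivalents.
#' @param bleach_rate fractional signal loss per frame (multiplicative
#'   exponential bleaching, identical for all cells in the "well").
#' @param baseline pre-release cytosolic background level, nM.
#' @param calib_error_rel relative calibration uncertainty carried through to
#'   the uncertainty budget (not applied to the traces themselves).
#' @param seed integer seed; identical spec + seed gives identical output.
#' @return object of class `trace_spec`.
#' @export
trace_spec <- function(n_cells = 50L, n_frames = 120L, frame_interval = 5,
                       event_rate = 0.25, magnitude_range = c(1, 40),
                       decay_rate = 0.05, noise_sd = 0.15,
                       bleach_rate = 0, baseline = 0,
                       calib_error_rel = 0.08, seed = 1L) {
  assert_that(n_frames >= 20, "n_frames must be >= 20")
  assert_that(all(magnitude_range > 0), "magnitude bounds must be positive")
  assert_that(magnitude_range[2] >= magnitude_range[1],
              "magnitude_range must be increasing")
  assert_that(bleach_rate >= 0 && bleach_rate < 1,
              "bleach_rate must be in [0, 1)")
  assert_that(event_rate >= 0, "event_rate must be non-negative")
  assert_that(noise_sd >= 0, "noise_sd must be non-negative")
  structure(list(
    n_cells = as.integer(n_cells), n_frames = as.integer(n_frames),
    frame_interval = frame_interval, event_rate = event_rate,
    magnitude_range = magnitude_range, decay_rate = decay_rate,
    noise_sd = noise_sd, bleach_rate = bleach_rate, baseline = baseline,
    calib_error_rel = calib_error_rel, seed = as.integer(seed)
  ), class = "trace_spec")
}

#' Generate a synthetic trace ensemble with ground truth
#'
#' Traces are `baseline + sum(events)` where each event contributes an
#' instantaneous step of magnitude `A` at its frame followed by exponential
#' decay `A * exp(-k * (t - t0))`, the sum is multiplied by cumulative
#' bleaching `(1 - bleach_rate)^(t-1)`, and Gaussian noise of SD `noise_sd`
#' is added. Event frames are drawn so that each event has enough history
#' (>= 11 frames) and persistence room (>= 6 frames) to be detectable in
#' principle; event counts per cell are Poisson with mean
#' `event_rate * duration_hours`.
#'
#' @param spec a [trace_spec()].
#' @return list with elements
#'   \describe{
#'     \item{traces}{data.frame `(track_id, frame, conc)`; `conc` in nM.}
#'     \item{truth}{object of class `ground_truth`: `events` data.frame
#'       `(track_id, frame, magnitude)`, `clean` matrix (cells x frames) of
#'       noiseless concentrations (bleaching applied), and the spec.}
#'   }
#' @examples
#' ens <- gen_trace_ensemble(trace_spec(n_cells = 5, seed = 42))
#' head(ens$traces)
#' ens$truth$events
#' @export
gen_trace_ensemble <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  set.seed(spec$seed)
  nf <- spec$n_frames
  nc <- spec$n_cells
  duration_h <- nf * spec$frame_interval / 60
  frames <- seq_len(nf)
  bleach <- (1 - spec$bleach_rate)^(frames - 1)

  ## event frames must leave history for detection (10-frame SD lookback)
  ## and room for the persistence check
  fmin <- 12L
  fmax <- nf - 6L
  ev_list <- vector("list", nc)
  clean <- matrix(spec$baseline, nrow = nc, ncol = nf)
  for (i in seq_len(nc)) {
    k <- rpois(1, spec$event_rate * duration_h)
    if (k > 0) {
      ef <- sort(sample(fmin:fmax, min(k, fmax - fmin + 1)))
      lo <- log(spec$magnitude_range[1])
      hi <- log(spec$magnitude_range[2])
      mag <- exp(runif(length(ef), lo, hi))
      ev_list[[i]] <- data.frame(track_id = i, frame = ef, magnitude = mag)
      for (j in seq_along(ef)) {
        t0 <- ef[j]
        idx <- t0:nf
        clean[i, idx] <- clean[i, idx] +
          mag[j] * exp(-spec$decay_rate * (idx - t0))
      }
    }
  }
  clean <- sweep(clean, 2, bleach, `*`)
  noisy <- clean + matrix(rnorm(nc * nf, sd = spec$noise_sd), nc, nf)

  events <- do.call(rbind, ev_list)
  if (is.null(events)) {
    events <- data.frame(track_id = integer(), frame = integer(),
                         magnitude = numeric())
  }
  traces <- data.frame(
    track_id = rep(seq_len(nc), each = nf),
    frame = rep(frames, times = nc),
    conc = as.vector(t(noisy))
  )
  truth <- structure(list(events = events, clean = clean, spec = spec),
                     class = "ground_truth")
  list(traces = traces, truth = truth)
}

#' Generate one synthetic event trace
#'
#' Building block for controlled ensembles: a single trace with release
#' events at known frames and magnitudes, exponential decay and Gaussian
#' noise. Uses the current RNG state (seed outside for reproducibility).
#'
#' @param n_frames trace length.
#' @param event_frames,magnitudes event positions (1-based) and step sizes
#'   (nM); equal length, possibly empty.
#' @param decay_rate per-frame exponential decay constant.
#' @param noise_sd additive Gaussian noise SD (nM).
#' @param baseline pre-event level (nM).
#' @return numeric vector of length `n_frames`.
#' @export
gen_event_trace <- function(n_frames, event_frames, magnitudes,
                            decay_rate = 0.05, noise_sd = 0.15,
                            baseline = 0) {
  assert_that(length(event_frames) == length(magnitudes),
              "event_frames and magnitudes must match")
  assert_that(all(magnitudes > 0), "magnitudes must be positive")
  tr <- rep(baseline, n_frames)
  for (j in seq_along(event_frames)) {
    idx <- event_frames[j]:n_frames
    tr[idx] <- tr[idx] + magnitudes[j] * exp(-decay_rate * (idx - event_frames[j]))
  }
  tr + rnorm(n_frames, sd = noise_sd)
}

#' Specification for a synthetic two-plane imaging scene
#'
#' Geometry and optics of a rendered two-z-plane field of view: disk-shaped
#' cells with nuclei, bright lipoplex puncta placed in either plane
#' (rendered out of focus in the other), a radial vignetting field, and
#' Poisson-Gaussian detector noise.
#'
#' @param image_size pixels per side (square field).
#' @param pixel_size micrometres per pixel.
#' @param z_spacing micrometres between the two planes (default 4).
#' @param cell_radius,nucleus_radius cell/nucleus radii in micrometres;
#'   nucleus must be smaller. Defaults give a median cytosol volume near the
#'   5000 fL typical of HeLa cells when combined with [cytosol_volume()].
#' @param n_lipoplexes bright puncta scattered over the field.
#' @param lipoplex_intensity mean punctum amplitude (arbitrary detector
#'   units; well above cytosolic levels).
#' @param vignette_min corner/centre sensitivity ratio of the multiplicative
#'   vignette field, in (0, 1].
#' @param psf_sigma_infocus,psf_sigma_outfocus Gaussian radii (pixels) used
#'   to render puncta in their own vs the other plane;
#'   `psf_sigma_outfocus > psf_sigma_infocus`.
#' @param unit_intensity detector units corresponding to the 1000 nM
#'   reference concentration at the field centre.
#' @param egfp_level,nuclear_level rendered eGFP and nuclear-stain
#'   amplitudes (detector units).
#' @param noise_gain,read_noise_sd Poisson gain (photons per unit) and
#'   additive Gaussian read noise; set `noise_gain = 0` for noiseless
#'   renders.
#' @param seed integer seed.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = 112L, pixel_size = 0.5, z_spacing = 4,
                       cell_radius = 12, nucleus_radius = 5.5,
                       n_lipoplexes = 6L, lipoplex_intensity = 4000,
                       vignette_min = 0.8,
                       psf_sigma_infocus = 1, psf_sigma_outfocus = 4,
                       unit_intensity = 1000,
                       egfp_level = 60, nuclear_level = 100,
                       noise_gain = 0, read_noise_sd = 0, seed = 1L) {
  assert_that(vignette_min > 0 && vignette_min <= 1,
              "vignette_min must be in (0, 1]")
  assert_that(psf_sigma_outfocus > psf_sigma_infocus,
              "psf_sigma_outfocus must exceed psf_sigma_infocus")
  assert_that(nucleus_radius < cell_radius,
              "nucleus radius must be smaller than cell radius")
  structure(list(
    image_size = as.integer(image_size), pixel_size = pixel_size,
    z_spacing = z_spacing, cell_radius = cell_radius,
    nucleus_radius = nucleus_radius, n_lipoplexes = as.integer(n_lipoplexes),
    lipoplex_intensity = lipoplex_intensity, vignette_min = vignette_min,
    psf_sigma_infocus = psf_sigma_infocus,
    psf_sigma_outfocus = psf_sigma_outfocus,
    unit_intensity = unit_intensity, egfp_level = egfp_level,
    nuclear_level = nuclear_level, noise_gain = noise_gain,
    read_noise_sd = read_noise_sd, seed = as.integer(seed)
  ), class = "scene_spec")
}

## Radial vignette field: 1 at the centre, vignette_min at the corners,
## quadratic fall-off in radius.
#' @noRd
vignette_field <- function(n, vmin) {
  ctr <- (n + 1) / 2
  d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`)
  1 - (1 - vmin) * d2 / max(d2)
}

#' @noRd
disk_mask <- function(n, cx, cy, r) {
  outer((seq_len(n) - cy)^2, (seq_len(n) - cx)^2, `+`) <= r^2
}

## Add a Gaussian spot of given amplitude and sigma (pixels) to an image.
#' @noRd
add_spot <- function(img, cx, cy, amp, sigma) {
  n <- nrow(img)
  gx <- exp(-((seq_len(n) - cx)^2) / (2 * sigma^2))
  gy <- exp(-((seq_len(n) - cy)^2) / (2 * sigma^2))
  img + amp * outer(gy, gx)
}

#' Render a two-plane multichannel image sequence from a trace ensemble
#'
#' Cells are laid out on a jittered grid of non-overlapping disks; the
#' cytosol (cell minus nucleus) of each cell carries the siRNA concentration
#' of its trace converted to detector units
#' (`conc / 1000 * unit_intensity`), scaled by the vignette field. Bright
#' lipoplex puncta are assigned at random to z1 or z2, rendered sharp
#' (`psf_sigma_infocus`) in their own plane and blurred
#' (`psf_sigma_outfocus`, flux-preserving amplitude scaling) in the other.
#' The nuclear channel carries nucleus disks, the eGFP channel cell disks.
#' With `noise_gain > 0` a Poisson-Gaussian noise model is applied.
#'
#' @param spec a [scene_spec()].
#' @param trace_truth the `truth` element of [gen_trace_ensemble()]; its
#'   `clean` matrix supplies per-cell, per-frame cytosolic concentrations.
#' @param frames optional integer vector of frame indices to render
#'   (defaults to all; rendering is the slow part of the simulator).
#' @return object of class `scene`: list with `frames` (per frame:
#'   `z1$sirna`, `z1$egfp`, `z1$nuclear`, `z2$sirna` matrices), `truth`
#'   (label masks `cell`, `nucleus`, `lipoplex_z1`, `lipoplex_z2`, the
#'   `vignette` field, per-cell geometry `cells`, and `lipoplexes`) and
#'   `spec`.
#' @export
gen_image_sequence <- function(spec, trace_truth, frames = NULL) {
  stopifnot(inherits(spec, "scene_spec"), inherits(trace_truth, "ground_truth"))
  set.seed(spec$seed)
  n <- spec$image_size
  nc <- nrow(trace_truth$clean)
  nf <- ncol(trace_truth$clean)
  frames <- frames %||% seq_len(nf)
  assert_that(all(frames >= 1 & frames <= nf),
              "requested frames outside trace ground truth")

  r_cell <- spec$cell_radius / spec$pixel_size
  r_nuc <- spec$nucleus_radius / spec$pixel_size

  ## jittered grid placement, error if the field cannot hold the cells
  per_side <- ceiling(sqrt(nc))
  pitch <- n / per_side
  assert_that(pitch >= 2 * r_cell + 2,
              "scene too small for requested cell count/radius")
  centers <- expand.grid(gx = seq_len(per_side), gy = seq_len(per_side))
  centers <- centers[seq_len(nc), , drop = FALSE]
  jit <- (pitch / 2 - r_cell - 1)
  cx <- (centers$gx - 0.5) * pitch + runif(nc, -jit, jit)
  cy <- (centers$gy - 0.5) * pitch + runif(nc, -jit, jit)

  cell_mask <- matrix(0L, n, n)
  nuc_mask <- matrix(0L, n, n)
  for (i in seq_len(nc)) {
    cell_mask[disk_mask(n, cx[i], cy[i], r_cell)] <- i
    nuc_mask[disk_mask(n, cx[i], cy[i], r_nuc)] <- i
  }

  ## lipoplexes: static positions, random plane, lognormal amplitudes
  nl <- spec$n_lipoplexes
  lip <- data.frame(
    x = runif(nl, 3, n - 3), y = runif(nl, 3, n - 3),
    plane = sample(1:2, nl, replace = TRUE),
    amp = rlnorm(nl, log(spec$lipoplex_intensity), 0.4)
  )
  vig <- vignette_field(n, spec$vignette_min)

  lip_z1 <- matrix(0, n, n)
  lip_z2 <- matrix(0, n, n)
  ## flux-preserving blur of out-of-focus puncta
  oof_scale <- (spec$psf_sigma_infocus / spec$psf_sigma_outfocus)^2
  for (j in seq_len(nl)) {
    sharp_in <- function(img) add_spot(img, lip$x[j], lip$y[j], lip$amp[j],
                                       spec$psf_sigma_infocus)
    blur_in <- function(img) add_spot(img, lip$x[j], lip$y[j],
                                      lip$amp[j] * oof_scale,
                                      spec$psf_sigma_outfocus)
    if (lip$plane[j] == 1) {
      lip_z1 <- sharp_in(lip_z1); lip_z2 <- blur_in(lip_z2)
    } else {
      lip_z2 <- sharp_in(lip_z2); lip_z1 <- blur_in(lip_z1)
    }
  }
  ## truth lipoplex label masks: in-focus footprint in each plane
  lip_mask_z1 <- matrix(0L, n, n)
  lip_mask_z2 <- matrix(0L, n, n)
  for (j in seq_len(nl)) {
    m <- disk_mask(n, lip$x[j], lip$y[j], 2 * spec$psf_sigma_infocus + 1)
    if (lip$plane[j] == 1) lip_mask_z1[m] <- j else lip_mask_z2[m] <- j
  }

  cyto <- cell_mask != 0 & nuc_mask == 0
  egfp_base <- (cell_mask != 0) * spec$egfp_level
  nuc_img <- (nuc_mask != 0) * spec$nuclear_level

  add_noise <- function(img) {
    if (spec$noise_gain <= 0 && spec$read_noise_sd <= 0) return(img)
    out <- img
    if (spec$noise_gain > 0) {
      out <- rpois(length(img), pmax(img, 0) * spec$noise_gain) /
        spec$noise_gain
      out <- matrix(out, n, n)
    }
    if (spec$read_noise_sd > 0) {
      out <- out + matrix(rnorm(n * n, sd = spec$read_noise_sd), n, n)
    }
    out
  }

  rendered <- lapply(frames, function(f) {
    sir <- matrix(0, n, n)
    for (i in seq_len(nc)) {
      ci <- cyto & cell_mask == i
      sir[ci] <- trace_truth$clean[i, f] / 1000 * spec$unit_intensity
    }
    z1s <- add_noise(sir * vig + lip_z1 * vig)
    z2s <- add_noise(lip_z2 * vig)
    z1e <- add_noise(egfp_base * vig)
    z1n <- add_noise(nuc_img * vig)
    list(z1 = list(sirna = z1s, egfp = z1e, nuclear = z1n),
         z2 = list(sirna = z2s))
  })
  names(rendered) <- as.character(frames)

  structure(list(
    frames = rendered, frame_index = frames,
    truth = list(cell = cell_mask, nucleus = nuc_mask,
                 lipoplex_z1 = lip_mask_z1, lipoplex_z2 = lip_mask_z2,
                 vignette = vig,
                 cells = data.frame(track_id = seq_len(nc), x = cx, y = cy,
                                    r_cell = r_cell, r_nucleus = r_nuc),
                 lipoplexes = lip),
    spec = spec, trace_truth = trace_truth
  ), class = "scene")
}

#' Render a synthetic calibration z-stack
#'
#' Emulates imaging a thin fluid column of reference solution. The default
#' axial profile is a plateau (planes inside the liquid column at full
#' intensity, tails at 30% — below the half-maximum), so the FWHM mean
#' projection of the stack equals the plateau value exactly and the
#' reference is consistent with the in-focus rendering of cells by
#' [gen_image_sequence()]. A `"gaussian"` profile is available for
#' exercising the FWHM plane-selection logic. Each plane is the profile
#' value times the vignette field, in the same detector units as the scene
#' (`unit_intensity` at the field centre corresponds to 1000 nM).
#'
#' @param spec a [scene_spec()].
#' @param n_planes planes in the stack.
#' @param conc_nM concentration of the imaged solution (default 1000, the
#'   1 uM reference).
#' @param profile `"plateau"` (default) or `"gaussian"`.
#' @param z_sigma axial Gaussian width in plane units (gaussian profile).
#' @param plateau_planes planes at full intensity (plateau profile).
#' @param noise_sd additive Gaussian noise per pixel.
#' @return 3-D array `[z, y, x]`.
#' @export
gen_reference_stack <- function(spec, n_planes = 15L, conc_nM = 1000,
                                profile = c("plateau", "gaussian"),
                                z_sigma = 3, plateau_planes = 7L,
                                noise_sd = 0) {
  profile <- match.arg(profile)
  n <- spec$image_size
  zc <- (n_planes + 1) / 2
  if (profile == "gaussian") {
    prof <- exp(-((seq_len(n_planes) - zc)^2) / (2 * z_sigma^2))
  } else {
    prof <- rep(0.3, n_planes)
    half <- (plateau_planes - 1) %/% 2
    sel <- pmax(1, round(zc) - half):pmin(n_planes, round(zc) + half)
    prof[sel] <- 1
  }
  vig <- vignette_field(n, spec$vignette_min)
  base <- conc_nM / 1000 * spec$unit_intensity
  stack <- array(0, dim = c(n_planes, n, n))
  for (z in seq_len(n_planes)) {
    pl <- base * prof[z] * vig
    if (noise_sd > 0) pl <- pl + matrix(rnorm(n * n, sd = noise_sd), n, n)
    stack[z, , ] <- pl
  }
  stack
}

#' Generate a synthetic single-cell knockdown dataset
#'
#' Simulates per-cell relative d1-eGFP expression curves after a single
#' cytosolic release of the given magnitude, from a [kinetic_model()] ODE
#' solution, with multiplicative lognormal cell-to-cell measurement noise.
#'
#' @param model a [kinetic_model()].
#' @param magnitudes per-cell peak cytosolic siRNA doses (nM); dose 0 means
#'   an untreated cell whose noiseless curve is identically 1.
#' @param times_h timepoints (hours since release) at which expression is
#'   reported.
#' @param noise_sd SD of the lognormal multiplicative noise (log scale).
#' @param seed integer seed.
#' @return list with `cells` data.frame `(track_id, dose)`, `expr` matrix
#'   (cells x timepoints) of noisy relative expression, `times_h`, and
#'   `truth` (noiseless curves matrix + the model).
#' @export
gen_knockdown_dataset <- function(model, magnitudes, times_h = seq(0, 14, 0.5),
                                  noise_sd = 0.1, seed = 1L) {
  stopifnot(inherits(model, "kinetic_model"))
  assert_that(all(magnitudes >= 0), "doses must be non-negative")
  set.seed(as.integer(seed))
  clean <- predict_knockdown(model, magnitudes, times_h)
  noise <- matrix(rlnorm(length(clean), 0, noise_sd),
                  nrow = nrow(clean), ncol = ncol(clean))
  list(
    cells = data.frame(track_id = seq_along(magnitudes), dose = magnitudes),
    expr = clean * noise,
    times_h = times_h,
    truth = list(clean = clean, model = model, dose = magnitudes)
  )
}

#' @export
print.trace_spec <- function(x, ...) {
  cat(sprintf(
    "trace_spec: %d cells x %d frames (%g min), event rate %g/h, mags [%g, %g] nM\n",
    x$n_cells, x$n_frames, x$frame_interval, x$event_rate,
    x$magnitude_range[1], x$magnitude_range[2]))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d events over %d cells\n",
              nrow(x$events), nrow(x$clean)))
  invisible(x)
}
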
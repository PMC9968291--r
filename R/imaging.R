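## Minimal image-processing primitives on numeric matrices. Implemented
## in-package (no imaging library in the supported dependency set) with
## vectorized matrix-shift algorithms; adequate for the synthetic fields
## and modest real frames this pipeline targets.

## Shift a matrix by (dy, dx), padding with `fill`.
#' @noRd
shift_mat <- function(m, dy, dx, fill = 0) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(fill, n1, n2)
  src_r <- max(1, 1 - dy):min(n1, n1 - dy)
  src_c <- max(1, 1 - dx):min(n2, n2 - dx)
  if (length(src_r) == 0 || length(src_c) == 0) return(out)
  out[src_r + dy, src_c + dx] <- m[src_r, src_c]
  out
}

#' Otsu threshold of an image
#'
#' Classic between-class-variance maximization on a 256-bin histogram.
#'
#' @param img numeric matrix.
#' @param n_bins histogram bins.
#' @return threshold value; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(img, n_bins = 256L) {
  v <- as.vector(img)
  rng <- range(v, finite = TRUE)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(pmax(
    findInterval(v, seq(rng[1], rng[2], length.out = n_bins + 1L),
                 all.inside = TRUE), 1L), n_bins), n_bins)
  p <- h / sum(h)
  mids <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  mids <- (mids[-1] + mids[-length(mids)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  bcv <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- 0
  mids[which.max(bcv)]
}

#' Separable Gaussian blur
#'
#' @param img numeric matrix.
#' @param sigma Gaussian SD in pixels; 0 returns the input unchanged.
#' @return blurred matrix (replicate-padded edges).
#' @export
gaussian_blur <- function(img, sigma = 1) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(m) {
    ## pad rows by replication, convolve along columns
    padded <- rbind(m[rep(1, r), , drop = FALSE], m,
                    m[rep(nrow(m), r), , drop = FALSE])
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) {
      out <- out + k[i] * padded[i:(i + nrow(m) - 1), , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(img))))
}

#' Connected-component labelling of a binary mask
#'
#' 8-connectivity, iterative minimum-label propagation. Labels are
#' consecutive integers ordered by first (column-major) pixel.
#'
#' @param mask logical matrix.
#' @return integer label matrix (0 = background).
#' @export
label_components <- function(mask) {
  n1 <- nrow(mask); n2 <- ncol(mask)
  full <- matrix(seq_len(n1 * n2), n1, n2) # unique ids, stable order
  cur <- ifelse(mask, full, 0L)
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0), ]
  repeat {
    nxt <- cur
    for (o in seq_len(nrow(offs))) {
      sh <- shift_mat(cur, offs$dy[o], offs$dx[o], fill = 0L)
      upd <- mask & sh > 0 & (nxt == 0 | sh < nxt)
      nxt[upd] <- sh[upd]
    }
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  u <- sort(unique(cur[cur > 0]))
  out <- matrix(0L, n1, n2)
  out[cur > 0] <- match(cur[cur > 0], u)
  out
}

#' Binary dilation by a disk
#'
#' @param mask logical or label matrix (nonzero = foreground).
#' @param radius disk radius in pixels.
#' @return logical matrix of the dilated footprint.
#' @export
dilate_mask <- function(mask, radius = 3) {
  fg <- mask != 0
  if (radius <= 0) return(fg)
  r <- ceiling(radius)
  out <- fg
  for (dy in -r:r) for (dx in -r:r) {
    if (dy * dy + dx * dx <= radius^2 && !(dy == 0 && dx == 0)) {
      out <- out | shift_mat(fg, dy, dx, fill = FALSE)
    }
  }
  out
}

## Grow seed labels into a foreground mask by iterative 8-neighbour
## propagation (a cheap seeded watershed substitute: each foreground pixel
## ends up with the label of the nearest seed along connected paths).
#' @noRd
grow_labels <- function(seeds, fg) {
  cur <- seeds
  cur[!fg & seeds == 0L] <- 0L
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0), ]
  repeat {
    changed <- FALSE
    for (o in seq_len(nrow(offs))) {
      sh <- shift_mat(cur, offs$dy[o], offs$dx[o], fill = 0L)
      upd <- fg & cur == 0L & sh > 0L
      if (any(upd)) {
        cur[upd] <- sh[upd]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  cur
}

## Centroids (and areas, px) of a label image.
#' @noRd
label_centroids <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0) {
    return(data.frame(label = integer(), y = numeric(), x = numeric(),
                      area = numeric()))
  }
  rows <- row(lab)[lab > 0]
  cols <- col(lab)[lab > 0]
  vals <- lab[lab > 0]
  data.frame(
    label = ids,
    y = tapply(rows, vals, mean)[as.character(ids)],
    x = tapply(cols, vals, mean)[as.character(ids)],
    area = as.numeric(table(vals)[as.character(ids)])
  )
}
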
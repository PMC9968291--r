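## Internal helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

## Abort with a consistent error class so callers can distinguish
## user/parameter errors from genuine failures.
#' @noRd
stop_param <- function(...) {
  stop(structure(
    class = c("cytorelease_param_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' @noRd
assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop_param(msg)
  invisible(TRUE)
}

## Avogadro constant, 2019 SI exact value (1/mol).
AVOGADRO <- 6.02214076e23

## Round to 2 significant figures, the reporting style used for molecule
## counts throughout.
#' @noRd
signif2 <- function(x) signif(x, 2)

## Quantile-based group index: split n sorted items into g groups of equal
## size (+/- 1), lowest values in group 1.
#' @noRd
quantile_bins <- function(n, g) {
  sizes <- rep(n %/% g, g)
  extra <- n %% g
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(g), times = sizes)
}

## Stable 32-bit polynomial hash of a character string (used for config
## provenance in run manifests; no cryptographic intent).
#' @noRd
config_hash <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "")))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

## t-based pointwise confidence band for a matrix of curves (rows = cells,
## cols = timepoints). Returns list(mean, lo, hi).
#' @noRd
curve_ci <- function(mat, level = 0.8) {
  m <- colMeans(mat, na.rm = TRUE)
  nn <- colSums(!is.na(mat))
  s <- apply(mat, 2, sd, na.rm = TRUE)
  se <- s / sqrt(pmax(nn, 1))
  tq <- qt(1 - (1 - level) / 2, df = pmax(nn - 1, 1))
  list(mean = m, lo = m - tq * se, hi = m + tq * se, n = nn)
}
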
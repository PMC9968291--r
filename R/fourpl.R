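## Four-parameter-logistic dose-response fitting on log10(dose), with the
## constraint style used for knockdown curves: top fixed at 1 (untreated
## level), bottom bounded in [0, 1], optional shared hillslope across
## curves, and bootstrap confidence intervals.

## 4PL response at log10-dose x.
#' @noRd
fourpl_curve <- function(x, top, bottom, hill, log_ic50) {
  bottom + (top - bottom) / (1 + 10^((log_ic50 - x) * hill))
}

## Absolute IC50: dose where the curve crosses response 0.5.
#' @noRd
fourpl_absolute_ic50 <- function(top, bottom, hill, log_ic50) {
  if (!(bottom < 0.5 && top > 0.5) || hill == 0) return(NA_real_)
  r <- (top - bottom) / (0.5 - bottom) - 1
  if (r <= 0) return(NA_real_)
  10^(log_ic50 - log10(r) / hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares 4PL on `log10(dose)` with the top asymptote fixed at 1 and
#' the bottom constrained to `[0, 1]`:
#' `y = bottom + (1 - bottom) / (1 + 10^((logIC50 - log10(d)) * hill))`.
#' The relative IC50 is the curve midpoint parameter; the absolute IC50 is
#' the dose where the fitted curve equals 0.5 (reported `NA` when the curve
#' never crosses 0.5). Optional bootstrap (resampling observations) gives
#' percentile confidence intervals for both.
#'
#' @param dose doses in nM (> 0).
#' @param response relative expression (1 = untreated).
#' @param top fixed top asymptote (default 1).
#' @param n_boot bootstrap replicates for CIs (0 = none).
#' @param ci_level confidence level for the bootstrap interval.
#' @param seed seed used when bootstrapping.
#' @return object of class `fourpl_fit`: `top, bottom, hillslope,
#'   ic50_relative, ic50_absolute, r_squared, degenerate`, plus
#'   `ci_relative`/`ci_absolute` when bootstrapped.
#' @export
fit_4pl <- function(dose, response, top = 1, n_boot = 0L, ci_level = 0.95,
                    seed = 1L) {
  assert_that(all(dose > 0), "doses must be positive")
  assert_that(length(dose) == length(response), "length mismatch")
  assert_that(length(unique(dose)) >= 4, "need >= 4 dose levels")
  x <- log10(dose)

  fit_once <- function(x, y) {
    obj <- function(p) {
      sum((y - fourpl_curve(x, top, p[1], p[2], p[3]))^2)
    }
    init <- c(max(0, min(1, min(tapply(y, x, mean)))), -1, median(x))
    op <- optim(init, obj, method = "L-BFGS-B",
                lower = c(0, -10, min(x) - 3),
                upper = c(min(1, top), 10, max(x) + 3))
    op
  }
  op <- fit_once(x, response)
  bottom <- op$par[1]; hill <- op$par[2]; log_i <- op$par[3]
  tss <- sum((response - mean(response))^2)
  r2 <- if (tss > 0) 1 - op$value / tss else 1
  degenerate <- diff(range(response)) < 0.05 || abs(hill) < 1e-3
  if (degenerate) warning("4PL fit is degenerate (flat response)")

  out <- list(top = top, bottom = bottom, hillslope = hill,
              ic50_relative = 10^log_i,
              ic50_absolute = fourpl_absolute_ic50(top, bottom, hill, log_i),
              r_squared = r2, degenerate = degenerate)

  if (n_boot > 0) {
    set.seed(as.integer(seed))
    n <- length(x)
    rel <- abs_ <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      idx <- sample(n, replace = TRUE)
      if (length(unique(x[idx])) < 4) next
      ob <- tryCatch(fit_once(x[idx], response[idx]), error = function(e) NULL)
      if (is.null(ob)) next
      rel[b] <- 10^ob$par[3]
      abs_[b] <- fourpl_absolute_ic50(top, ob$par[1], ob$par[2], ob$par[3])
    }
    a <- (1 - ci_level) / 2
    out$ci_relative <- unname(quantile(rel, c(a, 1 - a), na.rm = TRUE))
    out$ci_absolute <- unname(quantile(abs_, c(a, 1 - a), na.rm = TRUE))
    out$ci_level <- ci_level
  }
  structure(out, class = "fourpl_fit")
}

#' Fit multiple dose-response curves with a shared hillslope
#'
#' Joint least squares over several curves: each curve has its own bottom
#' and relative IC50, the hillslope is shared, top is fixed at 1.
#'
#' @param dose_list,response_list lists of equal length with per-curve dose
#'   and response vectors.
#' @return list of `fourpl_fit` objects (one per curve) with the common
#'   hillslope; attribute `"hillslope"` carries the shared value.
#' @export
fit_4pl_shared <- function(dose_list, response_list) {
  k <- length(dose_list)
  assert_that(k == length(response_list), "list length mismatch")
  xs <- lapply(dose_list, log10)
  obj <- function(p) {
    hill <- p[1]
    s <- 0
    for (i in seq_len(k)) {
      bot <- p[1 + i]
      li <- p[1 + k + i]
      s <- s + sum((response_list[[i]] -
                      fourpl_curve(xs[[i]], 1, bot, hill, li))^2)
    }
    s
  }
  init <- c(-1, rep(0.1, k), vapply(xs, median, numeric(1)))
  op <- optim(init, obj, method = "L-BFGS-B",
              lower = c(-10, rep(0, k), vapply(xs, min, numeric(1)) - 3),
              upper = c(10, rep(1, k), vapply(xs, max, numeric(1)) + 3))
  hill <- op$par[1]
  fits <- lapply(seq_len(k), function(i) {
    bot <- op$par[1 + i]; li <- op$par[1 + k + i]
    structure(list(top = 1, bottom = bot, hillslope = hill,
                   ic50_relative = 10^li,
                   ic50_absolute = fourpl_absolute_ic50(1, bot, hill, li),
                   r_squared = NA_real_, degenerate = FALSE),
              class = "fourpl_fit")
  })
  attr(fits, "hillslope") <- hill
  fits
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf(
    "4PL: bottom %.3f, hill %.3g | relative IC50 %.3g nM, absolute IC50 %s nM\n",
    x$bottom, x$hillslope, x$ic50_relative,
    if (is.na(x$ic50_absolute)) "NA" else sprintf("%.3g", x$ic50_absolute)))
  invisible(x)
}
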
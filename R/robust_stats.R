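# Shared robust statistics: a univariate adaptation of the ROUT outlier
# procedure (robust fit + FDR-controlled outlier tests) and 1D Gaussian
# fitting by maximum likelihood.

#' Univariate ROUT outlier detection
#'
#' Adaptation of the robust-regression-and-outlier-removal (ROUT) procedure
#' to a univariate sample: the robust "fit" is the sample median, the robust
#' standard deviation of the residuals (RSDR) is the 68.27th percentile of
#' the absolute residuals with a small-sample correction, and candidate
#' outliers (the most extreme 30% of points at most) are tested from the
#' least extreme candidate outward with a step-up false-discovery-rate
#' threshold at rate `Q` on t statistics. `side = "high"` tests only the
#' upper tail, as used when smoothing high outliers of enrichment curves.
#'
#' The flagged set is extreme-monotone: any value farther from the robust
#' center (on a tested side) than a flagged value is itself flagged.
#'
#' @param values numeric vector (>= 3 values for any flagging to occur).
#' @param Q false-discovery rate (0.001 corresponds to the conventional
#'   "Q = 0.1 percent" setting).
#' @param side `"both"` or `"high"`.
#' @return list with `mask` (logical, TRUE = outlier), `robust_center`,
#'   `rsdr`, and `Q`.
#' @export
rout_outliers <- function(values, Q = 0.001, side = c("both", "high")) {
  side <- match.arg(side)
  n <- length(values)
  out <- list(mask = logical(n), robust_center = NA_real_, rsdr = NA_real_,
              Q = Q)
  if (n < 3) {
    warnf("rout_outliers: fewer than 3 values, nothing flagged")
    return(out)
  }
  center <- median(values)
  res <- values - center
  # RSDR: 68.27th percentile of |residuals|, small-sample corrected
  p6827 <- quantile(abs(res), 0.6827, names = FALSE, type = 7)
  rsdr <- p6827 * n / (n - 1)
  out$robust_center <- center
  out$rsdr <- rsdr
  if (side == "high") {
    score <- res        # only positive residuals can be outliers
  } else {
    score <- abs(res)
  }
  ord <- order(score, decreasing = TRUE)
  m <- floor(0.3 * n)  # at most the most extreme 30% are candidates
  if (m < 1) return(out)
  cand <- ord[seq_len(m)]
  if (rsdr <= 0) {
    # degenerate spread: any nonzero residual on a tested side is infinitely
    # many robust SDs out
    flag <- if (side == "high") res[cand] > 0 else abs(res[cand]) > 0
    out$mask[cand[flag]] <- TRUE
    return(out)
  }
  tstat <- (if (side == "high") res[cand] else abs(res[cand])) / rsdr
  df <- n - 1
  p <- if (side == "high") pt(tstat, df, lower.tail = FALSE)
       else 2 * pt(tstat, df, lower.tail = FALSE)
  # step-up: find the largest i with p_i < Q * i / n; flag candidates 1..i
  i_seq <- seq_len(m)
  ok <- p < Q * i_seq / n
  if (any(ok)) {
    cut <- max(i_seq[ok])
    keep <- cand[seq_len(cut)]
    if (side == "high") keep <- keep[res[keep] > 0]
    out$mask[keep] <- TRUE
  }
  out
}

#' Maximum-likelihood Gaussian fit of a univariate sample
#'
#' @param values numeric vector (>= 3 values, nonzero spread).
#' @return list with `mu` (sample mean) and `sd` (sample standard deviation).
#' @export
fit_gaussian_1d <- function(values) {
  if (length(values) < 3) stopf("fit_gaussian_1d needs >= 3 values")
  s <- sd(values)
  if (!is.finite(s) || s <= 0) stopf("degenerate fit: zero variance")
  list(mu = mean(values), sd = s)
}
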
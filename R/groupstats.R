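#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For small tie-free samples (total n <= 20) the
#' p value is computed from the exact distribution of U; otherwise a
#' tie-corrected normal approximation with continuity correction is used.
#' When the pooled variance is zero (all values identical) the p value is 1.
#'
#' @param a,b numeric samples (non-empty).
#' @param method `"auto"` (default branch rule), or force `"exact"` /
#'   `"normal"`; the exact branch requires tie-free data.
#' @return list with `U` (statistic of the first sample), `p` (two-sided)
#'   and `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney <- function(a, b, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (!length(a) || !length(b)) stop("empty sample", call. = FALSE)
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  Ua <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  use_exact <- if (method == "auto") m + n <= 20 && !ties else
    method == "exact"
  if (use_exact && ties)
    stop("exact p values require tie-free samples", call. = FALSE)
  if (use_exact) {
    Umin <- min(Ua, m * n - Ua)
    p <- min(1, 2 * pwilcox(Umin, m, n))
    method <- "exact"
  } else {
    N <- m + n
    tt <- table(pooled)
    sigma2 <- m * n / 12 * ((N + 1) - sum(tt^3 - tt) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- max(abs(Ua - m * n / 2) - 0.5, 0) / sqrt(sigma2)
      p <- min(1, 2 * (1 - pnorm(z)))
    }
    method <- "normal"
  }
  list(U = Ua, p = p, method = method)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Sorted p values are multiplied by `m, m-1, ..., 1`, monotonicity is
#' enforced by a running maximum, values are capped at 1, and the input
#' order is preserved in the output.
#'
#' @param pvals numeric vector of p values in `[0, 1]`.
#' @return adjusted p values in the input order.
#' @export
holm_bonferroni <- function(pvals) {
  if (any(!is.finite(pvals) | pvals < 0 | pvals > 1))
    stop("p values must lie in [0, 1]", call. = FALSE)
  m <- length(pvals)
  o <- order(pvals)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * pvals[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Univariate patient-control comparison of all features
#'
#' One two-sided Mann-Whitney test per feature, adjusted jointly (one
#' family) by Holm-Bonferroni. Features significant before but not after
#' correction are flagged separately (`raw_significant`), mirroring the
#' common practice of reporting uncorrected p < 0.05 findings descriptively.
#'
#' @param ft feature table with a `group` column (`"patient"`/`"control"`)
#'   and feature columns from [feature_vocabulary()].
#' @param alpha significance level (default 0.05).
#' @return data frame (one row per feature): medians, `U`, `p_raw`,
#'   `p_holm`, `significant`, `raw_significant`.
#' @export
compare_cohort <- function(ft, alpha = 0.05) {
  if (!"group" %in% names(ft)) stop("feature table needs 'group'", call. = FALSE)
  feats <- intersect(feature_vocabulary(), names(ft))
  if (!length(feats)) stop("no known feature columns found", call. = FALSE)
  pat <- ft$group == "patient"
  ctl <- ft$group == "control"
  if (sum(pat) < 2 || sum(ctl) < 2)
    stop("both groups must have at least 2 subjects", call. = FALSE)
  res <- lapply(feats, function(f) {
    mw <- mann_whitney(ft[[f]][pat], ft[[f]][ctl])
    data.frame(feature = f,
               median_patient = median(ft[[f]][pat]),
               median_control = median(ft[[f]][ctl]),
               U = mw$U, p_raw = mw$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_holm <- holm_bonferroni(res$p_raw)
  res$significant <- res$p_holm < alpha
  res$raw_significant <- res$p_raw < alpha
  res
}

#' Per-bin power comparison between groups
#'
#' Mann-Whitney test of absolute power in every 0.25 Hz bin between 0.5 and
#' 20 Hz. Reported uncorrected by design: this is an exploratory analysis
#' for spotting narrow spectral effects that band averaging would mask.
#'
#' @param power matrix, subjects x bins, of channel-averaged absolute power.
#' @param groups `"patient"`/`"control"` per subject.
#' @param bin_low lower bin edges in Hz (shared grid for all subjects).
#' @param fmin,fmax analysed range (defaults 0.5--20 Hz; 78 bins at 0.25 Hz).
#' @return data frame: `bin_low`, `bin_high`, group means, `p` (uncorrected).
#' @export
per_bin_comparison <- function(power, groups, bin_low, fmin = 0.5,
                               fmax = 20) {
  power <- as.matrix(power)
  if (ncol(power) != length(bin_low))
    stop("bin grid does not match the power matrix", call. = FALSE)
  if (nrow(power) != length(groups))
    stop("one group label per subject required", call. = FALSE)
  df <- diff(sort(unique(bin_low)))[1]
  keep <- bin_low >= fmin - 1e-9 & bin_low + df <= fmax + 1e-9
  pat <- groups == "patient"
  res <- lapply(which(keep), function(k) {
    mw <- mann_whitney(power[pat, k], power[!pat, k])
    data.frame(bin_low = bin_low[k], bin_high = bin_low[k] + df,
               mean_patient = mean(power[pat, k]),
               mean_control = mean(power[!pat, k]), p = mw$p)
  })
  do.call(rbind, res)
}
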
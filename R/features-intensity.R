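## First-order feature families: intensity statistics (raw units),
## intensity-histogram features (FBN levels), and the intensity-volume
## histogram computed on the discretized levels.
##
## Population (1/N) moments are used throughout, matching the
## standardization document's conventions. Undefined values (zero-variance
## moments, single-level histograms) propagate as NaN sentinels and are
## never silently dropped.

sentinel <- NaN

## 18 intensity-based statistical features on raw intensities.
statFeatures <- function(x) {
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  q <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  sk <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else sentinel
  ku <- if (m2 > 0) mean((x - mu)^4) / m2^2 - 3 else sentinel
  inq <- x[x >= q[1] & x <= q[5]]
  c(stat_mean = mu,
    stat_variance = m2,
    stat_skewness = sk,
    stat_kurtosis = ku,
    stat_median = q[3],
    stat_minimum = min(x),
    stat_p10 = q[1],
    stat_p90 = q[5],
    stat_maximum = max(x),
    stat_interquartile_range = q[4] - q[2],
    stat_range = max(x) - min(x),
    stat_mean_absolute_deviation = mean(abs(x - mu)),
    stat_robust_mean_absolute_deviation = mean(abs(inq - mean(inq))),
    stat_median_absolute_deviation = mean(abs(x - q[3])),
    stat_coefficient_of_variation =
      if (mu != 0) sqrt(m2) / mu else sentinel,
    stat_quartile_coefficient_of_dispersion =
      if (q[4] + q[2] != 0) (q[4] - q[2]) / (q[4] + q[2]) else sentinel,
    stat_energy = sum(x^2),
    stat_root_mean_square = sqrt(mean(x^2)))
}

## 23 intensity-histogram features on discretized levels 1..ng.
ihFeatures <- function(g, ng) {
  n <- length(g)
  cnt <- tabulate(g, nbins = ng)
  p <- cnt / n
  mu <- mean(g)
  m2 <- mean((g - mu)^2)
  q <- stats::quantile(g, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  inq <- g[g >= q[1] & g <= q[5]]
  mode_level <- which.max(cnt)              # ties -> lowest level
  ## discrete histogram gradient, forward/backward differences at the ends
  if (ng >= 2) {
    grad <- c(cnt[2] - cnt[1],
              if (ng > 2) (cnt[3:ng] - cnt[1:(ng - 2)]) / 2,
              cnt[ng] - cnt[ng - 1])
    gmax <- max(grad); gmin <- min(grad)
    gmax_at <- which.max(grad); gmin_at <- which.min(grad)
  } else {
    gmax <- gmin <- gmax_at <- gmin_at <- sentinel
  }
  pp <- p[p > 0]
  c(ih_mean = mu,
    ih_variance = m2,
    ih_skewness = if (m2 > 0) mean((g - mu)^3) / m2^1.5 else sentinel,
    ih_kurtosis = if (m2 > 0) mean((g - mu)^4) / m2^2 - 3 else sentinel,
    ih_median = q[3],
    ih_minimum = min(g),
    ih_p10 = q[1],
    ih_p90 = q[5],
    ih_maximum = max(g),
    ih_mode = mode_level,
    ih_interquartile_range = q[4] - q[2],
    ih_range = max(g) - min(g),
    ih_mean_absolute_deviation = mean(abs(g - mu)),
    ih_robust_mean_absolute_deviation = mean(abs(inq - mean(inq))),
    ih_median_absolute_deviation = mean(abs(g - q[3])),
    ih_coefficient_of_variation = if (mu != 0) sqrt(m2) / mu else sentinel,
    ih_quartile_coefficient_of_dispersion =
      if (q[4] + q[2] != 0) (q[4] - q[2]) / (q[4] + q[2]) else sentinel,
    ih_entropy = -sum(pp * log2(pp)),
    ih_uniformity = sum(p^2),
    ih_max_gradient = gmax,
    ih_max_gradient_level = gmax_at,
    ih_min_gradient = gmin,
    ih_min_gradient_level = gmin_at)
}

## 7 intensity-volume-histogram features on discretized levels. The volume
## fraction nu(i) is the fraction of ROI voxels with level >= i; the
## intensity fraction runs over the level grid, gamma(i) = (i-1)/(ng-1).
## Vx = nu at the smallest grid point with gamma >= x; Ix = the smallest
## level whose volume fraction is at most x, mapped back to gamma. The AUC
## is the mean of nu over the gamma grid.
ivhFeatures <- function(g, ng) {
  n <- length(g)
  cnt <- tabulate(g, nbins = ng)
  nu <- rev(cumsum(rev(cnt))) / n            # P(level >= i)
  if (ng > 1) gamma <- (seq_len(ng) - 1) / (ng - 1) else gamma <- 0
  vAt <- function(x) nu[which(gamma >= x)[1]]
  iAt <- function(x) {
    hit <- which(nu <= x)
    if (length(hit)) gamma[hit[1]] else gamma[ng]
  }
  v10 <- vAt(0.10); v90 <- vAt(0.90)
  i10 <- iAt(0.10); i90 <- iAt(0.90)
  c(ivh_v10 = v10, ivh_v90 = v90, ivh_v10_minus_v90 = v10 - v90,
    ivh_i10 = i10, ivh_i90 = i90, ivh_i10_minus_i90 = i10 - i90,
    ivh_auc = mean(nu))
}
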
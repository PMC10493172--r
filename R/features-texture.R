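## Texture feature definitions for the six matrix families. Each function
## takes raw count matrices from the builders in texture-matrices.R,
## normalizes internally, and returns a named numeric vector. Entropies use
## base-2 logarithms. Undefined values (zero-variance correlation terms,
## single-level neighbourhood statistics) are NaN sentinels.

entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

## ---- GLCM (25) ---------------------------------------------------------

glcmFeatures <- function(M) {
  ng <- nrow(M)
  s <- sum(M)
  if (s == 0) return(setNames(rep(sentinel, 25), names(glcmFeatureNames())))
  P <- M / s
  i <- row(P); j <- col(P)
  pr <- rowSums(P)                       # = colSums by symmetry
  mu <- sum(seq_len(ng) * pr)
  sig2 <- sum((seq_len(ng) - mu)^2 * pr)
  dk <- abs(i - j)
  pd <- numeric(ng)                          # k = 0 .. ng-1
  acc <- rowsum(as.vector(P), as.vector(dk))
  pd[as.integer(rownames(acc)) + 1L] <- acc
  da <- sum((0:(ng - 1)) * pd)
  sk <- i + j
  ps <- numeric(2 * ng - 1)                  # k = 2 .. 2 ng
  acc <- rowsum(as.vector(P), as.vector(sk))
  ps[as.integer(rownames(acc)) - 1L] <- acc
  sa <- sum((2:(2 * ng)) * ps)
  hxy <- entropy2(P)
  qij <- outer(pr, pr)
  hxy1 <- -sum(P[qij > 0] * log2(qij[qij > 0]))
  hxy2 <- entropy2(qij)
  hx <- entropy2(pr)
  ic2arg <- 1 - 2^(-2 * (hxy2 - hxy))
  c(joint_maximum = max(P),
    joint_average = mu,
    joint_variance = sum((i - mu)^2 * P),
    joint_entropy = hxy,
    difference_average = da,
    difference_variance = sum(((0:(ng - 1)) - da)^2 * pd),
    difference_entropy = entropy2(pd),
    sum_average = sa,
    sum_variance = sum(((2:(2 * ng)) - sa)^2 * ps),
    sum_entropy = entropy2(ps),
    angular_second_moment = sum(P^2),
    contrast = sum((i - j)^2 * P),
    dissimilarity = sum(abs(i - j) * P),
    inverse_difference = sum(P / (1 + abs(i - j))),
    inverse_difference_normalised = sum(P / (1 + abs(i - j) / ng)),
    inverse_difference_moment = sum(P / (1 + (i - j)^2)),
    inverse_difference_moment_normalised = sum(P / (1 + (i - j)^2 / ng^2)),
    inverse_variance = sum(P[i != j] / (i - j)[i != j]^2),
    correlation = if (sig2 > 0) (sum(i * j * P) - mu^2) / sig2 else sentinel,
    autocorrelation = sum(i * j * P),
    cluster_tendency = sum((i + j - 2 * mu)^2 * P),
    cluster_shade = sum((i + j - 2 * mu)^3 * P),
    cluster_prominence = sum((i + j - 2 * mu)^4 * P),
    information_correlation_1 =
      if (hx > 0) (hxy - hxy1) / hx else sentinel,
    information_correlation_2 = sqrt(max(0, ic2arg)))
}

glcmFeatureNames <- function() {
  setNames(numeric(25), c(
    "joint_maximum", "joint_average", "joint_variance", "joint_entropy",
    "difference_average", "difference_variance", "difference_entropy",
    "sum_average", "sum_variance", "sum_entropy", "angular_second_moment",
    "contrast", "dissimilarity", "inverse_difference",
    "inverse_difference_normalised", "inverse_difference_moment",
    "inverse_difference_moment_normalised", "inverse_variance",
    "correlation", "autocorrelation", "cluster_tendency", "cluster_shade",
    "cluster_prominence", "information_correlation_1",
    "information_correlation_2"))
}

## ---- GLRLM (16) --------------------------------------------------------

glrlmFeatures <- function(R) {
  ns <- sum(R)
  jj <- seq_len(ncol(R))
  ii <- seq_len(nrow(R))
  nv <- sum(sweep(R, 2, jj, `*`))          # voxels covered by runs
  ri <- rowSums(R); rj <- colSums(R)
  P <- R / ns
  mu_i <- sum(ii * rowSums(P))
  mu_j <- sum(jj * colSums(P))
  c(short_runs_emphasis = sum(rj / jj^2) / ns,
    long_runs_emphasis = sum(rj * jj^2) / ns,
    low_gl_run_emphasis = sum(ri / ii^2) / ns,
    high_gl_run_emphasis = sum(ri * ii^2) / ns,
    short_run_low_gl_emphasis = sum(R / outer(ii^2, jj^2)) / ns,
    short_run_high_gl_emphasis = sum(R * outer(ii^2, 1 / jj^2)) / ns,
    long_run_low_gl_emphasis = sum(R * outer(1 / ii^2, jj^2)) / ns,
    long_run_high_gl_emphasis = sum(R * outer(ii^2, jj^2)) / ns,
    gl_non_uniformity = sum(ri^2) / ns,
    gl_non_uniformity_normalised = sum(ri^2) / ns^2,
    run_length_non_uniformity = sum(rj^2) / ns,
    run_length_non_uniformity_normalised = sum(rj^2) / ns^2,
    run_percentage = ns / nv,
    gl_variance = sum((matrix(ii, nrow(R), ncol(R)) - mu_i)^2 * P),
    run_length_variance =
      sum((matrix(jj, nrow(R), ncol(R), byrow = TRUE) - mu_j)^2 * P),
    run_entropy = entropy2(P))
}

## ---- zone-type families (GLSZM / GLDZM / NGLDM) ------------------------

## Shared emphasis/non-uniformity structure over a (gray level x column
## attribute) count matrix; `col_tag` names the column dimension.
zoneTypeFeatures <- function(S, nv, col_tag) {
  ns <- sum(S)
  ii <- seq_len(nrow(S)); jj <- seq_len(ncol(S))
  P <- S / ns
  si <- rowSums(S); sj <- colSums(S)
  mu_i <- sum(ii * rowSums(P))
  mu_j <- sum(jj * colSums(P))
  out <- c(
    small = sum(sj / jj^2) / ns,
    large = sum(sj * jj^2) / ns,
    low_gl = sum(si / ii^2) / ns,
    high_gl = sum(si * ii^2) / ns,
    small_low = sum(S / outer(ii^2, jj^2)) / ns,
    small_high = sum(S * outer(ii^2, 1 / jj^2)) / ns,
    large_low = sum(S * outer(1 / ii^2, jj^2)) / ns,
    large_high = sum(S * outer(ii^2, jj^2)) / ns,
    gl_non_uniformity = sum(si^2) / ns,
    gl_non_uniformity_normalised = sum(si^2) / ns^2,
    col_non_uniformity = sum(sj^2) / ns,
    col_non_uniformity_normalised = sum(sj^2) / ns^2,
    percentage = ns / nv,
    gl_variance = sum((matrix(ii, nrow(S), ncol(S)) - mu_i)^2 * P),
    col_variance =
      sum((matrix(jj, nrow(S), ncol(S), byrow = TRUE) - mu_j)^2 * P),
    col_entropy = entropy2(P))
  out
}

glszmFeatures <- function(S, nv) {
  v <- zoneTypeFeatures(S, nv, "zone_size")
  setNames(v, c(
    "small_zone_emphasis", "large_zone_emphasis", "low_gl_zone_emphasis",
    "high_gl_zone_emphasis", "small_zone_low_gl_emphasis",
    "small_zone_high_gl_emphasis", "large_zone_low_gl_emphasis",
    "large_zone_high_gl_emphasis", "gl_non_uniformity",
    "gl_non_uniformity_normalised", "zone_size_non_uniformity",
    "zone_size_non_uniformity_normalised", "zone_percentage",
    "gl_variance", "zone_size_variance", "zone_size_entropy"))
}

gldzmFeatures <- function(S, nv) {
  v <- zoneTypeFeatures(S, nv, "zone_distance")
  setNames(v, c(
    "small_distance_emphasis", "large_distance_emphasis",
    "low_gl_zone_emphasis", "high_gl_zone_emphasis",
    "small_distance_low_gl_emphasis", "small_distance_high_gl_emphasis",
    "large_distance_low_gl_emphasis", "large_distance_high_gl_emphasis",
    "gl_non_uniformity", "gl_non_uniformity_normalised",
    "zone_distance_non_uniformity",
    "zone_distance_non_uniformity_normalised", "zone_percentage",
    "gl_variance", "zone_distance_variance", "zone_distance_entropy"))
}

ngldmFeatures <- function(S, nv) {
  v <- zoneTypeFeatures(S, nv, "dependence_count")
  nm <- c(
    "low_dependence_emphasis", "high_dependence_emphasis",
    "low_gl_count_emphasis", "high_gl_count_emphasis",
    "low_dependence_low_gl_emphasis", "low_dependence_high_gl_emphasis",
    "high_dependence_low_gl_emphasis", "high_dependence_high_gl_emphasis",
    "gl_non_uniformity", "gl_non_uniformity_normalised",
    "dependence_count_non_uniformity",
    "dependence_count_non_uniformity_normalised",
    "dependence_count_percentage", "gl_variance",
    "dependence_count_variance", "dependence_count_entropy")
  out <- setNames(v, nm)
  c(out, dependence_count_energy = sum((S / sum(S))^2))
}

## ---- NGTDM (5) ---------------------------------------------------------

ngtdmFeatures <- function(tab) {
  n_i <- tab$n; s_i <- tab$s
  nv <- sum(n_i)
  p_i <- n_i / nv
  lev <- tab$level
  present <- which(p_i > 0)
  ngp <- length(present)
  pi_p <- p_i[present]; si_p <- s_i[present]; li_p <- lev[present]
  ps <- sum(p_i * s_i)
  coarseness <- if (ps > 0) 1 / ps else sentinel
  if (ngp > 1) {
    dij2 <- outer(li_p, li_p, `-`)^2
    contrast <- (sum(outer(pi_p, pi_p) * dij2) / (ngp * (ngp - 1))) *
      (sum(si_p) / nv)
    den <- sum(abs(outer(li_p * pi_p, li_p * pi_p, `-`)))
    busyness <- if (den > 0) ps / den else sentinel
    num <- outer(pi_p * si_p, pi_p * si_p, `+`)
    complexity <- sum(abs(outer(li_p, li_p, `-`)) * num /
                        outer(pi_p, pi_p, `+`)) / nv
    ssum <- sum(si_p)
    strength <- if (ssum > 0) sum(outer(pi_p, pi_p, `+`) * dij2) / ssum
                else 0
  } else {
    contrast <- sentinel
    busyness <- sentinel
    complexity <- 0
    strength <- 0
  }
  c(coarseness = coarseness, contrast = contrast, busyness = busyness,
    complexity = complexity, strength = strength)
}
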
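#' Berman clinical CAC stratification
#'
#' Maps coronary calcium scores to the established clinical strata:
#' exactly 0, (0, 10], (10, 100], (100, 400], (400, 1000], and > 1000,
#' returned as ordinals 1..6.
#'
#' @param score numeric vector of nonnegative CAC scores.
#' @return integer vector of categories in 1..6.
#' @examples
#' bermanCategory(c(0, 5, 100, 100.01, 2239))
#' @export
bermanCategory <- function(score) {
  if (any(score < 0)) stop("CAC scores must be nonnegative")
  as.integer(cut(score, breaks = c(-Inf, 0, 10, 100, 400, 1000, Inf),
                 labels = FALSE))
}

## Spearman rho with average ranks for ties.
spearmanRho <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

## Two-sided p for Spearman rho: t-approximation for n >= 10, exact
## permutation enumeration below that.
spearmanP <- function(x, y, rho = spearmanRho(x, y)) {
  n <- length(x)
  if (is.na(rho)) return(NA_real_)
  if (n >= 10) {
    if (abs(rho) >= 1) return(0)
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    return(2 * stats::pt(-abs(tt), df = n - 2))
  }
  rx <- rank(x); ry <- rank(y)
  perms <- permutationsAll(n)
  ry_perm <- matrix(ry[perms], nrow = nrow(perms))
  num <- ry_perm %*% rx
  mx <- mean(rx); my <- mean(ry)
  sx <- sqrt(sum((rx - mx)^2)); sy <- sqrt(sum((ry - my)^2))
  if (sx == 0 || sy == 0) return(NA_real_)
  rho_all <- (num - n * mx * my) / (sx * sy)
  mean(abs(rho_all) >= abs(rho) - 1e-12)
}

permutationsAll <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- permutationsAll(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

#' Spearman screening of features against a CAC outcome
#'
#' Per-feature Spearman rank correlation with the outcome, in continuous
#' mode (raw scores) or discrete mode (Berman categories of the scores),
#' with two-sided p-values and Benjamini-Hochberg pass flags at FDR level
#' \code{q}.
#'
#' @param x numeric matrix, subjects x features (column names = feature
#'   ids).
#' @param outcome numeric vector of CAC scores (>= 3 subjects).
#' @param mode \code{"continuous"} or \code{"discrete"}.
#' @param q FDR level for the pass flags.
#' @return data.frame with \code{feature_id}, \code{rho}, \code{p},
#'   \code{q_pass}.
#' @export
spearmanScreen <- function(x, outcome, mode = c("continuous", "discrete"),
                           q = 0.05) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need at least 3 subjects")
  if (stats::var(outcome) == 0) stop("outcome has zero variance")
  y <- if (mode == "discrete") bermanCategory(outcome) else outcome
  res <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    ok <- is.finite(v)
    if (sum(ok) < 3 || stats::var(v[ok]) == 0)
      return(c(NA_real_, NA_real_))
    r <- spearmanRho(v[ok], y[ok])
    c(r, spearmanP(v[ok], y[ok], r))
  }, numeric(2))
  p <- res[2, ]
  data.frame(feature_id = colnames(x), rho = res[1, ], p = p,
             q_pass = bhFdr(p, q), row.names = NULL)
}

#' Benjamini-Hochberg step-up pass flags
#'
#' @param pvals numeric p-values in [0, 1]; NAs never pass.
#' @param q FDR level.
#' @return logical vector: TRUE where the hypothesis is rejected at FDR
#'   level \code{q} under the standard step-up rule.
#' @examples
#' bhFdr(c(0.001, 0.01, 0.03, 0.2), q = 0.05)  # three rejections
#' @export
bhFdr <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) stop("empty p-value vector")
  adj <- stats::p.adjust(pvals, method = "BH")
  out <- !is.na(adj) & adj <= q
  out
}
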
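## Stepwise linear regression with F-test gates and an AIC criterion.
##
## Terms are blocks of design-matrix columns: a radiomic feature or a
## continuous covariate is one column; a categorical covariate enters and
## leaves as its whole dummy block. The intercept is immutable. At each
## step the admissible addition with the best criterion improvement is
## made (partial-F p <= p_enter; under the AIC criterion the move must
## also lower AIC); when no addition is possible, the worst in-model term
## with partial-F p >= p_remove is removed. Fits run on raw design
## matrices through QR for speed and numerical rank detection.

#' Stepwise-regression parameters
#'
#' @param p_enter F-test p-value at or below which a term may enter.
#' @param p_remove F-test p-value at or above which a term may leave.
#' @param criterion \code{"aic"} (AIC-ranked moves, F-test gates) or
#'   \code{"pvalue"} (pure F-test stepping).
#' @param screen_p pre-ordering Spearman p cutoff for candidate features.
#' @param inner_reps number of train/dev resamplings per trial.
#' @param outer_reps number of independent trials (test-set draws).
#' @param test_frac fraction held out as the independent test set.
#' @param dev_frac fraction of the remainder used as the dev set.
#' @param alpha significance level of the combined chi-squared test.
#' @param select \code{"aic"} picks the inner model with lowest AIC;
#'   \code{"loglik"} picks the highest log-likelihood.
#' @param log1p_outcome model log1p-transformed CAC instead of raw scores.
#' @param seed master seed; all trial seeds derive from it.
#' @return list of class \code{StepwiseParams}.
#' @export
stepwiseParams <- function(p_enter = 0.05, p_remove = 0.20,
                           criterion = c("aic", "pvalue"), screen_p = 0.3,
                           inner_reps = 20L, outer_reps = 50L,
                           test_frac = 0.15, dev_frac = 0.25,
                           alpha = 0.01, select = c("aic", "loglik"),
                           log1p_outcome = FALSE, seed = 1L) {
  criterion <- match.arg(criterion)
  select <- match.arg(select)
  stopifnot(p_enter > 0, p_enter < 1, p_remove > 0, p_remove < 1,
            p_enter < p_remove, test_frac > 0, test_frac < 1,
            dev_frac > 0, dev_frac < 1)
  structure(list(p_enter = p_enter, p_remove = p_remove,
                 criterion = criterion, screen_p = screen_p,
                 inner_reps = as.integer(inner_reps),
                 outer_reps = as.integer(outer_reps),
                 test_frac = test_frac, dev_frac = dev_frac,
                 alpha = alpha, select = select,
                 log1p_outcome = log1p_outcome, seed = as.integer(seed)),
            class = "StepwiseParams")
}

## Gaussian log-likelihood / AIC from a residual sum of squares.
rssLogLik <- function(rss, n) {
  -n / 2 * (log(2 * pi) + log(rss / n) + 1)
}
rssAic <- function(rss, n, p) {
  ## p model coefficients + 1 for sigma
  2 * (p + 1) - 2 * rssLogLik(rss, n)
}

## QR fit of y on X (X includes the intercept). Returns NULL when rank
## deficient.
qrRss <- function(X, y) {
  qr <- qr(X)
  if (qr$rank < ncol(X)) return(NULL)
  res <- qr.resid(qr, y)
  list(rss = max(sum(res^2), 1e-300), coef = qr.coef(qr, y))
}

partialFp <- function(rss0, rss1, df_extra, n, p_full) {
  if (rss1 <= 0) return(0)
  f <- ((rss0 - rss1) / df_extra) / (rss1 / (n - p_full))
  stats::pf(max(f, 0), df_extra, n - p_full, lower.tail = FALSE)
}

#' Fit a stepwise linear model
#'
#' @param design list with \code{X} (full numeric design matrix, no
#'   intercept column) and \code{terms} (named list mapping each term to
#'   its column indices in \code{X}).
#' @param y numeric response.
#' @param candidates character, candidate term names in entry order.
#' @param initial_terms terms of the starting model (beyond the intercept).
#' @param params a [stepwiseParams()] object.
#' @return list with \code{terms} (in entry order), \code{coefficients},
#'   \code{aic}, \code{log_likelihood}, \code{model_p} (overall F-test) and
#'   \code{rss}.
#' @export
stepwiseFit <- function(design, y, candidates,
                        initial_terms = character(0),
                        params = stepwiseParams()) {
  X <- design$X
  terms_map <- design$terms
  n <- length(y)
  candidates <- candidates[candidates %in% names(terms_map)]
  current <- intersect(initial_terms, candidates)
  modelCols <- function(terms) unlist(terms_map[terms], use.names = FALSE)
  fitModel <- function(terms) {
    Xm <- cbind(`(Intercept)` = 1, X[, modelCols(terms), drop = FALSE])
    qrRss(Xm, y)
  }
  cur <- fitModel(current)
  while (is.null(cur) && length(current)) {   # degenerate start: shrink
    current <- current[-length(current)]
    cur <- fitModel(current)
  }
  p_cur <- 1 + length(modelCols(current))
  aic_cur <- rssAic(cur$rss, n, p_cur)
  maxit <- 4L * length(candidates) + 8L
  for (it in seq_len(maxit)) {
    moved <- FALSE
    ## --- additions ---
    best <- NULL
    for (tm in setdiff(candidates, current)) {
      k <- length(terms_map[[tm]])
      p_new <- p_cur + k
      if (n - p_new < 2) next
      f1 <- fitModel(c(current, tm))
      if (is.null(f1)) next                    # rank-deficient candidate
      pval <- partialFp(cur$rss, f1$rss, k, n, p_new)
      aic1 <- rssAic(f1$rss, n, p_new)
      admissible <- pval <= params$p_enter &&
        (params$criterion != "aic" || aic1 < aic_cur)
      if (!admissible) next
      score <- if (params$criterion == "aic") aic1 else pval
      if (is.null(best) || score < best$score)
        best <- list(term = tm, fit = f1, aic = aic1, p = p_new,
                     score = score)
    }
    if (!is.null(best)) {
      current <- c(current, best$term)
      cur <- best$fit; aic_cur <- best$aic; p_cur <- best$p
      moved <- TRUE
    } else {
      ## --- removals ---
      worst <- NULL
      for (tm in current) {
        k <- length(terms_map[[tm]])
        f0 <- fitModel(setdiff(current, tm))
        if (is.null(f0)) next
        pval <- partialFp(f0$rss, cur$rss, k, n, p_cur)
        aic0 <- rssAic(f0$rss, n, p_cur - k)
        admissible <- pval >= params$p_remove &&
          (params$criterion != "aic" || aic0 < aic_cur)
        if (!admissible) next
        if (is.null(worst) || pval > worst$p_val)
          worst <- list(term = tm, fit = f0, aic = aic0,
                        p = p_cur - k, p_val = pval)
      }
      if (!is.null(worst)) {
        current <- setdiff(current, worst$term)
        cur <- worst$fit; aic_cur <- worst$aic; p_cur <- worst$p
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  ## overall model F-test vs intercept-only
  if (length(current)) {
    rss_null <- sum((y - mean(y))^2)
    k <- p_cur - 1
    model_p <- partialFp(rss_null, cur$rss, k, n, p_cur)
  } else model_p <- 1
  list(terms = current, coefficients = cur$coef, aic = aic_cur,
       log_likelihood = rssLogLik(cur$rss, n), model_p = model_p,
       rss = cur$rss)
}

#' Order candidate terms by outcome association
#'
#' Implements the entry-order heuristic: each numeric term is Spearman-
#' correlated with the outcome; terms with p below \code{screen_p} are
#' kept and sorted by |rho| descending (ties by catalog order).
#' Multi-column categorical blocks are ranked by a Kruskal-Wallis test,
#' with pseudo-|rho| = sqrt(H / (n - 1)) as the sort key.
#'
#' @param design a design list (see [stepwiseFit()]).
#' @param y outcome on the same rows.
#' @param screen_p screening p cutoff.
#' @param data optional data.frame holding the original factor columns for
#'   categorical terms.
#' @return character vector of retained term names, strongest first (may be
#'   empty).
#' @export
orderFeatures <- function(design, y, screen_p = 0.3, data = NULL) {
  n <- length(y)
  stopifnot(n >= 3)
  stats_tab <- vapply(names(design$terms), function(tm) {
    cols <- design$terms[[tm]]
    if (length(cols) == 1) {
      v <- design$X[, cols]
      if (stats::var(v) == 0) return(c(0, 1))
      r <- spearmanRho(v, y)
      c(abs(r), spearmanP(v, y, r))
    } else {
      f <- if (!is.null(data) && tm %in% colnames(data))
        droplevels(factor(data[[tm]]))
      else factor(apply(design$X[, cols, drop = FALSE], 1, paste,
                        collapse = "/"))
      if (nlevels(f) < 2) return(c(0, 1))
      kw <- stats::kruskal.test(y, f)
      c(sqrt(unname(kw$statistic) / (n - 1)), kw$p.value)
    }
  }, numeric(2))
  keep <- which(stats_tab[2, ] < screen_p)
  ord <- keep[order(-stats_tab[1, keep], keep)]
  names(design$terms)[ord]
}
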
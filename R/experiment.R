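## The nested resampling protocol: per trial, an independent test split is
## held out; the remainder is resampled into train/dev several times, a
## stepwise model is fit on train and refit on dev starting from the
## trained model; the best dev model is refit on the whole remainder and
## scored on the test set by Pearson correlation. Trials repeat with fresh
## shuffles and the test p-values combine by Fisher's method.

CLINICAL_TERMS <- c("gender", "race", "age", "smoking", "diabetes",
                    "hypertension", "hyperlipidemia", "family_history_cad",
                    "bmi", "lvef")

#' Build a stepwise design from a covariate/feature data.frame
#'
#' Numeric columns become single-column terms; factor columns become whole
#' dummy blocks built against the full level set (so resampled subsets
#' missing a level stay estimable; an absent level simply contributes an
#' all-zero, rank-checked column that the fitter skips).
#'
#' @param data data.frame of candidate predictors.
#' @return list with \code{X} (numeric matrix) and \code{terms} (term ->
#'   column indices).
#' @export
buildDesign <- function(data) {
  cols <- list()
  terms <- list()
  at <- 0L
  for (nm in colnames(data)) {
    v <- data[[nm]]
    if (is.factor(v)) {
      lv <- levels(v)
      block <- vapply(lv[-1], function(l) as.numeric(v == l),
                      numeric(nrow(data)))
      colnames(block) <- paste0(nm, lv[-1])
      cols[[nm]] <- block
      terms[[nm]] <- at + seq_len(ncol(block))
      at <- at + ncol(block)
    } else {
      cols[[nm]] <- matrix(as.numeric(v), dimnames = list(NULL, nm))
      terms[[nm]] <- at + 1L
      at <- at + 1L
    }
  }
  list(X = do.call(cbind, cols), terms = terms)
}

#' Assemble the modeling dataset for one segment and configuration
#'
#' @param fs a [RadiomicsFeatureSet-class] holding the cohort's features
#'   and outcomes.
#' @param segment one of the seven segment labels.
#' @param configuration \code{"radiomics"}, \code{"clinical"} or
#'   \code{"combined"}.
#' @param features selected radiomic feature ids (ignored for the clinical
#'   configuration).
#' @param gl gray level at which features are taken.
#' @return list with \code{y}, \code{data} (predictor data.frame),
#'   \code{design}.
#' @export
makeDataset <- function(fs, segment, configuration = c("combined",
                                                       "radiomics",
                                                       "clinical"),
                        features = NULL, gl = 64L) {
  configuration <- match.arg(configuration)
  segment <- match.arg(segment, segmentLabels())
  cd <- as.data.frame(colData(fs))
  col <- switch(sub("_(MIM|17)$", "", segment),
                MYO = "total", LAD = "lad", LCX = "lcx", RCA = "rca")
  y <- as.numeric(cd[[col]])
  preds <- NULL
  if (configuration != "radiomics") {
    cl <- cd[, CLINICAL_TERMS, drop = FALSE]
    for (nm in colnames(cl)) if (is.character(cl[[nm]]))
      cl[[nm]] <- factor(cl[[nm]])
    preds <- cl
  }
  if (configuration != "clinical") {
    rd <- rowData(fs)
    sel <- rd$gl == gl & rd$segment == segment
    if (!is.null(features)) sel <- sel & rd$feature_id %in% features
    fm <- t(featureValues(fs)[sel, , drop = FALSE])
    colnames(fm) <- rd$feature_id[sel]
    fm[!is.finite(fm)] <- 0        # sentinel-neutral for regression
    preds <- if (is.null(preds)) as.data.frame(fm)
             else cbind(preds, as.data.frame(fm))
  }
  list(y = y, data = preds, design = buildDesign(preds))
}

#' Run one trial of the resampling protocol
#'
#' Holds out the test fraction, resamples train/dev \code{inner_reps}
#' times (stepwise fit from the intercept on train, refit on dev starting
#' from the trained model), selects the best dev model (lowest AIC by
#' default; an intercept-only winner is skipped in favour of the best
#' model with more than one term), refits its terms on the full remainder,
#' and scores Pearson correlation on the test set.
#'
#' @param dataset a [makeDataset()] result.
#' @param params a [stepwiseParams()] object.
#' @param trial_seed integer seed for this trial's shuffles.
#' @return list: \code{terms}, \code{test_rho}, \code{test_p},
#'   \code{valid}, \code{test_idx}, \code{n_inner_models}.
#' @export
runTrial <- function(dataset, params, trial_seed) {
  y_all <- if (params$log1p_outcome) log1p(dataset$y) else dataset$y
  n <- length(y_all)
  design <- dataset$design
  withLocalSeed(trial_seed, {
    test_idx <- sort(sample.int(n, max(2L, round(params$test_frac * n))))
    rest <- setdiff(seq_len(n), test_idx)
    if (stats::var(y_all[test_idx]) == 0)
      return(list(valid = FALSE, reason = "degenerate test outcome",
                  test_idx = test_idx))
    inner <- vector("list", params$inner_reps)
    for (r in seq_len(params$inner_reps)) {
      dev <- sample(rest, max(2L, round(params$dev_frac * length(rest))))
      train <- setdiff(rest, dev)
      dtr <- list(X = design$X[train, , drop = FALSE],
                  terms = design$terms)
      cand <- orderFeatures(dtr, y_all[train], params$screen_p,
                            data = dataset$data[train, , drop = FALSE])
      fit_tr <- stepwiseFit(dtr, y_all[train], cand, character(0), params)
      ddv <- list(X = design$X[dev, , drop = FALSE], terms = design$terms)
      fit_dv <- stepwiseFit(ddv, y_all[dev], cand, fit_tr$terms, params)
      inner[[r]] <- fit_dv
    }
    score <- vapply(inner, function(f)
      if (params$select == "aic") f$aic else -f$log_likelihood, numeric(1))
    nterms <- vapply(inner, function(f) length(f$terms), integer(1))
    ord <- order(score)
    pick <- ord[1]
    if (nterms[pick] == 0) {
      multi <- ord[nterms[ord] > 0]
      if (!length(multi))
        return(list(valid = FALSE, reason = "all inner models intercept-only",
                    test_idx = test_idx))
      pick <- multi[1]
    }
    terms <- inner[[pick]]$terms
    cols <- unlist(design$terms[terms], use.names = FALSE)
    Xr <- cbind(1, design$X[rest, cols, drop = FALSE])
    fit <- qrRss(Xr, y_all[rest])
    while (is.null(fit) && length(terms)) {    # guard: degenerate refit
      terms <- terms[-length(terms)]
      cols <- unlist(design$terms[terms], use.names = FALSE)
      Xr <- cbind(1, design$X[rest, cols, drop = FALSE])
      fit <- qrRss(Xr, y_all[rest])
    }
    pred <- cbind(1, design$X[test_idx, cols, drop = FALSE]) %*% fit$coef
    if (stats::sd(pred) == 0)
      return(list(valid = FALSE, reason = "constant prediction",
                  test_idx = test_idx))
    ct <- stats::cor.test(as.numeric(pred), y_all[test_idx])
    list(valid = TRUE, terms = terms,
         test_rho = unname(ct$estimate), test_p = ct$p.value,
         test_idx = test_idx, n_inner_models = length(inner))
  })
}

#' Combine independent p-values by Fisher's method
#'
#' Computes \eqn{X = -2 \sum_i \ln p_i}, referred to a chi-squared
#' distribution with \eqn{2N} degrees of freedom; significance is declared
#' when X exceeds the upper-\code{alpha} quantile.
#'
#' @param pvals p-values in (0, 1]; zeros are clamped to the smallest
#'   positive double with a warning.
#' @param alpha significance level.
#' @return list: \code{X}, \code{df}, \code{critical}, \code{significant},
#'   \code{n}.
#' @examples
#' fisherCombine(rep(0.01, 50))$X   # 460.52
#' @export
fisherCombine <- function(pvals, alpha = 0.01) {
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  if (any(pvals == 0)) {
    warning("zero p-values clamped to the smallest positive double")
    pvals[pvals == 0] <- .Machine$double.xmin
  }
  X <- -2 * sum(log(pvals))
  df <- 2L * length(pvals)
  critical <- stats::qchisq(1 - alpha, df)
  list(X = X, df = df, critical = critical,
       significant = X > critical, n = length(pvals))
}

#' Run the full repeated-trials experiment for one segment/configuration
#'
#' Executes \code{outer_reps} independent trials (fresh test partitions),
#' redrawing any invalid trial with a fresh derived seed, and combines the
#' test p-values by Fisher's method.
#'
#' @param dataset a [makeDataset()] result.
#' @param params a [stepwiseParams()] object (its \code{seed} drives all
#'   trial seeds).
#' @return list with \code{trials} (data.frame: trial, test_rho, test_p,
#'   n_terms), \code{fisher} (a [fisherCombine()] result) and
#'   \code{invalid} (count of redrawn trials).
#' @export
runExperiment <- function(dataset, params = stepwiseParams()) {
  seeds <- withLocalSeed(params$seed,
                         sample.int(.Machine$integer.max - 1,
                                    params$outer_reps + 200L))
  spare <- params$outer_reps
  results <- vector("list", params$outer_reps)
  invalid <- 0L
  for (i in seq_len(params$outer_reps)) {
    res <- runTrial(dataset, params, seeds[i])
    while (!res$valid && spare < length(seeds)) {
      invalid <- invalid + 1L
      spare <- spare + 1L
      res <- runTrial(dataset, params, seeds[spare])
    }
    if (!res$valid)
      stop("could not obtain a valid trial after redraws")
    results[[i]] <- res
  }
  trials <- data.frame(
    trial = seq_len(params$outer_reps),
    test_rho = vapply(results, `[[`, numeric(1), "test_rho"),
    test_p = vapply(results, `[[`, numeric(1), "test_p"),
    n_terms = vapply(results, function(r) length(r$terms), integer(1)))
  list(trials = trials,
       fisher = fisherCombine(trials$test_p, alpha = params$alpha),
       invalid = invalid)
}

#' Fisher statistics across all segments and configurations
#'
#' Runs the repeated-trials experiment for every segment x configuration
#' cell and tabulates the Fisher X statistics with significance flags.
#'
#' @param fs a [RadiomicsFeatureSet-class].
#' @param features selected radiomic feature ids.
#' @param params a [stepwiseParams()] object.
#' @param gl gray level of the features used.
#' @param segments,configurations cells to run.
#' @param verbose print progress.
#' @return list with \code{fisher} (data.frame: segment, configuration, X,
#'   df, critical, significant) and \code{trials} (all per-trial rows).
#' @export
buildResultsTable <- function(fs, features, params = stepwiseParams(),
                              gl = 64L, segments = segmentLabels(),
                              configurations = c("radiomics", "clinical",
                                                 "combined"),
                              verbose = FALSE) {
  rows <- list(); trows <- list()
  for (seg in segments) {
    for (cf in configurations) {
      ds <- makeDataset(fs, seg, cf, features = features, gl = gl)
      ex <- runExperiment(ds, params)
      rows[[length(rows) + 1L]] <- data.frame(
        segment = seg, configuration = cf, X = ex$fisher$X,
        df = ex$fisher$df, critical = ex$fisher$critical,
        significant = ex$fisher$significant)
      trows[[length(trows) + 1L]] <- cbind(
        data.frame(segment = seg, configuration = cf), ex$trials)
      if (verbose)
        message(sprintf("%s / %s: X = %.2f (critical %.2f)", seg, cf,
                        ex$fisher$X, ex$fisher$critical))
    }
  }
  list(fisher = do.call(rbind, rows), trials = do.call(rbind, trows))
}
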
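## Clinical covariate and CAC score samplers for the synthetic cohort.

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Sample clinical covariate records
#'
#' Draws the ten clinical covariates: gender, race (7 levels), age, smoking
#' (3 levels), diabetes, hypertension, hyperlipidemia, family history of
#' CAD, BMI and LVEF. Categorical marginals default to the reference-cohort
#' frequencies; age, BMI and LVEF are truncated normals (age 62 +/- 12 on
#' [25, 90] years; BMI 29.5 +/- 6 on [15, 55] kg/m2; LVEF 60 +/- 8 on
#' [20, 85] %).
#'
#' Uses the caller's RNG stream; wrap in a seeded context (as
#' [generateCohort()] does) for reproducibility.
#'
#' @param params a [cohortParams()] object.
#' @param n number of records; defaults to \code{params$n_subjects}.
#' @return data.frame with one row per subject; categorical columns are
#'   factors over the full level sets.
#' @export
sampleClinical <- function(params, n = params$n_subjects) {
  if (n < 1) stop("n must be at least 1")
  m <- params$clinical_marginals
  drawCat <- function(marg) {
    factor(sample(names(marg), n, replace = TRUE, prob = marg),
           levels = names(marg))
  }
  data.frame(
    gender = drawCat(m$gender),
    race = drawCat(m$race),
    age = rtruncnorm1(n, 62, 12, 25, 90),
    smoking = drawCat(m$smoking),
    diabetes = drawCat(m$diabetes),
    hypertension = drawCat(m$hypertension),
    hyperlipidemia = drawCat(m$hyperlipidemia),
    family_history_cad = drawCat(m$family_history_cad),
    bmi = rtruncnorm1(n, 29.5, 6, 15, 55),
    lvef = rtruncnorm1(n, 60, 8, 20, 85))
}

## Standardized clinical risk index entering the CAC hurdle: a fixed linear
## combination of the covariates known to drive coronary calcium, centred
## so the index is ~N(0, 0.6^2) under the default marginals.
clinicalRiskIndex <- function(clinical) {
  z <- 0.035 * (clinical$age - 62) +
    0.40 * (clinical$diabetes == "Yes") +
    0.25 * (clinical$hypertension == "Yes") +
    0.25 * (clinical$hyperlipidemia == "Yes") +
    0.30 * (clinical$smoking == "Current smoker") +
    0.12 * (clinical$smoking == "Previous smoker") +
    0.20 * (clinical$family_history_cad == "Yes") +
    0.15 * (clinical$gender == "Male")
  z - 0.72   # centre under default marginals
}

#' Sample latent per-artery disease severity
#'
#' Gamma-distributed severities (one per artery: LAD, LCX, RCA), scaled up
#' with the clinical risk index. These latents drive both the regional
#' uptake suppression in the rendered image and the CAC hurdle, so image
#' texture and calcium burden share a common cause when
#' \code{severity_effect > 0}.
#'
#' @param params a [cohortParams()] object.
#' @param clinical data.frame from [sampleClinical()].
#' @return numeric matrix, subjects x 3, columns \code{lad,lcx,rca}.
#' @export
sampleSeverity <- function(params, clinical) {
  n <- nrow(clinical)
  z <- clinicalRiskIndex(clinical)
  s <- matrix(stats::rgamma(3 * n, shape = params$severity_shape,
                            rate = params$severity_rate), ncol = 3)
  s <- s * exp(0.3 * z)
  colnames(s) <- c("lad", "lcx", "rca")
  s
}

#' Sample per-artery CAC scores from the hurdle model
#'
#' Per artery, P(score > 0) is logistic in the clinical risk index and the
#' latent severity; the positive part is lognormal with a severity-shifted
#' log-mean. Under the default calibration about 58.4% of subjects have a
#' non-zero total score. Berman categories accompany every score.
#'
#' @param clinical data.frame from [sampleClinical()].
#' @param severity matrix from [sampleSeverity()].
#' @param params a [cohortParams()] object.
#' @return data.frame with \code{lad,lcx,rca,total} and per-score Berman
#'   categories \code{berman_lad,...,berman_total} (ordinal 1..6).
#' @export
sampleCac <- function(clinical, severity, params) {
  co <- params$cac_hurdle_coeffs
  if (!all(is.finite(co))) stop("hurdle coefficients must be finite")
  n <- nrow(clinical)
  z <- clinicalRiskIndex(clinical)
  mu <- params$cac_lognorm_mu_sigma[1]
  sig <- params$cac_lognorm_mu_sigma[2]
  scores <- matrix(0, n, 3, dimnames = list(NULL, c("lad", "lcx", "rca")))
  for (a in 1:3) {
    eta <- co[["intercept"]] + co[["severity"]] * severity[, a] +
      co[["clinical"]] * z
    nonzero <- stats::runif(n) < stats::plogis(eta)
    pos <- which(nonzero)
    scores[pos, a] <- stats::rlnorm(
      length(pos),
      meanlog = mu + params$cac_lognorm_severity_slope * severity[pos, a],
      sdlog = sig)
  }
  out <- as.data.frame(scores)
  out$total <- rowSums(scores)
  for (nm in c("lad", "lcx", "rca", "total"))
    out[[paste0("berman_", nm)]] <- bermanCategory(out[[nm]])
  out
}
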
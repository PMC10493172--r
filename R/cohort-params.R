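#' Parameters of the synthetic SPECT cohort generator
#'
#' Assembles and validates the full parameter set controlling the in-silico
#' cohort: left-ventricle shell geometry, count-like intensity texture, the
#' apical-thinning artifact, the latent per-artery disease severity that
#' couples image texture to calcium burden, clinical covariate marginals,
#' and the hurdle model for per-artery CAC scores.
#'
#' Defaults emulate the clinical acquisition the analysis assumes: 4.8 mm
#' isotropic voxels on a 64^3 grid, a half-ellipsoid left-ventricle shell
#' whose tight LAD vascular wedge averages about 460 voxels, categorical
#' clinical marginals matching the reference cohort tables, and a hurdle
#' calibration under which about 58.4% of subjects carry a non-zero total
#' CAC score.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param seed integer seed; the whole cohort is deterministic given it.
#' @param grid_shape 3 positive integers, volume dimensions.
#' @param voxel_mm isotropic voxel size in mm.
#' @param wall_thickness_mm myocardial wall thickness in mm.
#' @param outer_radii_mm outer semi-axes (x, y, z) of the shell in mm.
#' @param base_counts mean myocardial count level (arbitrary units).
#' @param texture_corr_len_mm correlation length of the smooth multiplicative
#'   intensity field, mm.
#' @param texture_rel_sd relative standard deviation of that field.
#' @param noise_poisson_scale scale of the Gaussian count-noise variance
#'   (variance = scale * mean, the Poisson surrogate); 0 disables noise.
#' @param artifact_prob probability of the apical-thinning artifact.
#' @param artifact_strength fractional apical count suppression when present.
#' @param severity_effect coupling of latent per-artery severity to regional
#'   uptake suppression; 0 gives the null model in which image texture is
#'   independent of CAC given the clinical covariates.
#' @param severity_shape,severity_rate gamma parameters of the latent
#'   per-artery severity (mean shape/rate).
#' @param cac_hurdle_coeffs named numeric vector \code{c(intercept,
#'   severity, clinical)}: logistic coefficients for P(artery CAC > 0) on
#'   the latent severity and the standardized clinical risk index.
#' @param cac_lognorm_mu_sigma numeric(2): baseline log-mean and log-sd of
#'   the positive CAC part; the log-mean additionally rises with severity.
#' @param cac_lognorm_severity_slope added log-mean per unit severity.
#' @param clinical_marginals optional replacement for the default
#'   categorical marginal frequencies (a named list; each element must sum
#'   to 1 within 0.01).
#' @return A validated list of class \code{CohortParams}.
#' @export
cohortParams <- function(n_subjects = 30,
                         seed = 1L,
                         grid_shape = c(64L, 64L, 64L),
                         voxel_mm = 4.8,
                         wall_thickness_mm = 15,
                         outer_radii_mm = c(42, 42, 72),
                         base_counts = 100,
                         texture_corr_len_mm = 12,
                         texture_rel_sd = 0.25,
                         noise_poisson_scale = 1,
                         artifact_prob = 0.3,
                         artifact_strength = 0.35,
                         severity_effect = 0.5,
                         severity_shape = 1.5,
                         severity_rate = 1.5,
                         cac_hurdle_coeffs = c(intercept = -1.896,
                                               severity = 0.8,
                                               clinical = 1.0),
                         cac_lognorm_mu_sigma = c(4.0, 1.8),
                         cac_lognorm_severity_slope = 0.4,
                         clinical_marginals = NULL) {
  if (n_subjects < 1) stop("n_subjects must be at least 1")
  if (length(voxel_mm) == 3) {
    if (diff(range(voxel_mm)) > 1e-6 * mean(voxel_mm))
      stop("voxel size must be isotropic")
    voxel_mm <- voxel_mm[1]
  }
  if (any(outer_radii_mm <= wall_thickness_mm))
    stop("outer radii must exceed the wall thickness")
  probs <- c(artifact_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  marg <- defaultClinicalMarginals()
  if (!is.null(clinical_marginals)) {
    for (nm in names(clinical_marginals)) {
      v <- clinical_marginals[[nm]]
      if (abs(sum(v) - 1) > 0.01)
        stop(sprintf("marginal '%s' does not sum to 1", nm))
      marg[[nm]] <- v / sum(v)
    }
  }
  structure(list(
    n_subjects = as.integer(n_subjects), seed = as.integer(seed),
    grid_shape = as.integer(grid_shape), voxel_mm = voxel_mm,
    wall_thickness_mm = wall_thickness_mm, outer_radii_mm = outer_radii_mm,
    base_counts = base_counts, texture_corr_len_mm = texture_corr_len_mm,
    texture_rel_sd = texture_rel_sd,
    noise_poisson_scale = noise_poisson_scale,
    artifact_prob = artifact_prob, artifact_strength = artifact_strength,
    severity_effect = severity_effect, severity_shape = severity_shape,
    severity_rate = severity_rate, cac_hurdle_coeffs = cac_hurdle_coeffs,
    cac_lognorm_mu_sigma = cac_lognorm_mu_sigma,
    cac_lognorm_severity_slope = cac_lognorm_severity_slope,
    clinical_marginals = marg), class = "CohortParams")
}

## Default categorical marginals: reference-cohort frequencies.
defaultClinicalMarginals <- function() {
  list(
    gender = c(Female = 0.497, Male = 0.503),
    race = c("African American" = 0.488, "Asian" = 0.022,
             "Hispanic/Latino" = 0.015, "Indian" = 0.004,
             "Middle eastern" = 0.041, "Native American" = 0.002,
             "White" = 0.427),
    smoking = c("Nonsmoker" = 0.477, "Current smoker" = 0.297,
                "Previous smoker" = 0.226),
    diabetes = c(No = 0.679, Yes = 0.321),
    hypertension = c(No = 0.299, Yes = 0.701),
    hyperlipidemia = c(No = 0.527, Yes = 0.473),
    family_history_cad = c(No = 0.614, Yes = 0.386))
}

#' @export
print.CohortParams <- function(x, ...) {
  cat(sprintf(
    "CohortParams: n = %d, grid %s @ %.1f mm, shell radii (%s) mm, wall %.0f mm\n",
    x$n_subjects, paste(x$grid_shape, collapse = "x"), x$voxel_mm,
    paste(x$outer_radii_mm, collapse = ", "), x$wall_thickness_mm))
  cat(sprintf("  severity_effect = %.2f, artifact_prob = %.2f, seed = %d\n",
              x$severity_effect, x$artifact_prob, x$seed))
  invisible(x)
}

## Evaluate a block with a local RNG state, restoring the caller's state.
withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}
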
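## Rendering of synthetic perfusion volumes: a half-ellipsoid left-ventricle
## shell with angular vascular wedges, a smooth correlated count field,
## latent-severity-driven regional suppression, an optional apical-thinning
## artifact, and Gaussian count noise with variance proportional to the mean
## (a Poisson surrogate keeping intensities continuous).

## Angular spans (degrees) of the vascular territories and the tight-wedge
## trims. The 17-segment-style grouping spans the whole shell (apex assigned
## to the LAD territory, as in the standard artery assignment); the
## MIM-style wedges are angularly trimmed and exclude basal and apex-tip
## bands, giving the tighter clinical vascular segments. Trims are
## calibrated so the tight LAD wedge averages ~460 voxels at default
## geometry.
WEDGE_BOUNDS <- c(lad0 = 0, lad1 = 150, lcx1 = 255, rca1 = 360)
MIM_ANGLE_TRIM <- 14      # degrees removed at each wedge boundary
MIM_BASAL_FRAC <- 0.12    # basal band (fraction of long axis) excluded
MIM_APEX_FRAC <- 0.94     # apex tip beyond this fraction excluded
APEX_FRAC_17 <- 0.80      # beyond this fraction of depth -> apical segment

## Smooth multiplicative field: white noise convolved with a Gaussian kernel
## (FFT, periodic wrap), standardized, then scaled to relative sd.
gaussianField3D <- function(dims, sigma_vox, rel_sd) {
  if (rel_sd <= 0) return(array(1, dims))
  w <- array(stats::rnorm(prod(dims)), dims)
  ax <- function(n) {
    d <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    d[seq_len(n)]
  }
  kx <- exp(-ax(dims[1])^2 / (2 * sigma_vox^2))
  ky <- exp(-ax(dims[2])^2 / (2 * sigma_vox^2))
  kz <- exp(-ax(dims[3])^2 / (2 * sigma_vox^2))
  ker <- outer(outer(kx, ky), kz)
  ker <- ker / sum(ker)
  sm <- Re(stats::fft(stats::fft(w) * stats::fft(ker), inverse = TRUE)) /
    prod(dims)
  sm <- (sm - mean(sm)) / stats::sd(sm)
  pmax(1 + rel_sd * sm, 0.05)
}

## Shell and wedge masks for one subject. `scale` jitters the semi-axes,
## `phi` rotates the wedge boundaries (degrees).
subjectMasks <- function(params, scale = 1, phi = 0) {
  d <- params$grid_shape
  vx <- params$voxel_mm
  ax <- (seq_len(d[1]) - (d[1] + 1) / 2) * vx
  ay <- (seq_len(d[2]) - (d[2] + 1) / 2) * vx
  az <- (seq_len(d[3]) - (d[3] + 1) / 2) * vx
  r <- params$outer_radii_mm * scale
  t <- params$wall_thickness_mm * scale
  ri <- r - t
  z0 <- r[3] / 2                     # base plane at zrel = 0
  X <- array(ax, d)
  Y <- aperm(array(ay, d[c(2, 1, 3)]), c(2, 1, 3))
  Z <- aperm(array(az, d[c(3, 1, 2)]), c(2, 3, 1))
  Zr <- Z - z0
  rho_out <- (X / r[1])^2 + (Y / r[2])^2 + (Zr / r[3])^2
  rho_in <- (X / ri[1])^2 + (Y / ri[2])^2 + (Zr / ri[3])^2
  myo <- rho_out <= 1 & rho_in > 1 & Zr <= 0
  if (!any(myo)) stop("shell empty at the given geometry")
  theta <- (atan2(Y, X) * 180 / pi + phi) %% 360
  depth <- -Zr / r[3]                # 0 at base .. 1 at apex tip
  b <- WEDGE_BOUNDS
  wLAD <- theta >= b["lad0"] & theta < b["lad1"]
  wLCX <- theta >= b["lad1"] & theta < b["lcx1"]
  wRCA <- theta >= b["lcx1"] & theta < b["rca1"]
  apex <- depth > APEX_FRAC_17
  lad17 <- myo & ((wLAD & !apex) | apex)
  lcx17 <- myo & wLCX & !apex
  rca17 <- myo & wRCA & !apex
  trim <- MIM_ANGLE_TRIM
  inBand <- function(lo, hi) {
    theta >= (lo + trim) & theta < (hi - trim)
  }
  tight <- myo & depth > MIM_BASAL_FRAC & depth < MIM_APEX_FRAC
  ladM <- tight & inBand(b["lad0"], b["lad1"])
  lcxM <- tight & inBand(b["lad1"], b["lcx1"])
  rcaM <- tight & inBand(b["lcx1"], b["rca1"])
  list(MYO = myo, LAD_MIM = ladM, LCX_MIM = lcxM, RCA_MIM = rcaM,
       LAD_17 = lad17, LCX_17 = lcx17, RCA_17 = rca17,
       depth = depth)
}

#' Render one synthetic subject
#'
#' Draws per-subject geometry jitter, renders the half-ellipsoid
#' left-ventricle shell with its seven segment masks, and synthesizes the
#' count image: \code{base_counts} x smooth correlated field x (1 -
#' severity-driven regional suppression), an optional apical-thinning
#' artifact with probability \code{artifact_prob}, plus Gaussian noise with
#' variance proportional to the mean. Uses the caller's RNG stream.
#'
#' @param params a [cohortParams()] object.
#' @param severity numeric(3), latent severities for \code{lad,lcx,rca}.
#' @return list with \code{image} (3D array) and \code{masks} (named list of
#'   the seven segment masks).
#' @export
renderSubject <- function(params, severity = c(0, 0, 0)) {
  scale <- min(max(stats::rnorm(1, 1, 0.06), 0.85), 1.15)
  phi <- stats::rnorm(1, 0, 8)
  mk <- subjectMasks(params, scale = scale, phi = phi)
  d <- params$grid_shape
  fld <- gaussianField3D(d, params$texture_corr_len_mm / params$voxel_mm,
                         params$texture_rel_sd)
  supp <- array(0, d)
  regions <- list(mk$LAD_17, mk$LCX_17, mk$RCA_17)
  for (a in 1:3) {
    f <- min(0.85, params$severity_effect * 0.15 * severity[a])
    if (f > 0) supp[regions[[a]]] <- f
  }
  img <- params$base_counts * fld * (1 - supp)
  img[!mk$MYO] <- 0.05 * params$base_counts * fld[!mk$MYO]
  if (stats::runif(1) < params$artifact_prob) {
    apexband <- mk$MYO & mk$depth > 0.70
    img[apexband] <- img[apexband] * (1 - params$artifact_strength)
  }
  if (params$noise_poisson_scale > 0) {
    img <- img + stats::rnorm(length(img)) *
      sqrt(params$noise_poisson_scale * pmax(img, 0))
    img <- pmax(img, 0)
  }
  list(image = img, masks = mk[segmentLabels()])
}
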
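#' Generate a complete synthetic SPECT cohort
#'
#' Produces an in-memory [SpectCohort-class]: clinical covariates, latent
#' per-artery severities, hurdle-model CAC scores, and one rendered volume
#' with seven segment masks per subject. Deterministic given
#' \code{params$seed}. With \code{severity_effect = 0} the image texture is
#' independent of CAC given the clinical covariates (the null model used by
#' type-I-error checks).
#'
#' @param params a [cohortParams()] object.
#' @param dir optional directory; when given, the cohort is also written to
#'   disk via [writeCohort()].
#' @return A \code{SpectCohort}.
#' @examples
#' ch <- generateCohort(cohortParams(n_subjects = 2, seed = 7))
#' ch
#' @export
generateCohort <- function(params, dir = NULL) {
  stopifnot(inherits(params, "CohortParams"))
  cohort <- withLocalSeed(params$seed, {
    clinical <- sampleClinical(params)
    severity <- sampleSeverity(params, clinical)
    cac <- sampleCac(clinical, severity, params)
    n <- params$n_subjects
    ids <- sprintf("S%04d", seq_len(n))
    images <- vector("list", n)
    masks <- vector("list", n)
    for (i in seq_len(n)) {
      sub <- renderSubject(params, severity[i, ])
      images[[i]] <- sub$image
      masks[[i]] <- sub$masks
    }
    new("SpectCohort", ids = ids, images = images, masks = masks,
        spacing = rep(params$voxel_mm, 3),
        clinical = DataFrame(clinical), cac = DataFrame(cac))
  })
  if (!is.null(dir)) writeCohort(cohort, dir)
  cohort
}

#' Write a cohort to disk
#'
#' Writes one NIfTI-1 image per subject under \code{dir/images}, one NIfTI
#' mask per segment under \code{dir/masks} (files
#' \code{<id>_<label>.nii.gz}), and \code{clinical.csv} / \code{cac.csv}
#' tables. Affines encode the isotropic voxel spacing.
#'
#' @param cohort a \code{SpectCohort}.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop(sprintf("cannot create output directory '%s'", dir))
  imgdir <- file.path(dir, "images"); maskdir <- file.path(dir, "masks")
  dir.create(imgdir, showWarnings = FALSE)
  dir.create(maskdir, showWarnings = FALSE)
  sp <- cohort@spacing
  for (i in seq_along(cohort@ids)) {
    id <- cohort@ids[i]
    nii <- RNifti::asNifti(cohort@images[[i]])
    RNifti::pixdim(nii) <- sp
    RNifti::writeNifti(nii, file.path(imgdir, paste0(id, ".nii.gz")))
    for (lab in segmentLabels()) {
      m <- RNifti::asNifti(array(as.integer(cohort@masks[[i]][[lab]]),
                                 dim(cohort@images[[i]])))
      RNifti::pixdim(m) <- sp
      RNifti::writeNifti(m, file.path(maskdir,
                                      paste0(id, "_", lab, ".nii.gz")))
    }
  }
  cl <- as.data.frame(cohort@clinical)
  cl <- cbind(subject_id = cohort@ids, cl)
  utils::write.csv(cl, file.path(dir, "clinical.csv"), row.names = FALSE)
  cc <- as.data.frame(cohort@cac)[, c("lad", "lcx", "rca", "total")]
  cc <- cbind(subject_id = cohort@ids, cc)
  utils::write.csv(cc, file.path(dir, "cac.csv"), row.names = FALSE)
  invisible(dir)
}

#' Load a cohort from disk
#'
#' Reads the layout written by [writeCohort()] and validates it: matching
#' subject ids across images, masks and tables; isotropic spacing; aligned
#' mask shapes; known factor levels. Berman categories are recomputed from
#' the scores.
#'
#' @param dir cohort directory (containing \code{images/}, \code{masks/}).
#' @param clinical_csv,cac_csv table paths; default to files inside
#'   \code{dir}.
#' @return A validated \code{SpectCohort}.
#' @export
loadCohort <- function(dir,
                       clinical_csv = file.path(dir, "clinical.csv"),
                       cac_csv = file.path(dir, "cac.csv")) {
  for (f in c(clinical_csv, cac_csv))
    if (!file.exists(f)) stop(sprintf("missing file '%s'", f))
  cl <- utils::read.csv(clinical_csv, stringsAsFactors = FALSE)
  cc <- utils::read.csv(cac_csv, stringsAsFactors = FALSE)
  ids <- cl$subject_id
  if (!setequal(ids, cc$subject_id))
    stop(sprintf("subject ids differ between tables (e.g. %s)",
                 setdiff(union(ids, cc$subject_id),
                         intersect(ids, cc$subject_id))[1]))
  cc <- cc[match(ids, cc$subject_id), ]
  lv <- clinicalLevels()
  for (nm in c("gender", "race", "smoking")) {
    bad <- setdiff(unique(cl[[nm]]), lv[[nm]])
    if (length(bad))
      stop(sprintf("subject %s: unknown %s level '%s'",
                   cl$subject_id[match(bad[1], cl[[nm]])], nm, bad[1]))
    cl[[nm]] <- factor(cl[[nm]], levels = lv[[nm]])
  }
  for (nm in c("diabetes", "hypertension", "hyperlipidemia",
               "family_history_cad"))
    cl[[nm]] <- factor(cl[[nm]], levels = c("No", "Yes"))
  images <- vector("list", length(ids))
  masks <- vector("list", length(ids))
  spacing <- NULL
  for (i in seq_along(ids)) {
    f <- file.path(dir, "images", paste0(ids[i], ".nii.gz"))
    if (!file.exists(f)) stop(sprintf("missing image for subject %s",
                                      ids[i]))
    nii <- RNifti::readNifti(f)
    sp <- RNifti::pixdim(nii)[1:3]
    if (diff(range(sp)) > 1e-6 * mean(sp))
      stop(sprintf("anisotropic spacing in '%s'", f))
    if (is.null(spacing)) spacing <- sp
    img <- array(as.numeric(nii), dim(nii))
    images[[i]] <- img
    ml <- list()
    for (lab in segmentLabels()) {
      mf <- file.path(dir, "masks", paste0(ids[i], "_", lab, ".nii.gz"))
      if (!file.exists(mf))
        stop(sprintf("missing mask %s for subject %s", lab, ids[i]))
      mm <- RNifti::readNifti(mf)
      if (!identical(dim(mm)[1:3], dim(img)))
        stop(sprintf("mask shape mismatch in '%s'", mf))
      ml[[lab]] <- array(as.numeric(mm) > 0.5, dim(img))
    }
    masks[[i]] <- ml
  }
  cacdf <- cc[, c("lad", "lcx", "rca", "total")]
  for (nm in c("lad", "lcx", "rca", "total"))
    cacdf[[paste0("berman_", nm)]] <- bermanCategory(cacdf[[nm]])
  cl$subject_id <- NULL
  new("SpectCohort", ids = ids, images = images, masks = masks,
      spacing = spacing, clinical = DataFrame(cl), cac = DataFrame(cacdf))
}

#' Outcome vector paired with a segment
#'
#' Maps a segment to its CAC outcome: the artery score for vascular
#' segments (identical for the two segmentation styles of the same artery),
#' and total CAC for the whole myocardium.
#'
#' @param cohort a \code{SpectCohort}.
#' @param label one of the seven segment labels.
#' @return numeric vector of CAC scores, one per subject.
#' @export
outcomeForSegment <- function(cohort, label) {
  label <- match.arg(label, segmentLabels())
  col <- switch(sub("_(MIM|17)$", "", label),
                MYO = "total", LAD = "lad", LCX = "lcx", RCA = "rca")
  as.numeric(cohort@cac[[col]])
}
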
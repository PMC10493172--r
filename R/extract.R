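## Feature extraction: evaluate the computable catalog (184 descriptors)
## for one ROI, and assemble the full subjects x (feature, GL, segment)
## table for a cohort.

## Pad GLRLM direction matrices to a common column count and sum (the
## "merged" aggregation: features of the direction-summed matrix).
sumPadded <- function(mats) {
  cmax <- max(vapply(mats, ncol, integer(1)))
  out <- matrix(0, nrow(mats[[1]]), cmax)
  for (m in mats) out[, seq_len(ncol(m))] <- out[, seq_len(ncol(m))] + m
  out
}

## Mean of per-direction feature vectors (the "averaged" aggregation).
## NaN sentinels propagate.
meanFeatures <- function(vlist) {
  Reduce(`+`, vlist) / length(vlist)
}

#' Compute all computable features for one ROI
#'
#' Discretizes the ROI by fixed bin number, builds the 3D texture matrices,
#' and evaluates the 184 computable descriptors: intensity statistics (raw
#' units), intensity histogram, intensity-volume histogram, GLCM and GLRLM
#' in both 3D aggregations (averaged over the 13 directions, and merged =
#' features of the direction-summed matrix), and the 3D GLSZM, GLDZM,
#' NGTDM and NGLDM.
#'
#' @param grid 3D numeric intensity array.
#' @param mask 3D logical ROI mask.
#' @param ng gray-level count for FBN discretization.
#' @return named numeric vector of 184 feature values (names are catalog
#'   feature ids); undefined values are NaN sentinels.
#' @export
computeSegmentFeatures <- function(grid, mask, ng) {
  droi <- discretizeFBN(grid, mask, ng)
  x <- grid[mask]
  g <- droi$levels[!is.na(droi$levels)]
  mats <- computeMatrices(droi)

  glcm_dir <- lapply(mats$glcm, glcmFeatures)
  glcm_avg <- meanFeatures(glcm_dir)
  glcm_mrg <- glcmFeatures(Reduce(`+`, mats$glcm))
  glrlm_dir <- lapply(mats$glrlm, glrlmFeatures)
  glrlm_avg <- meanFeatures(glrlm_dir)
  glrlm_mrg <- glrlmFeatures(sumPadded(mats$glrlm))

  nv <- mats$n_voxels
  out <- c(
    statFeatures(x),
    ihFeatures(g, ng),
    ivhFeatures(g, ng),
    setNames(glcm_avg, paste0("glcm_3d_avg_", names(glcm_avg))),
    setNames(glcm_mrg, paste0("glcm_3d_merged_", names(glcm_mrg))),
    setNames(glrlm_avg, paste0("glrlm_3d_avg_", names(glrlm_avg))),
    setNames(glrlm_mrg, paste0("glrlm_3d_merged_", names(glrlm_mrg))),
    setNames(glszmFeatures(mats$glszm, nv),
             paste0("glszm_3d_", names(glszmFeatures(mats$glszm, nv)))),
    setNames(gldzmFeatures(mats$gldzm, nv),
             paste0("gldzm_3d_", names(gldzmFeatures(mats$gldzm, nv)))),
    setNames(ngtdmFeatures(mats$ngtdm),
             paste0("ngtdm_3d_", names(ngtdmFeatures(mats$ngtdm)))),
    setNames(ngldmFeatures(mats$ngldm, nv),
             paste0("ngldm_3d_", names(ngldmFeatures(mats$ngldm, nv)))))
  out
}

#' Extract the full feature table of a cohort
#'
#' Evaluates every computable catalog descriptor for each requested gray
#' level and segment of every subject, returning a
#' [RadiomicsFeatureSet-class] (rows = feature instances, columns =
#' subjects). Deterministic; per-subject failures propagate with the
#' subject id.
#'
#' @param cohort a \code{SpectCohort}.
#' @param gls integer vector of gray-level counts.
#' @param segments character vector of segment labels.
#' @param verbose print progress.
#' @return A \code{RadiomicsFeatureSet}.
#' @export
extractFeatureTable <- function(cohort, gls = 64L,
                                segments = segmentLabels(),
                                verbose = FALSE) {
  stopifnot(is(cohort, "SpectCohort"))
  segments <- match.arg(segments, segmentLabels(), several.ok = TRUE)
  catalog <- buildCatalog()
  comp <- catalog[catalog$computed, ]
  ids <- cohort@ids
  combos <- expand.grid(feature_idx = seq_len(nrow(comp)),
                        gl = as.integer(gls), segment = segments,
                        stringsAsFactors = FALSE)
  rows <- nrow(combos)
  vals <- matrix(NA_real_, rows, length(ids),
                 dimnames = list(NULL, ids))
  for (si in seq_along(ids)) {
    img <- cohort@images[[si]]
    for (seg in segments) {
      msk <- cohort@masks[[si]][[seg]]
      for (gl in as.integer(gls)) {
        fv <- tryCatch(
          computeSegmentFeatures(img, msk, gl),
          error = function(e) stop(sprintf(
            "feature extraction failed for subject %s, segment %s, GL %d: %s",
            ids[si], seg, gl, conditionMessage(e)), call. = FALSE))
        sel <- combos$gl == gl & combos$segment == seg
        vals[sel, si] <- fv[comp$feature_id[combos$feature_idx[sel]]]
      }
    }
    if (verbose) message(sprintf("extracted subject %s (%d/%d)",
                                 ids[si], si, length(ids)))
  }
  rd <- DataFrame(feature_id = comp$feature_id[combos$feature_idx],
                  family = comp$family[combos$feature_idx],
                  aggregation = comp$aggregation[combos$feature_idx],
                  gl = combos$gl, segment = combos$segment)
  rownames(vals) <- paste(rd$feature_id, rd$gl, rd$segment, sep = "@")
  cd <- cbind(cohort@clinical, cohort@cac)
  rownames(cd) <- ids
  se <- SummarizedExperiment(assays = list(features = vals),
                             rowData = rd, colData = cd)
  new("RadiomicsFeatureSet", se)
}

#' Write a feature table as wide CSV
#'
#' One row per subject; columns named \code{feature_id@GL@segment}.
#'
#' @param fs a \code{RadiomicsFeatureSet}.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(fs, path) {
  m <- t(featureValues(fs))
  df <- cbind(data.frame(subject_id = rownames(m)), as.data.frame(m))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a wide feature-table CSV
#'
#' Inverse of [writeFeatureTable()] (without colData).
#'
#' @param path CSV path.
#' @return A \code{RadiomicsFeatureSet} (empty colData).
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- df$subject_id
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- ids
  parts <- strsplit(rownames(m), "@", fixed = TRUE)
  catalog <- buildCatalog()
  fid <- vapply(parts, `[`, character(1), 1)
  idx <- match(fid, catalog$feature_id)
  rd <- DataFrame(feature_id = fid,
                  family = catalog$family[idx],
                  aggregation = catalog$aggregation[idx],
                  gl = as.integer(vapply(parts, `[`, character(1), 2)),
                  segment = vapply(parts, `[`, character(1), 3))
  se <- SummarizedExperiment(assays = list(features = m), rowData = rd)
  new("RadiomicsFeatureSet", se)
}
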
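#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

## The seven analyzed cardiac segments: whole myocardium, plus the three
## vascular territories in two segmentation styles (tight vascular wedges,
## and groupings of the standard 17-segment polar model that span the whole
## left-ventricle shell).
SEGMENT_LABELS <- c("MYO", "LAD_MIM", "LCX_MIM", "RCA_MIM",
                    "LAD_17", "LCX_17", "RCA_17")

#' Segment labels analyzed by the pipeline
#' @return Character vector of the seven segment labels.
#' @export
segmentLabels <- function() SEGMENT_LABELS

CLINICAL_LEVELS <- list(
  gender = c("Female", "Male"),
  race = c("African American", "Asian", "Hispanic/Latino", "Indian",
           "Middle eastern", "Native American", "White"),
  smoking = c("Nonsmoker", "Current smoker", "Previous smoker"))

#' Clinical covariate level sets
#' @return Named list of factor level vectors for gender, race and smoking.
#' @export
clinicalLevels <- function() CLINICAL_LEVELS

#' SpectCohort: a cohort of perfusion volumes, segment masks and outcomes
#'
#' Container binding, per subject, a 3D intensity volume (arbitrary units,
#' isotropic voxels), seven aligned binary segment masks, the ten clinical
#' covariates, and per-artery coronary calcium (CAC) scores.
#'
#' @slot ids character, unique subject identifiers.
#' @slot images list of 3D numeric arrays, one per subject.
#' @slot masks list (per subject) of named lists of 3D logical arrays; names
#'   are the seven segment labels.
#' @slot spacing numeric(3), voxel spacing in mm (isotropic).
#' @slot clinical \code{DataFrame} of clinical covariates, one row per
#'   subject.
#' @slot cac \code{DataFrame} with columns \code{lad}, \code{lcx},
#'   \code{rca}, \code{total} and the corresponding Berman categories.
#' @export
setClass("SpectCohort",
  representation(ids = "character", images = "list", masks = "list",
                 spacing = "numeric", clinical = "DataFrame",
                 cac = "DataFrame"))

setValidity("SpectCohort", function(object) {
  n <- length(object@ids)
  msg <- character(0)
  if (anyDuplicated(object@ids)) msg <- c(msg, "subject ids must be unique")
  if (length(object@images) != n || length(object@masks) != n)
    msg <- c(msg, "images/masks length must match number of ids")
  if (nrow(object@clinical) != n || nrow(object@cac) != n)
    msg <- c(msg, "clinical/cac tables must have one row per subject")
  sp <- object@spacing
  if (length(sp) != 3 || diff(range(sp)) > 1e-6 * mean(sp))
    msg <- c(msg, "voxel spacing must be isotropic")
  for (i in seq_len(n)) {
    img <- object@images[[i]]
    if (!all(is.finite(img)))
      msg <- c(msg, sprintf("subject %s: non-finite intensities",
                            object@ids[i]))
    mk <- object@masks[[i]]
    if (!setequal(names(mk), SEGMENT_LABELS))
      msg <- c(msg, sprintf("subject %s: masks must cover the 7 segments",
                            object@ids[i]))
    for (lab in names(mk)) {
      if (!identical(dim(mk[[lab]]), dim(img)))
        msg <- c(msg, sprintf("subject %s: mask %s shape mismatch",
                              object@ids[i], lab))
      if (!any(mk[[lab]]))
        msg <- c(msg, sprintf("subject %s: mask %s is empty",
                              object@ids[i], lab))
    }
    if (length(msg) > 6) break    # avoid flooding on broken inputs
  }
  cc <- object@cac
  if (n > 0 && all(c("lad", "lcx", "rca", "total") %in% colnames(cc))) {
    if (any(cc$lad < 0 | cc$lcx < 0 | cc$rca < 0))
      msg <- c(msg, "CAC scores must be nonnegative")
    if (any(abs(cc$total - (cc$lad + cc$lcx + cc$rca)) > 1e-8))
      msg <- c(msg, "total CAC must equal lad + lcx + rca")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn SpectCohort-class number of subjects
#' @param object,x a \code{SpectCohort}.
#' @export
setMethod("length", "SpectCohort", function(x) length(x@ids))

setMethod("show", "SpectCohort", function(object) {
  cat(sprintf("SpectCohort: %d subjects, grid %s, %.1f mm voxels\n",
              length(object@ids),
              paste(dim(object@images[[1]]), collapse = "x"),
              object@spacing[1]))
  nz <- mean(object@cac$total > 0)
  cat(sprintf("  segments: %s\n", paste(SEGMENT_LABELS, collapse = ", ")))
  cat(sprintf("  non-zero total CAC: %.1f%%\n", 100 * nz))
})

#' @rdname SpectCohort-class
#' @export
subjectIds <- function(object) object@ids

#' @rdname SpectCohort-class
#' @export
clinicalData <- function(object) object@clinical

#' @rdname SpectCohort-class
#' @export
cacScores <- function(object) object@cac

#' @rdname SpectCohort-class
#' @export
voxelSpacing <- function(object) object@spacing

#' @rdname SpectCohort-class
#' @param i subject index or id.
#' @export
getImage <- function(object, i) {
  if (is.character(i)) i <- match(i, object@ids)
  object@images[[i]]
}

#' @rdname SpectCohort-class
#' @param label one of the seven segment labels.
#' @export
getMask <- function(object, i, label) {
  if (is.character(i)) i <- match(i, object@ids)
  label <- match.arg(label, SEGMENT_LABELS)
  object@masks[[i]][[label]]
}

#' RadiomicsFeatureSet: subjects x (feature, gray level, segment) values
#'
#' A \code{SummarizedExperiment} subclass. Rows are feature instances, one
#' per (feature_id, gray level, segment) combination, with that metadata in
#' \code{rowData}; columns are subjects, with clinical covariates and CAC
#' scores in \code{colData}. The single assay \code{"features"} holds the
#' feature values; undefined features are NaN sentinels, never dropped.
#'
#' @export
setClass("RadiomicsFeatureSet", contains = "SummarizedExperiment")

setValidity("RadiomicsFeatureSet", function(object) {
  rd <- rowData(object)
  need <- c("feature_id", "family", "aggregation", "gl", "segment")
  if (!all(need %in% colnames(rd)))
    return(sprintf("rowData must contain %s", paste(need, collapse = ", ")))
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    return("assay 'features' is required")
  TRUE
})

setMethod("show", "RadiomicsFeatureSet", function(object) {
  rd <- rowData(object)
  cat(sprintf(
    "RadiomicsFeatureSet: %d feature instances x %d subjects\n",
    nrow(object), ncol(object)))
  cat(sprintf("  features: %d unique, GLs: %s, segments: %s\n",
              length(unique(rd$feature_id)),
              paste(sort(unique(rd$gl)), collapse = "/"),
              paste(unique(rd$segment), collapse = ", ")))
})

#' @rdname RadiomicsFeatureSet-class
#' @param object a \code{RadiomicsFeatureSet}.
#' @export
featureValues <- function(object) assay(object, "features")

#' SelectionReport: audit trail of the feature-selection cascade
#'
#' @slot stages data.frame with one row per stage: name, number removed,
#'   number surviving.
#' @slot removed named list of removed feature-id vectors per stage.
#' @slot chosen_gl integer, the selected gray-level count.
#' @slot gl_diagnostics data.frame of per-GL diagnostics (identical-feature
#'   count, low-dynamic-range fraction, high-correlation pair count).
#' @slot notes character, free-form log entries.
#' @export
setClass("SelectionReport",
  representation(stages = "data.frame", removed = "list",
                 chosen_gl = "integer", gl_diagnostics = "data.frame",
                 notes = "character"))

setMethod("show", "SelectionReport", function(object) {
  cat("SelectionReport\n")
  if (nrow(object@stages)) {
    for (i in seq_len(nrow(object@stages)))
      cat(sprintf("  %-28s removed %4d -> %4d surviving\n",
                  object@stages$stage[i], object@stages$removed[i],
                  object@stages$surviving[i]))
  }
  if (length(object@chosen_gl))
    cat(sprintf("  chosen gray levels: %d\n", object@chosen_gl))
})

#' @rdname SelectionReport-class
#' @param object a \code{SelectionReport}.
#' @export
stageCounts <- function(object) object@stages

#' Serialize a SelectionReport to JSON
#' @param object a \code{SelectionReport}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSelectionReport <- function(object, path) {
  jsonlite::write_json(
    list(stages = object@stages, removed = object@removed,
         chosen_gl = object@chosen_gl,
         gl_diagnostics = object@gl_diagnostics, notes = object@notes),
    path, dataframe = "rows", auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
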
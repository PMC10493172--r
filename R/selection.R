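## The blind-to-outcome feature-selection cascade. Stages 1-2 act on the
## catalog (a priori usefulness); stages 3-7 act on computed feature values
## (identical values, redundant varieties, exact duplicates, dynamic range,
## correlation pruning); a final step picks the working gray-level count.
## CAC outcomes are never consulted: every stage sees feature values only.

#' @name selectionStages
#' @title Feature-selection cascade stages
#' @description
#' The seven-stage unsupervised cascade. Stage 1 removes all 2D/2.5D
#' aggregations (isotropic 3D voxels make them redundant: 487 -> 215).
#' Stage 2 removes families tied to absolute intensity or segment shape
#' (intensity statistics, local intensity, morphology: 215 -> 166). Stage 3
#' drops features identical across all subjects; under fixed-bin-number
#' discretization exactly four are forced constant (histogram minimum,
#' maximum, range, and NGLDM dependence-count percentage: 166 -> 162).
#' Stage 4 removes the redundant 3D aggregation variety of GLCM/GLRLM
#' (162 -> 121). Stage 5 removes one member of every Spearman-rho = 1 pair.
#' Stage 6 drops features with dynamic range (|variance/mean|) below 1e-5.
#' Stage 7 recursively prunes features correlated at |rho| >= 0.95.
NULL

## Stacked per-GL value matrix: rows = subject x segment, cols = feature_id.
stackedFeatureMatrix <- function(fs, gl) {
  rd <- rowData(fs)
  keep <- rd$gl == gl
  if (!any(keep)) stop(sprintf("no features at GL %d", gl))
  vals <- featureValues(fs)[keep, , drop = FALSE]
  rd <- rd[keep, ]
  segs <- unique(rd$segment)
  blocks <- lapply(segs, function(sg) {
    sel <- rd$segment == sg
    m <- t(vals[sel, , drop = FALSE])
    colnames(m) <- rd$feature_id[sel]
    rownames(m) <- paste(colnames(vals), sg, sep = ".")
    m
  })
  feat <- colnames(blocks[[1]])
  do.call(rbind, lapply(blocks, function(b) b[, feat, drop = FALSE]))
}

#' @rdname selectionStages
#' @param catalog a catalog from [buildCatalog()].
#' @return Stages 1-2: the filtered catalog. Stages 3-7: the filtered value
#'   matrix with attribute \code{removed} (feature ids); stage 5 also
#'   attaches \code{pairs}.
#' @export
stage1DropAggregations <- function(catalog) {
  drop <- grepl("^2", catalog$aggregation)
  out <- catalog[!drop, ]
  attr(out, "removed") <- catalog$feature_id[drop]
  out
}

#' @rdname selectionStages
#' @export
stage2DropNonquantitative <- function(catalog) {
  drop <- catalog$family %in% c("statistics", "local_intensity",
                                "morphology")
  out <- catalog[!drop, ]
  attr(out, "removed") <- catalog$feature_id[drop]
  out
}

## Exact column constancy, sentinel-aware (NaN == NaN counts as identical).
isConstantColumn <- function(v) {
  if (all(is.nan(v))) return(TRUE)
  if (any(is.nan(v))) return(FALSE)
  max(v) == min(v)
}

#' @rdname selectionStages
#' @param mat numeric matrix, rows = observations (subject x segment),
#'   columns = features.
#' @export
stage3DropConstant <- function(mat) {
  if (nrow(mat) < 2) stop("need at least 2 subjects to detect constants")
  const <- apply(mat, 2, isConstantColumn)
  if (all(const)) stop("all features constant: degenerate cohort")
  out <- mat[, !const, drop = FALSE]
  attr(out, "removed") <- colnames(mat)[const]
  out
}

#' @rdname selectionStages
#' @param verbose print the per-variety range sums.
#' @export
stage4DedupVariety <- function(mat, verbose = FALSE) {
  removed <- character(0)
  diag_rho <- list()
  for (fam in c("glcm", "glrlm")) {
    avg_cols <- grep(paste0("^", fam, "_3d_avg_"), colnames(mat),
                     value = TRUE)
    mrg_cols <- grep(paste0("^", fam, "_3d_merged_"), colnames(mat),
                     value = TRUE)
    if (!length(avg_cols) || !length(mrg_cols))
      stop(sprintf("family %s: one 3D variety is absent", fam))
    nm_avg <- sub(paste0("^", fam, "_3d_avg_"), "", avg_cols)
    nm_mrg <- sub(paste0("^", fam, "_3d_merged_"), "", mrg_cols)
    common <- intersect(nm_avg, nm_mrg)
    rng <- c(avg = 0, merged = 0)
    rho <- setNames(numeric(length(common)), common)
    for (nm in common) {
      a <- mat[, paste0(fam, "_3d_avg_", nm)]
      b <- mat[, paste0(fam, "_3d_merged_", nm)]
      ok <- is.finite(a) & is.finite(b)
      rho[nm] <- if (sum(ok) > 2 && stats::var(a[ok]) > 0 &&
                       stats::var(b[ok]) > 0)
        spearmanRho(a[ok], b[ok]) else NA_real_
      u <- range(c(a[ok], b[ok]))
      span <- diff(u)
      if (span > 0) {
        rng["avg"] <- rng["avg"] + diff(range(a[ok])) / span
        rng["merged"] <- rng["merged"] + diff(range(b[ok])) / span
      }
    }
    drop_variety <- if (rng["avg"] < rng["merged"]) "avg" else "merged"
    drop_cols <- if (drop_variety == "avg") avg_cols else mrg_cols
    removed <- c(removed, drop_cols)
    diag_rho[[fam]] <- rho
    if (verbose)
      message(sprintf("%s: range sums avg %.2f / merged %.2f -> drop %s",
                      fam, rng["avg"], rng["merged"], drop_variety))
  }
  out <- mat[, setdiff(colnames(mat), removed), drop = FALSE]
  attr(out, "removed") <- removed
  attr(out, "diagonal_rho") <- diag_rho
  out
}

## |Spearman| correlation matrix over finite pairs.
absSpearman <- function(mat) {
  rk <- apply(mat, 2, function(v) {
    v[!is.finite(v)] <- NA
    rank(v, na.last = "keep")
  })
  ## constant columns yield NA correlations by design; silence the sd=0 noise
  abs(suppressWarnings(stats::cor(rk, use = "pairwise.complete.obs")))
}

#' @rdname selectionStages
#' @export
stage5DropExactDuplicates <- function(mat) {
  rho <- absSpearman(mat)
  n <- ncol(mat)
  pairs <- which(upper.tri(rho) & !is.na(rho) & rho >= 1 - 1e-12,
                 arr.ind = TRUE)
  removed <- character(0)
  pair_list <- list()
  rngs <- apply(mat, 2, function(v) diff(range(v[is.finite(v)])))
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      i <- colnames(mat)[pairs[k, 1]]; j <- colnames(mat)[pairs[k, 2]]
      pair_list[[length(pair_list) + 1L]] <- c(i, j)
      if (i %in% removed || j %in% removed) next
      drop <- if (rngs[j] <= rngs[i]) j else i   # tie -> later catalog col
      removed <- c(removed, drop)
    }
  }
  out <- mat[, setdiff(colnames(mat), removed), drop = FALSE]
  attr(out, "removed") <- removed
  attr(out, "pairs") <- pair_list
  out
}

#' @rdname selectionStages
#' @param threshold dynamic-range threshold on |variance/mean|.
#' @export
stage6DropLowDynamicRange <- function(mat, threshold = 1e-5) {
  ratio <- apply(mat, 2, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2) return(0)
    vv <- stats::var(v)
    m <- mean(v)
    if (abs(m) < 1e-12) vv else abs(vv / m)
  })
  drop <- ratio < threshold
  out <- mat[, !drop, drop = FALSE]
  attr(out, "removed") <- colnames(mat)[drop]
  out
}

#' @rdname selectionStages
#' @param rho_max high-correlation threshold for the recursive pruning.
#' @export
stage7RecursivePrune <- function(mat, rho_max = 0.95) {
  rho <- absSpearman(mat)
  n <- ncol(mat)
  adj <- !is.na(rho) & rho >= rho_max
  diag(adj) <- FALSE
  counts <- colSums(adj)
  ord <- order(-counts, seq_len(n))       # ties broken by catalog order
  f_sorted <- colnames(mat)[ord]
  partners <- lapply(seq_len(n), function(i) colnames(mat)[adj[, i]])
  names(partners) <- colnames(mat)
  keep <- character(0)
  while (length(f_sorted)) {
    f_keep <- f_sorted[1]
    keep <- c(keep, f_keep)
    R <- setdiff(partners[[f_keep]], keep)
    frontier <- R
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(partners[frontier])), c(keep, R))
      R <- c(R, nxt)
      frontier <- nxt
    }
    f_sorted <- setdiff(f_sorted, c(f_keep, R))
  }
  keep <- colnames(mat)[colnames(mat) %in% keep]   # back to catalog order
  out <- mat[, keep, drop = FALSE]
  attr(out, "removed") <- setdiff(colnames(mat), keep)
  out
}

## Per-GL diagnostics used for discretization-level selection.
glDiagnostics <- function(mat, dr_threshold = 1e-5, rho_high = 0.9) {
  const <- sum(apply(mat, 2, isConstantColumn))
  ratio <- apply(mat, 2, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2) return(0)
    m <- mean(v); vv <- stats::var(v)
    if (abs(m) < 1e-12) vv else abs(vv / m)
  })
  lowdr <- mean(ratio < dr_threshold)
  rho <- absSpearman(mat)
  high <- sum(upper.tri(rho) & !is.na(rho) & rho >= rho_high)
  c(identical = const, low_dr_frac = lowdr, high_rho_pairs = high)
}

#' Select the working gray-level count
#'
#' Computes per-GL diagnostics (count of identical features, fraction with
#' low dynamic range, count of feature pairs with |Spearman| >= 0.9) on the
#' per-GL tables, excludes GLs dominated on all three diagnostics, and
#' returns the configured preference among the non-dominated set (default
#' 64; ties between equally good GLs resolve to the smaller count, since
#' coarser discretizations are cheaper and at least as robust).
#'
#' @param tables named list of per-GL value matrices (names = GL).
#' @param preference preferred GL when non-dominated.
#' @param dr_threshold,rho_high diagnostic thresholds.
#' @return list with \code{gl} (chosen count) and \code{diagnostics}
#'   (data.frame, one row per GL).
#' @export
selectGL <- function(tables, preference = 64L, dr_threshold = 1e-5,
                     rho_high = 0.9) {
  gls <- as.integer(names(tables))
  if (length(gls) == 1)
    return(list(gl = gls, diagnostics = data.frame(gl = gls)))
  d <- t(vapply(tables, glDiagnostics, numeric(3),
                dr_threshold = dr_threshold, rho_high = rho_high))
  diag_df <- data.frame(gl = gls, d)
  dominated <- vapply(seq_along(gls), function(i) {
    any(vapply(seq_along(gls), function(j) {
      j != i && all(d[j, ] <= d[i, ]) && any(d[j, ] < d[i, ])
    }, logical(1)))
  }, logical(1))
  cand <- gls[!dominated]
  gl <- if (preference %in% cand) as.integer(preference) else {
    rk <- rowSums(apply(d[!dominated, , drop = FALSE], 2, rank,
                        ties.method = "min"))
    cand[order(rk, cand)][1]
  }
  list(gl = gl, diagnostics = diag_df)
}

#' Run the full feature-selection cascade
#'
#' Chains catalog stages 1-2, value stages 3-7 per gray level, and the
#' gray-level selection, on a cohort feature table. The cascade is fully
#' unsupervised: CAC scores are never read. Value stages operate on the
#' subject-by-segment stacked matrix so one common feature set emerges
#' across segments.
#'
#' @param fs a [RadiomicsFeatureSet-class] covering the GLs of interest.
#' @param gl_preference preferred gray-level count (default 64).
#' @param rho_max stage-7 pruning threshold.
#' @param dr_threshold stage-6 dynamic-range threshold.
#' @return list with \code{features} (selected feature ids at the chosen
#'   GL), \code{gl}, \code{table} (selected stacked matrix) and
#'   \code{report} (a [SelectionReport-class]).
#' @export
runSelectionPipeline <- function(fs, gl_preference = 64L, rho_max = 0.95,
                                 dr_threshold = 1e-5) {
  catalog <- buildCatalog()
  s1 <- stage1DropAggregations(catalog)
  s2 <- stage2DropNonquantitative(s1)
  gls <- sort(unique(rowData(fs)$gl))
  tables <- lapply(gls, function(g) {
    m <- stackedFeatureMatrix(fs, g)
    m[, intersect(colnames(m), s2$feature_id), drop = FALSE]
  })
  names(tables) <- gls
  glsel <- selectGL(tables, preference = gl_preference,
                    dr_threshold = dr_threshold)
  mat <- tables[[as.character(glsel$gl)]]
  s3 <- stage3DropConstant(mat)
  s4 <- stage4DedupVariety(s3)
  s5 <- stage5DropExactDuplicates(s4)
  s6 <- stage6DropLowDynamicRange(s5, threshold = dr_threshold)
  s7 <- stage7RecursivePrune(s6, rho_max = rho_max)
  removed <- list(
    stage1_aggregations = attr(s1, "removed"),
    stage2_nonquantitative = attr(s2, "removed"),
    stage3_constant = attr(s3, "removed"),
    stage4_variety = attr(s4, "removed"),
    stage5_duplicates = attr(s5, "removed"),
    stage6_low_dynamic_range = attr(s6, "removed"),
    stage7_high_correlation = attr(s7, "removed"))
  surv <- c(nrow(catalog), nrow(s1), nrow(s2), ncol(s3), ncol(s4),
            ncol(s5), ncol(s6), ncol(s7))
  stages <- data.frame(
    stage = c("catalog", names(removed)),
    removed = c(0L, vapply(removed, length, integer(1))),
    surviving = surv)
  report <- new("SelectionReport", stages = stages, removed = removed,
                chosen_gl = as.integer(glsel$gl),
                gl_diagnostics = glsel$diagnostics,
                notes = sprintf("stage5 rho=1 pairs: %d",
                                length(attr(s5, "pairs"))))
  list(features = colnames(s7), gl = as.integer(glsel$gl), table = s7,
       report = report)
}
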
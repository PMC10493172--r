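## Pipeline orchestration: a single validated configuration drives the
## simulate -> extract -> select -> univariate -> multivariate -> report
## chain, each stage reading and writing the documented files so every
## artifact is re-derivable from config + seed alone.

#' Pipeline configuration
#'
#' Reads (or builds) the full pipeline configuration: cohort parameters,
#' gray-level list, segments, selection thresholds, stepwise parameters,
#' output directory and log level. Unknown keys are rejected.
#'
#' @param path optional YAML or JSON file; keys mirror the arguments of
#'   [cohortParams()] (under \code{cohort}), [stepwiseParams()] (under
#'   \code{stepwise}) and the top-level keys \code{gls}, \code{segments},
#'   \code{configurations}, \code{gl_preference}, \code{rho_max},
#'   \code{dr_threshold}, \code{out_dir}, \code{log_level}.
#' @param overrides named list applied over the file contents.
#' @return list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(path = NULL, overrides = list()) {
  cfg <- list(cohort = list(), stepwise = list(),
              gls = c(4L, 8L, 16L, 32L, 64L, 128L, 256L, 512L),
              segments = segmentLabels(),
              configurations = c("radiomics", "clinical", "combined"),
              gl_preference = 64L, rho_max = 0.95, dr_threshold = 1e-5,
              out_dir = "spect_out", log_level = "info")
  if (!is.null(path)) {
    raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                            simplifyVector = TRUE)
    else yaml::read_yaml(path)
    bad <- setdiff(names(raw), names(cfg))
    if (length(bad))
      stop(sprintf("unknown config key '%s'", bad[1]))
    cfg[names(raw)] <- raw
  }
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad)) stop(sprintf("unknown config key '%s'", bad[1]))
  cfg[names(overrides)] <- overrides
  badc <- setdiff(names(cfg$cohort), names(formals(cohortParams)))
  if (length(badc)) stop(sprintf("unknown cohort key '%s'", badc[1]))
  bads <- setdiff(names(cfg$stepwise), names(formals(stepwiseParams)))
  if (length(bads)) stop(sprintf("unknown stepwise key '%s'", bads[1]))
  ## YAML/JSON may deliver scalars wrapped in lists
  cfg$gls <- as.integer(unlist(cfg$gls))
  cfg$segments <- as.character(unlist(cfg$segments))
  cfg$configurations <- as.character(unlist(cfg$configurations))
  cfg$cohort <- lapply(cfg$cohort, function(v)
    if (is.list(v)) unlist(v) else v)
  cfg$stepwise <- lapply(cfg$stepwise, function(v)
    if (is.list(v)) unlist(v) else v)
  structure(cfg, class = "PipelineConfig")
}

pipeLog <- function(cfg, level, fmt, ...) {
  ranks <- c(debug = 1, info = 2, warn = 3)
  if (ranks[[level]] >= ranks[[cfg$log_level %||% "info"]])
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the whole pipeline from a configuration
#'
#' Generates (or loads) the cohort, extracts the feature table over the
#' configured gray levels, runs the unsupervised selection cascade, the
#' univariate Spearman/FDR screen per segment, and the multivariate
#' stepwise + Fisher experiments, writing \code{feature_table.csv},
#' \code{selection_report.json}, \code{univariate.csv},
#' \code{experiments.csv} and \code{fisher.csv} under \code{out_dir}.
#'
#' @param cfg a [pipelineConfig()] object.
#' @return invisibly, a list with the in-memory results.
#' @export
runPipeline <- function(cfg) {
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  params <- do.call(cohortParams, cfg$cohort)
  pipeLog(cfg, "info", "simulating cohort (n = %d, seed = %d)",
          params$n_subjects, params$seed)
  cohort <- generateCohort(params, dir = file.path(out, "cohort"))
  pipeLog(cfg, "info", "extracting features at GLs %s",
          paste(cfg$gls, collapse = ","))
  fs <- extractFeatureTable(cohort, gls = cfg$gls,
                            segments = cfg$segments)
  writeFeatureTable(fs, file.path(out, "feature_table.csv"))
  sel <- runSelectionPipeline(fs, gl_preference = cfg$gl_preference,
                              rho_max = cfg$rho_max,
                              dr_threshold = cfg$dr_threshold)
  writeSelectionReport(sel$report, file.path(out, "selection_report.json"))
  for (nm in names(sel$report@removed))
    utils::write.csv(
      data.frame(feature_id = sel$report@removed[[nm]]),
      file.path(out, paste0("removed_", nm, ".csv")), row.names = FALSE)
  pipeLog(cfg, "info", "selected %d features at GL %d",
          length(sel$features), sel$gl)
  ## univariate screen per segment, both outcome codings
  uni <- list()
  for (seg in cfg$segments) {
    rd <- rowData(fs)
    selr <- rd$gl == sel$gl & rd$segment == seg &
      rd$feature_id %in% sel$features
    x <- t(featureValues(fs)[selr, , drop = FALSE])
    colnames(x) <- rd$feature_id[selr]
    yy <- outcomeForSegment(cohort, seg)
    for (md in c("continuous", "discrete")) {
      sc <- spearmanScreen(x, yy, mode = md)
      uni[[length(uni) + 1L]] <- cbind(
        data.frame(segment = seg, mode = md), sc)
    }
  }
  uni <- do.call(rbind, uni)
  utils::write.csv(uni, file.path(out, "univariate.csv"),
                   row.names = FALSE)
  sw <- do.call(stepwiseParams, cfg$stepwise)
  pipeLog(cfg, "info", "running %d x %d stepwise experiments",
          length(cfg$segments), length(cfg$configurations))
  res <- buildResultsTable(fs, sel$features, params = sw, gl = sel$gl,
                           segments = cfg$segments,
                           configurations = cfg$configurations,
                           verbose = cfg$log_level == "debug")
  utils::write.csv(res$trials, file.path(out, "experiments.csv"),
                   row.names = FALSE)
  utils::write.csv(res$fisher, file.path(out, "fisher.csv"),
                   row.names = FALSE)
  invisible(list(cohort = cohort, features = fs, selection = sel,
                 univariate = uni, results = res))
}

#' Command-line entry point
#'
#' Subcommands: \code{simulate}, \code{extract}, \code{select},
#' \code{univariate}, \code{multivariate}, \code{report} and
#' \code{run-all}. Each consumes/produces the documented files; flags
#' \code{--config}, \code{--seed}, \code{--out}, \code{--subjects},
#' \code{--gl}, \code{--segments}, \code{--configurations},
#' \code{--log-level} override the configuration.
#'
#' @param args character vector of command-line arguments (subcommand
#'   first).
#' @return integer exit code: 0 on success, 1 on validation failure, 2 on
#'   I/O failure.
#' @export
cliMain <- function(args = commandArgs(trailingOnly = TRUE)) {
  sub <- args[1]
  known <- c("simulate", "extract", "select", "univariate",
             "multivariate", "report", "run-all")
  if (is.na(sub) || !sub %in% known) {
    message("usage: spectradiomics <", paste(known, collapse = "|"),
            "> [--config PATH] [--seed INT] [--out DIR] ...")
    return(1L)
  }
  spec <- list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--out", type = "character", default = NULL),
    optparse::make_option("--subjects", type = "integer", default = NULL),
    optparse::make_option("--gl", type = "character", default = NULL),
    optparse::make_option("--segments", type = "character",
                          default = NULL),
    optparse::make_option("--configurations", type = "character",
                          default = NULL),
    optparse::make_option("--log-level", type = "character",
                          default = NULL))
  opt <- tryCatch(
    optparse::parse_args(optparse::OptionParser(option_list = spec),
                         args = args[-1]),
    error = function(e) e)
  if (inherits(opt, "error")) {
    message("argument error: ", conditionMessage(opt))
    return(1L)
  }
  res <- tryCatch({
    ov <- list()
    if (!is.null(opt$out)) ov$out_dir <- opt$out
    if (!is.null(opt$gl)) ov$gls <-
      as.integer(strsplit(opt$gl, ",")[[1]])
    if (!is.null(opt$segments)) ov$segments <-
      strsplit(opt$segments, ",")[[1]]
    if (!is.null(opt$configurations)) ov$configurations <-
      strsplit(opt$configurations, ",")[[1]]
    if (!is.null(opt$log_level)) ov$log_level <- opt$log_level
    cfg <- pipelineConfig(opt$config, ov)
    if (!is.null(opt$seed)) cfg$cohort$seed <- opt$seed
    if (!is.null(opt$seed)) cfg$stepwise$seed <- opt$seed
    if (!is.null(opt$subjects)) cfg$cohort$n_subjects <- opt$subjects
    runCliSubcommand(sub, cfg)
    0L
  }, error = function(e) {
    msg <- conditionMessage(e)
    message("error: ", msg)
    if (grepl("cannot|missing file|unwritable|No such file", msg)) 2L
    else 1L
  })
  res
}

## Stage-wise execution sharing intermediate files under out_dir.
runCliSubcommand <- function(sub, cfg) {
  out <- cfg$out_dir
  if (sub == "run-all") {
    runPipeline(cfg)
    return(invisible(NULL))
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  params <- do.call(cohortParams, cfg$cohort)
  cohortDir <- file.path(out, "cohort")
  if (sub == "simulate") {
    generateCohort(params, dir = cohortDir)
    return(invisible(NULL))
  }
  cohort <- loadCohort(cohortDir)
  ftPath <- file.path(out, "feature_table.csv")
  if (sub == "extract") {
    fs <- extractFeatureTable(cohort, gls = cfg$gls,
                              segments = cfg$segments)
    writeFeatureTable(fs, ftPath)
    return(invisible(NULL))
  }
  fs <- readFeatureTable(ftPath)
  ## reattach outcomes for modeling stages
  cd <- cbind(cohort@clinical, cohort@cac)
  rownames(cd) <- cohort@ids
  colData(fs) <- cd[colnames(fs), , drop = FALSE]
  sel <- runSelectionPipeline(fs, gl_preference = cfg$gl_preference,
                              rho_max = cfg$rho_max,
                              dr_threshold = cfg$dr_threshold)
  if (sub == "select") {
    writeSelectionReport(sel$report,
                         file.path(out, "selection_report.json"))
    return(invisible(NULL))
  }
  if (sub == "univariate") {
    uni <- list()
    for (seg in cfg$segments) {
      rd <- rowData(fs)
      selr <- rd$gl == sel$gl & rd$segment == seg &
        rd$feature_id %in% sel$features
      x <- t(featureValues(fs)[selr, , drop = FALSE])
      colnames(x) <- rd$feature_id[selr]
      yy <- outcomeForSegment(cohort, seg)
      for (md in c("continuous", "discrete"))
        uni[[length(uni) + 1L]] <- cbind(
          data.frame(segment = seg, mode = md),
          spearmanScreen(x, yy, mode = md))
    }
    utils::write.csv(do.call(rbind, uni),
                     file.path(out, "univariate.csv"), row.names = FALSE)
    return(invisible(NULL))
  }
  if (sub == "multivariate") {
    sw <- do.call(stepwiseParams, cfg$stepwise)
    res <- buildResultsTable(fs, sel$features, params = sw, gl = sel$gl,
                             segments = cfg$segments,
                             configurations = cfg$configurations)
    utils::write.csv(res$trials, file.path(out, "experiments.csv"),
                     row.names = FALSE)
    utils::write.csv(res$fisher, file.path(out, "fisher.csv"),
                     row.names = FALSE)
    return(invisible(NULL))
  }
  if (sub == "report") {
    fp <- file.path(out, "fisher.csv")
    if (!file.exists(fp)) stop("missing file 'fisher.csv'; run multivariate")
    f <- utils::read.csv(fp)
    wide <- stats::reshape(f[, c("segment", "configuration", "X")],
                           idvar = "configuration", timevar = "segment",
                           direction = "wide")
    print(wide, row.names = FALSE)
    return(invisible(NULL))
  }
}
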
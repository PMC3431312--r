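#' Pipeline run configuration
#'
#' A plain named list describing one end-to-end run: mode
#' (\code{"simulate"} or \code{"tsv"}), input path (tsv mode), output
#' directory, master seed, normalization policy (\code{"auto"}: normalize
#' only raw inputs; \code{"yes"}; \code{"no"}), the chase design block, the
#' simulation block (simulate mode) and the threshold block. Serialized as
#' YAML; \code{readRunConfig} / \code{writeRunConfig} round-trip it
#' losslessly.
#'
#' @param seed master seed.
#' @return a named list with class \code{"RunConfig"}.
#' @export
defaultRunConfig <- function(seed = 1L) {
  structure(list(
    mode = "simulate",
    input = NULL,
    outdir = NULL,
    seed = as.integer(seed),
    normalize = "auto",
    design = list(
      time_points = c(0, 10, 50, 110, 230),
      n_replicates = 3L,
      conditions = c("CTRL", "KD"),
      actd_pretreat = 30
    ),
    sim = list(
      n_transcripts = 1389L,
      thalf_log_median = 120,
      thalf_log_sigma = 0.6,
      synth_log_median = 1,
      synth_log_sigma = 0.8,
      frac_stabilized = 40 / 1389,
      frac_destabilized = 24 / 1389,
      stabilization_fc_min = 1.19,
      stabilization_fc_max = 2.35,
      buffering_beta = 1.3,
      noise_cv = 0.15,
      background_level = 1
    ),
    thresholds = list(
      alpha_fit = 0.05,
      alpha_diff = 0.05,
      abundance_threshold = 1.5,
      detection_alpha = 0.05,
      min_detected = 2L
    ),
    premrna = list(enabled = TRUE, n_replicates = 3L, noise_cv = 0.1)
  ), class = "RunConfig")
}

#' @rdname defaultRunConfig
#' @param path YAML file path.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "RunConfig")
}

#' @rdname defaultRunConfig
#' @param config a RunConfig list.
#' @export
writeRunConfig <- function(config, path) {
  cfg <- unclass(config)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  writeLines(yaml::as.yaml(cfg, precision = 15), path)
  invisible(path)
}

.designFromConfig <- function(config) {
  d <- config$design
  ChaseDesign(timePoints = unlist(d$time_points),
              nReplicates = d$n_replicates,
              conditions = unlist(d$conditions),
              actdPretreat = d$actd_pretreat)
}

.simConfigFromConfig <- function(config) {
  s <- config$sim
  SimConfig(nTranscripts = s$n_transcripts,
            thalfLogMedian = s$thalf_log_median,
            thalfLogSigma = s$thalf_log_sigma,
            synthLogMedian = s$synth_log_median,
            synthLogSigma = s$synth_log_sigma,
            fracStabilized = s$frac_stabilized,
            fracDestabilized = s$frac_destabilized,
            stabilizationFcRange = c(s$stabilization_fc_min,
                                     s$stabilization_fc_max),
            bufferingBeta = s$buffering_beta,
            noiseCv = s$noise_cv,
            backgroundLevel = s$background_level,
            seed = config$seed)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full chase-decay pipeline
#'
#' Executes the stages in order -- obtain the expression matrix (simulate or
#' read TSV), normalize (policy-dependent), detection-filter, fit decay per
#' replicate, summarize with the replicate rule, compare half-lives between
#' conditions, estimate time-0 abundances and the decay-transcription
#' coupling, and (simulate mode) run the pre-mRNA consistency check -- and
#' collects per-stage censuses into a machine-readable run log. Warnings
#' raised by stages are recorded in the log. With an output directory the
#' result tables are written as TSV plus a JSON run log; a fixed seed yields
#' byte-identical outputs across runs.
#'
#' @param config a RunConfig list (see \code{\link{defaultRunConfig}}).
#' @param outdir output directory (default \code{config$outdir}; NULL =
#'   do not write).
#' @return a result bundle: list with experiment, truth, fits, summary,
#'   comparisons, tables, abundance, coupling, premrna, log.
#' @export
runPipeline <- function(config = defaultRunConfig(), outdir = config$outdir) {
  design <- .designFromConfig(config)
  th <- config$thresholds
  log <- list(seed = config$seed,
              package_version = as.character(utils::packageVersion("ChaseDecay")),
              r_version = as.character(getRversion()),
              mode = config$mode, censuses = list(), warnings = character())
  wlog <- function(expr) withCallingHandlers(expr, warning = function(w) {
    log$warnings <<- c(log$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  truth <- NULL
  if (identical(config$mode, "simulate")) {
    simcfg <- .simConfigFromConfig(config)
    truth <- .stage("simulate", generateTruth(simcfg, design))
    x <- .stage("simulate", simulateChase(truth, design, simcfg))
  } else {
    if (is.null(config$input)) stop("tsv mode requires config$input")
    log$input_md5 <- unname(tools::md5sum(config$input))
    x <- .stage("read", readExpressionTsv(config$input, design = design))
  }
  log$censuses$input <- list(n_transcripts = nrow(x), n_arrays = ncol(x))

  doNorm <- switch(config$normalize %||% "auto",
                   auto = identical(provenance(x), "raw"),
                   yes = TRUE, no = FALSE,
                   stop("normalize must be 'auto', 'yes' or 'no'"))
  if (doNorm) {
    x <- .stage("normalize", medianScale(x))
    x <- .stage("normalize", percentileFloorScale(x))
    log$censuses$normalized <- TRUE
  } else log$censuses$normalized <- FALSE

  if (!is.null(detectionP(x))) {
    x <- .stage("detection_filter",
                detectionFilter(x, alpha = th$detection_alpha,
                                minDetected = th$min_detected))
    log$censuses$detection <- S4Vectors::metadata(x)$census$detection
  }

  fits <- .stage("fit", wlog(fitAll(x, alpha = th$alpha_fit)))
  log$censuses$reliability <- attr(fits, "census")
  summary <- .stage("fit", summarizeStability(fits))

  comparisons <- .stage("diff", wlog(
    compareHalfLives(fits, conditions = conditionLabels(design),
                     alpha = th$alpha_diff)))
  abundance <- .stage("couple", abundanceAtT0(x, conditionLabels(design)))
  tables <- .stage("diff", stabilityTable(comparisons, abundance,
                                          alpha = th$alpha_diff))
  log$censuses$differential <- tables$counts

  coupling <- .stage("couple",
                     couplingScatter(comparisons, abundance,
                                     alpha = th$alpha_diff,
                                     censusThreshold = th$abundance_threshold))
  log$censuses$abundance <- couplingCensus(coupling)
  log$censuses$coupling_correlation <- couplingCorrelation(coupling)

  premrna <- NULL
  if (!is.null(truth) && isTRUE(config$premrna$enabled)) {
    pre <- .stage("premrna",
                  simulatePreMrna(truth,
                                  nReplicates = config$premrna$n_replicates,
                                  noiseCv = config$premrna$noise_cv))
    premrna <- .stage("premrna", premrnaConsistency(pre, coupling,
                                                    alpha = th$alpha_diff))
  }

  bundle <- list(experiment = x, truth = truth, fits = fits,
                 summary = summary, comparisons = comparisons,
                 tables = tables, abundance = abundance,
                 coupling = coupling, premrna = premrna, log = log)
  if (!is.null(outdir)) writeTables(bundle, outdir)
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a pipeline result bundle to a directory
#'
#' Emits expression.tsv, truth.tsv (simulate mode), fits.tsv, summary.tsv,
#' all_comparisons.tsv, stabilized.tsv, destabilized.tsv, abundance.tsv,
#' coupling.tsv, premrna.tsv (when present) and run_log.json.
#'
#' @param bundle result of \code{\link{runPipeline}}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeTables <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  writeExpressionTsv(bundle$experiment, file.path(dir, "expression.tsv"))
  if (!is.null(bundle$truth))
    writeTruthTsv(bundle$truth, file.path(dir, "truth.tsv"))
  wt(bundle$fits, "fits.tsv")
  wt(bundle$summary, "summary.tsv")
  wt(bundle$comparisons, "all_comparisons.tsv")
  wt(bundle$tables$stabilized, "stabilized.tsv")
  wt(bundle$tables$destabilized, "destabilized.tsv")
  wt(bundle$abundance, "abundance.tsv")
  wt(couplingTable(bundle$coupling), "coupling.tsv")
  if (!is.null(bundle$premrna)) wt(bundle$premrna, "premrna.tsv")
  jsonlite::write_json(bundle$log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}
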
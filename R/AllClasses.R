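#' @import methods
#' @importFrom S4Vectors metadata DataFrame SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Chase time-course design
#'
#' Layout of a transcription-shutoff (actinomycin D) chase experiment: the
#' time points at which RNA was sampled (minutes from the start of the chase,
#' i.e. from the end of the Act-D pretreatment), the number of replicate time
#' courses, the two condition labels (reference first, perturbed second), and
#' the length of the Act-D pretreatment, recorded as metadata only.
#'
#' @slot timePoints numeric, strictly increasing, starting at 0 (minutes).
#' @slot nReplicates integer, at least 2 (the reliability rule needs >= 2).
#' @slot conditions character of length 2: c(reference, perturbed).
#' @slot actdPretreat numeric, minutes of Act-D treatment before time 0.
#' @export
setClass("ChaseDesign",
  slots = c(
    timePoints = "numeric",
    nReplicates = "integer",
    conditions = "character",
    actdPretreat = "numeric"
  )
)

setValidity("ChaseDesign", function(object) {
  tp <- object@timePoints
  msg <- character()
  if (length(tp) < 3) msg <- c(msg, "need at least 3 time points")
  if (length(tp) && tp[1] != 0) msg <- c(msg, "first time point must be 0")
  if (any(diff(tp) <= 0)) msg <- c(msg, "time points must be strictly increasing")
  if (length(object@nReplicates) != 1 || object@nReplicates < 2L)
    msg <- c(msg, "nReplicates must be a single integer >= 2")
  if (length(object@conditions) != 2 || anyDuplicated(object@conditions))
    msg <- c(msg, "conditions must be two distinct labels (reference, perturbed)")
  if (length(object@actdPretreat) != 1 || object@actdPretreat < 0)
    msg <- c(msg, "actdPretreat must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Simulation configuration
#'
#' Parameters of the synthetic transcriptome generator. Reference half-lives
#' and synthesis rates are drawn from log-normal distributions; a fraction of
#' transcripts is stabilized (half-life multiplied by a factor drawn uniformly
#' from \code{stabilizationFcRange}) or destabilized (reciprocal factor) in
#' the perturbed condition. The buffering exponent couples synthesis-rate
#' changes inversely to half-life changes: perturbed synthesis = reference
#' synthesis x multiplier^(-beta), so beta = 0 means no coupling, beta = 1
#' perfect abundance buffering, beta > 1 overshoot (stabilized transcripts
#' lose abundance).
#'
#' @slot nTranscripts integer, number of transcripts.
#' @slot thalfLogMedian numeric, median half-life in minutes.
#' @slot thalfLogSigma numeric, log-normal sigma of half-lives (natural log).
#' @slot synthLogMedian numeric, median synthesis rate, arbitrary units/min.
#' @slot synthLogSigma numeric, log-normal sigma of synthesis rates.
#' @slot fracStabilized numeric in [0,1].
#' @slot fracDestabilized numeric in [0,1]; sum with fracStabilized <= 1.
#' @slot stabilizationFcRange numeric(2), (min, max) half-life fold change,
#'   min >= 1.
#' @slot bufferingBeta numeric >= 0, transcription-buffering exponent.
#' @slot noiseCv numeric >= 0, coefficient of variation of the multiplicative
#'   log-normal measurement noise.
#' @slot backgroundLevel numeric >= 0, additive background intensity floor.
#' @slot seed integer, master seed; all stochastic draws flow from it.
#' @export
setClass("SimConfig",
  slots = c(
    nTranscripts = "integer",
    thalfLogMedian = "numeric",
    thalfLogSigma = "numeric",
    synthLogMedian = "numeric",
    synthLogSigma = "numeric",
    fracStabilized = "numeric",
    fracDestabilized = "numeric",
    stabilizationFcRange = "numeric",
    bufferingBeta = "numeric",
    noiseCv = "numeric",
    backgroundLevel = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  one <- function(x) length(x) == 1 && is.finite(x)
  if (length(object@nTranscripts) != 1 || object@nTranscripts < 1L)
    msg <- c(msg, "nTranscripts must be a positive integer")
  if (!one(object@thalfLogMedian) || object@thalfLogMedian <= 0)
    msg <- c(msg, "thalfLogMedian must be positive")
  if (!one(object@synthLogMedian) || object@synthLogMedian <= 0)
    msg <- c(msg, "synthLogMedian must be positive")
  if (!one(object@thalfLogSigma) || object@thalfLogSigma < 0)
    msg <- c(msg, "thalfLogSigma must be >= 0")
  if (!one(object@synthLogSigma) || object@synthLogSigma < 0)
    msg <- c(msg, "synthLogSigma must be >= 0")
  fs <- object@fracStabilized; fd <- object@fracDestabilized
  if (!one(fs) || fs < 0 || fs > 1) msg <- c(msg, "fracStabilized must be in [0,1]")
  if (!one(fd) || fd < 0 || fd > 1) msg <- c(msg, "fracDestabilized must be in [0,1]")
  if (one(fs) && one(fd) && fs + fd > 1)
    msg <- c(msg, "fracStabilized + fracDestabilized must be <= 1")
  r <- object@stabilizationFcRange
  if (length(r) != 2 || any(!is.finite(r)) || r[1] < 1 || r[2] < r[1])
    msg <- c(msg, "stabilizationFcRange must be (min, max) with min >= 1 and max >= min")
  if (!one(object@bufferingBeta) || object@bufferingBeta < 0)
    msg <- c(msg, "bufferingBeta must be >= 0")
  if (!one(object@noiseCv) || object@noiseCv < 0)
    msg <- c(msg, "noiseCv must be >= 0")
  if (!one(object@backgroundLevel) || object@backgroundLevel < 0)
    msg <- c(msg, "backgroundLevel must be >= 0")
  if (length(object@seed) != 1 || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic transcriptome
#'
#' Per transcript and condition: true half-life (minutes), true synthesis
#' rate (arbitrary units/min), the implied steady-state abundance
#' A = s * t1/2 / ln(2), the class label (stabilized/destabilized/unchanged)
#' and the half-life multiplier applied in the perturbed condition.
#'
#' @slot table data.frame with columns transcript_id, condition, true_thalf,
#'   true_synthesis, true_steady_state, class_label, thalf_multiplier.
#' @slot config the \linkS4class{SimConfig} used.
#' @slot design the \linkS4class{ChaseDesign} used.
#' @export
setClass("SyntheticTruth",
  slots = c(table = "data.frame", config = "SimConfig", design = "ChaseDesign")
)

setValidity("SyntheticTruth", function(object) {
  tb <- object@table
  need <- c("transcript_id", "condition", "true_thalf", "true_synthesis",
            "true_steady_state", "class_label", "thalf_multiplier")
  if (!all(need %in% names(tb)))
    return(paste("truth table must have columns:", paste(need, collapse = ", ")))
  a <- tb$true_synthesis * tb$true_thalf / log(2)
  if (any(abs(a - tb$true_steady_state) > 1e-8 * pmax(a, 1e-300)))
    return("steady state must equal synthesis * thalf / ln(2)")
  if (!all(tb$class_label %in% c("stabilized", "destabilized", "unchanged")))
    return("invalid class_label")
  TRUE
})

#' Chase expression matrix
#'
#' A \linkS4class{SummarizedExperiment} holding transcript intensities over a
#' chase time course. Columns are arrays, one per (condition, replicate,
#' time); \code{colData} carries \code{condition}, \code{replicate} and
#' \code{time_min}. Assay \code{"intensity"} holds non-negative intensities;
#' the optional assay \code{"detection_p"} holds detection p-values for the
#' time-0 arrays (NA elsewhere). \code{metadata()} carries the
#' \linkS4class{ChaseDesign} under \code{design} and a provenance flag
#' (\code{"raw"} or \code{"normalized"}) under \code{provenance}.
#'
#' @export
setClass("ChaseExperiment", contains = "SummarizedExperiment")

setValidity("ChaseExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  msg <- character()
  need <- c("condition", "replicate", "time_min")
  if (!all(need %in% names(cd)))
    return(paste("colData must have columns:", paste(need, collapse = ", ")))
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    return("assay 'intensity' is required")
  key <- paste(cd$condition, cd$replicate, cd$time_min)
  if (anyDuplicated(key))
    msg <- c(msg, "duplicate (condition, replicate, time) arrays")
  grid <- with(as.data.frame(cd), table(condition, replicate))
  if (length(unique(grid[grid > 0])) > 1)
    msg <- c(msg, "incomplete design: unequal numbers of arrays per (condition, replicate)")
  x <- SummarizedExperiment::assay(object, "intensity")
  if (any(is.finite(x) & x < 0)) msg <- c(msg, "intensities must be non-negative")
  if ("detection_p" %in% SummarizedExperiment::assayNames(object)) {
    p <- SummarizedExperiment::assay(object, "detection_p")
    if (any(p < 0 | p > 1, na.rm = TRUE)) msg <- c(msg, "detection_p must be in [0,1]")
  }
  prov <- S4Vectors::metadata(object)$provenance
  if (is.null(prov) || !prov %in% c("raw", "normalized"))
    msg <- c(msg, "metadata()$provenance must be 'raw' or 'normalized'")
  if (length(msg)) msg else TRUE
})

#' First-order decay fit for one replicate time series
#'
#' Result of fitting y(t) = y0 * exp(-k t) by nonlinear least squares in
#' linear intensity space with k constrained >= 0. A non-decaying series sits
#' at the k = 0 boundary with an infinite half-life. The fit p-value is a
#' one-sided Wald test of decay (H0: k = 0; statistic k/se_k on a t
#' distribution with n - 2 df); the 95% half-life confidence interval is the
#' Wald interval on k inverted through t1/2 = ln(2)/k.
#'
#' @slot y0 fitted abundance at t = 0 (intensity units).
#' @slot k decay rate per minute (>= 0).
#' @slot tHalf half-life in minutes, ln(2)/k; Inf at the k = 0 boundary.
#' @slot seK standard error of k (NA at the boundary).
#' @slot ci95Thalf numeric(2), (low, high) half-life bounds in minutes.
#' @slot fitP one-sided p-value for decay.
#' @slot converged logical.
#' @slot nPoints integer, number of points used.
#' @slot residualSS residual sum of squares.
#' @export
setClass("DecayFit",
  slots = c(
    y0 = "numeric", k = "numeric", tHalf = "numeric", seK = "numeric",
    ci95Thalf = "numeric", fitP = "numeric", converged = "logical",
    nPoints = "integer", residualSS = "numeric"
  )
)

setValidity("DecayFit", function(object) {
  msg <- character()
  if (object@k > 0 && is.finite(object@tHalf) &&
      abs(object@tHalf - log(2) / object@k) > 1e-8 * object@tHalf)
    msg <- c(msg, "tHalf must equal ln(2)/k")
  if (!is.na(object@fitP) && (object@fitP < 0 || object@fitP > 1))
    msg <- c(msg, "fitP must be in [0,1]")
  if (length(object@ci95Thalf) != 2) msg <- c(msg, "ci95Thalf must have length 2")
  if (length(msg)) msg else TRUE
})

#' Decay-transcription coupling result
#'
#' Per-transcript half-life, abundance and inferred synthesis fold changes,
#' the cohort rank correlation between log half-life fold change and log
#' abundance fold change over transcripts with a significant stability
#' change, and the >= threshold-fold abundance-change census.
#'
#' @slot table data.frame, one row per transcript.
#' @slot correlation list with elements rho, p, n, method (rho/p NA when
#'   fewer than 3 significant transcripts or degenerate fold changes).
#' @slot census list: threshold, n_total, n_affected, n_up, n_down,
#'   down_fraction.
#' @export
setClass("CouplingResult",
  slots = c(table = "data.frame", correlation = "list", census = "list")
)
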
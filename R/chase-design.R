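#' Construct a chase design
#'
#' The default is the study design used throughout: samples collected at 0,
#' 10, 50, 110 and 230 minutes after transcription inhibition, three
#' replicate time courses, two conditions, and a 30-minute Act-D pretreatment
#' before time 0. Decay is modelled from the recorded time points; the
#' pretreatment length is metadata only (the offset cancels in first-order
#' half-life estimation).
#'
#' @param timePoints numeric vector of sampling times in minutes, strictly
#'   increasing, starting at 0.
#' @param nReplicates number of replicate time courses (>= 2).
#' @param conditions character(2): reference and perturbed condition labels.
#' @param actdPretreat minutes of actinomycin D treatment before time 0.
#' @return a \linkS4class{ChaseDesign}.
#' @examples
#' ChaseDesign()
#' @export
ChaseDesign <- function(timePoints = c(0, 10, 50, 110, 230),
                        nReplicates = 3,
                        conditions = c("CTRL", "KD"),
                        actdPretreat = 30) {
  new("ChaseDesign",
      timePoints = as.numeric(timePoints),
      nReplicates = as.integer(nReplicates),
      conditions = as.character(conditions),
      actdPretreat = as.numeric(actdPretreat))
}

#' @rdname ChaseDesign
#' @export
setMethod("timePoints", "ChaseDesign", function(x) x@timePoints)

#' @rdname ChaseDesign
#' @export
setMethod("nReplicates", "ChaseDesign", function(x) x@nReplicates)

#' @rdname ChaseDesign
#' @export
setMethod("conditionLabels", "ChaseDesign", function(x) x@conditions)

#' @rdname ChaseDesign
#' @export
setMethod("actdPretreat", "ChaseDesign", function(x) x@actdPretreat)

setMethod("show", "ChaseDesign", function(object) {
  cat("ChaseDesign\n")
  cat("  time points (min):", paste(object@timePoints, collapse = ", "), "\n")
  cat("  replicates:", object@nReplicates, "\n")
  cat("  conditions:", object@conditions[1], "(reference) vs",
      object@conditions[2], "(perturbed)\n")
  cat("  Act-D pretreatment:", object@actdPretreat, "min\n")
})

#' Construct a simulation configuration
#'
#' Defaults emulate the study conditions: 1389 transcripts (the matched set
#' with half-lives in both conditions), 40/1389 stabilized and 24/1389
#' destabilized, half-life fold changes uniform on (1.19, 2.35) as observed
#' for the stabilized set, log-normal reference half-lives with median 120
#' min and sigma 0.6 (most transcripts in the 50-400 min range), buffering
#' exponent 1.3 (slight overshoot: stabilized transcripts tend to lose
#' abundance), 15% multiplicative measurement noise and a small additive
#' background floor (about 0.5% of the median steady-state signal).
#'
#' @param nTranscripts number of transcripts.
#' @param thalfLogMedian median reference half-life, minutes.
#' @param thalfLogSigma log-normal sigma of half-lives (natural-log scale).
#' @param synthLogMedian median synthesis rate, arbitrary units per minute.
#' @param synthLogSigma log-normal sigma of synthesis rates.
#' @param fracStabilized fraction of transcripts stabilized in the perturbed
#'   condition.
#' @param fracDestabilized fraction destabilized.
#' @param stabilizationFcRange numeric(2), (min, max) half-life fold change
#'   for affected transcripts; min >= 1.
#' @param bufferingBeta buffering exponent: perturbed synthesis = reference
#'   synthesis x (half-life multiplier)^(-beta).
#' @param noiseCv coefficient of variation of the multiplicative log-normal
#'   measurement noise (0 = noiseless).
#' @param backgroundLevel additive background intensity floor.
#' @param seed master seed for all stochastic draws.
#' @return a \linkS4class{SimConfig}.
#' @examples
#' SimConfig(nTranscripts = 100, noiseCv = 0, backgroundLevel = 0, seed = 1)
#' @export
SimConfig <- function(nTranscripts = 1389,
                      thalfLogMedian = 120,
                      thalfLogSigma = 0.6,
                      synthLogMedian = 1,
                      synthLogSigma = 0.8,
                      fracStabilized = 40 / 1389,
                      fracDestabilized = 24 / 1389,
                      stabilizationFcRange = c(1.19, 2.35),
                      bufferingBeta = 1.3,
                      noiseCv = 0.15,
                      backgroundLevel = 1,
                      seed = 1L) {
  new("SimConfig",
      nTranscripts = as.integer(nTranscripts),
      thalfLogMedian = as.numeric(thalfLogMedian),
      thalfLogSigma = as.numeric(thalfLogSigma),
      synthLogMedian = as.numeric(synthLogMedian),
      synthLogSigma = as.numeric(synthLogSigma),
      fracStabilized = as.numeric(fracStabilized),
      fracDestabilized = as.numeric(fracDestabilized),
      stabilizationFcRange = as.numeric(stabilizationFcRange),
      bufferingBeta = as.numeric(bufferingBeta),
      noiseCv = as.numeric(noiseCv),
      backgroundLevel = as.numeric(backgroundLevel),
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nTranscripts, "transcripts\n")
  cat(sprintf("  t1/2 ~ logN(median %g min, sigma %g); synthesis ~ logN(median %g, sigma %g)\n",
              object@thalfLogMedian, object@thalfLogSigma,
              object@synthLogMedian, object@synthLogSigma))
  cat(sprintf("  stabilized %.3f / destabilized %.3f, fc range (%g, %g)\n",
              object@fracStabilized, object@fracDestabilized,
              object@stabilizationFcRange[1], object@stabilizationFcRange[2]))
  cat(sprintf("  buffering beta %g, noise CV %g, background %g, seed %d\n",
              object@bufferingBeta, object@noiseCv, object@backgroundLevel,
              object@seed))
})

#' @rdname SyntheticTruth
#' @param x a \code{SyntheticTruth}.
#' @export
setMethod("truthTable", "SyntheticTruth", function(x) x@table)

setMethod("show", "SyntheticTruth", function(object) {
  tb <- object@table
  n <- length(unique(tb$transcript_id))
  cls <- table(tb$class_label[tb$condition == object@design@conditions[2]])
  cat("SyntheticTruth:", n, "transcripts x 2 conditions\n")
  cat("  classes (perturbed):",
      paste(names(cls), as.integer(cls), collapse = ", "), "\n")
  cat("  seed:", object@config@seed, " beta:", object@config@bufferingBeta, "\n")
})
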
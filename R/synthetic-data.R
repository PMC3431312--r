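#' @importFrom stats rlnorm runif rnorm plnorm median quantile qt pt sd
#'   p.adjust cor.test setNames lm.fit t.test ave optimize
#' @importFrom utils read.delim write.table
NULL

# log-normal multiplicative noise with mean 1 and coefficient of variation cv
.rlnormCv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

# detection-above-background surrogate: upper-tail probability of an
# intensity under a log-normal background distribution with mean `bg`
# (fixed sdlog 0.5). bg <= 0 degenerates: any positive signal detects.
.detectionP <- function(x, bg, sdlog = 0.5) {
  if (bg <= 0) return(ifelse(x > 0, 0, 1))
  plnorm(x, meanlog = log(bg) - sdlog^2 / 2, sdlog = sdlog,
         lower.tail = FALSE)
}

#' Generate the ground truth of a synthetic transcriptome
#'
#' Draws per-transcript reference half-lives and synthesis rates from
#' log-normal distributions, assigns a fraction of transcripts a perturbed
#' half-life multiplier drawn uniformly from \code{stabilizationFcRange}
#' (reciprocal for destabilized transcripts), couples perturbed synthesis
#' rates to the multiplier through the buffering exponent
#' (synthesis x multiplier^(-beta)), and records steady-state abundances
#' A = s * t1/2 / ln(2). Deterministic given \code{config@seed}; the stream
#' order is: half-lives, synthesis rates, affected-transcript sample,
#' stabilization multipliers, destabilization multipliers.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param design a \linkS4class{ChaseDesign}.
#' @return a \linkS4class{SyntheticTruth}.
#' @examples
#' tr <- generateTruth(SimConfig(nTranscripts = 50, seed = 7), ChaseDesign())
#' head(truthTable(tr))
#' @export
generateTruth <- function(config, design = ChaseDesign()) {
  validObject(config); validObject(design)
  n <- config@nTranscripts
  conds <- design@conditions
  withr::with_seed(config@seed, {
    thalf <- rlnorm(n, log(config@thalfLogMedian), config@thalfLogSigma)
    synth <- rlnorm(n, log(config@synthLogMedian), config@synthLogSigma)
    nStab <- round(config@fracStabilized * n)
    nDest <- round(config@fracDestabilized * n)
    affected <- sample.int(n, nStab + nDest)
    mult <- rep(1, n)
    if (nStab > 0)
      mult[affected[seq_len(nStab)]] <-
        runif(nStab, config@stabilizationFcRange[1],
              config@stabilizationFcRange[2])
    if (nDest > 0)
      mult[affected[nStab + seq_len(nDest)]] <-
        1 / runif(nDest, config@stabilizationFcRange[1],
                  config@stabilizationFcRange[2])
  })
  cls <- ifelse(mult > 1, "stabilized", ifelse(mult < 1, "destabilized",
                                               "unchanged"))
  ids <- sprintf("T%05d", seq_len(n))
  ref <- data.frame(transcript_id = ids, condition = conds[1],
                    true_thalf = thalf, true_synthesis = synth,
                    class_label = cls, thalf_multiplier = 1,
                    stringsAsFactors = FALSE)
  kd <- data.frame(transcript_id = ids, condition = conds[2],
                   true_thalf = thalf * mult,
                   true_synthesis = synth * mult^(-config@bufferingBeta),
                   class_label = cls, thalf_multiplier = mult,
                   stringsAsFactors = FALSE)
  tb <- rbind(ref, kd)
  tb$true_steady_state <- tb$true_synthesis * tb$true_thalf / log(2)
  tb <- tb[c("transcript_id", "condition", "true_thalf", "true_synthesis",
             "true_steady_state", "class_label", "thalf_multiplier")]
  new("SyntheticTruth", table = tb, config = config, design = design)
}

#' Simulate a chase expression matrix
#'
#' Realizes the model the decay fitter assumes: measured intensity for
#' transcript i, condition c, replicate r at chase time t is
#' A(i,c) * exp(-ln(2) t / t1/2(i,c)) * eps + background, with eps
#' log-normal, mean 1 and coefficient of variation \code{noiseCv},
#' independent across observations. Time 0 is the end of the Act-D
#' pretreatment; decay is simulated only over the recorded time points.
#' A detection p-value is emitted for every time-0 array as the upper-tail
#' probability of the measured intensity under the background distribution
#' (so low-signal transcripts fail detection). Deterministic given the
#' config seed (this stage uses seed + 1).
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param design a \linkS4class{ChaseDesign}; defaults to the one in
#'   \code{truth}.
#' @param config a \linkS4class{SimConfig}; defaults to the one in
#'   \code{truth}.
#' @return a \linkS4class{ChaseExperiment} with provenance
#'   \code{"normalized"} (the generator emits background-corrected data on a
#'   common scale, as if array-normalized).
#' @export
simulateChase <- function(truth, design = truth@design, config = truth@config) {
  tb <- truth@table
  conds <- design@conditions
  times <- design@timePoints
  reps <- seq_len(design@nReplicates)
  ids <- unique(tb$transcript_id)
  n <- length(ids)

  cols <- expand.grid(time_min = times, replicate = reps, condition = conds,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cols <- cols[, c("condition", "replicate", "time_min")]
  nc <- nrow(cols)

  A <- matrix(NA_real_, n, 2, dimnames = list(ids, conds))
  TH <- A
  for (j in 1:2) {
    sub <- tb[tb$condition == conds[j], ]
    A[sub$transcript_id, j] <- sub$true_steady_state
    TH[sub$transcript_id, j] <- sub$true_thalf
  }

  withr::with_seed(config@seed + 1L, {
    eps <- matrix(.rlnormCv(n * nc, config@noiseCv), n, nc)
  })
  ci <- match(cols$condition, conds)
  signal <- A[, ci, drop = FALSE] *
    exp(-log(2) * rep(cols$time_min, each = n) / TH[, ci, drop = FALSE])
  intensity <- signal * eps + config@backgroundLevel

  detp <- matrix(NA_real_, n, nc)
  t0 <- which(cols$time_min == 0)
  detp[, t0] <- .detectionP(intensity[, t0, drop = FALSE],
                            config@backgroundLevel)

  ChaseExperiment(intensity, cols$condition, cols$replicate, cols$time_min,
                  detectionP = detp, design = design,
                  provenance = "normalized")
}

#' Simulate a qPCR Ct table for selected transcripts
#'
#' For each transcript, condition, replicate and time point the target Ct is
#' \code{c0 - log2(q(t)) + noise} where q(t) is the true abundance at chase
#' time t, and the reference-gene Ct comes from a constant reference quantity
#' (a stable housekeeping transcript). Gaussian noise in cycles.
#' Deterministic given the config seed (this stage uses seed + 2).
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param design a \linkS4class{ChaseDesign}.
#' @param transcripts character vector of transcript ids present in
#'   \code{truth}.
#' @param noiseSdCycles Gaussian Ct noise, in cycles.
#' @param c0 calibration constant mapping quantity 1 to this Ct.
#' @param refQuantity constant quantity of the reference gene.
#' @return data.frame with columns transcript_id, condition, replicate,
#'   time_min, ct_target, ct_reference.
#' @export
simulateQpcr <- function(truth, design = truth@design, transcripts,
                         noiseSdCycles = 0.2, c0 = 35, refQuantity = 100) {
  tb <- truth@table
  unknown <- setdiff(transcripts, tb$transcript_id)
  if (length(unknown))
    stop("unknown transcript id(s): ", paste(unknown, collapse = ", "))
  grid <- expand.grid(time_min = design@timePoints,
                      replicate = seq_len(design@nReplicates),
                      condition = design@conditions,
                      transcript_id = transcripts,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("transcript_id", "condition", "replicate", "time_min")]
  idx <- match(paste(grid$transcript_id, grid$condition),
               paste(tb$transcript_id, tb$condition))
  q <- tb$true_steady_state[idx] *
    exp(-log(2) * grid$time_min / tb$true_thalf[idx])
  withr::with_seed(truth@config@seed + 2L, {
    noiseT <- rnorm(nrow(grid), 0, noiseSdCycles)
    noiseR <- rnorm(nrow(grid), 0, noiseSdCycles)
  })
  grid$ct_target <- c0 - log2(q) + noiseT
  grid$ct_reference <- c0 - log2(refQuantity) + noiseR
  if (any(!is.finite(grid$ct_target) | grid$ct_target <= 0 |
          grid$ct_reference <= 0))
    stop("simulated Ct values are not finite and positive; adjust c0")
  grid
}

#' Simulate nascent pre-mRNA measurements
#'
#' Relative pre-mRNA quantity (nascent transcription, reference-RNA
#' normalized, as in a 4sU pulse assay) is proportional to the true synthesis
#' rate, with multiplicative log-normal noise; the proportionality constant
#' is common to both conditions, so condition ratios reflect synthesis-rate
#' ratios. Deterministic given the config seed (this stage uses seed + 3).
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param nReplicates replicates per condition.
#' @param noiseCv coefficient of variation of the measurement noise.
#' @param transcripts transcripts to measure (default: all).
#' @return data.frame with columns transcript_id, condition, replicate,
#'   relative_quantity.
#' @export
simulatePreMrna <- function(truth, nReplicates = 3, noiseCv = 0.1,
                            transcripts = NULL) {
  tb <- truth@table
  if (is.null(transcripts)) transcripts <- unique(tb$transcript_id)
  scale <- 1 / median(tb$true_synthesis[tb$condition ==
                                          truth@design@conditions[1]])
  grid <- expand.grid(replicate = seq_len(nReplicates),
                      condition = truth@design@conditions,
                      transcript_id = transcripts,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("transcript_id", "condition", "replicate")]
  idx <- match(paste(grid$transcript_id, grid$condition),
               paste(tb$transcript_id, tb$condition))
  withr::with_seed(truth@config@seed + 3L, {
    eps <- .rlnormCv(nrow(grid), noiseCv)
  })
  grid$relative_quantity <- scale * tb$true_synthesis[idx] * eps
  grid
}

#' Export a truth table as TSV (for parameter-recovery checks)
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param path output file.
#' @export
writeTruthTsv <- function(truth, path) {
  utils::write.table(truth@table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
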
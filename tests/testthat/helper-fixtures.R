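# Shared fixtures: hand-built truth objects and array matrices.

# Truth table with fully controlled half-lives, multipliers and synthesis
# rates (bypasses the random generator for closed-form checks).
manualTruth <- function(thalf, mult = rep(1, length(thalf)),
                        synth = rep(1, length(thalf)), beta = 1,
                        noiseCv = 0, background = 0, seed = 1L) {
  n <- length(thalf)
  cfg <- SimConfig(nTranscripts = n, bufferingBeta = beta, noiseCv = noiseCv,
                   backgroundLevel = background, seed = seed)
  ids <- sprintf("G%03d", seq_len(n))
  cls <- ifelse(mult > 1, "stabilized",
                ifelse(mult < 1, "destabilized", "unchanged"))
  mk <- function(cond, th, sy, mu) {
    data.frame(transcript_id = ids, condition = cond, true_thalf = th,
               true_synthesis = sy, true_steady_state = sy * th / log(2),
               class_label = cls, thalf_multiplier = mu,
               stringsAsFactors = FALSE)
  }
  tb <- rbind(mk("CTRL", thalf, synth, 1),
              mk("KD", thalf * mult, synth * mult^(-beta), mult))
  new("SyntheticTruth", table = tb, config = cfg, design = ChaseDesign())
}

# Minimal experiment from an explicit intensity matrix; columns are arrays.
arrayExperiment <- function(m, condition, replicate, time_min,
                            detectionP = NULL, provenance = "raw") {
  ChaseExperiment(m, condition, replicate, time_min,
                  detectionP = detectionP, provenance = provenance)
}

# Per-replicate fit rows sufficient for compareHalfLives/summarizeStability.
mkFits <- function(id, condition, thalfs, reliable = TRUE) {
  data.frame(transcript_id = id, condition = condition,
             replicate = seq_along(thalfs), t_half = thalfs,
             reliable = rep_len(reliable, length(thalfs)),
             stringsAsFactors = FALSE)
}

defaultTimes <- c(0, 10, 50, 110, 230)
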
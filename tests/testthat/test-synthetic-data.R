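test_that("generated truth satisfies the steady-state and buffering identities", {
  for (beta in c(0, 1, 1.3)) {
    cfg <- SimConfig(nTranscripts = 200, fracStabilized = 0.2,
                     fracDestabilized = 0.1, bufferingBeta = beta, seed = 42)
    tb <- truthTable(generateTruth(cfg))
    expect_equal(tb$true_steady_state,
                 tb$true_synthesis * tb$true_thalf / log(2))
    ref <- tb[tb$condition == "CTRL", ]
    kd <- tb[tb$condition == "KD", ]
    expect_identical(ref$transcript_id, kd$transcript_id)
    # log abundance ratio = (1 - beta) * log multiplier, exactly
    expect_equal(log(kd$true_steady_state / ref$true_steady_state),
                 (1 - beta) * log(kd$thalf_multiplier))
    expect_identical(kd$class_label,
                     ifelse(kd$thalf_multiplier > 1, "stabilized",
                            ifelse(kd$thalf_multiplier < 1, "destabilized",
                                   "unchanged")))
    if (beta == 1)  # perfect buffering: perturbed steady state unchanged
      expect_equal(kd$true_steady_state, ref$true_steady_state)
  }
})

test_that("planted class proportions match the configured fractions", {
  cfg <- SimConfig(seed = 3)  # defaults: 1389 transcripts, 40/1389, 24/1389
  kd <- truthTable(generateTruth(cfg))
  kd <- kd[kd$condition == "KD", ]
  expect_equal(sum(kd$class_label == "stabilized"), 40)
  expect_equal(sum(kd$class_label == "destabilized"), 24)
  expect_true(all(kd$thalf_multiplier[kd$class_label == "stabilized"] >= 1.19 &
                  kd$thalf_multiplier[kd$class_label == "stabilized"] <= 2.35))
})

test_that("generator is deterministic given the seed", {
  cfg <- SimConfig(nTranscripts = 50, seed = 9)
  t1 <- generateTruth(cfg); t2 <- generateTruth(cfg)
  expect_identical(serialize(truthTable(t1), NULL),
                   serialize(truthTable(t2), NULL))
  x1 <- simulateChase(t1); x2 <- simulateChase(t2)
  expect_identical(intensities(x1), intensities(x2))
  expect_identical(detectionP(x1), detectionP(x2))
  t3 <- generateTruth(SimConfig(nTranscripts = 50, seed = 10))
  expect_false(identical(truthTable(t1)$true_thalf, truthTable(t3)$true_thalf))
})

test_that("invalid configurations are rejected", {
  expect_error(SimConfig(fracStabilized = 0.7, fracDestabilized = 0.5),
               "<= 1")
  expect_error(SimConfig(thalfLogMedian = -5), "positive")
  expect_error(SimConfig(stabilizationFcRange = c(0.8, 2)), "min >= 1")
  expect_error(SimConfig(noiseCv = -0.1), ">= 0")
  expect_error(ChaseDesign(timePoints = c(10, 50, 110)), "must be 0")
  expect_error(ChaseDesign(nReplicates = 1), ">= 2")
})

test_that("noiseless chase intensities follow first-order decay exactly", {
  tr <- manualTruth(thalf = c(110, 55), synth = c(2, 3))
  x <- simulateChase(tr)
  cd <- SummarizedExperiment::colData(x)
  m <- intensities(x)
  A <- truthTable(tr)
  A0 <- A$true_steady_state[A$condition == "CTRL"]
  j0 <- which(cd$condition == "CTRL" & cd$replicate == 1 & cd$time_min == 0)
  j110 <- which(cd$condition == "CTRL" & cd$replicate == 1 & cd$time_min == 110)
  expect_equal(unname(m[, j0]), A0)
  # one half-life elapsed for the t1/2 = 110 transcript; two for t1/2 = 55
  expect_equal(unname(m[1, j110]), A0[1] / 2)
  expect_equal(unname(m[2, j110]), A0[2] / 4)
})

test_that("measurement noise is multiplicative with the configured CV and mean 1", {
  cfg <- SimConfig(nTranscripts = 10000, thalfLogSigma = 0, synthLogSigma = 0,
                   fracStabilized = 0, fracDestabilized = 0, noiseCv = 0.15,
                   backgroundLevel = 0, seed = 21)
  tr <- generateTruth(cfg)
  x <- simulateChase(tr)
  cd <- SummarizedExperiment::colData(x)
  m <- intensities(x)
  expected <- truthTable(tr)$true_steady_state[1] * 2^(-50 / 120)
  j <- which(cd$condition == "CTRL" & cd$time_min == 50)  # 30,000 draws
  ratio <- as.vector(m[, j]) / expected
  expect_lt(abs(mean(ratio) - 1), 0.01)
  expect_lt(abs(sd(ratio) / mean(ratio) - 0.15), 0.01)
})

test_that("detection p-values fall with signal strength and stay in [0,1]", {
  tr <- manualTruth(thalf = c(100, 100), synth = c(0.05, 50),
                    background = 5)
  x <- simulateChase(tr)
  p <- detectionP(x)
  cd <- SummarizedExperiment::colData(x)
  p0 <- p[, cd$time_min == 0]
  expect_true(all(p0 >= 0 & p0 <= 1))
  expect_true(all(p0[1, ] > p0[2, ]))  # weak signal -> larger p
  # zero background: any positive signal is detected
  x0 <- simulateChase(manualTruth(thalf = 100, synth = 1, background = 0))
  expect_true(all(detectionP(x0)[, cd$time_min == 0] == 0))
})

test_that("simulated Ct tables encode quantities on the log2 scale", {
  tr <- manualTruth(thalf = 50, synth = 4)
  ct <- simulateQpcr(tr, transcripts = "G001", noiseSdCycles = 0)
  sub <- ct[ct$condition == "CTRL" & ct$replicate == 1, ]
  # quantity halves over one half-life: Ct rises by exactly one cycle
  expect_equal(sub$ct_target[sub$time_min == 50] -
                 sub$ct_target[sub$time_min == 0], 1)
  # stable reference gene: constant reference Ct
  expect_equal(length(unique(sub$ct_reference)), 1L)
  expect_error(simulateQpcr(tr, transcripts = "nope"), "unknown transcript")
})

test_that("Ct noise has the configured standard deviation", {
  tr <- manualTruth(thalf = rep(100, 40), synth = rep(4, 40))
  ct <- simulateQpcr(tr, transcripts = sprintf("G%03d", 1:40),
                     noiseSdCycles = 0.2)
  # reference quantity is constant, so sd(ct_reference) estimates the noise
  expect_gt(nrow(ct), 1000)
  expect_lt(abs(sd(ct$ct_reference) - 0.2), 0.02)
})

test_that("pre-mRNA ratios track synthesis through the buffering exponent", {
  for (case in list(c(beta = 1, expect = 0.5),
                    c(beta = 0, expect = 1),
                    c(beta = 1.3, expect = 2^(-1.3)))) {
    tr <- manualTruth(thalf = 100, mult = 2, synth = 1, beta = case["beta"])
    pre <- simulatePreMrna(tr, noiseCv = 0)
    ratio <- mean(pre$relative_quantity[pre$condition == "KD"]) /
      mean(pre$relative_quantity[pre$condition == "CTRL"])
    expect_equal(unname(ratio), unname(case["expect"]), tolerance = 1e-12)
  }
})
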
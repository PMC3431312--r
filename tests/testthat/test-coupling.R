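noiselessRun <- function(beta, seed = 6, n = 120, fracStab = 0.25,
                         fracDest = 0.1) {
  cfg <- SimConfig(nTranscripts = n, fracStabilized = fracStab,
                   fracDestabilized = fracDest, bufferingBeta = beta,
                   noiseCv = 0, backgroundLevel = 0, seed = seed)
  tr <- generateTruth(cfg)
  x <- simulateChase(tr)
  fits <- suppressWarnings(fitAll(x))
  cmp <- suppressWarnings(compareHalfLives(fits, c("CTRL", "KD")))
  list(truth = tr, x = x, cmp = cmp, ab = abundanceAtT0(x))
}

test_that("perfect buffering leaves every time-0 abundance unchanged", {
  r <- noiselessRun(beta = 1)
  expect_equal(r$ab$fc_abundance, rep(1, nrow(r$ab)), tolerance = 1e-9)
})

test_that("without coupling the abundance change equals the half-life change", {
  r <- noiselessRun(beta = 0)
  tb <- truthTable(r$truth)
  mult <- tb$thalf_multiplier[tb$condition == "KD"]
  idx <- match(r$ab$transcript_id,
               tb$transcript_id[tb$condition == "KD"])
  expect_equal(r$ab$fc_abundance, mult[idx], tolerance = 1e-9)
})

test_that("the steady-state identity fc_A = fc_s * fc_thalf holds exactly", {
  r <- noiselessRun(beta = 1.3)
  cpl <- couplingScatter(r$cmp, r$ab)
  tab <- couplingTable(cpl)
  ok <- is.finite(tab$inferred_fc_synthesis)
  expect_gt(sum(ok), 50)
  expect_equal(tab$inferred_fc_synthesis[ok] * tab$fc_thalf[ok],
               tab$fc_abundance[ok])
})

test_that("the abundance census counts signed fold changes beyond a threshold", {
  ab <- data.frame(transcript_id = sprintf("t%03d", 1:250),
                   fc_abundance = c(rep(0.5, 100), rep(1, 150)),
                   signed_fc_abundance = c(rep(-2, 100), rep(1, 150)))
  cen <- abundanceCensus(ab, threshold = 1.5)
  expect_equal(cen$n_affected, 100)
  expect_equal(cen$n_down, 100)
  expect_equal(cen$down_fraction, 1)
  none <- abundanceCensus(ab[101:250, ], threshold = 1.5)
  expect_equal(none$n_affected, 0)
  expect_true(is.na(none$down_fraction))
  expect_error(abundanceCensus(ab, threshold = 0.8), ">= 1")
})

test_that("buffering overshoot drives affected transcripts down", {
  r <- noiselessRun(beta = 1.3)
  # with beta = 1.3, log fc_A = -0.3 log fc_thalf: stabilized transcripts
  # with large multipliers drop below a 1.1-fold threshold, all downward
  cpl <- couplingScatter(r$cmp, r$ab, censusThreshold = 1.1)
  cen <- couplingCensus(cpl)
  expect_gt(cen$n_affected, 0)
  expect_gt(cen$down_fraction, 0.5)
})

test_that("the coupling correlation has the generator-implied sign", {
  rNeg <- couplingScatter(noiselessRun(beta = 1.3)$cmp,
                          noiselessRun(beta = 1.3)$ab)
  expect_lt(couplingCorrelation(rNeg)$rho, 0)
  rPos <- couplingScatter(noiselessRun(beta = 0)$cmp,
                          noiselessRun(beta = 0)$ab)
  expect_gt(couplingCorrelation(rPos)$rho, 0)
  # no planted effects: no significant transcripts, correlation undefined
  rNull <- noiselessRun(beta = 1, fracStab = 0, fracDest = 0)
  cpl <- couplingScatter(rNull$cmp, rNull$ab)
  expect_true(is.na(couplingCorrelation(cpl)$rho))
})

test_that("synthesis-rate inference follows the steady-state balance", {
  expect_equal(inferSynthesisChange(1, 2), 0.5)
  expect_equal(inferSynthesisChange(2, 2), 1)
  # stabilized 2.35-fold with a -1.48 signed abundance change
  expect_equal(inferSynthesisChange(1 / 1.48, 2.35), 0.288,
               tolerance = 2e-3)
  expect_error(inferSynthesisChange(-1, 2), "positive")
  expect_error(inferSynthesisChange(1, 0), "positive")
})

test_that("pre-mRNA measurements corroborate inferred transcription changes", {
  # buffering: stabilized transcript, synthesis halved
  tr <- manualTruth(thalf = rep(100, 10), mult = c(2, rep(1, 9)),
                    synth = rep(1, 10), beta = 1, seed = 4)
  x <- simulateChase(tr)
  fits <- suppressWarnings(fitAll(x))
  cmp <- suppressWarnings(compareHalfLives(fits, c("CTRL", "KD")))
  cpl <- couplingScatter(cmp, abundanceAtT0(x))
  pre <- simulatePreMrna(tr, noiseCv = 0.02)
  pc <- premrnaConsistency(pre, cpl)
  stab <- pc[pc$transcript_id == "G001", ]
  expect_lt(stab$fc_premrna, 1)
  expect_lt(stab$premrna_p, 0.05)
  expect_identical(stab$agreement, "agree")
  # no coupling: pre-mRNA unchanged
  tr0 <- manualTruth(thalf = rep(100, 4), mult = c(2, 1, 1, 1),
                     synth = rep(1, 4), beta = 0, seed = 4)
  pre0 <- simulatePreMrna(tr0, noiseCv = 0)
  x0 <- simulateChase(tr0)
  fits0 <- suppressWarnings(fitAll(x0))
  cmp0 <- suppressWarnings(compareHalfLives(fits0, c("CTRL", "KD")))
  cpl0 <- couplingScatter(cmp0, abundanceAtT0(x0))
  pc0 <- premrnaConsistency(pre0, cpl0)
  expect_equal(pc0$fc_premrna, rep(1, 4))
  expect_identical(unique(pc0$agreement), "indeterminate")
})

test_that("measured pre-mRNA changes recover inferred synthesis changes with slope 1", {
  # both axes carry estimation error, so the slope is estimated by
  # geometric-mean regression (OLS would attenuate toward zero)
  slopes <- sapply(1:4, function(seed) {
    cfg <- SimConfig(nTranscripts = 300, fracStabilized = 0.3,
                     fracDestabilized = 0, noiseCv = 0.1,
                     backgroundLevel = 0, bufferingBeta = 1.3, seed = seed)
    tr <- generateTruth(cfg)
    x <- simulateChase(tr)
    fits <- suppressWarnings(fitAll(x))
    cmp <- suppressWarnings(compareHalfLives(fits, c("CTRL", "KD")))
    cpl <- couplingScatter(cmp, abundanceAtT0(x))
    pc <- premrnaConsistency(simulatePreMrna(tr, noiseCv = 0.1), cpl)
    tb <- truthTable(tr)
    stab <- unique(tb$transcript_id[tb$class_label == "stabilized"])
    j <- pc$transcript_id %in% stab & is.finite(pc$inferred_fc_synthesis)
    lx <- log(pc$inferred_fc_synthesis[j])
    ly <- log(pc$fc_premrna[j])
    sign(cor(lx, ly)) * sd(ly) / sd(lx)
  })
  expect_lt(abs(mean(slopes) - 1), 0.15)
})
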
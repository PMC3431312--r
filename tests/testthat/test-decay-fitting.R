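test_that("noiseless series are recovered exactly across the half-life range", {
  for (th in c(20, 58, 100, 149, 265, 400, 600)) {
    y <- 200 * 2^(-defaultTimes / th)
    f <- suppressWarnings(fitDecay(defaultTimes, y))
    expect_lt(abs(halfLife(f) - th) / th, 1e-6)
    expect_lt(abs(f@y0 - 200) / 200, 1e-6)
    expect_true(f@converged)
  }
})

test_that("a constant series sits at the no-decay boundary", {
  f <- fitDecay(defaultTimes, rep(100, 5))
  expect_equal(decayRate(f), 0)
  expect_identical(halfLife(f), Inf)
  expect_equal(fitPvalue(f), 1)
  expect_true(f@converged)
  expect_false(isReliable(f))
})

test_that("the control/knockdown pair of half-lives 149 and 265 is recovered", {
  fc <- suppressWarnings(fitDecay(defaultTimes, 300 * 2^(-defaultTimes / 149)))
  fk <- suppressWarnings(fitDecay(defaultTimes, 300 * 2^(-defaultTimes / 265)))
  expect_equal(halfLife(fc), 149, tolerance = 1e-7)
  expect_equal(halfLife(fk), 265, tolerance = 1e-7)
  expect_equal(round(halfLife(fk) / halfLife(fc), 2), 1.78)
})

test_that("t_half = ln2/k holds for every emitted fit", {
  set.seed(31)
  for (i in 1:30) {
    y <- 100 * 2^(-defaultTimes / runif(1, 30, 500)) *
      exp(rnorm(5, 0, 0.15))
    f <- fitDecay(defaultTimes, y)
    if (decayRate(f) > 0)
      expect_equal(halfLife(f), log(2) / decayRate(f))
  }
})

test_that("noiseless decay drives se_k to zero, p below any alpha, CI collapsed", {
  f <- suppressWarnings(fitDecay(defaultTimes, 50 * 2^(-defaultTimes / 80)))
  expect_lt(f@seK, 1e-12)
  expect_lt(f@fitP, 1e-20)
  expect_equal(halfLifeCI(f), c(halfLife(f), halfLife(f)), tolerance = 1e-6)
  expect_true(isReliable(f))
  # an exactly-zero standard error with k > 0 is reported as p = 0, warned
  exact <- new("DecayFit", y0 = 100, k = 0.01, tHalf = log(2) / 0.01,
               seK = 0, ci95Thalf = c(69.3, 69.3), fitP = 0,
               converged = TRUE, nPoints = 5L, residualSS = 0)
  expect_warning(p <- fitPvalue(exact), "zero standard error")
  expect_equal(p, 0)
})

test_that("a rate interval straddling zero yields an infinite upper bound", {
  # barely decaying, noisy series: k is positive but not distinguishable from 0
  f <- fitDecay(defaultTimes, c(100, 99, 101, 98, 100))
  expect_gt(decayRate(f), 0)
  ci <- halfLifeCI(f)
  expect_identical(ci[2], Inf)
  expect_false(isReliable(f))
})

test_that("reliability combines the fit p-value and the CI-width criterion", {
  mk <- function(th, ci, p)
    new("DecayFit", y0 = 100, k = log(2) / th, tHalf = th, seK = 0.001,
        ci95Thalf = ci, fitP = p, converged = TRUE, nPoints = 5L,
        residualSS = 1)
  expect_true(isReliable(mk(100, c(70, 150), 0.01)))   # width 80 < 200
  expect_false(isReliable(mk(100, c(40, 260), 0.01)))  # width 220 > 200
  expect_false(isReliable(mk(100, c(90, 110), 0.2)))   # good CI, poor fit p
})

test_that("the fitter agrees with an independent NLS implementation", {
  skip_if_not_installed("minpack.lm")
  set.seed(77)
  for (i in 1:20) {
    th <- runif(1, 40, 400)
    y <- 150 * 2^(-defaultTimes / th) * exp(rnorm(5, 0, 0.12))
    f <- fitDecay(defaultTimes, y)
    df <- data.frame(t = defaultTimes, y = y)
    or <- minpack.lm::nlsLM(y ~ y0 * exp(-k * t), data = df,
                            start = list(y0 = y[1], k = log(2) / 100),
                            lower = c(0, 0),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-13, ptol = 1e-13))
    ok <- coef(or)
    expect_equal(decayRate(f), unname(ok["k"]), tolerance = 1e-6)
    expect_equal(f@y0, unname(ok["y0"]), tolerance = 1e-6)
    se <- summary(or)$coefficients["k", "Std. Error"]
    expect_equal(f@seK, unname(se), tolerance = 1e-4)
  }
})

test_that("the Wald fit p-value matches a residual-bootstrap null", {
  bootP <- function(y, seed, B = 5000) {
    f <- fitDecay(defaultTimes, y)
    tobs <- decayRate(f) / f@seK
    r0 <- y - mean(y)
    set.seed(seed)
    tstar <- replicate(B, {
      yb <- mean(y) + sample(r0, 5, replace = TRUE)
      if (any(yb <= 0)) return(0)
      fb <- fitDecay(defaultTimes, yb)
      if (!fb@converged || decayRate(fb) <= 0 || is.na(fb@seK) ||
          fb@seK == 0) 0 else decayRate(fb) / fb@seK
    })
    c(wald = fitPvalue(f), boot = mean(tstar >= tobs))
  }
  cv <- function(n, cvv) { s <- sqrt(log(1 + cvv^2)); rlnorm(n, -s^2/2, s) }
  set.seed(42); y1 <- 200 * 2^(-defaultTimes / 100) * cv(5, 0.15)
  p1 <- bootP(y1, seed = 7)
  expect_lt(abs(p1["wald"] - p1["boot"]), 0.05)
  set.seed(43); y2 <- 100 * 2^(-defaultTimes / 400) * cv(5, 0.2)
  p2 <- bootP(y2, seed = 8)
  expect_lt(abs(p2["wald"] - p2["boot"]), 0.05)
})

test_that("the replicate rule needs at least two reliable fits per condition", {
  fits <- rbind(mkFits("t1", "CTRL", c(100, 105, 300),
                       reliable = c(TRUE, TRUE, FALSE)),
                mkFits("t1", "KD", c(150, 400, 500),
                       reliable = c(TRUE, FALSE, FALSE)))
  s <- summarizeStability(fits)
  expect_true(s$condition_reliable[s$condition == "CTRL"])
  expect_false(s$condition_reliable[s$condition == "KD"])
  # means use reliable replicates only
  expect_equal(s$mean_thalf[s$condition == "CTRL"], mean(c(100, 105)))
  expect_equal(s$mean_thalf[s$condition == "KD"], 150)
})

test_that("fitAll recovers every half-life on a noiseless simulation", {
  cfg <- SimConfig(nTranscripts = 40, fracStabilized = 0.2,
                   fracDestabilized = 0.1, noiseCv = 0, backgroundLevel = 0,
                   seed = 2)
  tr <- generateTruth(cfg)
  x <- simulateChase(tr)
  fits <- suppressWarnings(fitAll(x))
  s <- summarizeStability(fits)
  expect_true(all(s$condition_reliable))
  m <- merge(s, truthTable(tr), by = c("transcript_id", "condition"))
  expect_lt(max(abs(m$mean_thalf - m$true_thalf) / m$true_thalf), 1e-6)
  census <- attr(fits, "census")
  expect_equal(census$n_reliable_both, 40)
})

test_that("degenerate series are flagged, never aborting the batch", {
  expect_error(fitDecay(c(0, 10), c(5, 4)), "3 distinct")
  expect_error(fitDecay(defaultTimes, c(1, 2, NA, 4, 5)), "non-finite")
  expect_error(fitDecay(defaultTimes, c(1, 2, -3, 4, 5)), "positive")
  # in-batch: a series with too few usable points is simply unreliable
  tr <- manualTruth(thalf = c(100, 100), synth = c(2, 2))
  x <- simulateChase(tr)
  m <- intensities(x)
  m[1, 1:4] <- NA  # leaves < 3 usable points in one replicate series
  SummarizedExperiment::assay(x, "intensity") <- m
  fits <- suppressWarnings(fitAll(x))
  expect_equal(nrow(fits), 12)
  bad <- fits$transcript_id == "G001" & fits$condition == "CTRL" &
    fits$replicate == 1
  expect_false(any(fits$reliable[bad]))
})
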
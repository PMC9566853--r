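test_that("PPC matches its closed-form values", {
  expect_equal(pairwisePhaseConsistency(rep(0.7, 2)), 1)
  expect_equal(pairwisePhaseConsistency(rep(-2.1, 7)), 1) # any n of copies
  expect_equal(pairwisePhaseConsistency(c(0, pi)), -1)
  # {0, pi/2, pi}: distances {pi/2, pi, pi/2}, D = 2*pi/3, PPC = -1/3
  expect_equal(pairwisePhaseConsistency(c(0, pi / 2, pi)), -1 / 3)
  expect_error(pairwisePhaseConsistency(1.0), "2 phases")
})

test_that("PPC of uniform phases vanishes and rotation leaves PPC unchanged", {
  set.seed(5)
  u <- runif(10000, -pi, pi)
  expect_lt(abs(pairwisePhaseConsistency(u)), 0.02)

  ph <- rnorm(300, 1, 0.8)
  base <- pairwisePhaseConsistency(ph)
  for (rot in c(0.5, 2, -3)) {
    expect_equal(pairwisePhaseConsistency(spikecircuit:::wrapPhase(ph + rot)),
                 base, tolerance = 1e-10)
  }
})

test_that("rate-matched PPC subsampling behaves at the boundary and on locked data", {
  expect_equal(ppcRateMatched(rep(1, 250), seed = 1), 1)
  expect_true(is.na(ppcRateMatched(rep(1, 249))))

  # von Mises kappa = 2: subsampled estimate matches the full-sample value
  set.seed(6)
  n <- 1200
  vm <- atan2(sin(stats::rnorm(n, 0, 0.8)), cos(stats::rnorm(n, 0, 0.8)))
  full <- pairwisePhaseConsistency(vm)
  sub <- ppcRateMatched(vm, seed = 2)
  expect_equal(sub, full, tolerance = 0.05)
})

test_that("phase-locked spiking is detected; saturated locking concentrates the histogram", {
  cfg <- syntheticConfig(nPyr = 2, nInt = 1, duration = 300, kappa = 1,
                         intRate = list(meanlog = log(8), sdlog = 0.01),
                         seed = 31)
  gs <- generateSession(cfg)
  lfp <- preprocessLFP(lfpChannels(gs$session)[[1]])
  ab <- bandpassHilbert(lfp, c(60, 90))
  tr <- spikeTimes(sessionUnits(gs$session)[[3]])
  res <- couplingSignificance(tr, ab, nShuffles = 300, seed = 1)
  expect_true(res$significant)
  expect_gte(length(tr), 2000)
  # planted preferred phase 0
  expect_lt(abs(res$preferredPhase), 0.5)
  expect_gt(res$ppc, 0.1)
  expect_equal(sum(res$histogram), res$nSpikesUsed)

  # all spikes at a (nearly) identical phase: significant, mass in <= 2
  # bins; the phases straddle the histogram edge at 0 so both of the
  # adjacent bins are loaded (a strictly single-bin histogram can never
  # satisfy the two-consecutive-bin rule)
  peakSamples <- which(abs(ab$phase) < 0.05 &
                         ab$amplitude > quantile(ab$amplitude, 0.85))
  set.seed(2)
  atPeak <- sort(sample(peakSamples, min(400, length(peakSamples))) - 1) /
    1000
  res2 <- couplingSignificance(unique(atPeak), ab, nShuffles = 200, seed = 3)
  expect_true(res2$significant)
  expect_lte(sum(res2$histogram > 0), 2)
})

test_that("coupling false positives stay near the empirical rate of the 2-bin rule", {
  set.seed(9)
  lfp <- preprocessLFP(LFPChannel(rnorm(240000), fs = 1000))
  ab <- bandpassHilbert(lfp, c(60, 90))
  fp <- replicate(20, {
    tr <- poissonSpikes(8, 240)
    couplingSignificance(tr, ab, nShuffles = 200)$significant
  })
  # empirical rate of the criterion is ~5-10 %; regression bound with
  # binomial slack at n = 20
  expect_lte(mean(fp), 0.30)
})

test_that("detection power grows with von Mises concentration", {
  pow <- vapply(c(0, 0.5, 2), function(k) {
    hits <- vapply(1:6, function(i) {
      cfg <- syntheticConfig(nPyr = 2, nInt = 1, duration = 240, kappa = k,
                             intRate = list(meanlog = log(9), sdlog = 0.01),
                             seed = 1000 * k + i)
      gs <- generateSession(cfg)
      lfp <- preprocessLFP(lfpChannels(gs$session)[[1]])
      ab <- bandpassHilbert(lfp, c(60, 90))
      couplingSignificance(spikeTimes(sessionUnits(gs$session)[[3]]), ab,
                           nShuffles = 150, seed = i)$significant
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(pow) >= 0))
  expect_gt(pow[3], pow[1])
})

test_that("spike-triggered gamma recovers a constructed locking amplitude", {
  set.seed(11)
  n <- 240000
  tg <- (0:(n - 1)) / 1000
  carrier <- cos(2 * pi * 75 * tg)
  x <- 0.4 * carrier + rnorm(n) * 0.7
  lfp <- preprocessLFP(LFPChannel(x, fs = 1000))
  trueAmp <- 0.4 / sd(x) # amplitude on the z-scored scale

  locked <- sort(sample(which(carrier > 0.999), 1500)) / 1000
  stg <- spikeTriggeredGamma(lfp, locked, seed = 1)
  expect_length(stg$avgTrace, 1001)
  expect_equal(stg$lockedAmplitude, trueAmp, tolerance = 0.1)
  expect_lt(stg$randomAmplitude, trueAmp / 5)

  # independent spikes: locked and random amplitudes comparable, both small
  ind <- sort(runif(1500, 1, 239))
  stgI <- spikeTriggeredGamma(lfp, ind, seed = 2)
  expect_lt(stgI$lockedAmplitude, trueAmp / 5)

  # zero LFP gives zero amplitude
  zero <- LFPChannel(numeric(n), fs = 1000)
  zstg <- spikeTriggeredGamma(zero, locked, seed = 1)
  expect_equal(zstg$lockedAmplitude, 0)

  # exclusion below the spike minimum
  expect_null(spikeTriggeredGamma(lfp, locked[1:500], seed = 1))
})

test_that("presynaptically conditioned spike extraction follows the 2 ms rule", {
  expect_equal(presynConditionedSpikes(c(1.0015, 1.0030), list(1.000)),
               1.0015)
  expect_length(presynConditionedSpikes(c(1.0015, 1.0030), list(numeric())),
                0)
  # every INT spike preceded within 2 ms: full train retained
  pre <- c(0.999, 1.0995, 1.199)
  post <- c(1.000, 1.100, 1.200)
  expect_equal(presynConditionedSpikes(post, list(pre)), post)
  # lag exactly 2 ms is included, lag 0 is not
  expect_equal(presynConditionedSpikes(c(1.002, 1.05), list(c(1.000, 1.05))),
               1.002)
})
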
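test_that("cross-correlogram counts pairs in the right lag bins", {
  ccg <- crossCorrelogram(c(1.000, 2.000), c(1.0012, 2.0012))
  hit <- which(ccg$counts > 0)
  expect_length(hit, 1)
  expect_equal(ccg$counts[hit], 2)
  # +1.2 ms falls in the (0.8, 1.2] ms bin
  expect_true(ccg$lag[hit] > 0.0008 && ccg$lag[hit] < 0.0012)
  expect_equal(ccg$nRef, 2)

  # mirror symmetry: ccg(a,b) at +L equals ccg(b,a) at -L
  set.seed(1)
  a <- poissonSpikes(20, 60)
  b <- poissonSpikes(20, 60)
  f <- crossCorrelogram(a, b)
  r <- crossCorrelogram(b, a)
  expect_equal(f$counts, rev(r$counts))
})

test_that("CCG of independent Poisson trains matches the cross-product expectation", {
  set.seed(2)
  a <- poissonSpikes(10, 600)
  b <- poissonSpikes(10, 600)
  ccg <- crossCorrelogram(a, b)
  # E[count per bin] = rate_a * rate_b * T * binWidth = 24
  expect_equal(mean(ccg$counts), 24, tolerance = 0.15)
})

test_that("hollowed-Gaussian baseline preserves flat CCGs and suppresses the centre", {
  k <- spikecircuit:::hollowGaussianKernel(25, 0.6)
  expect_equal(sum(k), 1)
  centre <- (length(k) + 1) / 2
  # hollowing: centre weight is 40 % of its neighbours' scale
  expect_lt(k[centre], k[centre - 1])

  flat <- crossCorrelogram(numeric(), numeric())
  flat$counts <- rep(12L, length(flat$counts))
  withBase <- hollowGaussianBaseline(flat)
  expect_equal(withBase$baseline, rep(12, length(flat$counts)),
               tolerance = 1e-9)
  # conservation on a flat CCG
  expect_equal(sum(withBase$baseline), sum(flat$counts), tolerance = 1e-6)

  # a single spike-count peak contributes to its own baseline only through
  # the hollowed (reduced) centre weight
  spike <- flat
  spike$counts <- integer(length(flat$counts))
  spike$counts[125] <- 100L
  sb <- hollowGaussianBaseline(spike)
  g0 <- dnorm(0, sd = 25) # un-hollowed centre weight (unnormalized)
  expect_lt(sb$baseline[125], 100 * g0)
  expect_equal(sb$baseline[125], 100 * k[centre], tolerance = 1e-9)
})

test_that("Poisson significance matches closed forms and a brute-force tail oracle", {
  # n = 1, b_m = 0: maximal significance
  expect_equal(spikecircuit:::poissonTailCC(1, 0), 0)
  # n = 0, b_m = 2: 1 - 0.5 exp(-2)
  expect_equal(spikecircuit:::poissonTailCC(0, 2), 1 - 0.5 * exp(-2),
               tolerance = 1e-12)
  # brute-force oracle: explicit factorial sum of pmf terms
  bruteTail <- function(n, b) {
    terms <- vapply(0:n, function(x) exp(-b) * b^x / factorial(x), numeric(1))
    1 - sum(terms[seq_len(n)]) - 0.5 * terms[n + 1]
  }
  for (case in list(c(10, 2), c(3, 5), c(25, 12.5), c(0, 0.7))) {
    expect_equal(spikecircuit:::poissonTailCC(case[1], case[2]),
                 bruteTail(case[1], case[2]), tolerance = 1e-12)
  }
})

test_that("P_syn is monotone in the observed count and the baseline", {
  ns <- 0:20
  ps <- vapply(ns, spikecircuit:::poissonTailCC, numeric(1), mu = 4)
  expect_true(all(diff(ps) < 0)) # decreasing in n at fixed b_m
  bs <- seq(0.5, 12, by = 0.5)
  pb <- vapply(bs, function(b) spikecircuit:::poissonTailCC(6, b), numeric(1))
  expect_true(all(diff(pb) > 0)) # increasing in b_m at fixed n
})

test_that("connection test applies the dual-threshold rule on constructed CCGs", {
  strong <- connectionTest(mockCCG(nCausal = 60, bCausal = 10, nAnti = 10))
  expect_true(strong$connected)
  expect_lt(strong$pSyn, 0.001)
  expect_lt(strong$pCausal, 0.0026)
  expect_equal(strong$n, 60)

  # a peak that beats the baseline but not the anticausal count is rejected
  sym <- connectionTest(mockCCG(nCausal = 60, bCausal = 10, nAnti = 55))
  expect_false(sym$connected)
  expect_lt(sym$pSyn, 0.001)
  expect_gt(sym$pCausal, 0.0026)

  flat <- connectionTest(mockCCG(nCausal = 10, bCausal = 10, nAnti = 10))
  expect_false(flat$connected)
})

test_that("transmission probability is the baseline-corrected excess per presynaptic spike", {
  m <- mockCCG(nCausal = 20, bCausal = 10, nAnti = 10, nRef = 1000)
  expect_equal(spikeTransmissionProbability(m), 0.01)

  # independent trains: near zero, can be negative, never clipped
  set.seed(3)
  vals <- replicate(12, {
    ccg <- hollowGaussianBaseline(
      crossCorrelogram(poissonSpikes(6, 300), poissonSpikes(12, 300)))
    spikeTransmissionProbability(ccg)
  })
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se + 1e-4)

  m0 <- mockCCG(10, 10, 10, nRef = 0)
  expect_error(spikeTransmissionProbability(m0), "presynaptic")
})

test_that("planted transmission probabilities are recovered", {
  set.seed(4)
  pre <- poissonSpikes(5, 700)   # ~3500 presynaptic spikes
  post <- poissonSpikes(15, 700)
  for (p in c(0.05, 0.10)) {
    added <- injectConnection(pre, post, pTrans = p)
    ccg <- hollowGaussianBaseline(
      crossCorrelogram(pre, sort(unique(c(post, added)))))
    est <- spikeTransmissionProbability(ccg)
    expect_equal(est, p, tolerance = 0.2)
  }
})

test_that("session-level detection recovers planted connections without false positives", {
  cons <- data.frame(pyr = 1:8, int = rep(1:4, 2), pTrans = 0.05)
  cfg <- syntheticConfig(nPyr = 16, nInt = 4, duration = 1200,
                         pyrRate = list(meanlog = log(2), sdlog = 0.3),
                         gammaAmplitude = 0, comodAmp = 0.2,
                         connections = cons, seed = 41)
  gs <- generateSession(cfg)
  s <- gs$session
  unitLabels(s) <- gs$truth$labels
  dc <- detectConnections(s)

  planted <- paste(cons$pyr, 16 + cons$int)
  found <- paste(dc$pyr, dc$int)[dc$connected]
  tested <- paste(dc$pyr, dc$int)[dc$tested]
  recall <- mean(planted[planted %in% tested] %in% found)
  expect_gte(recall, 0.9)
  expect_lte(sum(!(found %in% planted)), 1)

  # distances reported for connected pairs with geometry
  expect_true(all(is.finite(dc$distanceUm[dc$tested])))

  # ordering invariance of the pair results
  dc2 <- detectConnections(s, pyr = rev(which(gs$truth$labels == "PYR")),
                           int = rev(which(gs$truth$labels != "PYR")))
  m1 <- dc[order(dc$pyr, dc$int), c("pSyn", "connected")]
  m2 <- dc2[order(dc2$pyr, dc2$int), c("pSyn", "connected")]
  expect_equal(m1$pSyn, m2$pSyn)
  expect_equal(m1$connected, m2$connected)
})

test_that("pairs below the 500-spike criterion are untested", {
  s <- Session(units = list(Unit(poissonSpikes(1, 100, seed = 1),
                                 label = "PYR", unitId = "p"),
                            Unit(poissonSpikes(1, 100, seed = 2),
                                 label = "INT", unitId = "i")),
               duration = 100)
  dc <- detectConnections(s)
  expect_false(any(dc$tested))
  expect_false(any(dc$connected))
})

test_that("intersomatic distance is Euclidean, symmetric, and needs geometry", {
  pos <- cbind(0, (0:3) * 40)
  wf <- spikecircuit:::makeWaveform(0.5, 0, nChannels = 4, peakChannel = 1)
  wf2 <- spikecircuit:::makeWaveform(0.5, 0, nChannels = 4, peakChannel = 2)
  uA <- Unit(c(1, 2), meanWaveform = wf, peakChannel = 1L,
             channelPositions = pos, unitId = "a")
  uB <- Unit(c(1, 2), meanWaveform = wf2, peakChannel = 2L,
             channelPositions = pos, unitId = "b")
  expect_equal(intersomaticDistance(uA, uA), 0)
  expect_equal(intersomaticDistance(uA, uB), 40)
  expect_equal(intersomaticDistance(uB, uA), intersomaticDistance(uA, uB))
  noGeo <- Unit(c(1, 2), unitId = "c")
  expect_error(intersomaticDistance(uA, noGeo), "positions")
})

test_that("planted distance-dependent transmission yields a negative rank correlation", {
  set.seed(6)
  nP <- 12
  post <- poissonSpikes(15, 900)
  dist <- seq(20, 460, length.out = nP)
  est <- vapply(seq_len(nP), function(i) {
    pre <- poissonSpikes(4, 900)
    p <- 0.08 * exp(-dist[i] / 200)
    added <- injectConnection(pre, post, pTrans = p)
    ccg <- hollowGaussianBaseline(
      crossCorrelogram(pre, sort(unique(c(post, added)))))
    spikeTransmissionProbability(ccg)
  }, numeric(1))
  expect_lt(cor(dist, est, method = "spearman"), -0.5)
})

test_that("convergence and divergence count connected pairs and conserve totals", {
  conns <- data.frame(pyr = c(1, 2, 1), int = c(9, 9, 10),
                      connected = TRUE, tested = TRUE)
  cd <- convergenceDivergence(conns)
  expect_equal(as.integer(cd$convergence[["9"]]), 2)
  expect_equal(as.integer(cd$divergence[["1"]]), 2)
  expect_equal(sum(cd$convergence), sum(cd$divergence))
  expect_equal(sum(cd$convergence), nrow(conns))

  empty <- convergenceDivergence(conns[0, ])
  expect_equal(length(empty$convergence), 0)
})
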
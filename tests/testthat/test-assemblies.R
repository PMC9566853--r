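test_that("Marchenko-Pastur limit matches the closed form and its asymptote", {
  expect_equal(marchenkoPasturLimit(2000, 100), (1 + 1 / sqrt(20))^2,
               tolerance = 1e-12)
  expect_equal(marchenkoPasturLimit(2000, 100), 1.4972, tolerance = 1e-4)
  expect_equal(marchenkoPasturLimit(1e9, 10), 1, tolerance = 1e-3)
  expect_error(marchenkoPasturLimit(50, 100), "q > 1")
})

test_that("the null keeps correlation eigenvalues below the limit", {
  set.seed(4)
  contained <- replicate(40, {
    M <- matrix(rpois(50 * 5000, 2), 50)
    Z <- t(scale(t(M)))
    ev <- eigen(tcrossprod(Z) / (5000 - 1), symmetric = TRUE,
                only.values = TRUE)$values
    max(ev) <= marchenkoPasturLimit(5000, 50)
  })
  expect_gte(mean(contained), 0.95)
})

test_that("deflation FastICA separates independent sources", {
  set.seed(5)
  n <- 5000
  S <- rbind(runif(n, -sqrt(3), sqrt(3)),         # uniform
             sign(rnorm(n)) * rexp(n) / sqrt(2),  # Laplace
             sin(seq_len(n) / 7) * sqrt(2))       # deterministic oscillation
  A <- matrix(rnorm(9), 3)
  X <- A %*% S
  # whiten
  Xc <- X - rowMeans(X)
  e <- eigen(tcrossprod(Xc) / n, symmetric = TRUE)
  K <- diag(1 / sqrt(e$values)) %*% t(e$vectors)
  W <- spikecircuit:::fastICADeflation(K %*% Xc, 3)
  Srec <- W %*% K %*% Xc
  # each true source matches one recovered component up to sign
  cors <- abs(cor(t(S), t(Srec)))
  expect_true(all(apply(cors, 1, max) > 0.95))
})

test_that("planted assemblies are detected with the right count and members", {
  cfg <- syntheticConfig(nPyr = 30, nInt = 2, duration = 600,
                         gammaAmplitude = 0,
                         assemblies = list(
                           list(members = 1:5, eventRate = 0.5,
                                memberProb = 0.8),
                           list(members = 6:10, eventRate = 0.5,
                                memberProb = 0.8)),
                         seed = 3)
  gs <- generateSession(cfg)
  trains <- lapply(sessionUnits(gs$session), spikeTimes)[1:30]
  pats <- detectPatterns(binSpikeCounts(trains, tEnd = 600), seed = 3)

  expect_equal(ncol(pats$weights), 2)
  expect_equal(ncol(pats$weights),
               sum(pats$eigenvalues > pats$eigenvalueLimit))
  j1 <- max(vapply(pats$members, jaccard, numeric(1), b = 1:5))
  j2 <- max(vapply(pats$members, jaccard, numeric(1), b = 6:10))
  expect_gte(j1, 0.8)
  expect_gte(j2, 0.8)

  # weight-vector conventions
  for (k in seq_len(ncol(pats$weights))) {
    w <- pats$weights[, k]
    expect_equal(sqrt(sum(w^2)), 1, tolerance = 1e-9)
    expect_gt(w[which.max(abs(w))], 0)
  }
})

test_that("independent populations yield no patterns in most runs", {
  hits <- vapply(1:10, function(i) {
    set.seed(i * 7)
    trains <- lapply(seq_len(15), function(j) poissonSpikes(2, 300))
    pats <- detectPatterns(binSpikeCounts(trains, tEnd = 300), seed = i)
    ncol(pats$weights)
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.9)
})

test_that("zero-variance neurons are dropped with a warning", {
  set.seed(8)
  trains <- c(lapply(1:11, function(j) poissonSpikes(3, 300)),
              list(numeric()))
  bc <- binSpikeCounts(trains, tEnd = 300)
  expect_warning(pats <- detectPatterns(bc, seed = 1), "zero-variance")
  expect_error(detectPatterns(binSpikeCounts(trains[1:5], tEnd = 300)),
               "at least 10")
})

test_that("activation quadratic form nulls single-neuron firing and respects sign flips", {
  set.seed(9)
  trains <- list(poissonSpikes(8, 120), poissonSpikes(8, 120))
  w <- matrix(c(1, 1) / sqrt(2), ncol = 1)
  tr <- activationStrength(w, trains, duration = 120)

  # sign flip of the whole pattern leaves A(t) unchanged
  trFlip <- activationStrength(-w, trains, duration = 120)
  expect_equal(tr[[1]], trFlip[[1]])

  # only one active neuron: off-diagonal-only projector gives A <= 0
  trains1 <- list(poissonSpikes(8, 120, seed = 10), numeric())
  tr1 <- activationStrength(w, trains1, duration = 120)
  expect_lte(max(tr1[[1]]), 1e-12)

  # keeping the diagonal restores the plain squared projection
  trKeep <- activationStrength(w, trains, duration = 120,
                               keepDiagonal = TRUE)
  expect_true(all(trKeep[[1]] >= tr[[1]] - 1e-12))

  expect_error(activationStrength(w, trains[1], duration = 120), "match")
})

test_that("planted events drive A above threshold and the planted rate is recovered", {
  # low base rates so chance member coincidences are rare relative to events
  cfg <- syntheticConfig(nPyr = 20, nInt = 2, duration = 600,
                         gammaAmplitude = 0,
                         pyrRate = list(meanlog = log(0.4), sdlog = 0.3),
                         assemblies = list(
                           list(members = 1:5, eventRate = 0.4,
                                memberProb = 0.9)),
                         seed = 12)
  gs <- generateSession(cfg)
  trains <- lapply(sessionUnits(gs$session), spikeTimes)[1:20]
  pats <- detectPatterns(binSpikeCounts(trains, tEnd = 600), seed = 2)
  expect_equal(ncol(pats$weights), 1)
  tr <- activationStrength(pats, trains, duration = 600)
  ev <- activationEvents(tr[[1]])

  # A exceeds threshold at planted event times
  evt <- gs$truth$assemblies[[1]]$eventTimes
  idx <- round(evt * 1000)
  nearMax <- vapply(idx, function(i)
    max(tr[[1]][max(1, i - 60):min(length(tr[[1]]), i + 60)]), numeric(1))
  expect_gte(mean(nearMax > 5), 0.9)

  # planted rate 0.4 Hz = 24 events/min, recovered within 20 %
  expect_equal(ev$eventRate, 0.4 * 60, tolerance = 0.2)
})

test_that("activation events are threshold crossings; strength averages above-threshold samples", {
  flat <- structure(rep(4, 1000), dt = 0.001)
  expect_equal(activationEvents(flat)$nEvents, 0)
  expect_true(is.na(activationEvents(flat)$meanEventStrength))

  two <- numeric(1000)
  two[100:120] <- 8
  two[500:520] <- 6
  res <- activationEvents(structure(two, dt = 0.001))
  expect_equal(res$nEvents, 2)
  expect_equal(res$meanEventStrength, mean(c(rep(8, 21), rep(6, 21))))
})

test_that("stronger within-event synchrony raises mean event strength", {
  strengths <- vapply(c(0.5, 1.0), function(p) {
    cfg <- syntheticConfig(nPyr = 20, nInt = 2, duration = 600,
                           gammaAmplitude = 0,
                           pyrRate = list(meanlog = log(0.4), sdlog = 0.3),
                           assemblies = list(
                             list(members = 1:5, eventRate = 0.4,
                                  memberProb = p)),
                           seed = 13)
    gs <- generateSession(cfg)
    trains <- lapply(sessionUnits(gs$session), spikeTimes)[1:20]
    pats <- detectPatterns(binSpikeCounts(trains, tEnd = 600), seed = 2)
    if (ncol(pats$weights) == 0) return(NA_real_)
    tr <- activationStrength(pats, trains, duration = 600)
    activationEvents(tr[[1]])$meanEventStrength
  }, numeric(1))
  expect_gt(strengths[2], strengths[1])
})

test_that("identical recording halves give a reactivation ratio of exactly 1", {
  set.seed(14)
  base <- lapply(1:12, function(i) poissonSpikes(3, 300))
  ev <- seq(5, 295, by = 2.5)
  for (m in 1:5) base[[m]] <- sort(unique(c(base[[m]], ev + m * 1e-4)))
  mirrored <- lapply(base, function(t) sort(c(t, t + 300)))
  ra <- reactivationStrength(mirrored, duration = 600, seed = 1)
  expect_gte(nrow(ra), 1)
  expect_equal(ra$ratio, rep(1, nrow(ra)), tolerance = 1e-9)
})

test_that("member neurons co-fire more than non-members", {
  cfg <- syntheticConfig(nPyr = 25, nInt = 2, duration = 600,
                         gammaAmplitude = 0,
                         assemblies = list(
                           list(members = 1:5, eventRate = 0.5,
                                memberProb = 0.8)),
                         seed = 15)
  gs <- generateSession(cfg)
  trains <- lapply(sessionUnits(gs$session), spikeTimes)[1:25]
  bc <- binSpikeCounts(trains, tEnd = 600)
  pats <- detectPatterns(bc, seed = 1)
  cf <- memberCofireCheck(bc, pats)
  expect_gte(nrow(cf), 1)
  expect_gt(cf$memberR[1], cf$nonMemberR[1])

  # duplicated spike trains as members give r = 1
  dup <- trains
  dup[[2]] <- dup[[1]]
  bcd <- binSpikeCounts(dup, tEnd = 600)
  fake <- pats
  fake$members <- list(c(1L, 2L))
  cfd <- memberCofireCheck(bcd, fake)
  expect_equal(cfd$memberR[1], 1)
})
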
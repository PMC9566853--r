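## Synthetic session generator with planted ground truth: lognormal-rate
## Poisson spiking, two waveform clusters, gamma-band LFP with von Mises
## phase-locked interneuron spiking, monosynaptic PYR->INT connections at
## 0.8-2.8 ms latency (optionally history-dependent), coactivating PYR
## assemblies, and laser-driven rate increases in tagged units.

#' Configuration for a synthetic session
#'
#' Defaults emulate a downscaled cortical recording: 40 PYRs and 8 INTs for
#' 20 minutes, lognormal firing rates (~1 Hz pyramidal, ~12 Hz fast-spiking),
#' 70 Hz gamma with a slow amplitude envelope over pink noise and theta.
#'
#' @param nPyr,nInt numbers of pyramidal cells and interneurons.
#' @param nTagged number of INTs that are light-tagged (labelled PVI in the
#'   ground truth).
#' @param duration session length, seconds.
#' @param pyrRate,intRate lognormal rate parameters,
#'   list(meanlog, sdlog), in log-Hz.
#' @param connections data.frame with columns `pyr`, `int` (1-based indices
#'   into the PYR and INT sets), `pTrans`, and optionally `latencyMean`,
#'   `latencySD` (s; latencies are truncated to (0.8, 2.8] ms),
#'   `resonanceGain` (multiplier on pTrans when a postsynaptic spike
#'   occurred 20-50 ms earlier), `distanceDecay` (length constant, um;
#'   scales pTrans by exp(-distance/lambda)).
#' @param gammaFreq,gammaAmplitude gamma oscillation frequency (Hz) and
#'   amplitude (in units of the pink-noise SD).
#' @param kappa von Mises concentration of INT phase locking to gamma;
#'   scalar or per-INT vector (0 = no locking).
#' @param prefPhase preferred gamma phase of locked INTs, radians.
#' @param assemblies list of specs: list(members = PYR indices,
#'   eventRate = Hz, memberProb, jitter = s window, default 0.025).
#' @param laser list(nPulses, rateMultiplier, pulseDuration = 0.05).
#' @param comodAmp,comodFreq shared slow rate co-modulation (fractional
#'   amplitude, Hz) exercising the slow-baseline correction of the CCG.
#' @param lfpFs LFP sampling rate, Hz.
#' @param nChannels,channelSpacing probe geometry (single column, um).
#' @param seed mandatory RNG seed.
#' @return list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(nPyr = 40, nInt = 8, nTagged = 0,
                            duration = 1200,
                            pyrRate = list(meanlog = log(1.2), sdlog = 0.6),
                            intRate = list(meanlog = log(12), sdlog = 0.4),
                            connections = NULL,
                            gammaFreq = 70, gammaAmplitude = 1,
                            kappa = 0, prefPhase = 0,
                            assemblies = list(),
                            laser = list(nPulses = 0, rateMultiplier = 5,
                                         pulseDuration = 0.05),
                            comodAmp = 0, comodFreq = 0.5,
                            lfpFs = 1000, nChannels = 16,
                            channelSpacing = 20, seed) {
  if (missing(seed)) stop("seed is mandatory for a synthetic session")
  if (duration <= 0) stop("duration must be positive")
  if (!is.null(connections)) {
    connections <- as.data.frame(connections)
    if (any(connections$pTrans < 0 | connections$pTrans > 1))
      stop("pTrans must be in [0, 1]")
    if (is.null(connections$latencyMean)) connections$latencyMean <- 0.0018
    if (is.null(connections$latencySD)) connections$latencySD <- 3e-4
    if (is.null(connections$resonanceGain)) connections$resonanceGain <- 1
    if (any(connections$latencyMean <= 8e-4 | connections$latencyMean > 2.8e-3))
      stop("connection latency means must lie in (0.8, 2.8] ms")
  }
  kappa <- rep(kappa, length.out = nInt)
  if (exp(pyrRate$meanlog) <= 0 || exp(intRate$meanlog) <= 0)
    stop("rates must be positive")
  structure(as.list(environment()), class = "SyntheticConfig")
}

## Homogeneous Poisson spike train on [0, duration).
poissonTrain <- function(rate, duration) {
  n <- stats::rpois(1, rate * duration)
  sort(stats::runif(n, 0, duration))
}

## Thinned inhomogeneous Poisson train with rate rate * env(t), where env
## is a function of time bounded by envMax.
thinnedTrain <- function(rate, duration, env, envMax) {
  base <- poissonTrain(rate * envMax, duration)
  if (!length(base)) return(base)
  base[stats::runif(length(base)) < env(base) / envMax]
}

## Parametric mean waveform with a negative trough and two positive bumps
## giving the requested trough-to-peak duration (ms) and asymmetry index.
## Returns a channels x samples matrix whose peak channel has the deepest
## trough.
makeWaveform <- function(troughToPeakMs, asymmetry, fs = 30000,
                         nSamples = 90, nChannels = 16, peakChannel = 1) {
  iTrough <- 30L
  iPeak <- iTrough + max(1L, round(troughToPeakMs / 1000 * fs))
  s <- seq_len(nSamples)
  total <- 0.6
  b <- total * (1 + asymmetry) / 2
  cc <- total * (1 - asymmetry) / 2
  shape <- -exp(-(s - iTrough)^2 / (2 * 2.5^2)) +
    b * exp(-(s - (iTrough - 12))^2 / (2 * 4^2)) +
    cc * exp(-(s - iPeak)^2 / (2 * 6^2))
  decay <- exp(-abs(seq_len(nChannels) - peakChannel) / 1.5)
  outer(decay, shape)
}

#' Add monosynaptically transmitted spikes to a postsynaptic train
#'
#' Each presynaptic spike independently evokes a postsynaptic spike with
#' probability `pTrans` at a normal latency truncated to (0.8, 2.8] ms.
#' When `resonanceGain != 1`, the probability is multiplied by the gain for
#' presynaptic spikes satisfying the resonance condition (a postsynaptic
#' spike 20-50 ms earlier and neither unit firing in the last 20 ms).
#' Evoked spikes closer than `refractory` to an existing or already-evoked
#' postsynaptic spike are discarded.
#'
#' @param pre presynaptic spike times.
#' @param post existing postsynaptic spike times.
#' @param pTrans transmission probability in [0, 1].
#' @param latencyMean,latencySD latency distribution, seconds.
#' @param resonanceGain history-dependent multiplier (default 1).
#' @param refractory postsynaptic refractory period, seconds.
#' @return numeric vector of added spike times (not merged).
#' @export
injectConnection <- function(pre, post, pTrans, latencyMean = 0.0018,
                             latencySD = 3e-4, resonanceGain = 1,
                             refractory = 0.001) {
  stopifnot(pTrans >= 0, pTrans <= 1)
  pre <- spikeTimes(pre)
  post <- sort(spikeTimes(post))
  if (!length(pre) || pTrans == 0) return(numeric())

  drawLatency <- function(n) {
    l <- stats::rnorm(n, latencyMean, latencySD)
    bad <- l <= 8e-4 | l > 2.8e-3
    while (any(bad)) {
      l[bad] <- stats::rnorm(sum(bad), latencyMean, latencySD)
      bad <- l <= 8e-4 | l > 2.8e-3
    }
    l
  }

  if (resonanceGain == 1) {
    hit <- stats::runif(length(pre)) < pTrans
    cand <- pre[hit] + drawLatency(sum(hit))
  } else {
    ## resonance condition must see evoked spikes too: sequential pass
    added <- numeric(0)
    cand <- numeric(0)
    for (t in pre) {
      inRes <- (findInterval(t - 0.02, post) - findInterval(t - 0.05, post,
                                                            left.open = TRUE) +
                  sum(added >= t - 0.05 & added <= t - 0.02)) > 0
      gapPost <- (findInterval(t, post, left.open = TRUE) -
                    findInterval(t - 0.02, post) +
                    sum(added > t - 0.02 & added < t)) > 0
      gapPre <- any(pre > t - 0.02 & pre < t)
      p <- if (inRes && !gapPost && !gapPre) min(1, pTrans * resonanceGain)
           else pTrans
      if (stats::runif(1) < p) {
        s <- t + drawLatency(1)
        cand <- c(cand, s)
        added <- c(added, s)
      }
    }
  }
  if (!length(cand)) return(numeric())
  cand <- sort(cand)
  ## refractory against existing post spikes
  if (length(post)) {
    idx <- findInterval(cand, post)
    below <- ifelse(idx >= 1L, cand - post[pmax(idx, 1L)], Inf)
    above <- ifelse(idx < length(post),
                    post[pmin(idx + 1L, length(post))] - cand, Inf)
    nearest <- pmin(below, above)
  } else {
    nearest <- rep(Inf, length(cand))
  }
  cand <- cand[nearest >= refractory]
  ## refractory among evoked spikes (greedy)
  if (length(cand) > 1L) {
    ok <- rep(TRUE, length(cand))
    last <- cand[1]
    for (i in seq_along(cand)[-1]) {
      if (cand[i] - last < refractory) ok[i] <- FALSE else last <- cand[i]
    }
    cand <- cand[ok]
  }
  cand
}

#' Embed coactivation events of assemblies into spike trains
#'
#' For each assembly, event times are Poisson with the configured rate; at
#' each event every member emits one spike within the jitter window with
#' the configured probability.
#'
#' @param trains list of spike-time vectors.
#' @param specs list of assembly specs (see [syntheticConfig()]).
#' @param duration session duration, seconds.
#' @return list with `trains` (modified) and `eventTimes` (list per
#'   assembly).
#' @export
embedAssemblies <- function(trains, specs, duration) {
  eventTimes <- vector("list", length(specs))
  allMembers <- unlist(lapply(specs, `[[`, "members"))
  if (anyDuplicated(allMembers))
    warning("assembly member sets overlap")
  for (j in seq_along(specs)) {
    sp <- specs[[j]]
    jitter <- if (is.null(sp$jitter)) 0.025 else sp$jitter
    ev <- poissonTrain(sp$eventRate, duration - jitter)
    eventTimes[[j]] <- ev
    for (m in sp$members) {
      fire <- ev[stats::runif(length(ev)) < sp$memberProb]
      newSpikes <- fire + stats::runif(length(fire), 0, jitter)
      trains[[m]] <- sort(unique(c(trains[[m]], newSpikes)))
    }
  }
  list(trains = trains, eventTimes = eventTimes)
}

## Pink (1/f) noise of length n via spectral shaping, unit variance.
pinkNoise <- function(n) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1) # symmetric frequency index
  X <- X / sqrt(f)
  x <- Re(stats::fft(X, inverse = TRUE) / n)
  (x - mean(x)) / stats::sd(x)
}

#' Generate a synthetic session with ground truth
#'
#' See [syntheticConfig()] for the generative model. Fully reproducible:
#' the same config (including seed) yields a bit-identical session.
#'
#' @param config a `SyntheticConfig`.
#' @return list with `session` (a [Session-class]) and `truth` (labels,
#'   rates, tagged units, connection table with effective pTrans, assembly
#'   members and event times, kappa and preferred phase per INT).
#' @export
generateSession <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed)
  dur <- config$duration
  nPyr <- config$nPyr
  nInt <- config$nInt
  nUnits <- nPyr + nInt

  ## --- LFP -----------------------------------------------------------------
  fs <- config$lfpFs
  nSamp <- round(dur * fs)
  tGrid <- (seq_len(nSamp) - 1) / fs
  gammaEnv <- 1 + 0.5 * sin(2 * pi * 1.0 * tGrid) # 1 Hz amplitude modulation
  gammaPhase <- 2 * pi * config$gammaFreq * tGrid
  lfpRaw <- pinkNoise(nSamp) +
    0.8 * cos(2 * pi * 8 * tGrid + stats::runif(1, 0, 2 * pi)) +
    config$gammaAmplitude * gammaEnv * cos(gammaPhase)

  ## --- geometry and waveforms ----------------------------------------------
  positions <- cbind(0, (seq_len(config$nChannels) - 1) * config$channelSpacing)
  peakChannels <- sample(config$nChannels, nUnits, replace = TRUE)
  tpPyr <- stats::rnorm(nPyr, 0.70, 0.05)
  tpInt <- stats::rnorm(nInt, 0.25, 0.03)
  asymPyr <- stats::rnorm(nPyr, 0.25, 0.12)
  asymInt <- stats::rnorm(nInt, -0.25, 0.12)
  tp <- c(tpPyr, tpInt)
  asym <- pmax(pmin(c(asymPyr, asymInt), 0.95), -0.95)

  ## --- base spiking ----------------------------------------------------------
  pyrRates <- stats::rlnorm(nPyr, config$pyrRate$meanlog, config$pyrRate$sdlog)
  intRates <- stats::rlnorm(nInt, config$intRate$meanlog, config$intRate$sdlog)
  comodPhi <- stats::runif(1, 0, 2 * pi)
  comod <- function(t) 1 + config$comodAmp * sin(2 * pi * config$comodFreq * t + comodPhi)
  comodMax <- 1 + abs(config$comodAmp)

  pyrTrains <- lapply(pyrRates, function(r)
    if (config$comodAmp != 0) thinnedTrain(r, dur, comod, comodMax)
    else poissonTrain(r, dur))

  intTrains <- vector("list", nInt)
  for (i in seq_len(nInt)) {
    k <- config$kappa[i]
    if (k > 0) {
      env <- function(t) {
        exp(k * cos(2 * pi * config$gammaFreq * t - config$prefPhase)) /
          besselI(k, 0) * comod(t)
      }
      envMax <- exp(k) / besselI(k, 0) * comodMax
      intTrains[[i]] <- thinnedTrain(intRates[i], dur, env, envMax)
    } else {
      intTrains[[i]] <- if (config$comodAmp != 0)
        thinnedTrain(intRates[i], dur, comod, comodMax)
      else poissonTrain(intRates[i], dur)
    }
  }

  ## --- assemblies ------------------------------------------------------------
  assemblyEvents <- list()
  if (length(config$assemblies)) {
    emb <- embedAssemblies(pyrTrains, config$assemblies, dur)
    pyrTrains <- emb$trains
    assemblyEvents <- emb$eventTimes
  }

  ## --- laser pulses and tagged units -----------------------------------------
  pulses <- matrix(numeric(), 0, 2)
  taggedInt <- integer()
  if (config$laser$nPulses > 0) {
    pd <- config$laser$pulseDuration
    onsets <- seq(dur * 0.05, dur * 0.95 - pd,
                  length.out = config$laser$nPulses) +
      stats::runif(config$laser$nPulses, 0, pd)
    pulses <- cbind(onsets, pd)
    taggedInt <- seq_len(min(config$nTagged, nInt))
    for (i in taggedInt) {
      extraRate <- (config$laser$rateMultiplier - 1) * intRates[i]
      extra <- unlist(lapply(onsets, function(on)
        on + poissonTrain(extraRate, pd)))
      intTrains[[i]] <- sort(unique(c(intTrains[[i]], extra)))
    }
  }

  ## --- monosynaptic connections ----------------------------------------------
  connTruth <- NULL
  if (!is.null(config$connections) && nrow(config$connections)) {
    cons <- config$connections
    cons$pTransEffective <- cons$pTrans
    for (r in seq_len(nrow(cons))) {
      pIdx <- cons$pyr[r]
      iIdx <- cons$int[r]
      pEff <- cons$pTrans[r]
      if (!is.null(cons$distanceDecay) && !is.na(cons$distanceDecay[r])) {
        d <- sqrt(sum((positions[peakChannels[pIdx], ] -
                         positions[peakChannels[nPyr + iIdx], ])^2))
        pEff <- pEff * exp(-d / cons$distanceDecay[r])
      }
      cons$pTransEffective[r] <- pEff
      added <- injectConnection(pyrTrains[[pIdx]], intTrains[[iIdx]],
                                pTrans = pEff,
                                latencyMean = cons$latencyMean[r],
                                latencySD = cons$latencySD[r],
                                resonanceGain = cons$resonanceGain[r])
      intTrains[[iIdx]] <- sort(unique(c(intTrains[[iIdx]], added)))
    }
    connTruth <- cons
  }

  ## --- assemble Session --------------------------------------------------------
  clip <- function(t) {
    t <- t[t >= 0 & t <= dur]
    unique(sort(t))
  }
  allTrains <- c(lapply(pyrTrains, clip), lapply(intTrains, clip))
  labels <- c(rep("PYR", nPyr),
              ifelse(seq_len(nInt) %in% taggedInt, "PVI", "INT"))
  unitsList <- lapply(seq_len(nUnits), function(i) {
    wf <- makeWaveform(tp[i], asym[i], nChannels = config$nChannels,
                       peakChannel = peakChannels[i])
    Unit(SpikeTrain(sprintf("u%03d", i), allTrains[[i]]),
         meanWaveform = wf, waveformFs = 30000,
         peakChannel = peakChannels[i], channelPositions = positions,
         label = "unclassified")
  })
  session <- Session(units = unitsList,
                     lfp = list(LFPChannel(lfpRaw, fs = fs,
                                           channelId = "ch1")),
                     laserPulses = if (nrow(pulses)) pulses else NULL,
                     duration = dur, group = "synthetic",
                     metadata = list(generator = "spikecircuit",
                                     seed = config$seed))
  truth <- list(labels = labels,
                pyrIndices = seq_len(nPyr), intIndices = nPyr + seq_len(nInt),
                rates = c(pyrRates, intRates),
                troughToPeakMs = tp, asymmetry = asym,
                tagged = nPyr + taggedInt,
                connections = connTruth,
                assemblies = lapply(seq_along(config$assemblies), function(j)
                  list(members = config$assemblies[[j]]$members,
                       eventTimes = assemblyEvents[[j]])),
                kappa = config$kappa, prefPhase = config$prefPhase,
                gammaFreq = config$gammaFreq)
  list(session = session, truth = truth)
}
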
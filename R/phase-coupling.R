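## Spike-gamma phase coupling: shuffle-controlled significance, pairwise
## phase consistency (PPC), and spike-triggered gamma amplitude.

## Phase and amplitude of an AnalyticBand at spike times (nearest sample).
spikePhaseSamples <- function(times, band) {
  idx <- round(times * band$fs) + 1L
  idx[idx < 1L] <- 1L
  idx[idx > length(band$phase)] <- length(band$phase)
  idx
}

## 18-bin histogram over (-pi, pi] of the phases at masked spike samples.
phaseHistogram <- function(phases, nBins = 18L) {
  b <- ceiling((phases + pi) / (2 * pi) * nBins)
  b[b < 1L] <- 1L
  b[b > nBins] <- nBins
  tabulate(b, nbins = nBins)
}

#' Spike-gamma phase-coupling significance
#'
#' Analysis is restricted to epochs where the band envelope exceeds its 80th
#' percentile. The spike-phase histogram (18 bins) is compared per-bin with
#' the 95th percentile of histograms from interspike-interval-shuffled
#' surrogate trains (same amplitude mask); coupling is significant when at
#' least two consecutive bins (circular adjacency) exceed their percentile.
#' The preferred phase is the circular mean of the masked spike phases and
#' is reported for significant units; PPC is computed on the same phases.
#'
#' @param train spike times (vector, [SpikeTrain-class] or [Unit-class]).
#' @param band an `AnalyticBand` from [bandpassHilbert()] covering the
#'   session.
#' @param nShuffles number of ISI shuffles (default 500).
#' @param nBins phase histogram bins (default 18).
#' @param ampQuantile envelope quantile defining high-amplitude epochs
#'   (default 0.8).
#' @param seed RNG seed for the shuffles.
#' @return list with `significant`, `histogram`, `binP95`, `preferredPhase`,
#'   `ppc`, `nSpikesUsed`, `phases`.
#' @export
couplingSignificance <- function(train, band, nShuffles = 500, nBins = 18L,
                                 ampQuantile = 0.8, seed = NULL) {
  times <- spikeTimes(train)
  if (!length(times)) stop("empty spike train")
  if (!is.null(seed)) set.seed(seed)
  thr <- stats::quantile(band$amplitude, ampQuantile, names = FALSE)
  mask <- band$amplitude > thr

  maskedPhases <- function(t) {
    idx <- spikePhaseSamples(t, band)
    band$phase[idx[mask[idx]]]
  }
  ph <- maskedPhases(times)
  hist <- phaseHistogram(ph, nBins)
  if (!length(ph)) {
    return(list(significant = FALSE, histogram = hist,
                binP95 = rep(NA_real_, nBins), preferredPhase = NA_real_,
                ppc = NA_real_, nSpikesUsed = 0L, phases = ph))
  }

  shuffHist <- matrix(0L, nShuffles, nBins)
  for (i in seq_len(nShuffles))
    shuffHist[i, ] <- phaseHistogram(maskedPhases(shuffleISI(times)), nBins)
  p95 <- apply(shuffHist, 2, stats::quantile, probs = 0.95, names = FALSE)

  above <- hist > p95
  sig <- any(above & c(above[-1], above[1])) # two consecutive, circular

  list(significant = sig, histogram = hist, binP95 = p95,
       preferredPhase = circMean(ph),
       ppc = if (length(ph) >= 2) pairwisePhaseConsistency(ph) else NA_real_,
       nSpikesUsed = length(ph), phases = ph)
}

#' Pairwise phase consistency
#'
#' PPC = (pi - 2 D)/pi where D is the mean absolute circular distance over
#' all spike pairs, D = 2/(N(N-1)) sum_{j<k} d(theta_j, theta_k) with d in
#' [0, pi]. PPC is 1 for identical phases, -1 for two antipodal phases, and
#' approaches 0 for uniform phases; it is invariant under global phase
#' rotation.
#'
#' @param phases numeric vector of spike phases, radians (N >= 2).
#' @return scalar PPC in [-1, 1].
#' @export
pairwisePhaseConsistency <- function(phases) {
  n <- length(phases)
  if (n < 2L) stop("need at least 2 phases")
  ## chunked pairwise mean absolute circular distance, O(N^2) work but
  ## bounded memory
  total <- 0
  chunk <- max(1L, floor(2e6 / n))
  for (s in seq(1L, n - 1L, by = chunk)) {
    rows <- s:min(s + chunk - 1L, n - 1L)
    d <- abs(outer(phases[rows], phases, "-")) %% (2 * pi)
    d <- pmin(d, 2 * pi - d)
    ## keep only j < k
    keep <- outer(rows, seq_len(n), "<")
    total <- total + sum(d[keep])
  }
  D <- 2 * total / (n * (n - 1))
  (pi - 2 * D) / pi
}

#' Rate-matched PPC by spike subsampling
#'
#' Mean PPC over `nIter` random subsamples of `nSub` spikes (without
#' replacement), controlling for the dependence of coupling estimates on
#' spike count. Units with fewer than `nSub` spikes are excluded (NA).
#'
#' @param phases spike phases, radians.
#' @param nSub subsample size (default 250).
#' @param nIter number of subsamples (default 100).
#' @param seed RNG seed.
#' @return mean PPC, or NA_real_ if fewer than `nSub` phases.
#' @export
ppcRateMatched <- function(phases, nSub = 250, nIter = 100, seed = NULL) {
  if (length(phases) < nSub) return(NA_real_)
  if (!is.null(seed)) set.seed(seed)
  mean(vapply(seq_len(nIter), function(i)
    pairwisePhaseConsistency(sample(phases, nSub)), numeric(1)))
}

#' Spike-triggered gamma-band LFP average
#'
#' Band-filters the LFP, extracts +-500 ms windows around each spike (spikes
#' closer than 500 ms to the edges are dropped), averages them, and measures
#' the envelope (absolute analytic signal of the average) in a 20 ms window
#' around the spike time. The same procedure on an equal number of uniformly
#' random trigger times gives the chance level.
#'
#' @param lfp a 1 kHz preprocessed [LFPChannel-class].
#' @param train spike times; at least `minSpikes` usable spikes required.
#' @param band frequency band, Hz (default high gamma, c(60, 90)).
#' @param minSpikes minimum usable spikes (default 1000); fewer returns NULL
#'   (exclusion), not an error.
#' @param seed RNG seed for the random triggers.
#' @return list with `avgTrace` (1001 samples, +-500 ms), `lockedAmplitude`,
#'   `randomAmplitude`, `nSpikes`, or NULL if excluded.
#' @export
spikeTriggeredGamma <- function(lfp, train, band = c(60, 90),
                                minSpikes = 1000, seed = NULL) {
  times <- spikeTimes(train)
  fs <- lfp@fs
  stopifnot(fs == 1000)
  n <- length(lfp@samples)
  half <- 500L
  usable <- times[times >= half / fs & times <= (n - half - 1) / fs]
  if (length(usable) < minSpikes) return(NULL)
  if (!is.null(seed)) set.seed(seed)

  ab <- bandpassHilbert(lfp, band)
  avgAt <- function(trig) {
    idx <- round(trig * fs) + 1L
    acc <- numeric(2L * half + 1L)
    for (i in idx) acc <- acc + ab$filtered[(i - half):(i + half)]
    acc / length(idx)
  }
  envCenter <- function(trace) {
    env <- Mod(analyticSignal(trace))
    mean(env[(half + 1L - 10L):(half + 1L + 10L)]) # +-10 ms window
  }
  avg <- avgAt(usable)
  randTrig <- stats::runif(length(usable), half / fs, (n - half - 1) / fs)
  list(avgTrace = avg, lockedAmplitude = envCenter(avg),
       randomAmplitude = envCenter(avgAt(randTrig)),
       nSpikes = length(usable))
}

#' Postsynaptically driven spike subset
#'
#' Retains the interneuron spikes that follow a spike of any connected
#' presynaptic pyramidal cell within `window` seconds (0 < lag <= window),
#' i.e. spikes plausibly evoked by local excitatory input.
#'
#' @param intTrain interneuron spike times.
#' @param pyrTrains list of presynaptic PYR spike-time vectors.
#' @param window maximal lag, seconds (default 0.002).
#' @return numeric vector: the retained INT spike times (possibly empty).
#' @export
presynConditionedSpikes <- function(intTrain, pyrTrains, window = 0.002) {
  s <- spikeTimes(intTrain)
  if (!is.list(pyrTrains)) pyrTrains <- list(pyrTrains)
  keep <- rep(FALSE, length(s))
  for (p in pyrTrains) {
    pt <- spikeTimes(p)
    if (!length(pt)) next
    ## spike s kept iff exists p with 0 < s - p <= window,
    ## i.e. p in [s - window, s)
    nBelow <- findInterval(s, pt, left.open = TRUE)
    nBelowLo <- findInterval(s - window, pt, left.open = TRUE)
    keep <- keep | (nBelow - nBelowLo) > 0
  }
  s[keep]
}
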
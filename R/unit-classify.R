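## Waveform-based PYR/INT classification and optogenetic tagging.
##
## Putative excitatory pyramidal cells (PYR) have broad spikes, putative
## fast-spiking interneurons (INT) narrow ones. Two waveform features are
## used: trough-to-peak duration and the asymmetry index (b - c)/(b + c)
## built from the positive peak amplitudes before (b) and after (c) the
## trough. ChR2-tagged parvalbumin interneurons (PVI) are identified by a
## rate increase during laser pulses exceeding an interspike-interval
## shuffle null.

#' Waveform features for unit classification
#'
#' Features are computed on the mean waveform of the peak channel, which is
#' assumed to be band-pass filtered already (0.3-6 kHz at acquisition).
#' Trough-to-peak is the time from the global minimum to the subsequent
#' maximum; the asymmetry index is (b - c)/(b + c) where b and c are the
#' maximum amplitudes before and after the trough.
#'
#' @param waveform numeric vector, mean waveform on the peak channel, or a
#'   [Unit-class] (its peak-channel waveform is used).
#' @param fs waveform sampling rate, Hz.
#' @return list with `troughToPeakMs` and `asymmetry`.
#' @export
waveformFeatures <- function(waveform, fs = 30000) {
  if (is(waveform, "Unit")) {
    fs <- waveform@waveformFs
    waveform <- waveform@meanWaveform[waveform@peakChannel, ]
  }
  w <- as.numeric(waveform)
  if (!length(w) || min(w) >= 0)
    stop("waveform has no negative deflection; cannot extract features")
  iTrough <- which.min(w)
  if (iTrough >= length(w))
    stop("waveform trough has no samples after it")
  after <- w[(iTrough + 1L):length(w)]
  iPeak <- iTrough + which.max(after)
  b <- if (iTrough > 1L) max(w[1:(iTrough - 1L)], 0) else 0
  cc <- max(after, 0)
  asym <- if (b + cc > 0) (b - cc) / (b + cc) else 0
  list(troughToPeakMs = (iPeak - iTrough) / fs * 1000, asymmetry = asym)
}

#' Classify units into PYR and INT by k-means on waveform features
#'
#' Two-cluster k-means in (trough-to-peak, asymmetry) space; features are
#' z-scored so the millisecond-scale duration does not dominate, and the
#' cluster with the shorter mean trough-to-peak duration is labelled INT.
#' Deterministic for a fixed seed, and invariant under unit reordering.
#'
#' @param features data.frame with columns `troughToPeakMs` and `asymmetry`
#'   (as from [waveformFeatures()]), or a list of such feature lists.
#' @param seed RNG seed for the k-means restarts.
#' @return character vector of labels, "PYR" or "INT".
#' @export
classifyUnits <- function(features, seed = 1L) {
  if (is.list(features) && !is.data.frame(features))
    features <- do.call(rbind, lapply(features, as.data.frame))
  X <- as.matrix(features[, c("troughToPeakMs", "asymmetry")])
  if (nrow(X) < 2L) stop("need at least 2 units to classify")
  if (any(apply(X, 2, stats::sd) == 0) && all(apply(X, 2, stats::sd) == 0))
    stop("degenerate features: all units identical")
  Xs <- scale(X)
  Xs[, apply(X, 2, stats::sd) == 0] <- 0
  set.seed(seed)
  ## order-invariance: k-means result depends only on the feature values via
  ## fixed deterministic starting centres (extreme durations), then Lloyd
  ## iterations; nstart on top for robustness
  init <- Xs[c(which.min(X[, 1]), which.max(X[, 1])), , drop = FALSE]
  km <- tryCatch(stats::kmeans(Xs, centers = init, iter.max = 100),
                 error = function(e) stats::kmeans(Xs, centers = 2,
                                                   nstart = 10, iter.max = 100))
  meansTP <- tapply(X[, 1], km$cluster, mean)
  intCluster <- as.integer(names(which.min(meansTP)))
  unname(ifelse(km$cluster == intCluster, "INT", "PYR"))
}

#' Optogenetic tagging by interspike-interval shuffling
#'
#' The firing rate in the last 25 ms of each light pulse (pulses are 50 ms)
#' is averaged over pulses and compared with the 99th percentile of the same
#' statistic computed on `nShuffles` surrogate trains obtained by shuffling
#' the interspike intervals (preserving first spike time and spike count).
#'
#' @param train spike times (vector, [SpikeTrain-class] or [Unit-class]).
#' @param pulses two-column matrix (onset s, duration s); durations default
#'   to 50 ms if a single onset vector is given.
#' @param nShuffles number of ISI shuffles for the null (default 1000).
#' @param duration session duration (s); pulses must fit inside it.
#' @param seed RNG seed.
#' @return list with `isTagged`, `lightRate` (Hz), `shuffleP99` (Hz),
#'   `nShuffles`.
#' @export
optoTag <- function(train, pulses, nShuffles = 1000, duration = NULL,
                    seed = NULL) {
  times <- spikeTimes(train)
  if (!length(times)) stop("empty spike train")
  if (is.null(dim(pulses))) pulses <- cbind(pulses, 0.05)
  if (!nrow(pulses)) stop("need at least one pulse")
  if (!is.null(duration) && any(pulses[, 1] + pulses[, 2] > duration))
    stop("laser pulses extend beyond the session")
  if (!is.null(seed)) set.seed(seed)
  winLo <- pulses[, 1] + pulses[, 2] - 0.025
  winHi <- pulses[, 1] + pulses[, 2]
  rateIn <- function(t) {
    mean(findInterval(winHi, t) - findInterval(winLo, t)) / 0.025
  }
  lightRate <- rateIn(times)
  shuffled <- vapply(seq_len(nShuffles),
                     function(i) rateIn(shuffleISI(times)), numeric(1))
  p99 <- stats::quantile(shuffled, 0.99, names = FALSE)
  list(isTagged = lightRate > p99, lightRate = lightRate,
       shuffleP99 = p99, nShuffles = nShuffles)
}

#' Laser-onset-triggered firing rate
#'
#' Gaussian-smoothed (SD 5 ms) firing rate averaged across laser pulses,
#' aligned to pulse onset.
#'
#' @param train spike times.
#' @param pulses pulse matrix as in [optoTag()].
#' @param kernelSD smoothing SD, seconds (default 0.005).
#' @param window c(before, after) around onset, seconds.
#' @param dt sample step of the returned trace, seconds.
#' @return data.frame with `time` (s relative to onset) and `rate` (Hz).
#' @export
laserPSTH <- function(train, pulses, kernelSD = 0.005,
                      window = c(-0.05, 0.1), dt = 0.001) {
  times <- spikeTimes(train)
  if (is.null(dim(pulses))) pulses <- cbind(pulses, 0.05)
  grid <- seq(window[1], window[2], by = dt)
  nb <- length(grid) - 1L
  acc <- numeric(nb)
  for (on in pulses[, 1]) {
    rel <- times - on
    rel <- rel[rel >= window[1] & rel < window[2]]
    acc <- acc + tabulate(floor((rel - window[1]) / dt) + 1L, nbins = nb)
  }
  rate <- convolveReflect(acc / nrow(pulses), gaussKernel(kernelSD / dt)) / dt
  data.frame(time = grid[-length(grid)] + dt / 2, rate = rate)
}
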
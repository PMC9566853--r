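## Monosynaptic PYR->INT connection detection from spike-train
## cross-correlograms (CCGs) and spike-transmission probability.
##
## A connection shows as a sharp CCG peak 0.8-2.8 ms after the presynaptic
## spike, exceeding (i) a slow baseline obtained by convolving the CCG with
## a partially hollowed Gaussian, and (ii) the count in the anticausal
## window (-2, 0] ms. Both excesses are assessed with a continuity-corrected
## Poisson tail probability.

CCG_BIN <- 4e-4   # 0.4 ms
CCG_MAXLAG <- 0.05

#' Spike-train cross-correlogram
#'
#' Counts spike pairs by lag (target minus reference) in half-open bins
#' (lo, hi] of `binWidth` seconds, with bin edges aligned to multiples of
#' the bin width over (-maxLag, +maxLag] so that the monosynaptic
#' (0.8, 2.8] ms and anticausal (-2, 0] ms windows coincide exactly with
#' bin boundaries. Positive lags are causal (reference fires first).
#'
#' @param ref reference (presynaptic) spike times.
#' @param tgt target (postsynaptic) spike times.
#' @param binWidth bin width, seconds (default 0.4 ms).
#' @param maxLag maximal lag, seconds (default 50 ms).
#' @return list of class `CCGResult` with `counts`, `lag` (bin centres, s),
#'   `binWidth`, `nRef`, `nTgt`, and `baseline` (NULL until computed).
#' @export
crossCorrelogram <- function(ref, tgt, binWidth = CCG_BIN,
                             maxLag = CCG_MAXLAG) {
  ref <- spikeTimes(ref)
  tgt <- spikeTimes(tgt)
  nb <- round(maxLag / binWidth) # bins per side
  counts <- integer(2L * nb)
  if (length(ref) && length(tgt)) {
    lo <- findInterval(ref - maxLag, tgt, left.open = FALSE)
    hi <- findInterval(ref + maxLag, tgt)
    nPer <- hi - lo
    sel <- nPer > 0L
    if (any(sel)) {
      tgtIdx <- sequence(nPer[sel], from = lo[sel] + 1L)
      lag <- tgt[tgtIdx] - rep(ref[sel], nPer[sel])
      ## half-open (lo, hi] bins: bin k covers ((k-1-nb)*bw, (k-nb)*bw]
      k <- ceiling(lag / binWidth - 1e-9) + nb
      k <- k[k >= 1L & k <= 2L * nb]
      counts <- tabulate(k, nbins = 2L * nb)
    }
  }
  structure(list(counts = counts,
                 lag = (seq_len(2L * nb) - nb - 0.5) * binWidth,
                 binWidth = binWidth, maxLag = maxLag,
                 nRef = length(ref), nTgt = length(tgt), baseline = NULL),
            class = "CCGResult")
}

#' Hollowed-Gaussian CCG baseline
#'
#' Convolves the raw CCG with a Gaussian kernel (SD 10 ms) whose centre
#' weight is multiplied by (1 - hollowFraction) and which is renormalized to
#' sum 1; the hollow prevents a monosynaptic peak from inflating its own
#' baseline while slow co-modulation of the two rates is tracked. Edges are
#' reflect-padded.
#'
#' @param ccg a `CCGResult` from [crossCorrelogram()].
#' @param hollowFraction fraction of the centre weight removed (default 0.6).
#' @param sdSec kernel SD in seconds (default 0.010).
#' @return the `CCGResult` with `baseline` filled in.
#' @export
hollowGaussianBaseline <- function(ccg, hollowFraction = 0.6, sdSec = 0.010) {
  k <- hollowGaussianKernel(sdSec / ccg$binWidth, hollowFraction)
  ccg$baseline <- convolveReflect(ccg$counts, k)
  ccg
}

## Gaussian kernel with partially removed centre weight, sum 1.
hollowGaussianKernel <- function(sdBins, hollowFraction) {
  half <- ceiling(5 * sdBins)
  k <- stats::dnorm(seq(-half, half), sd = sdBins)
  k[half + 1L] <- k[half + 1L] * (1 - hollowFraction)
  k / sum(k)
}

## Continuity-corrected Poisson upper-tail probability that a count of n
## would be observed at mean mu:
##   P = 1 - sum_{x=0}^{n-1} pois(x; mu) - 0.5 * pois(n; mu)
poissonTailCC <- function(n, mu) {
  if (!is.finite(n) || !is.finite(mu)) stop("non-finite count or mean")
  p <- 1 - stats::ppois(n - 1, mu) - 0.5 * stats::dpois(n, mu)
  min(max(p, 0), 1)
}

## Indices of the CCG bins making up a half-open (lo, hi] lag window.
windowBins <- function(ccg, lo, hi) {
  which(ccg$lag > lo & ccg$lag < hi)
}

#' Test a CCG for a monosynaptic connection
#'
#' `pSyn` is the continuity-corrected Poisson tail probability of the summed
#' counts n in the causal window given the summed hollowed-Gaussian baseline
#' b_m; `pCausal` is the same with the summed anticausal counts as the
#' Poisson mean. The pair is connected when pSyn < 0.001 and
#' pCausal < 0.0026.
#'
#' @param ccg a `CCGResult` with baseline (computed if absent).
#' @param windowCausal causal (monosynaptic) lag window, seconds,
#'   default c(0.0008, 0.0028], half-open.
#' @param windowAnticausal anticausal window, default c(-0.002, 0].
#' @param alphaSyn,alphaCausal detection thresholds (defaults 0.001, 0.0026).
#' @param aggregate "sum" (default) or "max": how counts/baseline are
#'   aggregated within each window.
#' @return list of class `ConnectionResult` with `pSyn`, `pCausal`,
#'   `connected`, `transmissionProb`, `n`, `bM`, `cAnticausal`, `nRef`.
#' @export
connectionTest <- function(ccg, windowCausal = c(0.0008, 0.0028),
                           windowAnticausal = c(-0.002, 0),
                           alphaSyn = 0.001, alphaCausal = 0.0026,
                           aggregate = c("sum", "max")) {
  aggregate <- match.arg(aggregate)
  if (is.null(ccg$baseline)) ccg <- hollowGaussianBaseline(ccg)
  agg <- if (aggregate == "sum") sum else max
  ic <- windowBins(ccg, windowCausal[1], windowCausal[2])
  ia <- windowBins(ccg, windowAnticausal[1], windowAnticausal[2])
  n <- agg(ccg$counts[ic])
  bM <- agg(ccg$baseline[ic])
  cAnti <- agg(ccg$counts[ia])
  pSyn <- poissonTailCC(n, bM)
  pCausal <- poissonTailCC(n, cAnti)
  structure(list(pSyn = pSyn, pCausal = pCausal,
                 connected = pSyn < alphaSyn && pCausal < alphaCausal,
                 transmissionProb = spikeTransmissionProbability(
                   ccg, windowCausal),
                 n = n, bM = bM, cAnticausal = cAnti, nRef = ccg$nRef,
                 windowCausal = windowCausal,
                 windowAnticausal = windowAnticausal),
            class = "ConnectionResult")
}

#' Spike-transmission probability
#'
#' Excess of the CCG over the hollowed-Gaussian baseline in the monosynaptic
#' window, per presynaptic spike:
#' sum_{causal bins} (counts - baseline) / nRef. Not clipped at zero;
#' sub-baseline pairs give negative values.
#'
#' @param ccg a `CCGResult` with baseline (computed if absent).
#' @param windowCausal causal window, seconds.
#' @return scalar transmission probability.
#' @export
spikeTransmissionProbability <- function(ccg,
                                         windowCausal = c(0.0008, 0.0028)) {
  if (is.null(ccg$baseline)) ccg <- hollowGaussianBaseline(ccg)
  if (ccg$nRef == 0) stop("no presynaptic spikes")
  ic <- windowBins(ccg, windowCausal[1], windowCausal[2])
  sum(ccg$counts[ic] - ccg$baseline[ic]) / ccg$nRef
}

#' Detect monosynaptic PYR->INT connections in a session
#'
#' Tests every ordered PYR->INT pair whose two units both fired at least
#' `minSpikes` spikes; pairs below the threshold are recorded as untested.
#'
#' @param session a [Session-class] with labelled units, or a list of
#'   spike-time vectors if `pyr`/`int` index vectors are given.
#' @param minSpikes minimum spikes per unit (default 500).
#' @param pyr,int optional integer indices overriding the session labels
#'   (PVI units count as INT by default).
#' @param ... passed to [connectionTest()].
#' @return data.frame with one row per PYR-INT pair: `pyr`, `int`, `tested`,
#'   `pSyn`, `pCausal`, `connected`, `transmissionProb`, `distanceUm`.
#' @export
detectConnections <- function(session, minSpikes = 500, pyr = NULL,
                              int = NULL, ...) {
  if (is(session, "Session")) {
    trains <- lapply(session@units, spikeTimes)
    labs <- unitLabels(session)
    if (is.null(pyr)) pyr <- which(labs == "PYR")
    if (is.null(int)) int <- which(labs %in% c("INT", "PVI"))
    sessionUnitsList <- session@units
  } else {
    trains <- lapply(session, spikeTimes)
    sessionUnitsList <- NULL
  }
  if (!length(pyr) || !length(int))
    return(data.frame(pyr = integer(), int = integer(), tested = logical(),
                      pSyn = numeric(), pCausal = numeric(),
                      connected = logical(), transmissionProb = numeric(),
                      distanceUm = numeric()))
  grid <- expand.grid(pyr = pyr, int = int)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    p <- grid$pyr[i]; q <- grid$int[i]
    if (length(trains[[p]]) < minSpikes || length(trains[[q]]) < minSpikes)
      return(data.frame(pyr = p, int = q, tested = FALSE, pSyn = NA_real_,
                        pCausal = NA_real_, connected = FALSE,
                        transmissionProb = NA_real_, distanceUm = NA_real_))
    ccg <- hollowGaussianBaseline(crossCorrelogram(trains[[p]], trains[[q]]))
    ct <- connectionTest(ccg, ...)
    d <- if (!is.null(sessionUnitsList))
      tryCatch(intersomaticDistance(sessionUnitsList[[p]],
                                    sessionUnitsList[[q]]),
               error = function(e) NA_real_)
    else NA_real_
    data.frame(pyr = p, int = q, tested = TRUE, pSyn = ct$pSyn,
               pCausal = ct$pCausal, connected = ct$connected,
               transmissionProb = ct$transmissionProb, distanceUm = d)
  })
  do.call(rbind, res)
}

#' Intersomatic distance between two units
#'
#' Euclidean distance between the probe coordinates of the two units' peak
#' channels (the channel with the largest negative waveform deflection
#' approximates the soma location).
#'
#' @param unitA,unitB [Unit-class] objects with channel positions.
#' @return distance in micrometres.
#' @export
intersomaticDistance <- function(unitA, unitB) {
  if (!nrow(unitA@channelPositions) || !nrow(unitB@channelPositions))
    stop("channel positions missing; unit excluded from distance analysis")
  a <- unitA@channelPositions[unitA@peakChannel, ]
  b <- unitB@channelPositions[unitB@peakChannel, ]
  sqrt(sum((a - b)^2))
}

#' Convergence and divergence of detected connections
#'
#' @param connections data.frame from [detectConnections()].
#' @return list with `convergence` (named count of presynaptic partners per
#'   INT) and `divergence` (postsynaptic partners per PYR), over connected
#'   pairs only.
#' @export
convergenceDivergence <- function(connections) {
  con <- connections[which(connections$connected), , drop = FALSE]
  list(convergence = if (nrow(con)) table(factor(con$int)) else table(integer()),
       divergence = if (nrow(con)) table(factor(con$pyr)) else table(integer()))
}
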
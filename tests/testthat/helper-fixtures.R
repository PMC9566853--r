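# Shared fixtures: all synthetic, generated in code at test time.

poissonSpikes <- function(rate, duration, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sort(runif(rpois(1, rate * duration), 0, duration))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Minimal hand-built session: two units with waveforms, one LFP channel,
# laser pulses, metadata.
tinySession <- function(seed = 1) {
  set.seed(seed)
  wfA <- spikecircuit:::makeWaveform(0.7, 0.3, nChannels = 4, peakChannel = 2)
  wfB <- spikecircuit:::makeWaveform(0.25, -0.2, nChannels = 4, peakChannel = 3)
  pos <- cbind(0, (0:3) * 20)
  Session(
    units = list(
      Unit(SpikeTrain("a", poissonSpikes(5, 60)), meanWaveform = wfA,
           peakChannel = 2L, channelPositions = pos, label = "PYR"),
      Unit(SpikeTrain("b", poissonSpikes(10, 60)), meanWaveform = wfB,
           peakChannel = 3L, channelPositions = pos, label = "INT")),
    lfp = list(LFPChannel(rnorm(60 * 1000), fs = 1000, channelId = "ch1")),
    laserPulses = cbind(c(5, 15, 25), 0.05),
    duration = 60, group = "ctrl",
    metadata = list(mouse = "m01", probe = "silicon")
  )
}

# Construct a CCGResult with prescribed causal/anticausal window contents,
# bypassing spike trains (for closed-form tests of the Poisson stage).
mockCCG <- function(nCausal, bCausal, nAnti, nRef = 1000,
                    binWidth = 4e-4, maxLag = 0.05) {
  nb <- round(maxLag / binWidth)
  counts <- integer(2 * nb)
  baseline <- rep(bCausal / 5, 2 * nb)
  lag <- (seq_len(2 * nb) - nb - 0.5) * binWidth
  causal <- lag > 0.0008 & lag < 0.0028
  anti <- lag > -0.002 & lag < 0
  counts[causal] <- diff(round(seq(0, nCausal, length.out = 6)))
  counts[anti] <- diff(round(seq(0, nAnti, length.out = 6)))
  structure(list(counts = counts, lag = lag, binWidth = binWidth,
                 maxLag = maxLag, nRef = nRef, nTgt = 1000,
                 baseline = baseline),
            class = "CCGResult")
}
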
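# spikecircuit

Circuit-level analysis of simultaneously recorded cortical single units and
local field potentials (LFPs), for electrophysiologists studying how
fast-spiking interneurons (INTs) are driven by local pyramidal cells (PYRs)
and how that shapes gamma oscillations and population coactivation.

The package implements, as one tested chain:

- **Cell-type classification** — 2-means clustering on trough-to-peak
  duration and waveform asymmetry `(b − c)/(b + c)`; **optogenetic
  tagging** of ChR2-expressing units against an interspike-interval-shuffle
  null (99th percentile, 1000 shuffles).
- **Spectral analysis** — Welch PSD of 1 kHz z-scored LFP (1 s windows
  zero-padded to 10 s), mean band power (theta 6–12, low gamma 20–40, high
  gamma 60–90 Hz), zero-phase Butterworth band-passing with analytic-signal
  phase/amplitude.
- **Spike–gamma coupling** — 18-bin phase histograms restricted to
  high-amplitude epochs (>80th percentile envelope), significance from ≥2
  consecutive bins above the 95th percentile of 500 ISI shuffles, coupling
  depth as pairwise phase consistency `PPC = (π − 2D)/π` with a
  rate-matched (250 spikes × 100 subsamples) variant, and spike-triggered
  gamma averages.
- **Monosynaptic PYR→INT detection** — cross-correlograms (0.4 ms bins,
  ±50 ms, ≥500 spikes per unit), hollowed-Gaussian baseline (hollow
  fraction 0.6, SD 10 ms), continuity-corrected Poisson tests on the
  (0.8, 2.8] ms causal and (−2, 0] ms anticausal windows
  (connected ⇔ `P_syn < 0.001` and `P_causal < 0.0026`), and
  **spike-transmission probability** = baseline-corrected causal excess per
  presynaptic spike:

  `P_syn = 1 − Σ_{x<n} e^{−b} b^x / x! − ½ e^{−b} b^n / n!`

- **Synchrony & resonance** — 25 ms coincidence index normalized by chance,
  INT–INT zero-lag synchrony, and spike-transmission gain for presynaptic
  spikes preceded by postsynaptic firing in the 20–50 ms resonance window.
- **Cell assemblies** — 25 ms binned, z-scored PYR matrices; pattern count
  from correlation eigenvalues above the Marčenko–Pastur limit
  `l = (1 + √(1/q))²`, weights from ICA in the significant subspace,
  activation strength `A(t) = Z(t)ᵀ P Z(t)` (zero-diagonal projector,
  threshold 5), event rates, reactivation across recording halves.
- **Group statistics** — the Welch / Student / Mann–Whitney selection
  logic, a circular permutation test for preferred phases, rate tertiles,
  and `runPipeline()` orchestration with per-session (mouse) averages.
- **A synthetic-session generator** (`generateSession()`) that plants known
  ground truth for every stage: waveform clusters, lognormal Poisson rates,
  von Mises gamma locking, monosynaptic connections at 0.8–2.8 ms latency
  with optional resonance gain, assembly coactivations, and laser-driven
  tagged units — so the whole chain is verifiable without any recordings.

## Worked example

```r
library(spikecircuit)

cfg <- syntheticConfig(
  nPyr = 20, nInt = 5, duration = 1200,
  pyrRate = list(meanlog = log(2), sdlog = 0.3),
  connections = data.frame(pyr = 1:10, int = rep(1:5, 2), pTrans = 0.05),
  gammaAmplitude = 0, comodAmp = 0.2, seed = 43)
gs <- generateSession(cfg)

s <- gs$session
unitLabels(s) <- gs$truth$labels
conns <- detectConnections(s)
subset(conns, connected)[1:3, c("pyr", "int", "pSyn", "transmissionProb")]
#>    pyr int pSyn transmissionProb
#> 1    1  21    0       0.05231125
#> 6    6  21    0       0.04391099
#> 22   2  22    0       0.04659889
mean(subset(conns, connected)$transmissionProb)
#> [1] 0.04627524
```

All 10 planted connections are recovered among the 100 tested PYR–INT
pairs (each `pSyn` underflows well below the 0.001 threshold) and the mean
estimated spike-transmission probability, 0.046, matches the planted 0.05
to within the estimator's known small downward bias. On a matched null
session (no planted connections) the same screen tests ~100 pairs and
flags none (see `scripts/acceptance.R`).

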
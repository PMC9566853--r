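---
title: "Methods: circuit inference from spike trains and field potentials"
author: "spikecircuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circuit inference from spike trains and field potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`spikecircuit` implements a complete analysis chain for simultaneously
recorded cortical single units and local field potentials (LFPs): cell-type
classification, optogenetic tagging, gamma-band spectral and spike-phase
analysis, monosynaptic connection detection with spike-transmission
probability, presynaptic synchrony and resonance, and cell-assembly
detection. This vignette documents the models, the parameters that matter,
the numerical choices made where the methodology was genuinely open, and
what the synthetic-session validation does and does not demonstrate.

## Data model

A `Session` holds `Unit`s (spike times in seconds, mean waveforms with
probe geometry) and `LFPChannel`s, plus optional laser pulses and a group
label. Spike times must be strictly increasing; duplicated timestamps are
rejected at load rather than silently deduplicated, because they almost
always indicate an upstream sorting error. All intervals are half-open
`[a, b)` and a spike on a bin edge belongs to the later bin, which removes
double-counting ambiguity in every binned quantity. Session bundles are
plain-text (JSON metadata, TSV tables for spikes, waveforms, LFP, laser
pulses) so they remain inspectable with standard command-line tools.

## Unit classification and tagging

Putative pyramidal cells (PYR) and fast-spiking interneurons (INT) are
separated by 2-means clustering on two waveform features measured on the
peak channel (the channel with the largest negative deflection): the
trough-to-peak duration (global minimum to subsequent maximum) and the
asymmetry index $(b-c)/(b+c)$, where $b$ and $c$ are the maximal positive
amplitudes before and after the trough, measured up to the waveform edges.
Features are z-scored before clustering so the millisecond-scale duration
does not dominate the dimensionless asymmetry; the cluster with the shorter
mean trough-to-peak duration is labelled INT. Cluster starts are placed on
the units with extreme durations, making labels deterministic and invariant
to unit order. Waveforms are assumed band-pass filtered at acquisition
(0.3–6 kHz); the feature extractor does not re-filter.

Optogenetic tagging of parvalbumin-positive interneurons (PVI) compares the
firing rate in the last 25 ms of each 50 ms light pulse against the 99th
percentile of the same statistic on 1000 surrogate trains obtained by
shuffling interspike intervals. The shuffle preserves the first spike time
and the total count, so the null conserves the unit's rate and ISI
distribution while destroying pulse alignment. Calibration on unmodulated
Poisson units reproduces the nominal ~1% false-positive rate.

## Spectral analysis and spike–gamma coupling

LFPs are anti-alias filtered, resampled to 1 kHz, and z-scored. Power
spectral density uses Welch averaging with 1 s Hann windows, 50% overlap,
and zero-padding to a 10 s grid (0.1 Hz resolution); density scaling is the
only normalization, so the PSD of the z-scored trace integrates to 1
(verified to 5% on white noise). Band power is the *mean* density over the
band — theta 6–12 Hz, low gamma 20–40 Hz, high gamma 60–90 Hz — rather than
the integral, so values are comparable across bands of different width.
Band-limited signals use a 4th-order Butterworth filter applied
forward–backward (zero phase, so spike–phase relations are not lag-biased)
followed by the FFT analytic signal. Phase convention: 0 rad at the
oscillation peak, ±π at the trough. Mains frequency (50 Hz) is not excised
from band averages; both gamma bands avoid it by construction.

Spike–gamma coupling is evaluated only where the band envelope exceeds its
80th percentile (computed per analyzed channel). The 18-bin spike-phase
histogram is compared per bin against the 95th percentile of 500
ISI-shuffled surrogates (the amplitude mask recomputed identically for each
surrogate); a unit is significantly coupled when at least two *circularly*
consecutive bins exceed their percentile — bins 18 and 1 are adjacent,
since phase is circular. This compound criterion has an empirical
false-positive rate of roughly 5–10%, which the test suite bounds by Monte
Carlo. Note one conservative edge case: if every spike falls into a single
phase bin, the two-consecutive-bin rule cannot fire by construction.

Coupling depth uses the pairwise phase consistency,
$\mathrm{PPC} = (\pi - 2D)/\pi$ with $D$ the mean absolute circular
distance over all spike pairs. PPC is 1 for identical phases, −1 for two
antipodal ones, ~0 for uniform phases, and is invariant under global phase
rotation. Because coupling estimates depend on spike count, a rate-matched
variant averages PPC over 100 subsamples of 250 spikes; units with fewer
than 250 spikes are excluded rather than reported.

Spike-triggered gamma analysis averages the band-filtered LFP in ±500 ms
windows around each spike of units with at least 1000 usable spikes and
measures the envelope of the average in a 20 ms window around the trigger;
count-matched uniformly random triggers give the chance level.

## Monosynaptic connections and spike transmission

Cross-correlograms (CCGs) use 0.4 ms bins to ±50 ms, computed for all
ordered PYR→INT pairs in which both units fired at least 500 spikes.
Bins are half-open `(lo, hi]` with edges aligned to multiples of the bin
width, so the monosynaptic window (0.8, 2.8] ms and the anticausal window
(−2, 0] ms each cover exactly five bins; lag 0 is a bin edge. (A
zero-*centred* bin grid cannot align with these windows — its edges fall on
odd multiples of 0.2 ms — so edge alignment was chosen.)

The slow baseline $b$ is the CCG convolved with a partially hollowed
Gaussian (SD 10 ms = 25 bins, centre weight × 0.4, kernel renormalized to
sum 1, reflect-padded edges so the baseline does not droop at ±50 ms). The
hollow prevents a genuine monosynaptic peak from inflating its own
baseline; the wide Gaussian tracks slow co-modulation of the two rates.

Significance uses the continuity-corrected Poisson tail,
$$P = 1 - \sum_{x=0}^{n-1} \frac{e^{-\lambda}\lambda^x}{x!}
      - \tfrac12 \frac{e^{-\lambda}\lambda^n}{n!},$$
applied twice: $P_{syn}$ with $n$ the summed causal-window count and
$\lambda$ the summed baseline, and $P_{causal}$ with $\lambda$ the summed
anticausal count (the two windows have equal width, so the counts are
directly comparable). Summation over window bins is the default
aggregation; a max-bin variant is available via the `aggregate` argument.
A pair is connected when $P_{syn} < 0.001$ and $P_{causal} < 0.0026$.
Spike-transmission probability is the causal-window excess over baseline
per presynaptic spike; it is deliberately not clipped at zero, so
sub-baseline pairs report negative values. On synthetic sessions with
planted connections the estimator recovers transmission with a small
(≲10%) downward bias, because the peak's own bins contribute to their
neighbours' baseline through the non-hollowed kernel taps and because
evoked spikes colliding with the postsynaptic refractory period are lost;
both effects shrink with window/kernel width ratio and are well inside the
20% recovery tolerance used in validation.

Intersomatic distance is the Euclidean distance between peak-channel
coordinates. Convergence (presynaptic partners per INT) and divergence
(postsynaptic partners per PYR) are counted over connected pairs only.

## Synchrony and resonance

The coincidence index counts comparison spikes within ±25 ms of each
reference spike and divides by the chance expectation
$2 f_{cmp} \cdot w \cdot n_{ref}$. Pair counting (rather than flagging each
reference spike once) is used deliberately: the chance term is an expected
pair count, and only pair counting makes the index converge to 1 for
independent stationary trains at any rate.

Resonance analysis isolates presynaptic spikes preceded by a postsynaptic
spike 20–50 ms earlier with neither unit firing in the final 20 ms gap.
Spike transmission for this subset uses the chance rate taken from the
*full-train* baseline scaled per presynaptic spike: the selection empties
the subset CCG at (−20, 0] ms by construction, and a baseline convolved
from the subset CCG itself would be dragged down near the monosynaptic
window (about 40% of the 10 ms kernel's mass falls in the emptied region),
inflating the apparent gain. Two gain figures are reported: the
conventional resonance/all ratio, and resonance/non-resonance. The former
is structurally diluted toward 1 — a true boost $g$ measures as
$g / (1 + (g-1)f)$ when a fraction $f$ of presynaptic spikes qualify as
resonance spikes ($f \approx 0.24$ at a 15 Hz postsynaptic rate) — while
the latter estimates the underlying boost without dilution and is the
quantity used for parameter-recovery validation. A minimum of 50 resonance
spikes is required before a gain is reported (variance control;
configurable).

INT–INT zero-lag synchrony is the mean CCG (1 ms bins, ±100 ms) in the
10 ms window around zero minus the mean over the −100 to −50 ms baseline
window.

## Cell assemblies

PYR spike trains (sessions with ≥10 PYRs) are binned at 25 ms and z-scored.
The number of assembly patterns is the number of correlation-matrix
eigenvalues above the Marčenko–Pastur upper edge
$l = (1 + \sqrt{1/q})^2$, $q = N_{bins}/N_{neurons}$. (The lower edge
$(1-\sqrt{1/q})^2$ cannot bound *excess* correlation, so the upper edge is
the only reading consistent with counting eigenvalues *above* a critical
limit.) That many independent components are then extracted from the data
projected into the significant eigenspace, using deflation-mode FastICA
(logcosh contrast, tolerance 1e-4, ≤1000 iterations, seeded
initialization); components are unit-normalized, oriented so the
largest-magnitude weight is positive, and ordered by explained variance.
Members are neurons whose weight exceeds 2 SD of the pattern vector.
Zero-variance neurons are dropped with a warning before z-scoring.

Activation strength over time is $A(t) = Z(t)^\top P Z(t)$, where $Z$ is
the spike matrix binned at 1 ms, smoothed with a Gaussian of
SD $= 25/\sqrt{12} \approx 7.2$ ms (variance-matched to the 25 ms
detection bin) and z-scored, and $P = ww^\top$ with the diagonal zeroed so
isolated single-neuron firing cannot produce activations (a
`keepDiagonal` switch restores the plain projector). Events are upward
crossings of $A(t) = 5$; event rate uses crossings, mean event strength
averages all above-threshold samples — the two statistics deliberately
follow different definitions because they answer different questions (how
often vs how strongly). Reactivation detects patterns on the first half of
a recording and reports the ratio of above-threshold mean strength in the
second half to the first.

At ordinary pyramidal rates, chance pairwise coactivations of member
neurons also cross the threshold (they are genuine activations of the
pattern, just not planted ones), so the planted event *rate* is validated
in a low-base-rate regime (~0.4 Hz members), while pattern counts,
memberships, stationarity, and member co-firing are validated at the
default study-scale conditions.

## The synthetic-session generator

`generateSession()` is a first-class, tested module, not a fixture. Its
defaults emulate a downscaled cortical recording: 40 PYRs and 8 INTs for
20 minutes; lognormal rate distributions (medians ~1.2 Hz for PYR, ~12 Hz
for INT); an LFP made of pink (1/f) noise, a theta component, and a 70 Hz
gamma oscillation whose amplitude is modulated at 1 Hz so the
80th-percentile amplitude mask is non-trivial. INTs can be von
Mises-locked to the gamma phase (inhomogeneous Poisson by thinning);
monosynaptic connections add postsynaptic spikes per presynaptic spike
with probability `pTrans` at normal latencies truncated to (0.8, 2.8] ms,
respecting a 1 ms postsynaptic refractory period, with an optional
resonance multiplier applied when the postsynaptic unit fired 20–50 ms
earlier; assemblies inject member coactivations inside 25 ms windows at
Poisson event times; laser pulses multiply the rates of tagged units.
Base spiking is homogeneous Poisson, with an optional shared slow rate
co-modulation (default fractional amplitude 0.2 in the validation
sessions) to exercise the hollowed-baseline correction. Everything is
reproducible bit-for-bit from the config seed.

What the generator does **not** emulate: refractory/bursting ISI structure
of real units, non-stationary behavioral state changes, spike-sorting
contamination, electrode drift, volume conduction, or cross-frequency
coupling. Passing the validation suite therefore demonstrates that the
estimators recover their targets under the stated point-process model —
not that the pipeline is robust to every pathology of real extracellular
data.

## Group statistics

Two-group comparisons use Welch's t-test when both groups have >30
observations; otherwise Student's or Welch's t-test (chosen by an SD ratio
≤ 1.5, a criterion the methodology left unspecified) when both samples
pass Shapiro–Wilk normality at α = 0.05, and a two-sided Mann–Whitney
U-test otherwise. Preferred-phase differences use a two-sample permutation
test on the circular distance between group circular means (10,000 pooled
re-splits); the p-value is the conventional
$(1 + \#\{d_{perm} \ge d_{obs}\})/(N+1)$ — the literal "count how often
the observed distance is larger" direction is significance-inverted and
only available behind a flag. Firing-rate tertiles take the lowest/highest
⌊n/3⌋ units by rank with stable tie-breaking. `runPipeline()` chains all
stages over a list of sessions, aggregates one value per session (mouse
averages), and compares groups per endpoint.

## Problem sizes used in validation

The shipped validation runs use sessions of 5–20 minutes with 12–30 PYRs
and 2–6 INTs, 100-pair null screens for connection false positives,
100-unit nulls for tagging, and 100 simulated populations for the
Marčenko–Pastur containment check — sizes at which every recovery
tolerance stated above is comfortably resolvable while the whole suite
runs in a few minutes on one core.
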
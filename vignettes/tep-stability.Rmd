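---
title: "Quantifying TMS-evoked potential stability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying TMS-evoked potential stability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Transcranial magnetic stimulation with simultaneous EEG (TMS–EEG) measures
cortical excitability by averaging the EEG response to many stimulator
pulses into a TMS-evoked potential (TEP). Every additional pulse improves
the signal-to-noise ratio of the average but lengthens the session — a real
cost in populations with limited tolerance, such as children with epilepsy.
`tepstab` implements a within-block *stability* analysis that asks: how many
pulses are enough before the average stops changing?

The logic is:

1. Average **all** pulses of a block into a *gold-standard* TEP.
2. Build *candidate* TEPs from growing pulse subsets — starting at 10 pulses
   and adding 5 at a time (consecutively, or in seeded random order to probe
   entrainment effects).
3. Score each candidate against the gold standard with Lin's concordance
   correlation coefficient (CCC),
   \[
   \mathrm{CCC}(x,y) \;=\;
   \frac{2\,\sigma_{xy}}{\sigma_x^2+\sigma_y^2+(\mu_x-\mu_y)^2},
   \]
   with population ($1/n$) moments. Unlike a Pearson correlation, the CCC
   penalizes differences in both location and scale, so it measures
   *agreement* of waveforms, not just similarity of shape.
4. The **minimum number of pulses (MNP)** is the smallest grid count whose
   CCC — and the CCC of *every larger* candidate — exceeds 0.8. The suffix
   condition guards against "local minima" where an early candidate crosses
   the threshold by chance and a later one falls back below it. When no
   grid count satisfies it, the result carries `attained = FALSE` rather
   than being silently assigned the block size.

Stability is assessed for two summary waveforms and two windows:

* **local TEP** — the mean of the five electrodes overlying the stimulated
  motor hotspot (C3, C1, C5, FC3, CP3 on the left; C4, C2, C6, FC4, CP4 on
  the right);
* **GMFA** — the global mean field amplitude, the spatial standard
  deviation of voltage across all good channels at each time point
  (population $1/K$ denominator — the classic global field power
  convention; the amplitude rather than squared-power variant);
* **early** window, 15–80 ms, and **late** window, 80–350 ms. The shared
  80 ms boundary belongs to the late window only (half-open early window),
  so the two windows tile 15–350 ms without double counting.

## Preprocessing chain

Raw epochs (−1000..1500 ms around each pulse) pass through a fixed,
logged, side-effect-free chain:

interpolate pulse artifact → resample to 1 kHz → baseline-correct
(−500..−10 ms) → high-pass 1 Hz → detect bad channels → *artifact hook* →
bandstop 58–62 Hz → reject bad trials → low-pass 200 Hz → common average
reference.

Numerical choices, with reasons:

* **Pulse-artifact interpolation** (−2..12 ms, half-open: the sample at
  exactly 12 ms is real data). Per trial and channel, autoregressive models
  are fitted by least squares (with intercept) to 20 ms of data on each
  side and extrapolated forward/backward across the window; the two
  extrapolations are blended by a linear cross-fade. The AR order defaults
  to 30 but is clipped to a third of the fitted sample count so the
  regression stays overdetermined — near-square fits extrapolate
  explosively on noisy segments. Rank-deficient designs (constants, ramps,
  pure sinusoids) are resolved by pivoted least squares with unused
  coefficients zeroed, which reproduces exact linear recurrences exactly —
  hence the unit guarantees that constants and ramps pass through
  unchanged. Non-finite or implausibly large extrapolations (beyond 10× the
  local data range) fall back to a linear bridge, logged.
* **Filters** are even-order Butterworth designs (zpk → bilinear transform
  → second-order sections, implemented in the package and verified against
  an independent reference implementation during development) applied
  forward and backward (`sosfiltfilt`): zero phase, squared magnitude.
  Epochs are extended by odd reflection with steady-state initial
  conditions so post-stimulus response does not smear into the
  pre-stimulus period through startup transients. Only the line-noise
  notch is conventionally a Butterworth design; we use Butterworth
  uniformly (order 4 one-pass) for simplicity.
* **Resampling** is anti-aliased integer-factor decimation (order-8
  zero-phase low-pass at 0.4× the target rate). Restricting to integer
  factors keeps the sample grid aligned with millisecond latencies.
* **Bad channels** are detected by robust statistics: a channel is flagged
  when its log noise power or its `1 − median` correlation with the other
  channels' average waveforms is a robust-z outlier (threshold 5), or when
  it is flat relative to the others. Both statistics are computed over the
  pre-stimulus baseline, where only noise lives — otherwise a strong
  evoked topography masquerades as excess power, and evoked-poor distal
  channels as "uncorrelated", whenever the SNR is high. More than 20% flagged raises a data-quality
  error. This is a deliberately simplified, reproducible substitute for
  published noise-estimation algorithms (Wiener-estimator channel
  rejection, SOUND, ICA component classification), which are third-party
  contributions outside this package's scope; an `artifact_hook` keeps
  their pipeline slot open; multiverse comparisons of TMS–EEG pipelines
  report MNP estimates insensitive to the preprocessing chain chosen,
  which is why a simplified chain is a defensible substitute here.
* **Trial rejection** replaces visual inspection with an absolute-amplitude
  criterion: any good-channel sample outside the pulse window beyond
  300 µV (configurable) flags the trial. Visual inspection is not
  reproducible; an amplitude rule is, and the generator's movement
  artifacts are injected well above the threshold so the rule's recall is
  testable exactly.
* **Candidate preprocessing** has two modes. `per_subset` preprocesses each
  pulse subset independently, faithfully mimicking an experiment that
  collected fewer pulses (the default). `subset_only` preprocesses the
  block once and sub-averages, which is much faster and gives the exact
  guarantee that the final grid point equals the gold standard (CCC = 1);
  oracle tests and large simulations use it. Pulse counts refer to pulses
  *delivered* (subset size before trial rejection); retained counts are
  recorded in provenance.

## The synthetic cohort

The emulated study's clinical recordings are not public, so the package ships a
generator whose defaults state a world resembling the recordings it
emulates: 100-pulse blocks, −1000..1500 ms epochs, a 64-channel 10-10
montage, and a pediatric evoked template dominated by a lateralized
N100-like deflection (P30-like +3 µV, N45-like −4 µV, N100-like −12 µV,
P180-like +6 µV; Gaussian peaks with Gaussian spatial decay over schematic
2-D scalp distance). Peak magnitudes are free parameters — no per-subject amplitudes or
noise spectra are published for the emulated cohort — chosen so the N100 is
at least twice any early peak, matching the reported morphology.

Noise and artifacts: band-limited (0.5–200 Hz) $1/f$ background with
analytically normalized time-domain SD (default 6 µV — a mid-range value;
nothing published calibrates it), 60 Hz line noise, a decaying pulse
artifact inside −2..12 ms, a damped 90 Hz muscle transient inside
11–30 ms, and occasional (p = 0.04, matching the reported ~4 contaminated
trials per 100) movement bursts of 1000 µV. Movement is modeled as a
Gaussian-windowed 3 Hz burst rather than sub-1 Hz drift: the chain's 1 Hz
high-pass precedes trial rejection, and a sub-band excursion would be
erased before the rejecter could see it — real movement transients carry
in-band energy. Channels far from the stimulation site carry 1.5× the
noise (`distal_noise_gain`), which makes the all-channel GMFA noisier than
the local 5-channel average *by construction* — the device by which the
local-versus-global stability contrast becomes testable.

Cohorts draw ages uniformly on 7–13 years, resting motor thresholds that
fall with age and often exceed 100% of maximum stimulator output (the
recorded value is capped at 100; suprathreshold stimulation is defined as
rMT < 100% MSO), antiseizure-medication use with probability 0.444, and a
schedule of four blocks per day (two per hemisphere, alternating, start
side randomized) over up to two days — 18 subjects with 3 single-day
attendees yields the default 132 blocks. Covariates act multiplicatively
on evoked amplitude: `1 + 0.15·(age − 7)` per year, ×1.3 when
suprathreshold, ×1.0 for ASM use (a null default: the emulated study found no ASM
effect), plus a log-normal block perturbation whose subject-level share
induces the within-subject correlation (default 0.3) that the GEE stage
must absorb. Every random component draws from its own derived seed, so
zeroing one component leaves the others bit-identical — the linearity
property the tests rely on.

What a green test does *not* establish: the generator has no biophysical
head model, no leadfield, no sensory-evoked contamination, no
age-dependent artifact rates, and its covariate effects are stated rather
than estimated — so simulated MNP magnitudes are not predictions of
pediatric values, and agreement of orderings (early less stable than late,
GMFA less stable than local, stability increasing with age and intensity)
demonstrates that the *pipeline* recovers what was built in, not that the
physiology must behave this way.

## Statistics

MNP outcomes are analyzed with a linear (identity link, Gaussian working
variance) generalized estimating equation with an **exchangeable** working
correlation clustered by subject and robust sandwich standard errors —
the marginal-model analysis standard for continuous repeated measures.
The implementation is the package's own (no GEE package is assumed
available) and reproduces a reference implementation's estimates, robust
SEs and estimated correlation to all printed digits. The outcome is
modeled untransformed: the emulated analysis reports stability changes
linearly, in pulses per year, implying an identity link. Z statistics
are referred to the standard normal, two-sided.

Two calibration caveats are documented rather than hidden. First, the
uncorrected sandwich estimator is known to be anticonservative with few
clusters (around 8–11% empirical size at 18 clusters instead of the
nominal 5%; Mancl & DeRouen 2001 describe the small-sample corrections
this package deliberately does not apply, since the emulated analysis used
the uncorrected form); the acceptance test for estimator size asserts a
band wide enough to include this known inflation. Second, interval
coverage of a true effect is checked by simulation (≥ 90% of 100
replicates cover an age slope of −4.6 pulses/year under within-subject
correlation 0.3).

Pipeline comparisons (e.g. with versus without trial rejection) use
paired t-tests on per-block values, with explicit conventions for
degenerate inputs: identical series report p = 1; a constant nonzero
shift reports p = 0 with a `degenerate` flag.

## Reproducibility and scale

Every stochastic operation is seeded; a single run seed fans out to
per-block seeds through a fixed mixing function, so any block is
independently reproducible and the full simulate → stability → stats
pipeline is byte-deterministic (asserted by an acceptance test). Output
directories carry a manifest with the package version and a configuration
fingerprint.

Desk-scale choices, disclosed: the generator's default acquisition rate is
2 kHz (the configured minimum) rather than the 25 kHz of the emulated
hardware — all operations are rate-agnostic and the resampler is tested at
25 kHz → 1 kHz; simulation-heavy tests use a 24-channel montage subset
(both local 5-channel sets plus distal channels) and −600..500 ms epochs
that cover every analysis window, keeping the suite inside its runtime
budget while leaving pulse counts, grids, thresholds, noise levels and
seeds-per-condition at their stated values. Internal block files are R's
native serialization; readers for vendor EEG containers are out of scope
in this build.

## Known limitations

* `per_subset` mode can in principle leave a block unattained (the
  independently preprocessed final candidate need not equal the gold
  standard, e.g. if bad-channel detection diverges); such blocks are
  reported `attained = FALSE`, surfacing an edge case the emulated design
  defined away by assuming stability within 100 pulses.
* The CCC threshold is a single value (0.8, from prior literature); the
  package exposes it as a parameter but provides no sensitivity analysis.
* No peak-based outcomes (N100 amplitude/latency) — stability is defined
  on whole-window waveforms.
* Across-day reliability (ICC and friends) is out of scope.
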
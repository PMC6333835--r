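---
title: "Analyzing rhythmic attention in pulvino-cortical recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing rhythmic attention in pulvino-cortical recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmnet)
```

## The scientific problem

Covert spatial attention is not a steady spotlight: target detection waxes
and wanes with the phase of slow (theta, ~5 Hz) brain rhythms, and
higher-frequency activity (alpha/low-beta bursts, gamma, broadband
high-frequency activity) is organized within the theta cycle.  In
multi-region recordings — here modeled on mediodorsal pulvinar (mdPul),
frontal eye fields (FEF), and lateral intraparietal area (LIP) during an
Egly–Driver spatial-cueing task — the interesting questions are *when*
(at which theta phase) and *in which direction* regions influence one
another, and whether behavior follows the same clock.

`rhythmnet` implements the full analysis chain for such data:

1. **Spike rates** — Gaussian-kernel rates (sigma = 10 ms), a
   randomization test of task responsiveness against a pre-cue baseline,
   max-normalized population PSTHs, and Wilcoxon rank-sum delay-period
   contrasts.
2. **LFP power** — Hanning-taper FFT spectra and IRASA, which separates
   the scale-free 1/f ("fractal") background from genuine oscillatory
   peaks.
3. **Phase–behavior coupling** — hit rate as a function of pre-target
   oscillatory phase in 72 overlapping 180° bins, summarized per
   frequency by a one-cycle sine fit, with outcome-shuffle permutation
   nulls, and re-analyzed within "good"/"poor" theta half-cycles.
4. **Spike–field coupling** — pairwise phase consistency (PPC), condition
   contrasts, theta-phase-dependent PPC, and a power-equating
   stratification control.
5. **Directed influence** — MVAR spectral Granger causality (pairwise,
   conditional, and theta-binned on half-theta-cycle epochs).
6. **Cross-frequency coupling** — phase–amplitude coupling within and
   between regions, using the 80–200 Hz band (HFB) as a spiking proxy.
7. **Synthetic sessions** — a generator that produces all of the above
   structure with recorded ground truth, so every estimator is validated
   by parameter recovery rather than by eye.

Because the kind of data this package targets is not publicly deposited,
the test suite is built entirely on the synthetic generator.

## Time, phase, and binning conventions

* Times are in milliseconds, the alignment event (cue or target) at
  t = 0, and all analysis windows are half-open `[start, stop)`.
* Phase follows the **cosine convention**: phase 0 at the signal maximum,
  increasing with time, reported in `[-pi, pi)` radians internally and
  degrees at user-facing boundaries.  A quarter cycle after a peak the
  phase is +90°.
* Phase-binned functions use **72 overlapping 180° bins** whose centers
  step by 5°; a trial (or spike, or time sample) at phase φ contributes
  to the 36 bins whose half-open window `[c − 90°, c + 90°)` contains φ.
  Because bin edges align with the 5° grid, binning is computed exactly
  by pooling 5° fine bins — there are no boundary approximations.
* The **one-cycle sine fit** of a 72-bin function is the least-squares
  fit of `m + A·cos(φ − ψ)`.  On the complete grid the design is
  orthogonal, so the fit equals keeping the second FFT component of the
  72-point sequence; `A` is exact to machine precision for a pure
  one-cycle input and exactly 0 for a two-cycle input.  Up to 4 flagged
  (empty) bins are tolerated by the least-squares route; more refuse.

## The synthetic generator and what it emulates

`task_config()` encodes the behavioral design: 78% cue validity, 10%
catch trials, 12% non-cued targets split equally between same-object and
different-object locations; fixation and bar-cue delays uniform in
500–1200 ms and the cue–target delay uniform in 300–1600 ms; hits require
responses 150–650 ms after the target.

`signal_config()` builds per-trial LFP epochs as a sum of

* frequency-domain-shaped **1/f^χ fractal noise** (amplitude ∝ f^(−χ/2),
  random phases; default χ = 1.5, SD 5 µV),
* a **5 Hz theta sinusoid** with a random phase per trial (default
  10 µV),
* an **alpha/low-beta carrier** (frequency drawn per trial from 10–20 Hz,
  default 5 µV) whose envelope is `1 + m·cos(φ_theta − φ_pref)` —
  theta-gated bursts with depth `pac_depth`,
* optional **alpha-gated gamma** and an optional broadband **80–200 Hz
  component** whose envelope can follow an external region's phase
  (between-region PAC ground truth), and
* white measurement noise (default 1 µV).

Ground truth (theta phase offsets, carrier frequencies/phases, configs)
always travels with the signal (`truth` element; `true_phase()` reads the
analytic phase), so recovery tests never re-estimate truth from data.
Defaults were chosen once as plausible magnitudes for macaque LFPs: theta
clearly visible above the 1/f background but not dominating it, bursts of
the same order as the background at their band, and an SNR at which
wavelet phase estimates at 5 Hz correlate >0.95 with truth.

`synthesize_spikes()` draws inhomogeneous-Poisson spikes with intensity
∝ `exp(κ·cos(φ_band(t) − μ))`, normalized to the requested mean rate;
with a theta gate the coupling applies only while theta phase is within
±90° of the gate center, the process being homogeneous elsewhere.  The
expected PPC of von Mises phases is `(I₁(κ)/I₀(κ))²`, which the tests use
as a closed-form oracle.  `synthesize_coupled_regions()` simulates
trial-wise vector autoregressions with unit-variance innovations (with
stability checked via the companion matrix) and can zero the cross-terms
on a per-trial gate, creating theta-phase-dependent directed influence.
`synthesize_behavior()` makes `P(hit) = p0 + m·cos(φ_theta(t_est) −
φ_good)` at the −250 ms estimation time, with an optional nested
higher-frequency modulation that multiplies in only within one theta
half-cycle.

What the generator does **not** emulate: evoked transients, non-Poisson
spiking (bursting, refractoriness), non-stationary 1/f slopes, eye
movements, and session-to-session heterogeneity.  Passing recovery tests
therefore demonstrates estimator correctness under the stated model, not
robustness to every pathology of real recordings.

## Statistical machinery

All permutation p-values use the +1 correction,
`p = (1 + #{null ≥ observed}) / (n_perm + 1)`, so with 1500 permutations
the floor is 1/1501 ≈ 0.00067.  Holm's sequential correction
(`p.adjust(..., "holm")`) controls family-wise error across frequencies;
with m tests, Holm needs `p ≤ α/m`, so the permutation count must keep
the floor below that (1500 permutations support up to ~75 tests at
α = 0.05).

Permutation units are chosen to break exactly the dependence under test:
outcome labels for phase–behavior coupling, trial condition labels for
PPC contrasts, spikes' theta-bin assignments for theta-dependent PPC,
whole trials of the phase series for PAC.  For the Granger *asymmetry*
statistic `GC(A→B) − GC(B→A)` the default null randomly swaps the two
channels within each trial: this is the exchangeability null for
direction, so symmetric bidirectional coupling is correctly
non-significant, while a trial-pairing shuffle (available as
`scheme = "pairing"`) tests the stronger null of full independence and
over-rejects for the asymmetry statistic when coupling is symmetric.

The **responsiveness test** samples, per trial, the kernel-rate value at
one uniformly random time in the response window and averages across
trials; the null does the same from the −350–0 ms baseline, 5000 times by
default.  Sampling both sides identically makes observed and null
exchangeable under a homogeneous-rate null, so the test is calibrated
(type-I ≈ α with two one-sided tests at α/2).  A window-mean response
statistic (`response_stat = "mean"`) is also provided; it is markedly
conservative, because a 250 ms mean has far lower variance than a
sampled point.

**Stratification** (`stratify()`) equates a nuisance variable between two
groups by histogram matching: a common 20-bin histogram over the pooled
range, each bin subsampled without replacement to the smaller group
count.  For identical distributions at n = 500 this retains ~89% of the
data on average (binomial fluctuation of per-bin counts accounts for the
loss).  In the theta-PPC control the stratification unit is the *spike*,
with alpha/low-beta power evaluated at each spike time, because the
power confound being removed (phase-estimate reliability grows with
power) varies within a trial along the theta cycle; subsampling whole
trials cannot equate it.  The subsample differs per run, so the
procedure repeats 1500 times and reports the mean ± SD across runs.

## Spectral estimation choices

* **Morlet wavelets** default to 3 cycles for 3–60 Hz analyses
  (configurable); the theta phase used for binning uses the 2-cycle 5 Hz
  wavelet read at −250 ms.  Wavelets are normalized so a unit-amplitude
  cosine at the wavelet's frequency yields unit coefficient magnitude.
  Edges are reflect-padded and any sample whose ±3.5 SD wavelet support
  leaves the epoch is flagged edge-contaminated; flagged samples are
  excluded from every statistic.  Low frequencies therefore need long
  epochs: a −250 ms estimate at 3 Hz (3 cycles) requires the epoch to
  extend about 560 ms on both sides of it.
* **Power spectra** use a Hanning taper, one-sided and
  taper-compensated so a sinusoid of amplitude a has peak power a²/2;
  oscillatory analyses stop at 60 Hz (above that the signal is treated
  as broadband), except the 80–200 Hz HFB proxy.
* **IRASA** resamples each epoch by factors h ∈ {1.1, 1.15, …, 1.9} and
  their reciprocals (cubic-spline time stretching at the nominal rate),
  takes the geometric mean of each h/1-over-h spectral pair, and the
  median across h as the fractal spectrum; the oscillatory residual is
  total − fractal, so the decomposition identity holds exactly.  The
  analysis contract restricts input to trials whose relevant delay is at
  least 750 ms, avoiding cue-evoked transients.
* **HFB** computes wavelet power at 80, 90, …, 200 Hz, z-scores each
  step against its own baseline distribution (pooled over trials and
  baseline times) *before* averaging across steps — this equalizes the
  1/f drop-off so every sub-band contributes comparably.  Because the
  result is a z-score with near-zero mean, HFB-based PAC reports the
  raw one-cycle sine amplitude (z units) instead of percent modulation,
  whose denominator would be ill-defined; power-based PAC keeps the
  percent-modulation normalization `(bin − mean)/mean × 100`, which is
  scale-invariant.

## Granger causality

Signals are decimated to 250 Hz (Butterworth anti-alias filter after
per-trial demeaning) and z-normalized per trial and channel.  MVAR models
(order 8 by default, matching the first AIC minimum for this class of
signal; an AIC diagnostic over orders is available) are fitted by
multi-trial least squares — lagged regressions stacked across trials —
which is what makes order-8 fits on 25-sample half-theta-cycle epochs
possible.  Spectral GC follows Geweke:
`f(ω) = ln(S_yy / (S_yy − (Σ_xx − Σ_xy²/Σ_yy)|H_yx|²))`, evaluated on a
0.5 Hz grid and reported over 3–60 Hz.  For the lagged-copy model
`Y_t = X_{t−1} + ε` this is flat at ln 2, the closed form used in tests.
Conditional GC compares the full trivariate model against the reduced
(sink + conditioning) model through the partition-matrix construction,
after normalizing residuals so the sink innovation is uncorrelated with
the others; a chain X→Z→Y then yields conditional GC ≈ 0 while direct
influence is preserved.  Estimation noise can make conditional GC
slightly negative; values within a small tolerance are clamped to zero
and larger negatives raise an error.

The theta-binned variant assigns trials to good/poor half-cycles from
the 2-cycle wavelet phase at −250 ms and fits each bin's model on 100 ms
epochs (half a 5 Hz cycle, 25 samples at 250 Hz) centered there.

## Problem sizes used by the test suite

The suite validates each stage at the smallest size at which its
statistical claim is meaningful: 10,000 trials for task composition;
2000 trials and 1500 permutations for behavioral-modulation recovery
(depth 0.2 recovered as (2/π)·0.2 ≈ 0.127 by the boxcar-attenuation
law); 200 trials × 200 samples for MVAR closed forms; 50 seeded runs of
800 trials for the theta-gated Granger dissociation; 200 null
simulations per permutation test (with reduced permutation counts,
since family-wise calibration does not depend on n_perm) and 1000
homogeneous-Poisson units for responsiveness type-I error.

## Known limitations

* Pairwise spectral GC is parametric; no nonparametric
  (spectral-factorization) route is provided.
* PPC pools spikes across trials (the estimator is pairwise over
  spikes); an option to exclude same-trial spike pairs is future work —
  with Poisson generators the difference is negligible.
* Spectral leakage is physical: a strong oscillation leaks phase
  information into neighboring wavelet bands, so phase-coupling spectra
  have a bandwidth set by the wavelet width, not a single line.
* The percent-modulation PAC normalization assumes strictly positive
  power; it is replaced by raw amplitude for z-scored inputs (HFB).
* Aborted trials are carried in sessions but never analyzed; how they
  were logged in real datasets is outside this package's scope.
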
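---
title: "Phonatory and time-frequency analysis of sustained vowels: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phonatory and time-frequency analysis of sustained vowels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bulbarvoice)
```

# The problem and the pipeline

Bulbar involvement in ALS degrades laryngeal control. In a sustained vowel
this surfaces as cycle-to-cycle irregularity of the glottal period (jitter)
and amplitude (shimmer), a lower harmonics-to-noise ratio (HNR), and
attenuation of the upper harmonics. `bulbarvoice` quantifies a recording
with 50 features — 15 from the phonatory subsystem and 35 from a
Cohen-class time–frequency representation — screens them for statistical
significance per clinical contrast, and evaluates five supervised
classifiers under cross-validation.

This vignette documents the models and estimators, every tunable parameter
with its unit and default, the synthetic cohort the tests run on, the
numerical edge-case policies, and the places where the design was genuinely
open together with the choice made. It states no empirical result that the
test suite does not itself compute.

# Preprocessing

* **Decimation** (`decimate_signal`, factor 5, 44 100 → 8820 Hz). Vowel
  spectra carry their diagnostic content below ~4 kHz, and halving-plus the
  rate five-fold makes the quadratic time–frequency stage tractable. An
  anti-aliasing FIR is applied before sample dropping: zero-phase windowed
  sinc (Hamming, `20·factor + 1` taps), cutoff at 0.8 of the new Nyquist
  (3528 Hz at defaults). The filter itself is a design choice — any
  reasonable low-pass changes downstream features slightly; the cutoff
  margin means band 7 (3000–4410 Hz) partially overlaps the transition
  band, which matters when interpreting `E_Bn7` (see below). Rates not
  divisible by the factor are an error, not silently resampled.
* **Standardization** (`standardize`). The z-score uses the *population*
  SD (divide by N): the whole recording is the population being
  standardized, not a sample from it. The sample-SD convention is available
  via `sd_type = "sample"`; the two differ by `sqrt(N/(N-1))`, irrelevant
  at N ≈ 26 000 but visible in toy examples. Constant signals are a
  degenerate-input error.
* **Segment cut** (`cut_segment`, 150 ms). The analysis unit is
  `round(duration·rate)` = 1323 samples centred at the recording midpoint,
  as the half-open window `[c − ⌊L/2⌋, c − ⌊L/2⌋ + L)` with `c = ⌊N/2⌋`
  (0-based). The order is fixed: decimate → z-score the whole decimated
  recording → cut, so the cut is from a unit-SD parent. Whether z-scoring
  should cover the whole phonation or only the analysed region is not
  determined by the protocol; the whole recording is used because the
  z-score is defined on the re-sampled signal as a unit.

# The phonatory estimators

## Pitch and HNR

`estimate_pitch_track` divides the signal into frames (step 10 ms, length
`3/floor` = 40 ms at the default 75 Hz floor) and computes, for lags
between `rate/ceiling` and `rate/floor` (defaults 75–600 Hz), the
**normalized cross-correlation over the frame–lag overlap**:

    r(τ) = Σ x_t x_{t+τ} / sqrt(Σ x_t² · Σ x_{t+τ}²)

This is the "cc" flavour of the classical autocorrelation method. The
design alternative — a tapered-window autocorrelation divided by the window
autocorrelation — was rejected for one concrete reason: for a strictly
periodic signal the NCC attains r(T0) = 1 *exactly*, while the tapered
estimator falls short by ~10⁻³ for realistic windows, which would make the
HNR of a noise-free signal ~30 dB instead of hitting its documented cap.
Candidate lags are interior local maxima of r; a small per-octave cost
(0.01/octave, favouring the higher-frequency candidate as in standard
practice) prevents locking onto the 2·T0 subharmonic peak, and excluding
edge peaks stops formant-ringing correlation piling up at the shortest
allowed lag from masquerading as f0. The winning lag is refined by
parabolic interpolation; frames with r below the voicing threshold (0.45)
are flagged unvoiced; a fully unvoiced segment is an error carrying the
best r seen.

Per frame, `HNR = 10·log10(r/(1−r))` with r clipped to `[10⁻⁶, 1−10⁻⁶]`:
the formula diverges as r → 1, so perfectly periodic signals report the
~60 dB cap (`hnr_cap_db()`). The HNR features are the mean and SD over the
voiced frames of the 150 ms segment (whether the reference protocol used
the segment or the full phonation is unstated; the segment keeps all 50
features functions of the same excerpt).

## Cycle marking

`mark_cycles` walks outward from the highest waveform peak near the segment
centre, locating each successive cycle peak within `[0.8, 1.25]` local
periods; the local period comes from the pitch track (frame-averaged, hence
robust — guiding the window by the previous measured period lets a single
bad mark cascade) and is clamped to `[0.5, 2]` times the global median.
Peak positions are refined by parabolic interpolation.

Peak picking alone is not enough: formant ringing gives each cycle several
lobes ~1/F1 apart, and at jitter ≳ 4% the highest lobe hops, inflating
measured jitter severalfold. The periods are therefore re-measured by
**waveform matching**: `T_i` is the lag maximizing the NCC between
consecutive cycle-length windows anchored at the marks (window half-width
0.35 and lag range 0.7–1.4 of the global median period; both constant
across cycles so that identical cycles yield bit-identical periods,
preserving the exact zero-jitter identity). Amplitudes `A_i` are the
waveform peak-to-peak range within `[m_i, m_{i+1})`.

## Jitter and shimmer

The four jitter and five shimmer measures are the classical
perturbation-quotient family (absolute/relative, rap, ppq5; dB, relative,
apq3/5/11). The moving-average quotients use the standard *P*-point centred
window averaged over its valid positions (divisor = number of terms): the
sometimes-printed variants with a fixed 3-term inner sum and a 1/(N−1)
prefactor are not internally consistent under any indexing (the first
window position would index cycle 0), so the standard Praat-compatible
definitions are the default and the 3-term literal variant is available
behind `literal_window = TRUE`. Every vectorized implementation is tested
to 10⁻¹² against a naive loop transcription. All relative measures are
invariant to time scaling and amplitude gain respectively; uncomputable
measures (too few cycles) become NA with a warning, and downstream stages
drop incomplete rows with a warning.

# The synthetic voice

`synthesize_vowel` is a source–filter model with exact, recorded ground
truth:

* **Source**: a differentiated Rosenberg glottal pulse (opening 41.3%,
  closing 15.3% of the period — deliberately not round fractions: for
  integer-period signals, landmarks like 0.40 of a 350-sample period fall
  exactly on a sample and float round-off then classifies that sample
  inconsistently across cycles, breaking exact periodicity). The closure
  discontinuity makes the source rich in harmonics across all seven bands.
  The pulse *shape* is tied to the mean period T0, not the instantaneous
  one: a period-scaled pulse shifts the waveform landmark within each cycle
  by ~0.5·ΔT, which would low-pass the injected jitter as seen by any
  landmark-based estimator (this halves measured jitter in practice).
* **Perturbations**: per-cycle periods `T_i = T0(1+ε_i)` and source
  amplitudes `A_i = 1+η_i`, with ε, η i.i.d. Gaussian truncated at ±3.5 SD.
  The SDs are calibrated so the *expected relative perturbation estimate*
  equals the requested percentage: for i.i.d. Gaussian ε with SD s,
  `E|ε_i − ε_{i−1}| = 2s/√π`, so `s = (target/100)·√π/2`. Pulse phase is
  evaluated in continuous time, so injected jitter is not quantized to the
  sample grid. A separate slow drift knob (`f0_drift_pct`, ~0.8 Hz
  sinusoid) models long-range pitch variability, which jitter statistics
  deliberately exclude.
* **Filter**: a cascade of four second-order resonators per vowel. F1/F2
  follow published adult Spanish vowel averages (e.g. /a/ 700/1200 Hz, /i/
  300/2300 Hz), F3/F4 generic, female frequencies ×1.17; bandwidths
  80–150 Hz.
* **Tilt**: `tilt_db` dB/octave applied above 1500 Hz in the frequency
  domain, emulating the high-harmonic attenuation of affected voices.
* **Noise**: white noise shaped by the same resonators, scaled so the
  harmonic/noise power ratio equals `hnr_db` exactly; both components are
  recorded, so the achieved HNR is verifiable by power accounting rather
  than by a (biased) estimator.
* **Type 2 voices**: alternate-cycle amplitude modulation (an f0/2
  subharmonic) plus slow 2.5 Hz amplitude modulation — voices with strong
  modulations/subharmonics, on which perturbation analysis is known to be
  fragile.
* **Ground truth**: the cycle table (start, `T_i`, source amplitude,
  peak-to-peak of the clean output within the true cycle) restricted to
  steady state (first 50 ms skipped — the resonator startup transient is
  not phonation), plus the relative-jitter/shimmer values obtained by
  applying the defining formulas to that table. Recovery tests compare the
  estimators against this table, not against the nominal knob: the table
  *is* the realized truth.

## The cohort and what a green test establishes

`make_cohort` draws a single-sex, three-group cohort (C controls, B bulbar,
NB non-bulbar ALS; five vowels per subject). One latent severity s ∈ [0,1]
drives all knobs: jitter ×(1+6s) of a 0.4% baseline, shimmer ×(1+3.5s) of
2.5%, HNR −13s dB from 23 dB, tilt −8s dB/oct, drift ×(1+3s), type 2 above
s = 0.7; healthy baselines get per-subject log-normal biological variation,
f0 ~ N(118, 12) Hz for males and N(208, 18) Hz for females. Controls have
s = 0; B subjects s ~ U(0.5, 1); NB subjects are healthy *except for a
fixed 30% "lookalike" fraction with s ~ U(0.4, 0.8)* — modelling patients
whose bulbar involvement exists but has not been diagnosed. This makes
B vs NB intrinsically harder than C vs B (the lookalikes are
near-indistinguishable from mild B but carry the NB label), reproducing
the qualitative clinical ordering; at s = 1 the parameters sit well inside
conventional pathological ranges (jitter > 1.04%, shimmer > 3.81%).

The generator emulates quasi-periodic phonation with controllable
perturbations. It does **not** emulate: articulation dynamics or
co-articulation, onset/offset behaviour (recordings are steady by
construction, so no voice-activity detection exists or is needed),
room/microphone channel effects, dBSPL calibration, or the physiology of
real vocal-fold lesions. A green end-to-end test therefore establishes that
the pipeline's machinery is correct and sensitive to the acoustic
correlates it targets — not that real ALS voices will classify at the same
accuracy.

Recovery/calibration tests run on noise-free synthesis (`hnr_db = Inf`),
holding the other knob at its default: a calibration isolates the quantity
being calibrated. Additive noise at realistic HNR inflates low shimmer
estimates by a couple of percent (the noise moves per-cycle extrema),
which is estimator physics shared with standard tools, not a recovery
defect; the HNR target itself is checked by the generator's exact power
accounting.

# The time–frequency stage

## Wigner distribution

`wigner_distribution` computes the discrete pseudo-Wigner distribution of
the (by default) analytic signal:
`W(t,f) = Σ_μ w(μ)·x(t+μ)x*(t−μ)·e^{−j4πfμ/rate}` on `n_freq` = 660
frequency bins covering 0–4410 Hz (~6.7 Hz bins) and, for the feature
pipeline, every 4th time sample (~0.45 ms; the implementation smooths at
full time resolution first, and features are required by test to be stable
within 2% between steps 2 and 4). Choices:

* **Analytic signal on by default** (flag to disable): with real signals
  the positive/negative-frequency cross-terms land at low frequencies and
  contaminate band 1 (0–80 Hz) features.
* **Hann lag taper by default** (`lag_window = "rect"` restores the
  truncated literal definition, on which the O(N²)-oracle equivalence test
  runs). With a rectangular cutoff at ±329 lags the spectrum is convolved
  with a Dirichlet kernel whose clipped sidelobes spread ~15% of a tone's
  mass across the whole axis, destroying band localization; the taper
  removes this at the price of a slightly wider line.
* Energy bookkeeping is exact: each time column of the lag-FFT sums to
  `n_freq` times the analytic power at that sample, so the pre-normalized
  mass is proportional to segment energy.

## Choi–Williams smoothing and the joint density

`choi_williams` multiplies the ambiguity function by
`exp(−(θμ)²/σ)` (θ doppler in rad/sample, μ lag in samples): auto-terms
live near the axes and pass; cross-terms oscillate away from them and are
attenuated. σ defaults to 1, a value at which the two-tone midpoint ridge
drops by more than an order of magnitude while auto-term peaks stay within
a bin (both under test). The smoothed distribution is normalized to **unit
total mass** (CWDN) — among the plausible normalizations (unit energy,
max = 1), unit mass is the one under which the marginals are probability
densities, which the joint-density construction requires.

`tfr_marginals` forms `m_t` (column sums) and `m_f` (row sums), clips
negatives and renormalizes. Negativity up to 5% of the marginal's maximum
is clipped silently — truncating the lag window leaves sidelobes of that
order on any tonal input, so a tighter diagnostic threshold would warn on
every vowel and carry no information; anything more negative indicates an
ill-behaved grid and warns. `joint_density` is the outer product
`p_D(f,t) = m_f(f)·m_t(t)`: non-negative, unit mass, rank 1 by
construction — interference-free, at the price of assuming the marginals
independent. That assumption is checked, not presumed:

`joint_moments` computes central *standardized* joint moments
`E[z_f^n z_t^m]` of the CWDN mass (negatives clipped first, as in the
marginal policy — signed mass can cancel an axis variance). `t1f1` is then
exactly the t–f correlation: 0 on any separable grid, and small on
stationary vowels (|t1f1| < 0.05 under test). High-order standardized
moments (`t7f7`, `t15f15`) are large in magnitude on spiky spectra — the
near-zero independence diagnostic is `t1f1`; the high orders serve as
shape features for the classifier after per-fold standardization. Raw
(non-central, bin-unit) moments sit behind `standardized = FALSE`. Whether
the original protocol used raw, central or standardized moments is not
recoverable; standardized central moments are the only convention under
which "near zero" is scale-free.

## The 35 features

Per band of the 7-band scheme (0–80, 80–250, 250–550, 550–900, 900–1500,
1500–3000, 3000–4410 Hz; half-open, last closed — resolving the f0 region,
the first formants, and the high harmonics):

* `E_Bn`: time-aggregated band energy (the band's share of total mass;
  the seven values sum to 1 exactly). The band quantities are defined as
  time profiles; aggregation over time is required to report one number,
  and total mass is the aggregation under which the partition identity
  holds.
* `f_Cres`: per-time argmax frequency within the band (ties to the lower
  bin), time-averaged with instantaneous-energy weights; `f_Med`: per-time
  band centroid, energy-weighted likewise. Energy weighting stabilizes both
  where the band's instantaneous mass is tiny (a plain mean would let
  empty time slices dominate). On the rank-1 `p_D` both collapse to
  band-restricted functionals of `m_f`. Zero-mass bands give NA with a
  warning.
* `H_t`, `H_f`: Shannon entropies (bits) of the marginals, used directly
  as discrete probability vectors on the grid (no re-binning — they are
  already quantified; 0·log 0 := 0); `H_tf = H_t + H_f` *by definition*
  (the joint density is a product, so its entropy is the sum — the
  identity is exact in code and asserted as such).
* `IE_Bn`: mean of `−log2 m_f` over the band's positive-mass bins
  (zero-mass bins carry no information and are excluded).
* `K`: the fourth standardized central moment of `m_t` (3 for a
  Gaussian-shaped power profile, 1.8 uniform, 1 two-point). The printed
  product form this feature is sometimes given in is not a well-formed
  kurtosis; the standardized-4th-moment reading is the reconstruction
  implemented.
* `t1f1`, `t7f7`, `t15f15` as above. Total: 7·5 + 3 + 1 + 3 = 35; with the
  15 phonatory features, 50 per (subject, vowel) — the count is a test.

One interpretation caveat established during development and encoded in
the tests: after decimation, band 7 holds genuine harmonic energy only for
vowels whose F3/F4 sit below the 3528 Hz filter cutoff (e.g. /i/); for /a/
its measured mass is dominated by residual cross-term floor and is not a
tilt readout.

# Feature screening

`screen_features` runs, per comparison and sex, a one-way MANOVA omnibus
(Wilks' Λ via the F approximation) on the full feature matrix when the
within-group covariance is estimable (n > p + 2), then per-feature
equal-variance F tests — the standard univariate follow-ups — retaining
features with p < 0.05. Design choices: the observation unit is one row
per (subject, vowel) — features are defined per vowel and no cross-vowel
aggregation is part of the protocol; equal-variance tests by default,
mirroring standard between-subjects follow-ups, with Welch tests behind
`var_equal = FALSE`; no
multiple-testing correction by default, matching the screening-not-
inference role, with Benjamini–Hochberg behind `adjust = "BH"` for honest
reuse. The per-feature test is validated against a permutation oracle, and
its type-I error is calibrated on 200 null tables (the calibration
exercises the test, not the audio front end, so null *feature tables*
suffice and keep the suite inside its time budget).

# Classification

`run_cv` evaluates RF, LR, LDA, NN and SVM under stratified 10-fold CV.
Inside each fold: the scaler (centre/scale) is fitted on training rows
only; the training minority class is upsampled with replacement to balance
(never the test fold); models are fitted; held-out rows are scored at the
0.5 probability threshold. Metrics are computed from fold-pooled confusion
counts (not averaged per-fold metrics — pooling is exact for the quantities
reported and well-defined when a fold has few positives). Sensitivity
counts the affected group as positive.

Model implementations: the target environment provides LDA (`MASS`) and
penalized logistic regression (`glmnet`, ridge λ = 0.01 — a mild penalty so
separable training folds don't diverge); the random forest (500 CART trees,
Gini, `mtry = ⌊√p⌋`, grown to purity, vote-fraction probabilities), the
single-hidden-layer neural network (10 logistic units, weight decay 0.01,
BFGS on the cross-entropy), and the SVM are implemented in the package. The
SVM is a **least-squares SVM** (RBF kernel, γ = 1/p on standardized
features, cost 1) with Platt-calibrated probabilities — solving a linear
system instead of the hinge-loss QP; on problems of this size the decision
functions are close and the probability contract is what the 50% threshold
needs. All fits are seeded deterministically from the CV seed.

Fold assignment is per observation (per vowel) by default; with five
vowels per speaker this shares speakers between training and test folds,
which can flatter accuracy on speaker-correlated features —
`group_by_subject = TRUE` assigns whole subjects to folds. Both modes are
provided because the reference protocol does not state which was used; the
default mirrors the apparent per-sample procedure and the caveat is
documented here deliberately.

# Degenerate inputs and numerical policies (summary)

constant signal → error at `standardize`; fully unvoiced segment → error
with diagnostics; < 2 cycles → error, per-measure NA below each quotient's
minimum; r clipped to `[10⁻⁶, 1−10⁻⁶]` (HNR in [−60, 60] dB); marginal
negativity: clip ≤ 5% of max silently, warn beyond; 0·log 0 := 0 and
−log2(0) excluded from band means; zero-mass band → NA + warning; zero
axis variance in moments → error; per-recording extraction failures become
NA rows, aborting only past 20% failures; every random path takes an
explicit seed and restores the caller's RNG state.

# Known limitations

* The phonatory estimators are Praat-*like*, not Praat: no candidate
  lattice with Viterbi path, no sinc-interpolated autocorrelation. Exact
  numerical parity with any external tool is out of scope; the contracts
  are the identities and recovery bounds in the test suite.
* `E_Bn7`/`IE_Bn7` sit partly in the decimation filter's transition band;
  interpret them jointly with band 6.
* The jitter/shimmer estimators carry a ~10–15% systematic negative bias
  at moderate perturbation levels (landmark noise partially averages
  consecutive-cycle differences); the recovery contract is 20% relative.
* The synthetic cohort is a stated world: its group separations are
  chosen, not discovered, and classifier accuracies on it say nothing
  quantitative about clinical performance.
* With per-vowel CV folds (the default), speaker identity leaks between
  training and test; use `group_by_subject = TRUE` for speaker-disjoint
  evaluation.
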
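---
title: "Methods: ECG feature construction and one-day-forward wellness prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ECG feature construction and one-day-forward wellness prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Daily self-rated wellness of community-dwelling older adults is an ordinal,
noisy, and subject-specific quantity, yet it carries clinically useful
information: a day that a person rates as worse than their own usual tends to
be followed by further worse days. `ecgwellness` implements a pipeline that
predicts tomorrow's binary wellness state (Better/Worse relative to the
subject's own distribution) from today's short (20–25 s) single-lead ECG
record, by constructing a fixed 184-dimensional feature vector per 5-second
ECG segment and training standard classifiers on it.

The working hypothesis is physiological: wellness correlates with
beat-to-beat regularity of the cardiac cycle. Two ECG traces can have almost
identical amplitude ranges while differing in how regular their oscillation
is; amplitude statistics alone therefore separate the classes poorly, and
the feature set deliberately mixes four families that are sensitive to
regularity at different levels:

1. **Time- and frequency-domain statistics (F1–F26).** Thirteen classical
   waveform indicators — absolute mean $x_{av}$, peak $x_p$, peak-to-peak
   $x_{p\text{-}p}$, the variance-like $D_x = \frac1N\sum_i (x_i-x_{av})^2$,
   root amplitude $x_r = (\frac1N\sum_i \sqrt{|x_i|})^2$, crest factor
   $C_f = x_p/x_{rms}$, skewness, kurtosis, shape factor $S_f$, clearance
   factor $CL_f = x_p/x_r$, impulse factor $I_f$, RMS, and variation
   coefficient $K_x = D_x/x_{av}$ — computed once on the raw segment and
   once on its one-sided FFT amplitude spectrum. Two of the formulas are
   intentionally non-standard and preserved as such: $D_x$ is centered on
   the *absolute* mean, and $K_x$ is a ratio of a squared quantity to a
   first-order one.
2. **Wavelet-packet sub-band energies (F27–F34).** A full three-level
   wavelet-packet tree (db4 by default) splits the segment bandwidth into
   $2^3 = 8$ equal sub-bands; the feature is the energy
   $E_w = \sum \text{coeff}^2$ of each terminal node, ordered low→high
   frequency.
3. **EEMD per-IMF statistics (F35–F164).** Ensemble empirical mode
   decomposition adaptively splits the segment into intrinsic mode
   functions (IMFs) ordered from high to low frequency; the 13 time-domain
   statistics of family 1 are computed on each of 10 IMF slots.
4. **RCMSE entropy curve (F165–F184).** Refined composite multiscale sample
   entropy over scales $\tau = 1..20$: at each scale the $m$- and
   $(m{+}1)$-template match counts are summed over all $\tau$
   coarse-graining offsets *before* the logarithm,
   $\mathrm{RCMSE}(\tau) = -\ln\left(\sum_k B^{m+1}_k \big/ \sum_k B^m_k\right)$,
   which markedly reduces the incidence of undefined (zero-count) entropies
   on 500-point segments compared with naive multiscale sample entropy.

## Pipeline

```{r}
library(ecgwellness)

cohort  <- generate_cohort(cohort_spec(n_subjects = 6, days_per_subject = 10,
                                       class_effect = 1.5, seed = 1))
dataset <- make_segment_dataset(cohort, window_s = 5, step_s = 1,
                                target_len = 500, lag = 1)
X   <- extract_matrix(dataset, fs = 100,
                      feature_configs(eemd = eemd_config(trials = 10)))
idx <- split_holdout(dataset$labels, 0.70, seed = 2)
nrm <- fit_minmax(X[idx$train, ])
rf  <- train_rf(apply_minmax(nrm, X[idx$train, ]), dataset$labels[idx$train])
evaluate(predict(rf, apply_minmax(nrm, X[idx$test, ])),
         dataset$labels[idx$test])
```

Records are segmented with a 5 s window slid by 1 s (a 20 s record gives 16
segments, a 25 s record 21), each window is polyphase-resampled from 2500
raw samples to the 500-point model input (effective rate 100 Hz), features
are min–max normalized with parameters learned on the training split only,
and a subject's ordinal health-index (HI) series is converted to binary
labels by Fisher–Yates normalization: within-subject mid-ranks $G$ of the
HI values are mapped through $\varphi^{-1}(G/(I+1))$ and thresholded at 0
(positive score → Better → label 0; ties and negatives → Worse → label 1).
The one-day-forward pairing attaches day $t{+}1$'s label to day $t$'s
segments.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| window / step | 5 / 1 | s | the study's segmentation protocol |
| segment length | 500 | samples | the model input length; resampling avoids aliasing |
| wavelet | db4, level 3 | — | widely used for ECG; depth fixed by the 8-band layout |
| EEMD trials $M$ | 100 | — | classical ensemble size; 1/√M noise cancellation |
| EEMD noise ratio | 0.2 | × sd | the originating EEMD literature's common setting |
| IMF slots | 10 | — | fixed rectangular layout (13 × 10 statistics) |
| RCMSE $m$, $r$ | 2, 0.15 | —, × sd | canonical multiscale-entropy settings |
| RCMSE $\tau_{max}$ | 20 | — | the 20-feature entropy curve |
| RF trees / mtry | 500 / 12 or 20 | — | mtry 12 for 184 features, 20 for 500 raw inputs |
| PSO | 20 particles, 200 iters, tol $10^{-3}$, $c_1{=}1.5$, $c_2{=}1.7$, box $[0.1,100]^2$ | — | the study's search protocol for $(C,\gamma)$ |
| train fraction | 0.70 | — | stratified hold-out protocol |

## The synthetic cohort

The original nursing-home cohort is private, so the package ships a seeded
generator that emulates its *structure*: per subject-day, a quasi-periodic
waveform built from Gaussian P-QRS-T bumps on a jittered beat grid
(~75 bpm), additive measurement noise at 20 dB SNR, 500 Hz sampling, and a
uniform 20–25 s duration. The two wellness regimes differ only in
regularity: "worse" records get beat-interval jitter and per-beat
morphology perturbation inflated by the factor `class_effect` (default
1.5), while their amplitude ranges remain deliberately similar — amplitude
is not the discriminating cue.

Because no HI distribution is published, each subject's HI series follows a
latent AR(1) process ($\rho = 0.6$) discretized to the five ordinal levels
with a realistic mild-skew marginal. The persistence is not cosmetic: with
independent daily HI, tomorrow's label would be unpredictable from today's
signal and a one-day-forward design would be meaningless. The waveform
regime of a day is tied to its HI through exactly the rank rule the
labelling stage applies downstream (Fisher–Yates score > 0 → "better"
regime), so generator and labels agree by construction.

What passing tests on this cohort do **not** show: robustness to baseline
wander, electrode artifacts, arrhythmias, device-specific noise, or real
HI–physiology coupling. The generator demonstrates that the pipeline
recovers a regularity signal when one exists; it cannot validate the
clinical claim on real data.

## Numerical choices

* **Frequency-domain statistics** are computed on the one-sided *amplitude*
  spectrum (not power), calibrated so a pure sinusoid of amplitude $A$
  yields a dominant bin of height $A$; the DC bin is included by default
  and can be dropped (`drop_dc`).
* **Wavelet packets** use periodized orthonormal filtering with the segment
  zero-padded to the next multiple of $2^{level}$. Zero padding adds no
  energy and periodization keeps the transform exactly orthonormal, so the
  eight energies sum to the signal energy to round-off — an identity the
  test suite checks at 1e-8 relative. Terminal nodes are re-ordered from
  the filter-path ("natural") order to frequency order by the Gray-code
  permutation, because decimation flips the spectrum under the high-pass
  branch.
* **EMD sifting** uses natural cubic-spline envelopes through the local
  extrema with two mirrored extrema at each boundary, the classical
  normalized squared envelope-mean stopping criterion (threshold 0.2, at
  most 10 siftings per IMF), and stops extracting when the residue has
  fewer than two maxima or minima. Monotone inputs return zero IMFs and the
  input as residue — not an error.
* **RCMSE** anchors the absolute tolerance $r \cdot \mathrm{sd}(x)$ once to
  the original series, the standard multiscale-entropy convention. Scales
  with a zero aggregate count are imputed 0, flagged in an attribute, and
  warned about, keeping the 20-vector rectangular.
* **Degenerate statistics** (zero denominators on e.g. all-zero IMF slots)
  are set to 0 with a warning, keeping feature matrices rectangular.
* **Ties in HI** take mid-ranks; a score of exactly 0 (e.g. an all-constant
  HI series) is labelled Worse, since only strictly positive scores mean
  Better.
* **Constant features** under min–max normalization map to 0 everywhere.
* **PSO** uses a linearly decreasing inertia weight (0.9 → 0.4), clips
  positions to the box and velocities to the box width, and stops when the
  global best improves by less than `tol` over a 20-iteration window.
* The "threefold cross-validation" of the evaluation protocol is
  implemented as it is described: three seeded stratified 67/33 resampling
  rounds with arithmetically averaged metrics. Classical disjoint k-fold is
  available via `scheme = "kfold"`.

## Design decisions that were genuinely open

* The 13 frequency-domain indicators are nowhere defined beyond "via FFT";
  applying the same 13 formulas to the amplitude spectrum is this package's
  reading, chosen because the indicator set is presented exactly twice with
  the same 13 names.
* The rank plug-in is $G/(I+1)$ rather than the literal $G/I$, because
  $\varphi^{-1}(1) = \infty$ at the top rank; the correction is the
  standard normal-scores one and preserves sign and ordering.
* Whether the 2500-sample windows were decimated to 500 points or reduced
  some other way is unstated; anti-aliased polyphase resampling was chosen
  because naive subsampling would corrupt every frequency-sensitive
  feature downstream.
* The positive class for recall/precision is label 1 ("Worse"): detecting
  deterioration is the clinical aim. It is configurable; accuracy is
  unaffected.
* The wavelet family (db4) and the EEMD/RCMSE constants are unstated in the
  protocol and fixed here at the field-standard values in the table above.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run the full pipeline on cohorts
of 6 subjects × 10 days (≈ 1000–1100 segments after windowing), with EEMD
ensembles of M = 10 and 200-tree forests for cohort-scale runs; single-
segment checks use the full M = 100 default. The directional comparison
(RF on 184 constructed features vs. RF on the raw 500-point segments)
is repeated over 10 cohort seeds. These sizes are the package's chosen
defaults for its own verification runs; all of them are arguments, not
constants.

## Known limitations

* The generator's beat model is a Gaussian-bump morphology, not a
  dynamical ECG model; clinical beat semantics (QRS detection, HRV from
  true R peaks) are intentionally out of scope — the pipeline itself never
  uses them.
* Feature selection and class-imbalance handling are not implemented (the
  underlying protocol uses none).
* Deep-model baselines are excluded; `cross_validate()`'s `fit`/`predict`
  contract is the plug-in point for adding other classifiers.
* Sample-entropy counting is exact but $O(n^2)$ per offset; it is fast at
  the 500-point segment length the pipeline uses, not for minute-scale
  records at full rate.
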
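---
title: "Channel selection for two-state EEG: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Channel selection for two-state EEG: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the science implemented by `eegchansel`: the
feature definitions, the weighting and selection procedure, the synthetic
data model used for validation, and the numerical and design choices made
where the underlying method left details open. It states no empirical
result beyond what the package's own tests and `scripts/acceptance.R`
compute.

## The problem

Two-condition EEG protocols (here: rested "JX" vs fatigued "ZD" driving)
record tens of electrodes, but most channels are redundant for the
discrimination at hand. The question the package answers is: *which small
electrode subset preserves classification accuracy?* The answer must be
reproducible (seeded end to end) and cheap enough to run on a laptop.

## Processing model

1. **Resampling.** Recordings (typically 1000 Hz) are reduced to 128 Hz
   by polyphase FIR resampling (`signal::resample`, delay-compensated
   anti-alias low-pass). 128 Hz gives a 64 Hz Nyquist, comfortably above
   the highest analysis band (30 Hz), and makes a 6-level wavelet-packet
   tree land on 1 Hz terminal nodes.
2. **Epoching.** Each state's recording is cut into contiguous,
   non-overlapping 1 s windows (128 samples); trailing partial windows
   are dropped. Each epoch carries its state label (JX = 0, ZD = 1).
3. **Features per epoch x channel.**
   - *Subband standard deviation*: a 6-level wavelet-packet decomposition
     splits 0-64 Hz into 64 terminal nodes of 1 Hz; Theta (4-8), Alpha
     (8-13), Beta1 (13-20) and Beta2 (20-30 Hz) are each reconstructed
     from exactly their nodes, and the population SD (divisor N) of the
     reconstruction is the feature.
   - *Fuzzy entropy*: windows of length m and m+1 (N - m windows of each
     length) are compared pairwise by Chebyshev distance d; memberships
     exp(-(d/r_eff)^n_exp) are averaged excluding self-comparisons, giving
     Phi_m and Phi_{m+1}; FE = ln Phi_m - ln Phi_{m+1}. Regular signals
     (e.g. near-sinusoidal fatigue theta) score low, irregular ones high.
4. **Channel weighting.** Two-class ReliefF on the feature matrix:
   min-max scale columns; sample `m_iter` epochs without replacement; for
   each, find the `k_nn` nearest same-class and other-class epochs
   (Euclidean); subtract mean hit differences and add mean miss
   differences, per column, normalized by the number of sampled epochs.
   A channel's weight is the mean of its columns' weights, so a fused
   matrix averages its two features.
5. **Subset evaluation.** Subsets are the prefixes of the descending
   weight ranking. Each subset is scored by stratified 5-fold
   cross-validated KNN accuracy (K = 10), with confusion counts pooled
   over folds. The optimal subset is the smallest size attaining the
   maximum accuracy.

Assumptions worth keeping in mind: epochs are treated as exchangeable
samples (no within-subject correlation modelling); classes are balanced
by construction of the protocol; no artifact rejection or re-referencing
is performed (out of scope by design).

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `target_fs` | 128 | Hz | working rate; 1 Hz terminal nodes at 6 levels |
| `epoch_length_s` | 1 | s | epoch window |
| `levels` | 6 | -- | wavelet-packet depth |
| `wavelet` | `db16` | -- | see "Wavelet choice" below |
| `m` | 2 | samples | FE embedding length |
| `r` | 0.25 | x SD | FE tolerance, relative mode by default |
| `n_exp` | 2 | -- | FE membership exponent |
| `m_iter` | 80 | epochs | ReliefF sampled instances |
| `k_nn` | 10 | epochs | ReliefF nearest hits/misses |
| `K` | 10 | epochs | KNN neighbours |
| `folds` | 5 | -- | CV folds (each an 80/20 split) |

All seeds (generator, ReliefF sampling, fold shuffling) are explicit
arguments; every pipeline output embeds the seeds and a hash of the
configuration, and identical configurations produce byte-identical
report files.

## Numerical choices

**Periodized wavelet transform.** The wavelet-packet analysis uses
circular (periodized) extension rather than symmetric padding. For the
dyadic 128-sample epochs this keeps the transform exactly orthogonal at
every depth: reconstruction is the transpose of analysis, reconstruction
length equals epoch length with no truncation bookkeeping, and terminal
coefficient energy equals signal energy to machine precision (the
energy-conservation property the tests assert at 1e-6 is in practice
~1e-15).

**Terminal-node frequency ordering.** After a high-pass/decimate step the
child node's spectrum is mirrored, so the natural ("Paley") node order is
not the frequency order. The implementation tracks the mirrored
orientation down the tree and flips child ordering inside mirrored nodes
(equivalent to the Gray-code correction), then assigns each 1 Hz terminal
node to the band containing its interval. Band edges must be multiples of
the node bandwidth; the four bands use disjoint node sets by
construction. The ordering is validated against an FFT oracle: tones at
6, 10, 16, and 25 Hz must land in Theta/Alpha/Beta1/Beta2.

**Wavelet choice.** The wavelet family is configurable (`haar`, `db2`,
`db4`, `db8`, `db16`). The default is `db16`: at depth 6 the terminal
filters of short wavelets have wide transition bands, and with `db4` a
pure 6 Hz tone leaves only ~85% of its energy in the Theta
reconstruction, which is too blunt an instrument for band-resolved
features. With `db16` the 6/10/16/25 Hz probes each keep >= 97% of their
energy in band. (These fractions are asserted by the test suite; the
`db4` figure was additionally cross-checked against an independent
wavelet implementation during development.)

**Fuzzy-entropy conventions.** Three details of the FE definition are
commonly left ambiguous, and are fixed here as follows:

- *Window counts*: N - m windows for both lengths m and m + 1, the
  standard convention that makes Phi_{m+1} <= Phi_m pairwise and hence
  FE >= 0.
- *Tolerance scale*: `r` is interpreted as a fraction of the epoch's
  population SD (`r_mode = "relative"`, default). An absolute tolerance
  in microvolts would make FE depend on signal amplitude, which is
  undesirable for a complexity measure; an `"absolute"` mode is exposed
  for completeness.
- *Membership grouping*: the membership is exp(-(d/r_eff)^n_exp), i.e.
  the tolerance divides the distance *inside* the power. With the
  exponent outside (exp(-d^n/r)), relative tolerance would not make the
  measure amplitude-invariant for n != 1; with the grouping used here,
  FE(c x) = FE(x) exactly for any c != 0, which the tests assert.
- *Degenerate input*: a constant epoch returns exactly 0 (all distances
  zero, both averages 1), never NaN.

**ReliefF details.** Columns are min-max scaled before neighbour search
and difference computation — necessary for fused matrices where subband
SD (microvolts) and FE (dimensionless) are incomparable; after scaling,
each column's value range is 1, so differences are already normalized.
Constant columns scale to zero and contribute exactly zero weight.
Instances are sampled without replacement. Weight ties in the final
ranking break toward the lower channel index.

**KNN details.** Features are min-max scaled using training-fold
statistics (applied unchanged to the test fold), for the same
mixed-units reason as in ReliefF. Neighbour-distance ties resolve by
lower training index (stable ordering); vote ties — possible since
K = 10 is even — resolve toward class 0. Cross-validation is stratified
(per-class shuffle, round-robin fold assignment) and accuracy is pooled
over folds' confusion counts rather than averaged per fold; for balanced
folds the two differ by less than CV noise.

**Selection.** The canonical `relieff_sfs()` evaluates prefixes of the
weight ranking: the forward-selection step degenerates to "add the
highest-weighted remaining channel", which is the method's defining
simplification. The classical accuracy-greedy SFS is kept as
`greedy_sfs()` for comparison; its step ties also break toward the lower
channel index. "Smallest size attaining the maximum" resolves accuracy
plateaus toward fewer electrodes.

## The synthetic data model

Real datasets of this kind are typically private, so validation uses a
generative stand-in (`synth_spec()` / `synth_generate()`), with defaults
chosen to emulate a 10-subject study: per subject, 300 s per state at
1000 Hz over the standard 30-electrode montage. Each channel is

- 1/f-shaped ("pink") background noise, SD 10 uV (flattened below 1 Hz),
- plus alpha-band (8-13 Hz) band-limited Gaussian noise, SD 4 uV (the
  resting rhythm, present in all channels and both states),
- plus theta-band (4-8 Hz) band-limited Gaussian noise, SD 4 uV.

In the informative channels (default: T6, O1, Oz, T4, P3, FC3 —
temporo-parieto-occipital sites plausibly sensitive to fatigue), the
fatigue state (i) multiplies the theta amplitude by `theta_power_shift`
(default 2: fatigue EEG shows clearly elevated theta power, and the
planted effect is sized so that the two states are nearly separable, the
regime the method is intended for) and (ii) becomes more regular by
`complexity_shift` (default 0.4): a 6 Hz sinusoid of amplitude
0.4 x 8 uV is added and the background noise damped by a factor
1 - 0.4/2, lowering fuzzy entropy. The two effects are separately
switchable so power-driven (`Theta_Std`) and regularity-driven (`FE`)
selection can each be validated in isolation; setting both to their null
values (1 and 0) yields label-free data on which accuracy must sit at
chance, which the tests assert.

What the generator does **not** emulate: within-subject autocorrelation
beyond the 1/f spectrum, inter-subject variability in electrode
sensitivity, eye-blink/muscle artifacts, electrode drift, or volume
conduction (channels are generated independently). Passing the planted
recovery tests therefore demonstrates that the pipeline's machinery is
correct and sensitive to the intended effect directions — not that the
selected channels would transfer to any particular real cohort.

## Problem sizes used by the tests

The simulation-based checks run at a reduced scale chosen to exercise
every stage with comfortable statistical margins: 2 subjects x 60 s per
state (240 one-second epochs, 120 per class), 20 seed replicates for
end-to-end claims, and 100 seed replicates for the single-stage ReliefF
planted-channel check. `scripts/acceptance.R` regenerates the same
reduced-scale study from a user-supplied seed and reports the optimal
subset size and accuracy per feature set, the planted-channel recovery,
and the fused accuracy at subset size 6.

## Known limitations

- Two classes only; the multi-class ReliefF extension is out of scope.
- Evaluation is KNN-only, matching the method's definition; other
  classifiers would need their own evaluation function.
- Epoch-level cross-validation mixes epochs of the same subject across
  folds; with very few subjects this estimates within-cohort, not
  across-subject, generalization.
- The EDF reader supports 16-bit continuous EDF/EDF+C with a uniform
  sampling rate across kept signals; discontinuous (EDF+D) files are
  rejected.
- `relieff_sfs()` evaluates all 30 prefix sizes; `greedy_sfs()` is
  quadratic in channels and intended for small montages or comparisons.
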
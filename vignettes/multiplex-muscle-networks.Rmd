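---
title: "Methods: synergies, coherence and multiplex muscle networks during walking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synergies, coherence and multiplex muscle networks during walking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and estimators, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, the numerical
choices, and the design decisions taken where the method left room.

## 1. The problem

During treadmill walking the arm swing locks to the leg rhythm at a 2:1
frequency ratio at very low speeds and at 1:1 near normal speed, with an
unstable transition regime between. The package quantifies how this change
of coordination is expressed in multichannel muscle activity along two
complementary routes: *muscle synergies* (co-variation of EMG amplitude
envelopes over the gait cycle) and *intermuscular coherence* (frequency-
resolved correlation of rectified EMG, indexing shared neural input). Both
are condensed into multiplex networks over the same 26 muscles
(`muscle_labels()`: 13 per body side, distal leg to arm) and compared
across coordination modes.

## 2. Gait events and coordination modes (`detect_heel_strikes`, `classify_mode`)

Heel strikes are upward crossings of `fraction × mean(force)` of the
right-foot vertical force, `fraction = 0.08` by default. A refractory
period of 0.25 × the median inter-event interval suppresses double
crossings on noisy rising edges; it is not part of the original criterion
but is required for robustness and cannot delete true events at realistic
stride-time variability. Detection is quantized to the sampling grid, so
planted onsets are recovered to within one sample (plus one more when
onsets fall between samples).

Mode evidence combines two measures:

* **Spectral overlap.** Both traces' Welch spectra are normalized to unit
  area; the leg spectrum's frequency axis is stretched by the candidate
  ratio (2 or 1) and the overlap is the integral of the pointwise minimum.
  The rescaling is implemented by time-compressing the leg signal rather
  than interpolating its spectrum: both spectra then keep the same
  window-limited peak width, so perfectly locked trials overlap near 1.
  Interpolating the spectrum instead would double the rescaled peak's
  width and cap the overlap near 0.6 even for perfect locking.
* **Generalized relative phase.** Each trace is band-passed around its
  dominant spectral peak (± 50% bandwidth, FFT brick-wall, zero-phase) and
  `Φ = p·φ_arm − q·φ_leg` is formed from analytic-signal phases
  (sine-referenced). Its circular variance `1 − |mean(exp(iΦ))|` is ~0 for
  stable locking and →1 under drift.

The label rule: 2:1 when `overlap_21 − overlap_11 > δ` *and*
`circvar_21 < v`; 1:1 symmetrically; otherwise transition. Defaults
`δ = 0.15`, `v = 0.2` are exposed in the configuration. No numeric
thresholds were published for "dominant" overlap; these values sit far
from both failure modes on synthetic trials (locked trials show overlap
differences > 0.8 and circular variances < 0.05; transition trials show
both circular variances > 0.5).

## 3. EMG conditioning (`highpass_rectify`, `emg_envelope`, `time_normalize`, `amplitude_normalize_average_concat`)

Rectification uses the modulus of the analytic signal after a 2nd-order
bidirectional (zero-phase) Butterworth high-pass at 30 Hz; envelopes are
the 10 Hz zero-phase low-pass of the rectified signal, clipped at zero
because the factorization requires non-negative input. Strides (right heel
strike to next right heel strike) are linearly interpolated to N = 200
samples; linear interpolation is exact on linear segments and introduces
no overshoot. Amplitudes are normalized per subject and muscle by the
*mean* envelope during the fastest speed (4.0 km/h) — "average activity"
is read as the mean, not the peak. Strides are averaged within each
(subject, coordination mode) cell and the cell averages are concatenated
row-wise into `X` (`SC·N × 26`).

Optional heartbeat removal (`remove_heartbeat`, off by default) runs
FastICA (tanh contrast, symmetric decorrelation — implemented in the
package since no ICA dependency is available) and zeroes components whose
raw waveform autocorrelation exceeds 0.5 at a lag corresponding to
0.8–1.5 Hz. The original criterion was unspecified; an envelope-spectrum
rule was rejected because stride-periodic EMG envelopes (≈ 0.8 Hz at slow
walking) fall in the cardiac band, whereas *waveform* periodicity
separates a deterministic QRS wavelet train (autocorrelation ≈ 1 at the
beat lag) from amplitude-modulated noise (≈ 0). ICA can only isolate
contamination that is actually visible; the stage is validated against a
planted artifact at realistic (large) amplitude and verified to be a
near-identity on clean data.

## 4. Synergy extraction (`nmf_synergies`, `select_rank`)

`X ≈ t(W A)` with muscle weights `W ≥ 0` (26 × m, unit-maximum columns)
and activation waveforms `A ≥ 0`, fitted by Lee–Seung multiplicative
updates on the Frobenius norm (RcppArmadillo inner loop; tolerance 1e-6 on
the relative error change, ≤ 1000 iterations, best of 5 random restarts by
default — all unpublished in the original method and therefore fixed and
seed-exposed here). Reconstruction quality is
`λ(m) = (1 − ‖X − WA‖²_F/‖X‖²_F)·100`; per-synergy contributions use the
same formula with a single rank-1 term and may legitimately be negative.

**Rank rule.** `m` is the smallest rank with `λ(m) ≥ 80%` while every rank
up to `m` adds ≥ 1.5% ("and, additionally" is read as a conjunction). Each
rank is warm-started from the previous rank's solution plus one small
random column in addition to the random restarts; multiplicative updates
never increase the objective, so the λ profile is non-decreasing by
construction — an invariant the rule implicitly assumes.

Synergies are ordered by the circular mean location of the per-stride
activation maximum (ties broken by the index of the largest muscle
weight).

## 5. Intermuscular coherence (`welch_coherence`, `surrogate_correct`, `nmf_frequency_components`)

Rectified EMG is anti-alias filtered and resampled to 256 Hz, mean-centered
per segment and concatenated per condition. Squared coherence
`C² = |P_xy|²/(P_xx·P_yy)` uses a 200 ms Hamming taper (51 samples), hop 26
samples ("about 50%"), FFT zero-padded to 256 samples. The padding defines
a 1 Hz grid — convenient because the native resolution of a 200 ms taper
(~5 Hz) is coarser than the 4–8 Hz band — but adds no information:
neighboring 1 Hz bins are correlated over ~5 Hz, which matters for
counting independent observations (see §8).

**Bias correction and masking.** 100 phase-randomized surrogates (identical
amplitude spectra, uniform phases) provide a zero-coherence null. Its
per-bin mean `μ(f)` estimates the finite-sample bias (≈ 1/K for K averaged
segments). Under the null, `2·C²/μ(f)` follows a χ² distribution with two
degrees of freedom, so bins with `C² ≤ μ(f)·qchisq(0.95, 2)/2` are set to
exactly zero; surviving bins are reported as `C² − μ(f)` (floored at 0).
The published prose ("served as normalization factor") also admits a pure
ratio `C²/μ`, but that changes units: downstream the corrected values act
as network edge weights on the coherence scale (≤ 1), and mean corrected
values on independent noise must be ≪ 1. The subtractive form keeps the
scale while removing the bias; this choice is fixed and tested.

Corrected spectra over 4–60 Hz (57 bins) for all 325 pairs are assembled
into a frequency × (SC·325) matrix (subject-condition-major, pair-minor
column order, written to the JSON header) and decomposed with the same NMF
engine and rank rule at the adjusted cutoffs 55% / 4%. Each component's
dominant band is the contiguous bin run at ≥ 50% of the profile maximum.
The low-frequency variant repeats the pipeline with a 5 s taper over
0.6–4 Hz. Masking happens per subject-condition pair spectrum, before any
subject averaging, following the order in which the processing steps are
described.

## 6. Multiplex networks (`synergy_layers`, `coherence_layers`, `minimally_connect`, `communities_multiplex`, `layer_metrics`)

Synergy layer `j` is `w_j w_jᵀ` with zero diagonal, scaled by the summed
trapezoidal integral of synergy `j`'s condition-averaged waveform over the
gait cycle. Coherence layers place the 325 component weights into a
symmetric 26 × 26 adjacency per frequency component × condition, averaged
over subjects (averaging before thresholding, one of two defensible
orders).

**Minimal connectivity.** `τ*` is the largest global threshold at which
every muscle keeps ≥ 1 supra-threshold edge in some layer — equivalently
the minimum over nodes of the strongest incident edge across layers, which
an exhaustive search over candidate thresholds confirms on random toys.
`k` is the largest per-layer count of edges ≥ τ*; every layer keeps its
`k` strongest edges, supra-threshold first, padded with its strongest
sub-threshold edges so edge counts are constant across layers (one
consistent reading of the equal-edge-count requirement; fixed and
brute-force-tested). Mean ± sd of removed and kept weights are reported.

**Communities.** The published method names Louvain but not a multilayer
variant. Layers are normalized to unit total weight and averaged, Louvain
(igraph) runs on the aggregate with seeded restarts (best modularity
kept), and per-layer modularity is evaluated post hoc by applying the
partition to each layer. A coupled multilayer Louvain is the untaken
alternative; the aggregate contract is deterministic and matches
"community structure across layers".

**Metrics.** With weights normalized by the layer maximum: global
efficiency is the mean inverse weighted shortest-path length (edge length
= 1/weight; disconnected pairs contribute 0), transitivity is the ratio of
closed to all weighted triplets with geometric-mean triangle weights
(complete unit graph → 1, star → 0), and average strength is the mean raw
row sum. The cited literature gives no formulas; these are the standard
weighted-graph conventions.

## 7. Waveform and metric statistics (`spm_paired`, `metric_anova`)

Synergy waveforms are compared pointwise between modes with paired t
curves; cluster-level inference uses sign-flip permutations of the subject
difference waveforms with a max-cluster-mass null (cluster-forming
threshold = two-sided α quantile of t). The original analysis used
random-field-theory SPM; the permutation test is assumption-free, exact
for exchangeable nulls, and verifiable at desk scale — this deviation is
deliberate. Comparisons run on raw and per-subject maximum-normalized
waveforms, at the Bonferroni-corrected α = 0.05/(3 condition pairs × 5
synergies) = 1/300 ("(3.5)" is read as 3 × 5). Network metrics get a
repeated-measures ANOVA (subject as random factor, values averaged over
layers within subject × condition) and post-hoc paired t tests per
frequency component at α = 0.005; on two conditions the omnibus F equals
the squared paired t, which is tested numerically.

## 8. The synthetic world: what it states and what a green test means

`generate_study()` emulates the experimental design at reduced scale
(default 2 subjects × 3 speeds × 16 strides; the original had 16 subjects
× 7 speeds, with ≥ 15 strides per trial). The stated world:

* **Kinematics.** Leg sinusoid at the stride frequency (+ weak second
  harmonic); arm at twice that in 2:1 mode, equal in 1:1, and a linear
  chirp from 2× to 1× across the trial in the transition (phase-drift
  model, chosen over random switching for an unambiguous ground truth).
  Stride times are jittered at 3% CV (typical treadmill variability).
* **Force.** The trace is the *right-foot* vertical force: one smoothed
  stance pulse (60% duty, raised-cosine edges) per stride. With both feet
  summed, double support would keep the total force permanently above the
  8% threshold and threshold crossings could not mark heel strikes; the
  single-foot trace is what the kinetic criterion needs.
* **EMG.** Five synergies: circular Gaussian activation bumps (width 0.07
  cycle) at 5/25/45/65/85% of the cycle, block-structured non-negative
  weights with weak cross-talk, a tonic baseline of 0.25, multiplied by
  independent broadband carriers. Band-limited common input (4–8, 8–22,
  22–60 Hz; disjoint muscle groups; modulation depth 0.5) *amplitude-
  modulates* the carriers of its muscle subset. An additive band-limited
  term was rejected: the 30 Hz high-pass removes any additive 4–22 Hz
  component before rectification, so it could never reach the coherence
  stage; multiplicative modulation is demodulated by rectification exactly
  as common synaptic drive is in real EMG. Optional heartbeat: a
  Gaussian-derivative wavelet train at 1.2 Hz with a fixed mixing
  gradient.
* **Calibrations stated once.** `synth_envelope_matrix()` scales the
  planted signal to carry 80% of `‖X‖²_F` after the non-negativity clip —
  the reconstruction share reported at the selected rank — so the λ
  profile crosses the 80% cutoff at the planted rank exactly as in the
  motivating data. `synth_coherence_set()` plants near-disjoint pair
  loadings per band plus sparse exponential clutter scaled so planted
  structure carries 57% of the squared norm, mirroring the reported
  decomposition where three components held ~19% each.

What the generator does **not** emulate: biomechanical limb dynamics,
muscle-specific EMG morphology, inter-subject variability of weights and
band gains (exposed as free parameters, not fixed — no published
magnitudes exist), electrode artifacts beyond the heartbeat, and the
acquisition band-pass. Consequently a green test establishes that the
estimators recover *planted* structure under realistic noise — not that
they would reproduce any subject-level physiological finding.

Two honest consequences of the scaled-down default study: its concatenated
envelopes are cleaner than real data, so the 80%-cutoff rule can stop at
rank 4 of 5 planted synergies (the cumulative share crosses 80% early);
and its corrected coherence retains stride-locked leakage through the
~5 Hz taper mainlobe, so the 55% rule may merge the low bands into two
components. The dedicated generators above, calibrated to the reported
shares, recover rank 5 and all three bands reliably; those are the tested
claims.

## 9. Numerical choices

* Butterworth filters are 2nd-order bilinear-transform designs applied
  forward and backward (zero phase, squared magnitude); edge effects are
  handled by reflective padding (≤ 300 samples).
* Resampling and narrow-band filtering use FFT brick-wall masks: exact,
  zero-phase, and deterministic; acceptable here because all downstream
  estimators are spectral.
* The surrogate-masked false-positive rate is ~5% per *independent* bin;
  with the 1 Hz zero-padded grid, ~11 of the 57 bins in 4–60 Hz are
  independent, which is the Bernoulli count used when checking calibration.
* NMF column matching against planted weights maximizes total cosine
  similarity by exhaustive permutation search (m ≤ 8).
* All stochastic stages take explicit seeds; `run_study()` records the
  full parameter snapshot in its report. Stage outputs are not cached on
  disk: a full synthetic study runs in minutes and cache invalidation
  would be the larger risk.

## 10. Known limitations

* The layer-aggregate Louvain contract cannot detect communities that
  exist only in anti-correlated layers.
* The equal-edge-count padding rule can re-admit sub-threshold edges in
  sparse layers; the reported `removed`/`kept` summaries make this
  visible.
* The transition classifier assumes a monotone frequency drift; real
  transitions with intermittent re-locking would need a time-resolved
  extension.
* Configs and reports use JSON rather than YAML (no YAML parser among the
  package's allowed dependencies).
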
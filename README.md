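# gaitmuscnet

Muscle synergies and multiplex coherence networks during walking.

When walking speed rises from very slow to normal, the arm swing switches
spontaneously from a 2:1 to a 1:1 frequency locking with the legs.
`gaitmuscnet` implements the full analysis chain used to study how that
switch is reflected in coordinated muscle activity, going from raw
multichannel surface EMG (26 bilateral muscles at 2 kHz), ground reaction
force and arm/leg kinematics (70 Hz) to:

1. **Gait events and coordination modes** — heel strikes from an 8%-of-mean
   force threshold; trial labels (2:1, transition, 1:1) from the spectral
   overlap of arm and leg power spectra after frequency-axis rescaling,
   combined with the circular variance of the generalized relative phase
   `p·φ_arm − q·φ_leg`.
2. **Muscle synergies** — EMG envelopes (30 Hz zero-phase high-pass →
   analytic-signal rectification → 10 Hz low-pass → 200-sample stride
   normalization → amplitude normalization and concatenation into an
   `X ≈ W·A` matrix) factorized by multiplicative-update NMF. The rank is
   the smallest `m` with reconstruction quality
   `λ(m) = (1 − ‖X − W A‖²_F / ‖X‖²_F)·100 ≥ 80%` while every synergy up to
   `m` still adds ≥ 1.5%.
3. **Intermuscular coherence** — Welch squared coherence
   `C²(f) = |P_xy|²/(P_xx P_yy)` (200 ms Hamming taper, ~50% overlap, 1 Hz
   grid at 256 Hz) for all 26·25/2 = 325 muscle pairs, bias-corrected with
   100 phase-randomization surrogates and masked at α = 0.05 against the
   χ²₂ null; the frequency × (subjects·conditions·325) matrix is then
   NMF-decomposed into frequency components (cutoffs 55% / 4%). A
   low-frequency variant (5 s taper, 0.6–4 Hz) is included.
4. **Multiplex muscle networks** — synergy layers from outer products
   `w_j w_jᵀ` weighted by activation-waveform integrals; coherence layers
   per frequency component × condition; thresholding to a
   minimally-connected equal-edge-count multiplex; Louvain community
   structure; weighted global efficiency, transitivity and average
   strength; Rand / adjusted Rand comparison of partitions.
5. **Statistics** — 1D statistical parametric mapping of synergy waveforms
   between coordination modes (paired t curves, sign-flip max-cluster-mass
   permutation inference at the Bonferroni-corrected α = 0.05/(3·5) =
   1/300) and repeated-measures ANOVA of network metrics across conditions
   with post-hoc paired tests.

Because no public recording exists, the package ships a first-class
synthetic-data module (`generate_study()`, `synth_envelope_matrix()`,
`synth_coherence_set()`) that plants known synergies, band-limited common
inputs (4–8, 8–22, 22–60 Hz), coordination modes and heel strikes, so every
stage is tested against ground truth. See the methods vignette
(`vignettes/multiplex-muscle-networks.Rmd`) for the model, parameter
choices and limitations.

## Worked example

```r
library(gaitmuscnet)

## a synthetic trial: very slow walking, planted 2:1 arm-leg locking
rec <- generate_recording(subject = 1, speed_kmh = 1.0, seed = 42)
rec
#> <gait_recording> subject 1, 1.0 km/h, mode 2:1, 16 strides
#>   EMG 67221 x 26 @ 2000 Hz; kinematics @ 70 Hz

classify_mode(rec$kin$arm, rec$kin$leg, rec$fs_kin)
#> <mode_evidence> label 2:1 | overlap 2:1 0.97 / 1:1 0.02 | circvar 2:1 0.00 / 1:1 1.00

detect_heel_strikes(rec$kin$grf, rec$fs_kin)
#> <gait_events> 16 heel strikes (right), threshold 35.85

## synergy rank selection on a planted rank-5 envelope matrix
sm  <- synth_envelope_matrix(n_sc = 6, noise_sd = 0.05, seed = 1)
sel <- select_rank(sm$X, seed = 1)
sel$m
#> [1] 5
round(sel$lambda_profile, 1)
#> [1] 41.0 54.8 66.9 77.9 87.7 88.3 89.0 89.7
match_columns(sel$models[[sel$m]]$W, sm$W_true)$cosines
#> [1] 0.998 0.998 0.998 0.998 0.999

## frequency components of a planted 3-band coherence set
scs <- synth_coherence_set(n_sc = 6, seed = 1)
nmf_frequency_components(scs$C, freqs = scs$freqs, seed = 1)
#> <coherence_components> m = 3; bands: 4-8 Hz, 22-60 Hz, 8-22 Hz
```

The mode evidence reads: spectral overlap is near 1 at the 2:1 frequency
ratio and near 0 at 1:1, and the 2:1 generalized relative phase is almost
constant (circular variance 0.00), so the trial is labelled 2:1. The λ
profile crosses the 80% cutoff at rank 5 (77.9% → 87.7%) while a sixth
synergy would add only 0.6%, and the recovered muscle-weight columns match
the planted ones at cosine ≥ 0.998 after optimal assignment. The coherence
decomposition selects three components whose dominant bands are exactly the
planted 4–8, 8–22 and 22–60 Hz bands.

A full study (generation → modes → synergies → coherence → networks →
statistics) runs with:

```r
report <- run_study(default_config(seed = 1))
validate_against_ground_truth(report, default_ground_truth(seed = 1))
```

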
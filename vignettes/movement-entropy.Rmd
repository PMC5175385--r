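---
title: "Spectral entropy of movement-related EEG desynchronization: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral entropy of movement-related EEG desynchronization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Voluntary movement suppresses sensorimotor oscillations — the mu rhythm
(~8–13 Hz) and the beta rhythm (~14–30 Hz) desynchronize relative to rest.
In young adults this event-related desynchronization (ERD) is deep and
narrowband, confined to a few frequency bins near 10 and 20 Hz over the
contralateral sensorimotor cortex. In healthy aging the response flattens:
the power decrease spreads across the whole 8–25 Hz range and over a wider
set of channels, including frontal and ipsilateral sensorimotor sites. The
package quantifies this difference in *spectral shape* with a single number
per channel — the normalized spectral entropy of the baseline-relative power
spectrum — and provides the inferential machinery to test it at the sensor
level.

## The analysis chain

**Relative power.** Power spectra are estimated per trial and channel from 8
to 25 Hz in 1-Hz steps by a single-Hanning-taper FFT of 1-s movement epochs.
Movement power is expressed as percent change against a resting baseline:

$$\mathrm{Pow}_{rel} = 100 \times
  \frac{\mathrm{Pow}_{move} - \mathrm{Pow}_{baseline}}
       {\mathrm{Pow}_{baseline}}.$$

Per-trial percent change is computed first and trials are averaged
afterwards, giving one participant-level spectrum per task and channel.

**Spectral entropy.** The participant-level spectrum over a band of $N$ bins
is magnitude-normalized, $p_i = |\mathrm{Pow}_{rel}(i)| / \sum_j
|\mathrm{Pow}_{rel}(j)|$, and summarized by

$$H = -\frac{1}{\ln N} \sum_i p_i \ln p_i \in [0, 1],$$

with $0\ln 0 := 0$. A flat ("aged-like") spectrum gives $H \to 1$; a peaked
("young-like") spectrum gives $H \to 0$. Entropy is computed in the broad
8–25 Hz band ($N = 18$) and in 13–19 Hz ($N = 7$), the band where group
differences of relative power are largest.

**Statistics.** Channel-wise group contrasts use Student's pooled-variance
t-test for band-mean relative power and a Wilcoxon rank-sum test for
entropy, each followed by Benjamini–Hochberg FDR correction across channels;
per-bin contrasts over the left sensorimotor ROI (FC3, C3, CP3) are FDR
corrected across the 18 bins. Pooling tasks, a random-intercept linear mixed
model `value ~ group + task + (1 | participant)` is fitted per channel; the
group p-value per channel is FDR corrected. Post-hoc task differences within
each group come from pairwise comparisons of estimated marginal (least-square)
means under the group × task interaction model.

## The synthetic-data generator

The study's raw EEG is not public, so the package ships a seeded generator
whose outputs carry the group signatures above by construction. Signals are
synthesized in the frequency domain: every positive-frequency DFT
coefficient is drawn as a circular complex Gaussian whose variance follows a
target one-sided PSD, so each epoch is an independent realization of a
stationary Gaussian process with exactly the intended spectrum in
expectation. The target PSD is a $1/f^{\beta}$ background plus Gaussian
spectral bumps (center, FWHM bandwidth, peak height); during movement each
bump's power is multiplied by $1 - d$, $d \in [0, 1)$, so the configured
depth *is* the fractional power decrease at the bump — depth acts on power,
not amplitude, because the percent-change formula operates on power.

Preset profiles encode the two groups. *Young*: mu (10 Hz, FWHM 2 Hz, depth
0.75) and beta (20 Hz, FWHM 2.5 Hz, depth 0.7) bumps confined to FC3/C3/CP3,
with task-scaled depth (whole-hand grip 0.65 × pinch grip) to create the
task-specific response seen only in young participants. *Elderly*: one wide
bump (center 16.5 Hz, FWHM 17 Hz, depth 0.45) over nine channels spanning
frontal, contralateral and ipsilateral sensorimotor sites — shallower per
bin but broadband and spatially extended. Bump heights are 4–6 × the
background at their peak so percent change at affected bins is dominated by
the oscillatory component. These depths were calibrated once, to the
qualitative pattern only; no per-channel magnitudes are published to match.

Defaults mirror the recorded cohort: 1000 Hz sampling, 1-s movement epochs,
2-s baseline segments (60 per participant, i.e. 2 min of rest, within the
recorded 2–5 min pre- plus post-experimental range), 64 trials per grip
task, 32 elderly / 34 young participants, and common-average re-referencing
as the final generation step. Between-participant variability is a
multiplicative jitter on depth (multiplier ~ Normal(1, 0.1), effective depth
truncated to [0, 0.95]). Per-participant sub-seeds derive deterministically
from the master seed through a counter scheme, so regeneration is
bit-identical and independent of generation order.

What the generator does **not** emulate: eye/muscle artifacts (an
amplitude-threshold rejection utility exists but synthetic data are clean),
volume conduction from a head model, non-Gaussian or non-stationary
dynamics, and line noise. Passing tests therefore demonstrate correctness of
the analysis chain and its statistical calibration on signals with known
ground truth — not robustness to the artifacts of real recordings.

## Numerical and design choices

- **Taper normalization.** One-sided PSD, $P(f) = 2|X_w(f)|^2 / (f_s \sum
  w^2)$: white noise is flat and unbiased, and a unit sinusoid at a bin
  center yields $T/3$ at any sampling rate. Any fixed convention would do —
  percent change cancels scale — but this one makes absolute PSD checks
  against the generator target meaningful.
- **Baseline windows.** 2-s baseline segments have 0.5-Hz native resolution;
  the percent-change formula needs bin-identical grids, so baselines are cut
  into non-overlapping 1-s sub-windows and power is averaged over all
  sub-windows of all segments.
- **Entropy normalization.** Magnitudes (absolute values) are used in both
  numerator and denominator so $p$ is a probability vector, which together
  with the $1/\ln N$ factor guarantees $H \in [0,1]$. An all-zero band
  raises an error rather than returning 0 or NaN — the quantity is undefined
  and silent propagation would poison downstream tests.
- **Wilcoxon.** Midranks for ties; exact two-sided p by exhaustive
  enumeration of group assignments for pooled sizes up to 12 (the exact path
  cannot exceed 1 by construction), otherwise a normal approximation with
  tie-corrected variance and continuity correction.
- **FDR.** Benjamini–Hochberg step-up (the cited procedure), not
  Benjamini–Yekutieli.
- **t-test.** Pooled-variance Student by default, Welch behind a flag.
- **Mixed models.** REML estimates; the group p-value is a likelihood-ratio
  test of maximum-likelihood refits with and without the group term
  (always from the additive model — a main-effect test inside an interaction
  model is ill-posed). Singular fits (zero participant variance) are
  reported, not hidden; optimizer failures raise errors with diagnostics.
  Estimated marginal means are computed exactly from the fixed effects and
  their covariance (every group × task cell is in the reference grid);
  post-hoc contrasts use the emmeans machinery with the asymptotic (z)
  reference, chosen over Kenward–Roger for determinism and speed at
  simulation scale. The χ²(1) reference of the LRT is asymptotic in the
  number of participants and mildly anticonservative at a few dozen
  participants per group, which is why the type-I calibration study uses
  100 participants per group.
- **Problem sizes in the test-suite simulations.** Calibration studies run
  at reduced size (16-channel montage, 128 Hz, 6 participants/group, 200
  replicates for the null discovery fraction; 500 direct LMM replicates for
  type-I error); the pattern-recovery study uses 15 participants per group —
  the recorded grip-task subgroup sizes — with the desk-scale pipeline
  defaults (16 channels, 40 trials, 30 baseline segments) over 20 seeds.
  These sizes were chosen to make Monte-Carlo error small relative to the
  tested margins.

## Known limitations

- The generator's spectral synthesis produces Gaussian, trial-stationary
  epochs; real EEG is neither, and entropy values on real data will sit in a
  different part of [0, 1] than the synthetic ones.
- The Hanning-taper periodogram smears a target spectrum over ±1 bin
  (weights 1/6, 2/3, 1/6), so very narrow components are estimated slightly
  low at their peak; bin-wise *ratios* (hence percent change) are unaffected.
- Single-taper power on 1-s epochs has high per-trial variance; all
  inference is done on trial-averaged, participant-level values.
- The whole-study mixed models treat channels independently (as in the
  original analysis); no spatial correction beyond FDR across channels is
  attempted.
- EDF export quantizes to 16 bits over each channel's range; round trips are
  exact only to (range / 65535).
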
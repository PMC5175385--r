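# erdentropy

Sensor-level analysis of movement-related EEG desynchronization, built
around a simple question: does movement suppress oscillatory power in a few
narrow frequency bands, or across the board? In young adults, voluntary
movement produces deep, narrowband power decreases near 10 Hz (mu) and
20 Hz (beta) over the contralateral sensorimotor cortex. In healthy aging
the response flattens into a broadband, frequency-unspecific
desynchronization over a wider set of channels. `erdentropy` quantifies that
difference in spectral *shape* and tests it channel by channel. It is
written for EEG researchers who want a reproducible, fully seeded pipeline —
from raw (synthetic or imported) epochs to FDR-corrected topographic
statistics — without any external data dependency.

## The method

Per trial and channel, power is estimated on the 8–25 Hz grid (1-Hz steps,
18 bins) with a single-Hanning-taper FFT of 1-s epochs, and expressed as
percent change against a resting baseline:

```
Pow_rel = 100 × (Pow_move − Pow_baseline) / Pow_baseline
```

Trials are then averaged per participant. The shape of the resulting
spectrum is summarized by the normalized spectral entropy

```
H = −(1 / ln N) Σ_i p_i ln p_i,   p_i = |Pow_rel(i)| / Σ_j |Pow_rel(j)|
```

so `H ∈ [0, 1]`: a flat, broadband ("aged-like") spectrum gives `H ≈ 1`, a
peaked, narrowband ("young-like") one gives `H ≈ 0`. Group inference uses
Student's t (relative power) or Wilcoxon rank-sum (entropy) per channel with
Benjamini–Hochberg FDR correction, per-bin t-tests over the left
sensorimotor ROI (FC3, C3, CP3; FDR over 18 bins), and — pooling tasks —
per-channel random-intercept mixed models `value ~ group + task +
(1 | participant)` with post-hoc task contrasts via estimated marginal
means.

A seeded synthetic-EEG generator (frequency-domain synthesis over a
`1/f^β` background, Gaussian oscillatory components whose power is scaled
by `1 − d` during movement) provides ground-truth data with young-like and
elderly-like presets, so the whole chain is testable offline.

## Worked example

```r
library(erdentropy)
library(dplyr)

cfg <- pipeline_config()             # toy16 montage, 10/group, seed 1
res <- run_pipeline(cfg, out_dir = "erd_out")

res$bands$beta$metrics |>
  filter(metric == "entropy", channel == "C3") |>
  group_by(group) |>
  summarise(mean_H = mean(value))
#>   group   mean_H
#> 1 elderly  0.967
#> 2 young    0.865
```

The elderly group's 13–19 Hz spectrum at C3 is nearly flat (`H ≈ 0.97`)
while the young group's is peaked (`H ≈ 0.87`). The per-channel mixed model
localizes the effect (negative `estimate` = lower entropy in the young
group; `emmean_*` are model-based group means):

```r
res$bands$beta$group_effects$entropy |>
  filter(channel %in% c("FC3", "C3", "CP3", "F3", "Oz"))
#>   channel estimate  p_value p_adjusted significant emmean_elderly emmean_young
#> 1      C3 -0.10212 2.15e-06   1.15e-05        TRUE          0.967        0.865
#> 2     CP3 -0.10792 6.60e-06   2.11e-05        TRUE          0.967        0.859
#> 3      F3 -0.08668 1.85e-04   3.70e-04        TRUE          0.968        0.881
#> 4     FC3 -0.09499 9.83e-07   7.86e-06        TRUE          0.967        0.872
#> 5      Oz -0.00808 5.32e-01   6.08e-01       FALSE          0.898        0.890
```

Sensorimotor and frontal channels are flagged; occipital channels are not.
The per-bin ROI test shows why: the young desynchronize deeply at 9–11 Hz
(−58 to −64%) and barely at 13–16 Hz, while the elderly sit near −30%
everywhere, producing a significant mid-beta block:

```r
res$binwise$pinch_grip |> select(freq, mean_elderly, mean_young, significant)
#>  freq mean_elderly mean_young significant
#>     8        -31.5      -26.8       FALSE
#>     9        -30.0      -58.2        TRUE
#>    10        -32.5      -63.8        TRUE
#>    ...
#>    13        -31.7       -1.0        TRUE
#>    14        -29.3        0.6        TRUE
```

`plot_topomap()`, `plot_bin_spectrum()` and `autoplot()` methods draw the
corresponding topographies and bin profiles; `tidy()`/`glance()` work on the
mixed-model fits. A thin CLI wrapper lives at `inst/cli/erd-pipeline.R`
(subcommands `simulate`, `power`, `entropy`, `stats`, `run`).

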
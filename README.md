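# phagoquant

Quantitative image analysis of large-particle internalization by B cells,
and of localized RAC1 activation during engulfment.

B cells can take up whole bacteria and micron-sized beads through their
IgM B-cell receptor. Two measurements anchor that biology, and this package
implements both as open, tested pipelines:

1. **Internalization scoring of imaging-flow-cytometry events.** Each event
   is one multi-channel image of a single cell (brightfield, nuclear stain,
   surface marker, particle fluorescence). The cell and the particle are
   segmented, events where either object is out of the focal plane are
   excluded, and each remaining particle-positive event gets the
   radius-corrected centroid-distance score

   *s* = *R* / max(*d*, ε),

   where *R* is the equivalent-circle cell radius (μm), *d* the distance
   between cell and particle centroids (μm), and ε one pixel. A particle
   sitting on the membrane gives *s* ≈ 1; events with *s* ≥ 2 (the particle
   centroid inside half the cell radius) are classified **internalized**,
   others **bound**. Cohorts are summarized as % interacting (particle-
   positive among focused cells) and % internalized (among particle-positive
   cells), with trapezoidal AUC for time courses and paired t-tests for
   donor-matched comparisons.

2. **Ratiometric FRET biosensor analysis of RAC1 activation.** For a
   Cerulean3 (donor) / Venus (acceptor) RAC1 biosensor time-lapse, the chain
   is: background correction (median outside the cell, per frame and
   channel), integer-pixel alignment to frame 1 by cross-correlation, 3×3
   mean smoothing, then the bleed-through-corrected ratio

   *F* = (*V* − β·*C*) / *C*, with β = 0.62 by default,

   where pixels below an acceptor-channel threshold become NaN. RAC1
   activation at the particle contact is summarized as
   *A*(t) = mean ratio in a membrane band facing the particle / mean ratio
   in the adjacent cytosol. β can be recalibrated from donor-only cells via
   least-squares regression of acceptor on donor intensity.

A **synthetic-data module** generates ground-truthed event images and
biosensor stacks (geometry classes, defocus blur, Gaussian noise, stage
drift, donor leakage), so every stage of both pipelines is testable without
any instrument data.

## Worked example: scoring a synthetic cohort

```r
library(phagoquant)

cohort <- generate_cohort(200, mixture = c(0.1, 0.35, 0.35, 0.2),
                          noise_sd = 30, seed = 42)
scored <- score_events(cohort)
dplyr::select(scored, event_id, label, R_um, d_um, score, label_pred)
#>   event_id label        R_um  d_um  score label_pred
#> 1 ev_0001  no_particle  3.50 NA    NA     no_particle
#> 2 ev_0002  no_particle  3.50 NA    NA     no_particle
#> 3 ev_0003  bound        3.51  4.00  0.878 bound
#> 4 ev_0004  off_plane    3.52  3.98  0.883 excluded_unfocused
#> ...

summarize_cohort(scored)
#>   n_total n_focused n_particle_positive n_internalized pct_interacting pct_internalized
#> 1     200       155                 129             66            83.2             51.2
```

200 simulated events: 45 are excluded by the focus gate (the truth mixture
contains 20% out-of-plane events), 129 of the remaining 155 contain a
particle (83.2% interacting), and 66 of those score *s* ≥ 2 (51.2%
internalized). `plot_score_histogram(scored)` draws the score distribution
with the bound/internalized shading, and
`auc_time_course(c(5, 10, 20, 30), c(12.1, 24.8, 39.5, 41.2))` returns
`817.25` %·min for a 4-point uptake time course.

## Worked example: FRET activation trace

```r
gen <- generate_fret_stack(fret_truth(frames = 8, engulf_frames = 3:6),
                           noise_sd = 20, seed = 1)
res <- fret_pipeline(gen$stack, beta = 0.62)
res$trace
#>   frame time_min membrane_mean cytosol_mean activation_ratio
#> 1     1      0.0        0.9992       0.9987           1.0005
#> 3     3      1.0        1.9953       1.0456           1.9082
#> 5     5      2.0        1.9875       1.0452           1.9016
#> 7     7      3.0        0.9994       0.9992           1.0002
```

During the simulated engulfment window (frames 3–6) the membrane band at
the particle contact reads ~2× the cytosol, and *A*(t) returns to ~1
afterwards. `render_ratio_heatmap(res$ratio_map, dir = "heatmaps")` writes
the blue-to-red ratio images. Calibration from donor-only cells:

```r
fit <- estimate_bleedthrough(generate_donor_only(50, beta = 0.62,
                                                 noise_sd = 20, seed = 1)$stacks)
glance(fit)
#>   beta_hat beta_pct n_cells n_pixels r.squared
#> 1    0.612     61.2      50   242050     0.954
```

## Command line

`inst/cli/phagoquant.R` wraps the same functions:

```sh
Rscript inst/cli/phagoquant.R simulate --n 200 --mixture 0.1,0.35,0.35,0.2 --seed 42 --out events/
Rscript inst/cli/phagoquant.R score    --in events/ --threshold 2 --out scored/
Rscript inst/cli/phagoquant.R run      --config experiment.json --out run1/
```

`run_experiment()` (the `run` subcommand) executes simulate → score →
summarize (→ FRET) from one JSON config and writes all tables, the resolved
configuration with derived seeds, a log, and an MD5 manifest; identical
configs reproduce identical tables.

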
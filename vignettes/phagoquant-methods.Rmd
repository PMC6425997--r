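---
title: "Methods: internalization scoring and FRET ratiometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: internalization scoring and FRET ratiometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagoquant)
```

This vignette explains the models behind the two pipelines, the parameters
that matter, what the synthetic generators do and do not emulate, and the
numerical and design choices made where the method left room.

## The internalization score

Imaging flow cytometry produces one multi-channel image per cell event. To
decide whether a micron-scale particle (a bacterium of ~1 μm, or a 3 μm
IgM-coated bead) is membrane-bound or fully engulfed, the pipeline reduces
each event to three geometric quantities: the cell's equivalent-circle
radius $R = \sqrt{\mathrm{area}/\pi}$ (μm), the particle centroid, and the
distance $d$ (μm) between the two centroids. The score is

$$s = \frac{R}{\max(d, \varepsilon)}, \qquad \varepsilon = 1\ \text{pixel},$$

and an event is called **internalized** when $s \ge \tau$ with $\tau = 2$.
The geometry makes the boundary interpretable: a particle centred exactly
on the membrane has $d = R$, hence $s = 1$; a centroid halfway to the cell
centre has $s = 2$. Membrane-bound particles necessarily sit at
$d \ge R$, so bound events live at $s \le 1$, well clear of the cutoff.
The floor $\varepsilon$ keeps $s$ finite when the centroids coincide.

Only a verbal description of the feature exists — "centroid distance after
correction for the cell radius", with a boundary at 2 — so two readings are
plumbed: the dimensionless ratio above (default) and a depth reading
$s = R - d$ in μm (`formula = "depth"`). The ratio was chosen as the
default because it is scale-invariant (a larger cell with a proportionally
deeper particle scores the same) and because its value at the membrane is
exactly 1 regardless of cell size, which makes the published boundary of 2
coherent without further calibration. The phrase "similar to or >2" is
implemented as $s \ge 2$. Both $\tau$ and the formula are arguments, not
constants.

### Segmentation

The cell mask is the largest connected component of an Otsu threshold of
the **surface-marker channel**, holes filled; the surface stain gives the
highest-contrast outline of the plasma membrane, which is the boundary that
matters for an internalization call (the brightfield channel has much lower
contrast and the nucleus understates the cell). Centroids are
intensity-weighted. The particle channel is first smoothed with a 3×3 mean
(a cheap matched filter for blob-like objects) and a particle is reported
only when at least 3 pixels exceed the channel median plus five MADs —
without the minimum-area term, a single Gaussian noise excursion in one of
thousands of background pixels would occasionally fake a particle. When
several components qualify, the largest wins and a warning records the
multiplicity; multi-particle events are rare at the particle-to-cell ratios
simulated here and a principled multi-particle treatment is out of scope.

### Focus gating

Events are scored only when cell and particle were imaged in the same
focal plane. Sharpness is measured per channel as the RMS of the
central-difference gradient magnitude over the (slightly dilated) object
mask, normalized by the in-mask contrast; the normalization makes the
metric insensitive to brightness and exposure. The pass cutoffs (0.1 for
the cell channel, 0.8 for the particle channel, in units of px⁻¹) were
calibrated once against the generator's sharp (0.15 μm defocus) and
out-of-plane (≥ 1.2 μm defocus) populations at 5% noise, where the two
populations measure ≥ 1.8 and ≤ 0.5 respectively, and then frozen as
package defaults. Unfocused events are excluded from every denominator
except the total event count.

### Cohort statistics

The gating chain is total → focused → particle-positive → internalized,
with `% interacting = 100 · particle-positive / focused` and
`% internalized = 100 · internalized / particle-positive`; the latter is
reported as missing (not zero) when no event is particle-positive. Uptake
time courses are reduced to a trapezoidal AUC (%·min), and donor-matched
condition comparisons use the two-sided paired t-test; zero-variance
differences leave the statistic undefined rather than coercing it.

## The event generator

`generate_event()` renders a four-channel scene: a darker cell disc on a
bright brightfield background (1000 → 700 counts), a nuclear disc at 55% of
the cell radius, a surface disc of 600 counts over a 100-count background,
and a particle disc of 3000 counts. Discs are anti-aliased by 4×4
supersampled area coverage — without sub-pixel rendering, centroid
quantization alone shifts $d$ by ~0.1 px, which is material for deeply
internalized particles where $d$ is small. Each channel carries a mild
0.15 μm Gaussian defocus; `off_plane` events blur the particle channel at
1.2 μm. Noise is additive Gaussian (a deliberate simplification over
Poisson statistics: every downstream contract is tolerance-based, and the
additive model makes noise levels exactly controllable), and the default
pixel size is 0.33 μm/px, consistent with a ~7 μm B cell spanning ~21 px.

Class geometry follows the definitions: `bound` places the particle
centroid exactly at $R + p/2$ from the cell centre; `internalized` draws
the centroid distance uniformly from $[0,\ \min(0.4R,\ R - p/2)]$, so true
classes sit clearly on both sides of the $\tau = 2$ boundary and residual
classification error reflects segmentation accuracy, not label ambiguity.
What the generator does **not** emulate: optical point-spread functions,
rod-shaped bacteria, multiple particles per cell, Poisson shot noise, and
debris/doublets. Passing tests therefore demonstrate that the analysis
recovers the geometry it is defined on — not that it is robust to every
artifact of real ImageStream data.

## The FRET ratiometric chain

The biosensor reports RAC1 activation as the Venus/Cerulean3 emission
ratio. The processing order is fixed and matters:

1. **Background correction** — per frame and channel, subtract the median
   intensity outside the cell mask (Otsu on the donor channel), clip at 0.
2. **Alignment** — integer-pixel translation of every frame to frame 1 by
   FFT cross-correlation of the donor channel; the same shift is applied to
   donor, acceptor and particle channels. Sub-pixel registration is
   deliberately out of scope: at 0.102 μm/px an integer grid already
   resolves a tenth of a micron.
3. **Smoothing** — 3×3 uniform mean on both fluorescence channels
   (configurable kernel).
4. **Ratio** — $F = (V - \beta C)/C$ with $\beta = 0.62$ by default.
   The threshold is applied to the acceptor channel only (default:
   background median + 3 MAD), failing pixels become NaN, and $C = 0$
   pixels are NaN-guarded with a logged count.

Background correction must precede the bleed-through subtraction because
$\beta$ multiplies the background-free donor signal; applying the chain in
this order to the noiseless forward model inverts it exactly, which the
tests assert to 10⁻⁶. The 62% default is the leakage constant the DORA
RAC1 sensor is used with; since the calibration behind it is not public,
`estimate_bleedthrough()` re-derives it from donor-only cells as the
least-squares slope of acceptor on donor pixel intensity. With 2% noise
this slope shows the classic errors-in-variables attenuation (the noisy
donor is the regressor), recovering ~61.2% for a true 62% — a bias of under
one point, well inside the ±2-point contract the calibration is held to.

### Membrane versus cytosol activation

$A(t)$ compares a membrane band (in-mask pixels within 0.5 μm of the mask
boundary, inside a ±45° sector centred on the cell-to-particle direction)
against the adjacent cytosol (in-sector pixels deeper than the band), as
NaN-aware means. Both the half-angle and the band width are invented
defaults — the underlying ROI geometry is not published — and both are
arguments. $A(t)$ is exactly invariant to rescaling the whole ratio map.

### The FRET generator and the contrast ceiling

`fret_truth()` builds a circular cell (radius 5 μm) whose activation map is
basal (1.0) everywhere and elevated (2.0 by default) in the contact
membrane sector during an engulfment window, using the *same* ROI helper
the analysis measures with, widened by one pixel of rasterization margin.
The pixel size defaults to 0.102 μm/px — a 63× objective with a 6.45 μm
camera pixel — which makes the 0.5 μm membrane band ~5 px wide. That width
is what lets the band survive the 3×3 smoothing: with the margin, the
smoothed membrane mean stays at ~1.99, while the margin leaks ~4–5% of
activation into the top of the cytosol ROI. The measured contrast for a 2×
construction therefore converges to ~1.91, not 2.00; this ~4–5%
discretization ceiling is inherent to measuring a 5-px band through a 3-px
mean filter and is why the recovery contract on $A$ is stated at ±5%.
Stage drift is integer-valued by construction (matching the integer
registration), and the forward model $V = (a + \beta)\,C$ holds exactly at
zero noise, which pins every stage of the inversion in tests.

## Numerical conventions

- Pixels are 0-based, $(x, y) = (\text{column}, \text{row})$; all physical
  quantities are in μm and minutes.
- Determinism: every generator takes a seed; cohorts derive per-event seeds
  from the master seed, so any subset regenerates identically.
  `run_experiment()` hashes its output tables into a manifest and identical
  configs reproduce identical bytes.
- Degenerate inputs fail loudly and early: constant channels ("no cell
  detected"), frames too small for the requested geometry, invalid
  mixtures (the offending class is named), $\beta \ge 1$, non-monotone
  time grids.
- Absence is a value, not an error: missing particles yield `no_particle`
  classifications, undefined percentages and trace frames are `NA`, never 0.

## Problem sizes

The test suite and the acceptance script run entirely on generated data at
deliberate desk scale: 400-event cohorts at 64×64 px for classifier
recovery, 50 donor-only cells at 96×96 px for the bleed-through
calibration, and 8-frame 128×128 px stacks for the ratiometric chain.
These sizes put the estimators comfortably in their asymptotic regime
(ROI means over hundreds of pixels, regressions over ~2.4 × 10⁵ pixels)
while keeping a full run under a minute.

## Known limitations

- The score presumes one particle per cell; multiplicity is flagged, not
  modelled.
- The focus gate is calibrated on the generator's defocus model; real
  instrument focus metrics (and their thresholds) will differ.
- No photobleaching, cross-excitation or spectral-unmixing terms beyond the
  single bleed-through coefficient.
- 2-D analysis only; a particle directly above or below the cell centre is
  indistinguishable from an internalized one, which is precisely why the
  focal-plane gate exists.
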
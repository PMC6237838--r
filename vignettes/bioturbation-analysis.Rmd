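---
title: "Quantifying clam bioturbation from fluorescent sediment profile images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying clam bioturbation from fluorescent sediment profile images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioturbr)
```

## The measurement problem

Burrowing bivalves rework the upper sediment column, transporting particles
and solutes and thereby shaping nutrient cycling at the sediment-water
interface. Fluorescent sediment profile imaging (f-SPI) measures this
non-invasively: pink fluorescent-dyed tracer particles (luminophores,
125-250 µm) are laid on the sediment surface of a glass-walled aquarium and
the transparent face is photographed; the depth distribution of tracer
pixels below the sediment surface records how deeply the animals have mixed
the deposit.

`bioturbr` implements the full analysis chain for a replicated microcosm
experiment contrasting stocking ratios of two *Ruditapes* clams — the
native grooved carpet-shell (Rd, burrowing to about 120 mm) and the
invasive Manila clam (Rp, to about 80 mm) — against unstocked controls:

1. **Image quantification**: segment luminophores, detect the sediment
   interface, flatten it, and aggregate a depth profile.
2. **Mixing statistics** per aquarium: maximum (`l_max`), median (`l_med`)
   and mean (`l_mean`) mixed depth, and surface boundary roughness (`sbr`).
3. **Inference**: one-way PERMANOVA main tests among stocking ratios,
   pairwise permutation-t contrasts of each ratio against the control, and
   a principal component ordination of the water nutrients (NH4-N, NOx-N,
   PO4-P).
4. **Synthetic experiments**: a generator that produces profile images with
   known particle-depth ground truth and nutrient series with the
   experiment's statistical structure, so every stage is testable without
   any raw data.

## Image quantification

### Segmentation

A pixel is a luminophore when it is pink-dominant on the 0-255 scale:
`R >= 150`, `R - G >= 50` and `R - B >= 40` by default (`colour_rule()`).
Thresholds this wide separate the rendered palette by more than five noise
standard deviations at the default noise level, so segmentation on
synthetic frames is exact; on real imagery the thresholds are configuration
and should be set against a handful of annotated frames.

### Interface detection and the control convention

The interface is traced per column as the topmost row from which a sliding
vertical window (default 9 rows) is at least 60 % occupied, with the
candidate row itself occupied. The first-row condition anchors a clean
interface exactly; the window vetoes isolated particles floating in the
water column, which would otherwise fake an early interface. Two occupancy
definitions implement the two experimental conventions:

* **treatment mode** — occupied means any non-water pixel (sediment *or*
  luminophore): the sediment-water interface. Stocked aquaria rework all
  tracer, so particles at the surface are part of the surface.
* **control mode** — luminophore pixels are excluded, so the trace follows
  the boundary between the never-reworked surface carpet and the sediment
  beneath it. All carpet pixels then lie above the interface and clip to
  depth zero, which is exactly what an undisturbed control should report.

A short running-median filter (default 5 columns) despeckles the raw trace:
single-column artefacts narrower than half the filter vanish while monotone
topography passes through unchanged. We chose 9 rows / 60 % over a shorter
majority window after checking two failure modes explicitly: a 5-row
majority window detects a flat interface two rows early (the window
reaches majority while still straddling water) and is satisfied by a
floating 5-pixel disc.

### Flattening and the depth profile

Each luminophore pixel contributes depth
`max(0, row - interface_row(column)) * resolution` (mm); pixels above the
interface are clipped to zero rather than discarded, so the carpet
contributes a defined depth-0 mass — without it the control median would be
undefined. The profile is the pixel count per depth; its total equals the
mask count (mass conservation, tested as an invariant).

## Mixing statistics

From the pixel-weighted depth distribution of the whole image:

* `l_max` — greatest depth with tracer (long-term extent of mixing);
* `l_med` — pixel-weighted median (typical short-term mixing depth), with
  midpoint interpolation at even counts;
* `l_mean` — pixel-weighted mean (time-integrated mixing);
* `sbr` — surface boundary roughness, `(max - min interface elevation) *
  resolution`; defined only in treatment mode, since a control has no
  reworked sediment-water interface (`sbr()` refuses control-mode traces).

Metrics are computed image-wide rather than per column then averaged: the
depth distribution of particle redistribution is a property of the whole
imaged face, and the image-wide form keeps the control's depth-0 carpet
mass well defined. Ordering (`l_med, l_mean <= l_max`) and scale
equivariance in the resolution are tested invariants.

## Inference

For a distance matrix on `N` samples in `a` groups, with `d_ij` the
Euclidean distance after a `log(X + 1)` transform,

* `SS_total = (1/N) * sum_{i<j} d_ij^2`
* `SS_within = sum_g (1/n_g) * sum_{i<j in g} d_ij^2`
* `pseudo-F = (SS_among / (a - 1)) / (SS_within / (N - a))`,
  `SS_among = SS_total - SS_within`.

For univariate data this is algebraically the classical one-way ANOVA F,
which the tests verify to ten significant digits against `aov()` (and, for
multivariate data, against an independent implementation). The p-value
comes from group-label permutations: 9999 random permutations by default
with the positively biased, valid estimator
`(1 + #{F_perm >= F_obs}) / (1 + n_perm)`; ties count as exceeding. When
the number of distinct label assignments `N! / prod(n_g!)` is at most
`n_perm`, the test switches to exhaustive enumeration and reports the exact
`#{F_perm >= F_obs} / #assignments` without the +1 correction (the
observed assignment is counted once among all of them). With five
replicates per group every control contrast (5 vs 5) is exhaustive over the
252 assignments, so the smallest attainable p is 1/252. Pairwise contrasts
restrict the distance matrix to the two groups and report
`t = sqrt(pseudo-F)`, unadjusted — the study design reports raw pairwise
p-values; a Bonferroni multiplication can be applied downstream if wanted.

The test battery mirrors the experiment's published table layout: for each
mixing depth one among-ratios main test (control excluded — its inclusion
is rejected as a precondition violation, not silently filtered) plus one
control-vs-ratio contrast per ratio; for SBR the main test only; the same
1 + 5 layout per nutrient at the analysis day. The nutrient PCA ordinates
per-treatment per-day mean concentration vectors (6 groups x 7 days = 42
points, 3 variables) in correlation form, because the three nutrients share
units but differ in scale by more than an order of magnitude; per-aquarium
points and covariance form are available as options.

## The synthetic generator

### What it emulates

* **Burial depths**: a fraction of particles (`surface_fraction`) stays in
  the surface carpet at depth exactly 0; the rest are exponential with
  scale `mixing_scale_mm`, truncated at 120 mm where the native clam is
  present and 80 mm where only the invasive clam is (the species' burial
  limits). The exponential is the simplest monotone mixing profile and
  keeps the ground-truth metrics analytically checkable (the truncated
  mean has a closed form used as a test oracle). Controls use
  `surface_fraction = 1`.
* **Interface relief**: smoothed Brownian motion rescaled so that the
  trace's span equals the SBR target to the nearest pixel. Moving-average
  white noise was rejected: after rescaling it retains column-to-column
  jitter of many pixels — single-column spikes no physical sediment
  surface has — which corrupts both SBR and depth recovery.
* **Rendering**: water above the trace, sediment below, one pink disc per
  particle at `interface_row + depth/resolution`; 8-bit quantisation makes
  the PNG round trip lossless. Two placement details depart from the naive
  rule, both so that rendered geometry matches the semantics of "burial
  depth": carpet particles (depth 0) rest *on* the interface, entirely
  above it, so their deepest pixel is at depth 0 and controls quantify to
  exactly zero; shallowly buried discs are embedded flush (top never above
  the interface), so surface relief equals the interface trace by
  construction rather than being roughened by protruding discs.
* **Nutrients**: linear trends between day-0 and day-21 endpoints with
  Gaussian noise clipped at zero. Endpoints follow the observed behaviour:
  ammonium and phosphate build up strongly in stocked aquaria (NH4-N to
  9.2-11.2 mg/L, higher with more native clams) and weakly in controls
  (to 3.56 mg/L); oxidised nitrogen accumulates only in controls (0.17 to
  1.42 mg/L), where the undisturbed surface favours nitrification. No
  within-sample error model is reported for single water samples, so
  truncated Gaussian noise is the package's own choice.

### Calibration of the treatment effects

Group means anchor the levels: a base mixing scale of 8.5 mm gives the
monospecific native treatment a mean mixed depth near 5.9 mm, and
between-aquarium variation (scale SD 2.2 mm, SBR SD 4 mm) reproduces the
observed replicate spread of roughly 1.5-4 mm. The *slopes* of the
treatment effects (0.18 mm mixing scale and 0.25 mm SBR target per
invasive clam) are deliberately gentle: they are sized so that the
expected among-ratios pseudo-F sits at the weak, clearly non-significant
level the experiment reports (F of roughly 0.8-2.2 with five replicates),
while the control contrasts remain overwhelming. Treating the printed
spread of group means as the true effect with the printed within-group SDs
would give the among-ratios test about 80 % power and invert the
experiment's headline conclusion, so that spread is read as mostly
sampling noise — which the reported F values imply. The number of visible
particles per face (600) is a free parameter of the generator; nothing in
the source experiment constrains it.

The four tracer additions of the real protocol are pooled into a single
analysis-day population: only the final day's images enter the analysis,
and the pooled population is what that image sees.

### What passing tests do not show

The generator produces ideal colour separation, a single-valued interface
per column, no overhangs, burrow walls, shadows, glass-wall artefacts or
illumination gradients, and treatment effects that are exactly the
calibrated ones. Recovery and pattern tests therefore validate the
*algorithmic chain* — segmentation, interface logic, flattening, the
statistics — not robustness to real-world imaging conditions. Colour
thresholds in particular must be re-tuned for real photographs.

## Numerical choices

* Coordinates are 0-based with row 0 at the top of the frame; depth is
  positive downward in mm; the image crop is half-open `[0, width)`.
* Even-count medians use midpoint interpolation.
* Degenerate inputs fail loudly: empty profiles, all-water columns,
  all-zero distance matrices and constant columns under normalised PCA are
  errors, not NAs; a column with no detectable sediment aborts the image,
  because a partial frame signals a data problem.
* `SS_within = 0` with `SS_among > 0` reports an infinite pseudo-F whose
  permutation p-value is still well defined (ties count as exceeding).
* Permutation seeds are required arguments and are logged in every result
  and report; reruns with the same inputs and seed are byte-identical
  (report timestamps are deliberately omitted).

## Problem sizes used by the test suite

The default geometry is a 21 mm wide analysis window (300 columns) at
0.07 mm/px with a 150 mm sediment column — the depth statistics do not
depend on the window width, and this width renders and segments quickly.
The shipped checks use: 100 random one-way designs for the ANOVA oracle;
1000 null datasets of 6 groups x 5 replicates at 999 permutations for the
size of the test; 20 aquaria spanning mixing scales 2-40 mm for
ground-truth recovery; and 20 full 30-aquarium experiments for the
headline significance pattern. Main tests in the pattern runs use 999
permutations — the p-resolution needed at the 0.05 threshold — while the
5-vs-5 contrasts are exhaustive (252 assignments) regardless.

## Known limitations

* One fixed factor only; no nested or multi-factor permutation designs, no
  dispersion test, and Euclidean distance only.
* The asymptotic "Monte-Carlo P" approximation some commercial PERMANOVA
  implementations print alongside the permutation p is not reconstructed;
  the package reports permutation (or exact enumeration) p-values only.
* Time-lapse analysis across days is out of scope; one analysis day is
  quantified.
* The depth law is phenomenological; no mechanistic transport model or
  biodiffusion coefficient is fitted.
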
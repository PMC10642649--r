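---
title: "Quantifying mycelial networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mycelial networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycofrac)
```

## The measurement problem

Filamentous fungi grown in a patchy 2D habitat — microliter drops of liquid
medium at fixed spacing on a hydrophobic dish — colonize the gaps between
drops with a branched hyphal network. Two quantities summarize how a
mycelium responds to the nutrient content of the drops it reaches:

* the **mass fractal dimension (FD)** of the hyphal network imaged between
  two drops, a single scalar in $[0, 2]$ describing its space-filling
  complexity; and
* the **fraction of a drop's area covered by red pigment** secreted by the
  fungus, measured on a colour photograph of the whole dish.

`mycofrac` implements both measurements, the statistics applied to the
resulting tables, and a synthetic-data module that generates inputs with
known ground truth so every stage can be validated without microscope data.

## Mass fractal dimension by box counting

A binary mask (foreground = filament edge pixels) is overlaid with square
grids of side $s$ for a geometric series of sizes, by default
$s \in \{3, 6, 12, 24, 48, 96, 192, 384\}$ pixels. For each $s$ the number
$N(s)$ of grid cells containing at least one foreground pixel is recorded,
and the dimension is the negative slope of the ordinary least-squares fit
of $\ln N(s)$ on $\ln s$:

$$\mathrm{FD} = -\frac{d \ln N(s)}{d \ln s}.$$

The sign convention is fixed by requiring $\mathrm{FD} = 2$ for a filled
square ($N(s) = (L/s)^2$) and $\mathrm{FD}=1$ for a one-pixel line. The
Sierpinski carpet, built by recursive removal of centre ninths, gives
exactly $N(3^k) = 8^{\,\ell-k}$ at level $\ell$ and recovers
$\log 8 / \log 3 \approx 1.8928$ with $R^2 = 1$; these closed forms are the
estimator's primary validation fixtures.

Numerical choices, each of which changes counts and is therefore fixed and
documented rather than configurable by accident:

* **Single grid origin** at the mask's top-left; no multi-offset
  minimization. This matches the counting convention of interactive image
  analysis tools and keeps counts bit-stable.
* **Partial border boxes count as cells.** The default series does not
  divide arbitrary crop sizes; counting partial cells keeps $N(s)$ defined
  for every mask shape.
* **Sizes larger than both mask dimensions are skipped with a warning**
  (their count is pinned at 1 and carries no slope information); a fit
  needs at least 3 surviving scales.
* $R^2$ is always reported; fits with $R^2 < 0.95$ are flagged
  (`low_r_squared`) but not rejected, and dimensions outside $[0,2]$ are
  flagged (`fd_outside_0_2`), never clipped.

`fd_sensitivity()` re-estimates one mask under several size series and
`fd_rank_stability()` checks that the *ordering* of a set of masks is
preserved across series — the property that matters for comparative
experiments, since the absolute FD value does shift with the series.

## Image treatment ahead of counting

Raw micrographs of hyphae between drops are treated in five steps, each a
separate exported function and composed by `fd_pipeline()`:

1. **Crop** to a rectangular region of interest, removing the drops and
   scale bar (`crop_rect()`), with any remaining intrusions blanked by
   polygon fill (`mask_out_polygons()`; even–odd rule, boundary pixels
   inside, so pixel counts are reproducible to the pixel).
2. **Kuwahara smoothing** (`kuwahara()`). The default is the *linear*
   variant: for each pixel, the mean and variance of the intensities along
   line segments of length $L = 5$ at 8 orientations $k\pi/8$ through the
   pixel are computed, and the pixel is replaced by the mean of the
   least-variance segment. Because some orientation always lies wholly on
   one side of a filament edge, edges survive smoothing exactly — the
   property that makes this filter the right adaptive denoiser for thin
   bright filaments. The classic four-quadrant variant is also provided.
   Ties between regions go to the lowest region index so output is
   deterministic.
3. **Sobel edge detection** (`sobel_magnitude()`): the standard $3\times3$
   kernels, magnitude $\sqrt{G_x^2+G_y^2}$ clipped to 8 bits. A vertical
   step of height $\Delta$ produces magnitude $4\Delta$ in the two flanking
   columns — the hand-checkable anchor for the implementation.
4. **Automatic thresholding** (`compute_threshold()`): isodata (iterative
   intermeans) by default — the usual default of interactive binarization —
   with Otsu, Huang and fixed thresholds selectable. All scan every
   candidate threshold in the occupied gray range and break ties toward the
   smallest value.
5. **Binarization** (`binarize()`): foreground = pixels strictly above the
   threshold, i.e. the filament *edges* appear white on black.

Borders are replicate-padded in every filter: zero-padding would
manufacture a bright frame of spurious edges that inflates box counts at
small scales. Filters compute in floating point and quantize to 8 bits
(round half away from zero) only at their boundaries.

A featureless image (noise, no filaments) still yields *some* threshold, so
`fd_pipeline()` flags estimates where the largest Sobel magnitude is below
128 — i.e. no intensity step of at least 32 gray levels exists anywhere in
the image — as `low_contrast`. Any genuine filament at the default
rendering contrast saturates the Sobel response at 255, so the guard cannot
fire on real structure; an image whose mask comes out empty is flagged
`empty_mask` with `fd = NA` rather than aborting a batch.

## Huang thresholding and pigment quantification

Red pigment is quantified on the CIELAB $a^*$ axis (green negative, red
positive). `rgb_to_lab8()` converts sRGB (D65 assumed; cameras rarely state
a profile) to CIELAB via `grDevices::convertColor` and re-encodes to the
8-bit convention of Lab image stacks: $L^*$ scaled to 0–255, $a^*, b^*$
offset by $+128$ and clipped, so neutral is 128 and sRGB red lands near
208.

`quantify_red_in_drops()` computes **one Huang threshold per image** from
the full a-plane histogram — not per drop, which would make each drop's
threshold depend on its own pigment content — classifies pixels strictly
above it as red, optionally discards 8-connected components smaller than
`min_particle_px` (default 0: no size filter), and reports per-drop
percentages over polygonal drop ROIs. Drops whose polygon leaves the canvas
are flagged `excluded`, not dropped.

The Huang threshold minimizes the Shannon fuzziness of the two-class
partition: with class means $m_0(t), m_1(t)$ and $C = g_{\max} - g_{\min}$,
each level $g$ has membership $\mu(g) = 1/(1 + |g - m|/C) \in [0.5, 1]$ and

$$S(t) = \sum_g h(g)\,\bigl[-\mu \ln \mu - (1-\mu)\ln(1-\mu)\bigr]$$

is minimized over all candidate $t$ (smallest minimizer on ties). The
implementation is validated against an independent brute-force scan in the
test suite.

One degenerate case needs an explicit rule: an image with *no* red class.
An automatic threshold always splits the histogram somewhere, and on a
pigment-free image it merely splits noise, which would report a spurious
red fraction. The guard is `min_class_separation` (default 16 of 255): if
the mean a-values of the two classes differ by less than it, the image is
declared pigment-free and every drop scores zero. Pigmented and unpigmented
media in a typical scene differ by 40–60 a-units, an order of magnitude
above noise-induced splits, so the default separates the two regimes
comfortably.

## The synthetic-data generators

The generators define the package's test conditions; their defaults are
chosen once, for realism, and the validation results must be read with
their limits in mind.

**Mycelium simulator** (`simulate_mycelium()`): a lattice-free tip-growth
model. Tips start on the left edge heading right (the geometry of an image
taken between an inoculum drop and a target drop), advance 4 px per step
with Gaussian heading jitter (s.d. 0.2 rad), branch with per-tip per-step
probability `branch_prob` at a mean absolute angle of 0.6 rad, and die on
leaving the 384 px canvas. Strokes 2 px wide at intensity 200 are rendered
on background 30, then a 30-level horizontal illumination gradient and
Gaussian noise (s.d. 10) are applied, in that order, with clipping before
noise so output stays 8-bit. The skeleton mask (all stroked pixels before
degradation) is returned as ground truth.

Per-tip branching is exponential, so active tips are capped (`max_tips`,
default 60; branching is suppressed at the cap). The cap models crowding —
unlimited branching would fill most of the canvas at the upper branching
levels, which is neither what micrographs of inter-drop hyphae look like
nor a regime where an edge-based FD can discriminate density. With the
default cap, branching probabilities 0.01 / 0.05 / 0.15 produce skeleton
coverages of roughly 2% / 16% / 27%: thin-filament scenes whose mean
pipeline FD rises strictly with branching, the property the comparative
experiments rely on.

What the simulator does **not** emulate: anastomosis (hyphal fusion),
nutrient-directed tropism, hyphal thickness variation, depth-of-field blur,
and the specific texture of stereoscope backgrounds. Passing tests
therefore show that the pipeline measures network density differences of
this *kind*; they cannot certify absolute FD values on any particular
microscope's output.

**Drop scenes** (`render_drop_scene()`): circular drops of medium colour on
a bright background; inside each drop exactly
$\lfloor \text{red\_fraction} \times |\text{interior}| \rfloor$ randomly
selected pixels are painted the pigment colour, and that exact fraction is
stored as ground truth. Default colours — background (245, 245, 245),
medium (210, 200, 150), pigment (180, 30, 40) — reproduce the relevant
structure of a photographed dish on the a-plane: medium slightly *below*
neutral ($a^* \approx -4$), pigment far above ($a^* \approx +58$).
Overlapping drops are rejected (ambiguous ground truth), as are drops
touching the canvas edge. Channel noise (s.d. 4) is applied last.

**Fractal fixtures** (`render_fractal()`): the exact line, filled square,
Sierpinski carpet and seeded random-dust masks used to validate the
estimator, each carrying its theoretical dimension.

All generators take an explicit integer seed and run under
`withr::with_seed`, so identical parameters give bit-identical images and
the caller's RNG state is never disturbed.

## Statistics

Measurement tables are long-format data frames (value, medium, timepoint,
replicate). `two_way_anova()` fits `value ~ medium * timepoint` and reports
**Type II sums of squares** (`car::Anova`): drop experiments are mildly
unbalanced (replicates lost to drying or focus), and Type II is the
conventional choice for main-effect tests when the interaction is not
assumed. Type III is available via the `type` argument. `tukey_hsd()` wraps
the studentized-range correction for all pairwise level contrasts.

Two-group comparisons use the **Welch** unequal-variance $t$ test
(`welch_t_test()`), with Satterthwaite degrees of freedom

$$\nu = \frac{(v_1+v_2)^2}{v_1^2/(n_1-1) + v_2^2/(n_2-1)},
  \qquad v_i = s_i^2/n_i,$$

also available directly from summary statistics as `welch_df(n1, s1, n2,
s2)`: two groups of 6 network images with standard deviations 0.050 and
0.077 give $\nu = 8.58$, the fractional df characteristic of reported
drop-assay comparisons (a printed value of 8.57 is consistent with these
inputs once their own rounding to 3 decimals is propagated, which spans
$\nu \in [8.49, 8.67]$). A pooled-variance option exists but the Welch form
is the default precisely because fractional dfs are what unbalanced
variances produce.

Significance is flagged at $\alpha = 0.05$ in reporting only; no
computation depends on it.

## Pipeline, reproducibility and problem sizes

`pipeline_simulate()`, `pipeline_fd()`, `pipeline_colour()` and
`pipeline_stats()` (composed by `pipeline_all()`) run a whole study from
one YAML config with a versioned schema; unknown keys anywhere are rejected
before any file is written, and a resolved copy of the config is stored
next to the outputs. Every per-image seed is derived deterministically from
the single master seed, so a run is reproducible byte-for-byte: the test
suite asserts that two `pipeline_all()` runs with the same config produce
identical CSVs. One corrupt image yields one flagged row, never an aborted
batch.

The packaged validation workloads use 384 × 384 simulated micrographs (10
seeds per branching level), level-5 carpets (243 × 243), and 12 drops per
pigment level in 120 px-pitch scenes — sizes at which every closed-form
property above is exercised exactly and a full validation run completes in
well under a minute on a laptop.

## Known limitations

* FD values depend on the box-size series and on the binarization method;
  only comparisons within a fixed configuration are meaningful. The
  sensitivity helpers exist to make exactly that check easy.
* The physical pixel scale of a micrograph cannot be inferred from the
  image; `pixel_scale()` values must come from calibration and are a
  required input wherever areas in cm² are reported.
* The colour stage assumes sRGB input and one dominant pigment on the
  red–green axis; two pigments, or strong illumination colour casts, would
  need spectral unmixing, which is out of scope.
* The growth model is phenomenological. It is adequate for validating the
  measurement chain, not for inference about hyphal biology.
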
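# mycofrac

Quantitative image analysis for fungal mycelia grown in **drop habitats**:
microliter drops of liquid medium deposited at fixed spacing on a
hydrophobic dish form a 2D patchy environment that a mycelium colonizes by
sending hyphae across the air gaps. `mycofrac` measures two things from
images of such systems, and ships the statistics and synthetic data needed
to validate both:

1. **Mass fractal dimension (FD)** of the hyphal network imaged between two
   drops — a scalar in [0, 2] summarizing space-filling complexity.
   Treatment chain: rectangular crop and polygon blanking (drops, scale
   bar) → Kuwahara edge-preserving smoothing (linear variant by default) →
   Sobel gradient magnitude → automatic binarization (isodata/Otsu/Huang) →
   box counting over a geometric size series (default 3, 6, 12, 24, 48,
   96, 192, 384 px) → FD = −slope of the OLS fit of ln N(s) on ln s.
2. **Percent red pigment per drop** from colour photographs: sRGB → CIELAB,
   one Huang threshold per image on the 8-bit a\* plane, particle filtering,
   and per-drop percentages over polygonal drop ROIs.

Measurement tables feed a statistics stage: two-way ANOVA (Type II sums of
squares, for the mildly unbalanced replication typical of drop assays),
Tukey HSD contrasts, and Welch *t* tests with Satterthwaite degrees of
freedom.

Because such studies rarely deposit raw micrographs, the package includes a
first-class synthetic-data module: a seeded tip-growth simulator producing
mycelium-like images with ground-truth skeletons, analytic fractal fixtures
with known dimension (line, filled square, Sierpinski carpet, random dust),
and pigmented drop scenes with exact painted red fractions.

## Worked example

```r
library(mycofrac)

# a synthetic micrograph: hyphae crossing the gap between two drops
sim <- simulate_mycelium(mycelium_params(branch_prob = 0.05, seed = 42))
est <- fd_pipeline(sim$image)
est
#> Mass fractal dimension: 1.8321 (R^2 = 0.9984, 8 scales)
est$log$threshold        # isodata threshold chosen on the edge image: 139
est$log$counts           # occupied boxes per size: 7139 2316 732 216 60 16 4 1
```

The dimension (1.83 here) rises with network density: sparser branching
(`branch_prob = 0.01`) gives values near 1.4, denser (`0.15`) near 1.9, and
the test suite asserts that ordering over seeded replicates. The fit's
R², the per-stage log (threshold, foreground pixel count, box counts) and
quality flags (`low_r_squared`, `low_contrast`, `empty_mask`) come along
with every estimate.

The estimator itself is validated on closed forms:

```r
carpet <- render_fractal("sierpinski_carpet", level = 5)   # 243 x 243
res <- box_count(carpet$mask, box_size_series(c(3, 9, 27, 81, 243)))
res$counts               # 4096 512 64 8 1  (exactly 8^(5-k))
fit_fd(res)
#> Mass fractal dimension: 1.8928 (R^2 = 1.0000, 5 scales)  = log 8 / log 3
```

Pigment quantification against generated ground truth:

```r
drops <- data.frame(cx = c(60, 180, 300), cy = 60, r = 45,
                    red_fraction = c(0.10, 0.50, 0.75))
p  <- drop_scene_params(360, 120, drops, seed = 3)
sc <- render_drop_scene(p)
rois <- lapply(p$drops, function(d) circle_polygon(d$cx, d$cy, d$r))
quantify_red_in_drops(sc$image, rois)$percent_red
#> 10.00 49.99 75.00   (truth: 10, 50, 75)
```

And the summary-statistic form of the Welch test:

```r
welch_df(6, 0.050, 6, 0.077)   # two groups of 6 network images
#> 8.58
```

Whole studies run from a YAML config via `pipeline_simulate()`,
`pipeline_fd()`, `pipeline_colour()`, `pipeline_stats()` or `pipeline_all()`
(CLI wrapper in `inst/cli/mycofrac.R`); identical config + seed reproduce
every output file byte-for-byte.

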
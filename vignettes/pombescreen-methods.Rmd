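---
title: "Models and methods behind pombescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pombescreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, estimator choices and limitations of
the package; the README shows the user-facing workflow.

## 1. The interaction-scoring model

A synthetic genetic array (SGA) screen reads genetic interactions off
double-mutant colony sizes. The scoring layer implements the classical
ratio-threshold scheme:

* every plate is **normalized to its median colony size**, which absorbs
  differential growth between plates (incubation time, agar batch,
  camera exposure). Only *retained* positions — unflagged and of
  positive size — enter the median, because dead pins and empty
  positions would drag it down. With an even position count (1536), the
  median is the midpoint of the two central order statistics.
* the **interaction ratio** of gene *g* is its normalized query size
  divided by its normalized control size at the same array position.
  Because library layouts are fixed, any positional growth factor
  (e.g. the edge effect, §2) appears in both numerator and denominator
  and cancels — whereas plate-median normalization alone does *not*
  remove positional structure. This is a real limitation of
  median normalization, and the reason the ratio, not the normalized
  size, is the unit of inference.
* ratios from the independent **query isolates** (four by default) are
  averaged arithmetically into a mean ratio. A gene needs at least
  `min_isolates = 2` defined ratios to be scored; a normalized control
  below `control_floor = 0.05` makes the ratio undefined rather than
  explosive.
* mean ratios below 0.8 are **negative** interactions and above 1.2
  **positive** ones, with strict inequalities — a ratio of exactly 0.8
  is no call. Calls are intersected across biological replicates and
  kept only when every replicate agrees in sign; genes with opposite
  signs are reported as discordant, not kept.

Two readings of the published procedure were genuinely open and are
resolved as follows: each plate is normalized **separately** (not pooled
with its partner plate), which is the closest reading of normalizing
"each plate"; and replicate intersection requires a **matching sign**,
not mere presence, since a gene negative in one replicate and positive
in the other has not replicated in any meaningful sense.

The hub summary (`hub_fraction()`) reports the percentage of negative
interactors inside a supplied gene list **truncated** to one decimal
(39/131 = 29.77 % prints as 29.7), matching how such figures are
conventionally printed. The shipped 131-gene negative set and 39-member
hub list are synthetic fixtures (`inst/extdata/synthetic_*`) carrying
realistic counts; they are not the real screen's gene identities, which
were never deposited.

## 2. The synthetic screen generator

`simulate_screen()` draws colony sizes from

$$ s_g \;=\; b_g \cdot f_{\text{plate}} \cdot f_{\text{pos}} \cdot
   \varepsilon_g \cdot \eta, $$

with per-gene baseline $b_g$ (lognormal, mean `base_size = 200` px²,
CV `base_size_cv = 0.2` — typical colony footprints and
strain-to-strain fitness spread in plate photographs), per-plate scale
$f_{\text{plate}}$ (lognormal, CV `plate_scale_sd = 0.1`), positional
factor $f_{\text{pos}}$ (= `edge_effect = 1.1` on the outermost two rows
and columns, 1 elsewhere — the canonical nutrient-access artifact of
pinned arrays), planted interaction effect $\varepsilon_g$ (query plates
only; 0.5 or 1.5 for 2 % of genes each by default, 1 otherwise) and
multiplicative lognormal noise $\eta$ with mean 1 and CV
`noise_cv = 0.1`. Multiplicative (lognormal) noise keeps sizes positive
and reflects the roughly proportional variability of colony growth;
none of the distributional choices is prescribed by the screening
protocol itself, so they were fixed once at values a screen of this
kind plausibly shows.

Genes fill consecutive 1536-format plates row-major, identically across
isolates, replicates and roles, as a fixed deletion library would. A
library larger than one plate therefore gets several plates per
isolate/role (each with its own $f_{\text{plate}}$), and the "grid too
small" error is reserved for an explicitly fixed `n_plates` that cannot
hold the library. All randomness derives from the config's single seed;
identical configs give bit-identical output.

What the generator does **not** model: agar smears and condensation,
pinning-robot dynamics, spatial gradients smoother than the edge ring,
and real library layouts. Recovery results on synthetic screens
(recall/precision ≥ 0.95/0.90 at the default conditions) therefore
demonstrate correctness of the scoring arithmetic under the stated
noise model, not performance on any particular laboratory's plates.

## 3. Colony quantification from images

`render_plate_image()` draws each colony as a filled disc of area equal
to its size, so rendered plates come with exact geometric truth.
`fit_grid()` finds the array by smoothed row/column intensity
projections: local maxima above a prominence threshold (default 0.2 of
the profile range above its median) give candidate centres; if some
pins are missing the candidates are regularized onto an arithmetic grid
(pitch from the median peak spacing, phase by least squares). Fewer
than half the expected peaks on an axis raises "grid not found" rather
than guessing.

`quantify_colonies()` then works window by window (half-width = half
the fitted pitch, so windows cannot overlap): the local background is
the median of the window's 2-px border frame, the threshold is that
median plus `threshold_k = 3` MADs, and the colony is the largest
connected foreground blob (ties broken by distance to the window
centre, which resolves debris). Because the threshold is a location
plus a scale statistic of the same pixels, sizes are invariant to
rescaling the image intensity. Size is the blob's pixel count by
default; an `intensity` option sums background-subtracted intensities
instead, since grid quantifiers in the field differ on this point and
the original tooling's definition is not stated. Coordinates in all
tabular output are 0-based `(row, col)`, row-major, to match plate
nomenclature conventions; matrices inside R stay 1-based.

On noise-free renders the quantified sizes correlate with truth at
r > 0.99 and fitted centres are exact; residual deviation from unity
slope is rasterization (a disc of nominal area πr² occupies
πr² ± O(r) pixels).

## 4. The elongation statistic

Cell elongation is $E = 1 - 4\pi A / P^2$: 0 for a circle, rising
toward 1 for elongated shapes, dimensionless and scale-free (so pixel
vs calibrated geometry is immaterial). The delicate part is estimating
the perimeter $P$ of a rasterized mask: naive pixel-edge counting gives
a "Manhattan" perimeter of $8r$ for a digital disc, which would score
$1 - \pi^2/16 \approx 0.38$ instead of 0 and destroy the statistic's
interpretability. The package instead traces the 0.5-level
marching-squares contour of the mask, smooths the vertex chain with a
7-point circular moving average, and takes **both** the perimeter (arc
length) and the area (shoelace formula) from the same smoothed polygon.
Numerically: an ideal disc scores ≤ 0.005 at radii 10–50 px, a 2:1
ellipse lands within 0.003 of the exact elliptic-integral value
(0.159), and a 4:1 rectangle within 0.006 of its closed form
$1 - 16\pi/100 = 0.497$ (corner rounding by the smoothing costs a few
thousandths). Discretization can push the raw value slightly negative
for near-circles; it is clamped at 0. Scores of the same shape at
doubled resolution agree within 0.01 and under 90° rotation within
0.02.

The smoothing half-window (3 vertices, ≈ 7 px of boundary) trades
corner fidelity against staircase suppression and is fixed; shapes with
boundary features finer than ~7 px (septation notches, buds) would be
smoothed over — acceptable for wall-stained fission-yeast outlines,
which are convex and smooth at the 0.05 µm/px scale assumed throughout.

Condition summaries (`summarize_elongation()`) average the first 30
cells per dataset in raster order, then report mean ± SEM **across
dataset means**: the independent experiment, not the cell, is the
replication unit, so cell-to-cell variance does not masquerade as
biological precision.

## 5. Segmentation, viability, vacuoles

`segment_cells()` uses a global Otsu threshold on the wall channel
(computed on an intensity subsample above 10⁶ px — the threshold is a
histogram statistic and does not need every pixel), fills the bright
cell outlines into solid regions, labels connected components, filters
by area and drops border-touching cells. This is a deliberately simple
threshold-plus-contour segmenter: it assumes non-overlapping,
well-separated cells, which the generator guarantees and which
reasonable fields of wall-stained yeast approximate; it does not split
touching cells (no watershed) and will merge them instead.

`score_viability()` counts dead cells as wall-segmented cells in which
more than half the pixels carry dead-stain signal above background
(median of the dead channel plus half its dynamic range — relative, so
intensity scaling changes nothing). The first `n_scored = 500` cells in
raster order are scored, making the count deterministic; a seeded
random sample would serve equally and the raster order is itself
arbitrary with respect to biology.

`measure_vacuoles()` thresholds the ring-dye channel at background
median + 3 MAD, fills ring interiors, and reports each vacuole's
**equivalent-circle diameter** ($2\sqrt{A/\pi}$ × pixel size). How a
"diameter" is read off a ring by eye (line tool vs area) is not
standardized; the equivalent diameter is reproducible and agrees with
the drawn ring's outer diameter within 2 px for the generator's
geometry, i.e. 0.1 µm at 0.05 µm/px. The generator draws each ring so
its outer edge matches the stated diameter, one vacuole per live cell;
multi-vacuole and fragmented morphologies are out of scope.

## 6. The statistical layer

`sem()` is the sample SD (n−1) over √n. `unpaired_t()` defaults to the
pooled-variance Student t — the convention behind "unpaired t test" in
the mainstream analysis software this layer mirrors — with Welch as an
option. The summary form reconstructs a test from printed mean ± SEM
and n as $t = \Delta\bar x / \sqrt{SEM_1^2 + SEM_2^2}$ on
$n_1 + n_2 - 2$ df, which coincides with the pooled statistic at equal
group sizes; it exists because published figures rarely come with raw
replicate values. `anova_tukey()` delegates to `stats::aov` and
`stats::TukeyHSD` and reports, alongside each adjusted p, the
unadjusted per-pair p computed from the **same** pooled error (MSE and
residual df), so the studentized-range adjustment is the only
difference between the two columns and adjusted ≥ unadjusted holds as
an exact property. Stars follow 0.05/0.01/0.001. Under a null
simulation (n = 3 per group, 10⁴ reps) the t test's type-I error sits
within 0.05 ± 0.01.

## 7. Pipeline and reproducibility

`run_pipeline()` executes simulate → score → simulate-cells → phenotype
from one config (YAML or list) and one root seed, writing TSV tables,
TIFF channels and a JSON manifest with MD5 checksums; identical
config + seed reproduces the checksums exactly. Test and acceptance
problem sizes — a 3,000-gene screen (two 1536 plates per isolate/role),
one full 1536 rendered plate for the quantification round-trip, a
520-cell field for the 500-cell viability count, 10⁴ null simulations —
were chosen as the smallest sizes at which the corresponding claims are
meaningfully exercised.

## 8. Known limitations

* Median normalization leaves positional structure in normalized sizes;
  only the query/control ratio removes it, and only because layouts
  match. A LOESS-style spatial correction is deliberately out of scope.
* No multiplicative-model fitting (S-scores and relatives): the
  threshold scheme is the method being provided, not improved upon.
* The segmenter merges touching cells; the generator never produces
  them, so real crowded fields need upstream dilution or a different
  segmenter.
* The image generators use ideal optics: no point-spread function,
  shading or chromatic offsets. Round-trip accuracies quoted here are
  upper bounds on what degraded real images would give.
* Failed-pinning prevalence in real screens is unknown; the generator
  exposes `dropout_prob` but defaults it to 0.
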
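---
title: "Rule-based DAB quantification: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based DAB quantification: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihcquant)
```

## The measurement problem

Immunohistochemistry (IHC) with a DAB chromogen marks a target protein
brown against a hematoxylin-blue counterstain on a near-white slide
background. The quantity of interest is the **stain fraction**: the number
of DAB-positive pixels divided by the number of tissue (non-background)
pixels in a region. `ihcquant` computes this for manually selected regions
of interest, for entire tissue-block scans, and for every core of a tissue
microarray (TMA), and then compares per-sample fractions — and the
Ki-67/CD31 ratio known as the proliferative vascular index (PVI) — between
low (Gleason 6–7) and high (Gleason 8–9) grade groups.

## The two pixel rules

Every analysis reduces to two per-pixel decisions on 8-bit RGB values.

**Background.** A pixel is background when it is bright and achromatic:

$$\min(R,G,B) \ge \texttt{bg\_min} \quad\text{and}\quad
  \max(R,G,B) - \min(R,G,B) \le \texttt{bg\_uniformity}.$$

Scanned slide backgrounds are not perfectly white but typically exceed 230
in every channel, and they are gray — tissue pixels are either dark or
strongly colored, so they fail one of the two conditions. The defaults are
`bg_min = 230` and `bg_uniformity = 25`. The uniformity test is our
concrete reading of the qualitative requirement that background values be
"consistent" across channels; both numbers are exposed parameters.

**Stain.** A sample (non-background) pixel is DAB-positive when it is dark
enough and not blue-dominant:

$$\min(R,G,B) < \texttt{dark\_threshold} \quad\text{and}\quad
  \neg\,\bigl(B \ge \alpha R \;\wedge\; B \ge \beta G\bigr),$$

with defaults `dark_threshold = 125`, $\alpha = 1.00$, $\beta = 1.25$.
Comparing $B$ against scaled $R$ and $G$ rather than using absolute channel
values makes the call robust to overall darkness: a dark stained region can
have a numerically lower blue value than a light unstained one, yet the
*relative* comparison still identifies hematoxylin (blue-dominant) versus
DAB (red/brown-dominant). Two boundary conventions matter and are fixed
deliberately: the darkness test is strict (`< 125`), and the dominance
comparisons use `>=`, so a pixel exactly on the dominance boundary counts
as blue-dominant (unstained) — the conservative direction, biased against
false-positive stain calls. The blue-dominance connective is AND (both
comparisons must favor blue); this is the only reading consistent with the
reference pixel (75, 175, 100) being called stained
($100 \ge 75$ but $100 < 218.75$).

Background is tested first; `is_stained()` is only meaningful for pixels
that already failed the background test.

```{r pixel-demo}
classify_pixel(rbind(c(255, 255, 255),   # slide background
                     c(75, 175, 100),    # DAB brown
                     c(175, 175, 125)))  # hematoxylin tissue
```

## Regions of interest and whole blocks

`quantify_roi()` classifies every pixel in one vectorized pass and returns
integer tallies; `background + stained + unstained` always equals the pixel
count exactly. The stain fraction of a region with no tissue is **undefined
(`NA`), never 0**, so that downstream ratios fail loudly rather than
silently propagate a fake zero.

`quantify_whole_block()` processes large scans as a fixed grid of tiles
(default 4 × 4, sixteen segments), classifying one tile at a time and
accumulating tallies. Tiling exists to bound the working set, not to change
semantics: the cumulative result is identical, tally for tally, to a single
pass, and the test suite asserts that equality exactly. When a dimension is
not divisible by the grid, interior tiles take the floor size and the last
row/column of tiles absorbs the remainder — exact "equal size" is
impossible in integer pixels, and preserving exact totals is the property
that matters. Callers pass either an in-memory array or a file path; only
one tile is classified at a time.

`normalize_by_max()` rescales a vector of per-sample measurements by its
maximum, for comparing relative stain levels between methods whose absolute
scales differ (automated quantification typically underreports relative to
manual thresholding, while preserving proportions).

## TMA de-arraying

`detect_cores()` builds the foreground mask (NOT background per the pixel
rule — cores are the white objects), then applies morphological closing
with a disc of radius `struct_radius` (default 5 px) to merge fragmented
cores, fills holes to solidify each core, labels connected components, and
discards components with area outside `[min_area, max_area]` — removing
debris below and merged core pairs above. When the bounds are not given
they are derived from the estimated spacing (expected core radius
$r = 0.4 \times$ spacing; `min_area` $= 0.2\pi r^2$, `max_area`
$= 2.5\pi r^2$), which keeps them resolution-independent; for arrays whose
cores are much smaller than their spacing, explicit bounds are the right
tool.

`assemble_grid()` assigns each detected centroid a design-grid cell:

1. **Spacing.** The initial estimate is the median nearest-neighbour
   centroid distance. Because a nearest-neighbour distance is a minimum
   statistic, it sits systematically low under centroid jitter (about 10%
   low at ±10% jitter) — enough to mis-round a three-step gap. The estimate
   is therefore refined from axis-aligned pair gaps: each gap is divided by
   its step count and the median unit distance is iterated to a fixed
   point. Per-step distances are symmetric around the true spacing, so the
   refined estimate is unbiased.
2. **Origin.** The core with the smallest $x + y$ is taken as nearest the
   image origin (ties: smaller $y$, then smaller $x$). Its *absolute* cell
   is anchored by its offset from the minimal centroid coordinates — if
   the top-left design cell happens to be empty, the origin core is
   correctly recognized as row 2 (or column 2) rather than silently
   shifting every label.
3. **Baseline.** The first column is walked from the origin: at each step
   the nearest unused centroid is accepted if its horizontal offset is
   within `col_tolerance` (0.35) of the spacing and its vertical offset
   lies in the window for gap size $k$, expanding $k$ past missing cores.
   Each $k$'s window is the configured `spacing_window` intersected with
   $(k \pm 0.5) \times$ spacing, so that consecutive gap sizes claim
   disjoint distance ranges (for $k = 1$ this is exactly the configured
   window). If the column recovers fewer than `baseline_min_fraction`
   (50%) of its expected cores, the first row is used as the baseline
   instead; if both fail, gridding errors out with the detected centroids
   listed. Walks run in both directions, so cores above/left of the origin
   are reachable.
4. **Fill.** Every grid line is walked from its baseline core; lines whose
   baseline cell is empty start from a position predicted by a linear fit
   of the baseline centroids (with a check for a core at the virtual cell
   itself). A final rescue pass matches any still-unassigned core to the
   lattice fitted through all assigned cores, under the same perpendicular
   tolerance. Assignment is injective by construction: a centroid is
   consumed when accepted, and two cores can never share a cell.

The tolerances (0.35 perpendicular, window $(0.5, 1.5)$) are chosen so that
±10% jitter passes while a diagonal neighbour (offset $\approx 1.41 \times$
spacing at 45°) can never be captured. There is no rotation correction: an
array skewed beyond the perpendicular tolerance is a documented failure
mode, not something silently absorbed.

`invert_grid_labels()` flips first and last rows/columns (and is an
involution), because TMA scans are commonly oriented opposite to the
pathologist's numbering; the pipeline applies it by default
(`invert_labels = TRUE`). `scale_centroids()` maps thumbnail centroids to
the full-resolution image by per-axis size ratios (aspect ratios must agree
within 1%; otherwise the rasters are not the same scene) with
round-half-even rounding. `score_core()` quantifies a square window centred
on each scaled centroid; the default side equals the spacing scaled to full
resolution, so windows abut but do not overlap neighbouring cores — since
the score is stained/tissue, background inside the window is harmless.
`join_annotations()` attaches pathologist Gleason scores by (row, col),
erroring on duplicate annotation keys and warning on unmatched records;
`export_results()` writes the results CSV in row-major grid order, with
undefined fractions as empty cells.

Coordinates are 1-based pixel indices throughout, R's native convention;
grid labels are 1-based as pathologist spreadsheets expect.

## Group statistics

`compute_pvi()` forms Ki-67/CD31 per sample; a zero CD31 denominator is an
error, and the join helper `join_marker_tables()` excludes such samples
with an explicit message. `categorize_gleason()` splits scores at ≤ 7
(low) versus ≥ 8 (high). `compare_groups()` runs the classical two-sample
**equal-variance** Student's t-test, two-tailed, with
$df = n_1 + n_2 - 2$, flagged at $\alpha = 0.05$ — the pooled form is the
method named and used here, taken literally; Welch's form is available
behind `welch = TRUE` for sensitivity analysis. No multiple-testing
correction is applied: endpoints are reported with per-comparison
significance only, a deliberate fidelity choice that callers can override
by adjusting downstream. Whether blocks or subjects are the unit of
analysis is the caller's decision; the functions operate on whatever rows
they are given.

## The synthetic-data generator

The generator exists so that every stage is testable against exact ground
truth without any slide data.

* **Color models.** Background: all channels in [240, 255] with spread
  ≤ 10. Unstained tissue: hematoxylin-like, $B$ the largest channel with
  $B \ge 1.25\,G$ and $R \le B$. Stained tissue: DAB-like, $R$ the largest
  channel, $B < \min(R, 125)$. Every drawn color is verified against
  `classify_pixel()` with rejection sampling, so generator labels and
  classifier labels agree *exactly*; a color model drifting out of rule
  space is a build-breaking error, not noise.
* **Exact counts.** Target fractions are realized by placing exact pixel
  counts at shuffled positions — `gen_tissue_image(100, 100, 0.2, 0.5)`
  contains exactly 5 000 tissue pixels of which exactly 1 000 are stained —
  so recovery tests assert equality, not approximation.
* **TMA scenes.** `gen_tma_image()` renders circular cores on a jittered
  lattice with controllable missing-core probability, fragmentation (two
  half-disks separated by a 3-px gap, within reach of the default closing
  radius), and sub-threshold debris. The full-resolution image is an exact
  integer upscale of the thumbnail scene, so per-core stain fractions are
  scale-invariant by construction. Standard experiment settings are a 5 × 5
  design, 60 px spacing, and 18 px core radius on the thumbnail with a 4×
  upscale — proportions matching ~1 mm cores spaced ~3 mm apart imaged at
  thumbnail resolution — with ±10% jitter and 20% missing cores as the
  stress condition.
* **Marker pairs.** `gen_marker_pairs()` draws CD31 fractions from
  Uniform(0.02, 0.08) (a realistic stain-area range for a vascular marker
  in prostate sections) identically in both groups, and sets each sample's
  Ki-67 as PVI × CD31, with the PVI equal to the group mean times mean-one
  lognormal noise. With `noise_sd = 0` every sample's PVI equals its group
  mean exactly. Because CD31 is group-independent by construction, a PVI
  difference between groups is attributable to the ratio, which is what
  the end-to-end statistics test exploits.

What the generator does **not** emulate: nuclei morphology, texture,
stain-intensity gradients, scanner chromatic aberration, or colors near
the rule boundaries in ambiguous mixtures. Passing tests certify the
pipeline's logic — rule arithmetic, tallies, tiling exactness, de-arraying
geometry, statistics — not the biological adequacy of the thresholds on
any particular scanner's output; thresholds are parameters precisely so
they can be recalibrated per staining protocol.

## Numerical and degenerate-input conventions

* Tallies are exact integers (stored as doubles for headroom on very large
  scans); all conservation identities hold exactly, and the test suite
  checks them with identity comparisons, not tolerances.
* Empty images, images smaller than the tile grid, empty centroid tables,
  all-zero normalization inputs, zero CD31 denominators, groups smaller
  than 2, and zero pooled variance are all hard errors naming the
  offending input.
* An all-background scoring window yields `sample = 0`, an undefined
  fraction, and a warning — never a zero fraction.
* Classification is stateless and deterministic; generator outputs are
  byte-identical for identical seeds.

## Problem sizes used by the test and acceptance runs

Unit and property tests use images from 2 × 2 up to 150 × 150 pixels,
5 × 5 TMA thumbnails (~330 px square, 4× full resolution), 100 random
64 × 64 images for the loop-equivalence oracle, ten seeds for the
de-arraying recovery experiment, and 1 000 replicates at $n = 10$ per
group for the t-test calibration and power checks. These sizes exercise
every code path, including remainder-absorbing tiles and clipped edge
windows, while keeping the whole suite fast enough to run on every change.

## Known limitations

* Axis-aligned grids only; no rotation or hex-pack support.
* The RGB rules are threshold-based by design — no color deconvolution,
  HSV/Lab transforms, or learned classifiers; stains other than
  DAB/hematoxylin need re-parameterization at minimum.
* PNG and TIFF rasters only; pyramidal whole-slide formats must be
  exported to flat TIFF (at whatever resolution the user deems
  appropriate — pixel size is treated as pass-through metadata).
* Grid dimensions are declared by the user, matching the physical TMA
  design; they are never inferred from the image.
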
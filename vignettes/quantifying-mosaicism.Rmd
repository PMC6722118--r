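---
title: "Quantifying cardiomyocyte mosaicism from DAB immunohistochemistry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cardiomyocyte mosaicism from DAB immunohistochemistry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# The problem

Some sarcomeric proteins — MYL4, the atrial essential light chain, is the
motivating case — are expressed in adult ventricle by only a subset of
otherwise indistinguishable cardiomyocytes. On a DAB immunostain this reads
as a mosaic: scattered dark-brown myocytes among blush-stained neighbours on
a hematoxylin counterstain. The quantity of interest per tissue-microarray
(TMA) core is the *percent mosaicism*: the fraction of total myocyte area
occupied by strongly positive cells, expressed as a percent. Scored across
hundreds of cores, it becomes the outcome of cohort models asking whether
mosaicism varies with sex, age or cardiac disease.

This vignette documents the model and the design choices behind
`mosaicquant`, in the order the pipeline runs.

# Stain model and brown-intensity extraction

Brightfield staining is multiplicative: each stain absorbs light, so
per-channel transmittance is `exp(-OD)` where the optical density `OD` is a
nonnegative combination of stain-specific colour vectors (Beer–Lambert). We
use the standard hematoxylin and DAB unit vectors
(H = (0.650, 0.704, 0.286), DAB = (0.269, 0.568, 0.778) in RGB absorbance,
normalised), exposed by `stain_vectors()`. `compute_brown_intensity()`
converts an 8-bit RGB image to OD (clamping at 1/255 so black stays finite)
and solves the two-stain least-squares unmixing per pixel; the DAB
coefficient is the brown intensity map. Pure white background has OD 0 and
maps to exactly zero; a hematoxylin-only pixel maps to zero DAB up to 8-bit
quantisation. A simpler channel-arithmetic mode (`"blue_ratio"`: OD blue
minus OD red, floored at zero) is available behind a config flag for
sensitivity analysis of the unmixing step.

The synthetic image generator renders through the *same* forward model, so
deconvolution has a physically sensible inverse and pixel-level recovery can
be tested to quantisation error (about 1% at typical concentrations).

# Thresholding: one Otsu cut, twelve masks

A single global 2-class Otsu threshold `t` is computed per core on a 256-bin
histogram of the brown-intensity map (`otsu_base_threshold()`). Numerical
choices, all fixed in `quant_config()`:

* **Background exclusion.** Pixels with intensity below `bg_epsilon = 0.02`
  (essentially unstained/white) are left out of the histogram so the empty
  area around and inside a core cannot dominate the class statistics.
* **Tie-break.** Between-class variance is computed for all 255 cuts; the
  lowest maximising cut wins. This matters on well-separated bimodal maps,
  where the criterion is flat across the empty gap between modes: the
  returned threshold then sits just above the blush mode.
* **Degeneracy.** A constant histogram (blank or fully excluded core) raises
  a typed `degenerate core` condition; at the batch level
  (`quantify_cores()`) such cores become `NA` rows flagged `unevaluable`,
  mirroring the removal of unevaluable images from a real study.

Masks are then thresholds of the same map at multiples of `t`. The printed
ladder of "intensity thresholds from 1.5 to 2.75" in the workflow this
package re-implements cannot be absolute intensities for a [0, 1]-scaled
map; we interpret the values as *threshold correction factors* — multipliers
on the automatically computed Otsu cut, the convention CellProfiler uses.
Eleven factors from 1.5 to 2.75 in steps of 0.125 (uniform spacing assumed;
the exact spacing is not printed) give the MYL4+ candidate masks, and one
factor of 0.5 gives the all-myocyte mask that catches every shade of brown.
Because all masks cut the same map, they are strictly nested in the factor,
and every MYL4+ mask is a subset of the myocyte mask — which is what confines
the area ratio to [0, 100]. The nesting survives the size filter: a
component of at least 50 px at a higher factor sits inside a component at
least as large at any lower factor.

**Size filter.** Connected components below 50 pixels are removed
(`filter_small_objects()`), the published debris/staining-noise rule. The
threshold is kept in pixels regardless of resolution, as published; a
µm²-based override is possible when pixel-size metadata exists by rescaling
`min_size_px`. Connectivity is 8 (CellProfiler-like) by default and
configurable to 4; both are tested against a flood-fill oracle. The
implementation labels with EBImage's 4-connectivity `bwlabel` and merges
diagonally-touching labels through a small label graph, which is orders of
magnitude faster than a per-pixel union-find in R.

# Selecting the factor and scoring

In the original workflow the best factor per core was chosen manually,
blinded. `score_mosaicism()` supports that as `selection = "manual"` with a
recorded index, and offers a deterministic `auto_rule` default: choose the
factor whose (pre-filter) mask maximises the between-class variance of the
intensity partition it induces *within the myocyte mask* — i.e. the factor
that best splits blush from dark brown, the same separation idea a human
applies, computed at pixel level so it needs no cell segmentation. Ties go
to the lowest factor. If no factor induces a proper two-class split (a core
with no positive cells), the score is 0 with a QC flag rather than an error.

The statistic itself is the defining ratio
`100 * area(selected MYL4+ mask) / area(myocyte mask)`. Manual exclusion of
non-myocyte regions (vessels, adipose, fibrosis) is honoured by blanking
excluded pixels to white (`apply_manual_exclusion()`), which removes them
simultaneously from the histogram, the masks and both area counts.

# The synthetic data: what it emulates and what it does not

`image_spec()` / `generate_core_image()` render cores with:

* convex elliptical myocytes (~300–1250 px at the default 512×512 size) on a
  jittered grid, guaranteeing no overlap; with `myocyte_area_px_sd = 0`
  every cell is an identical integer-centred circle, so cell areas are
  exactly equal (used by the count-vs-area concordance fixtures);
* a minority of cells rendered DAB-dark (mean concentration 0.85), the rest
  blush (0.30), both on hematoxylin 0.6, with cell-level and pixel-level
  noise splitting the stated `dab_intensity_sd` 0.8/0.6;
* debris specks below 50 px of DAB-dark material on background, placed so
  they never touch tissue (they must be removed by size, not by masking);
* vessel-shaped unstained holes recorded in the exclusion mask;
* exact ground truth (label map, per-cell areas and positivity, pixel
  counts) recorded from what was *rendered*, not what was requested, so
  recovery tests compare against exact truth. Rendering granularity is about
  one myocyte (~1% of tissue area at the defaults).

The blush/dark levels were chosen from the constraint structure of the
method itself, before any end-to-end run: the Otsu cut on a well-separated
bimodal map lands just above the blush mode (~0.42 at the defaults), so the
myocyte mask at 0.5·t (~0.21) must lie below the blush lower tail, and at
least one factor in 1.5–2.75 (1.5·t ≈ 0.63) must land in the empty gap below
the dark mode (lower tail ~0.73). Intensity SD 0.025 keeps ~4σ tails inside
those margins. The published workflow gives no quantitative intensity
distributions for "blush" vs "moderate to strong" staining; these defaults
are stated, not fitted.

What passing tests on this generator *show* is that the masking, filtering
and ratio arithmetic are correct and unbiased when the intensity model
holds; what they *cannot* show is robustness to real-slide phenomena —
stain variation across slides, touching cells, partial-intensity edges,
folds, out-of-focus regions, scanner artifacts. Real cores are harder than
synthetic ones, and the near-exact recovery on fixtures is a correctness
statement, not an accuracy claim for tissue.

`cohort_spec()` / `generate_cohort()` emulate the cohort: 668 subjects
across 5 TMAs, 69.2% male, age 55 ± 16 (floored at 18.5 so that exclusion
tests control their own minors), ~12% of subjects contributing a second core
(a few a third), replicate cores sharing the subject's random intercept and
sometimes sitting on a different TMA so subjects cross TMAs. The outcome is
built on the sqrt-fraction scale — intercept 0.29, sex effect 0.097, age
effect −0.00013, disease shifts (HCM 0.21, SCD−CAD −0.049, …) — plus
subject, TMA and residual noise, clipped to [0, 1] and squared. The fixed
effects are the published cohort-scale estimates; the variance components
are not published, so they are package defaults chosen once: subject SD 0.10
(supports the observed wide cohort spread), TMA SD 0.02 (slides are similar
after staining together), residual SD 0.04 — the one calibrated value,
set so the mean absolute difference between replicate cores is ≈3.5
percentage points at the cohort's typical level, the reproducibility
figure the design targets.

# Cohort statistics

`apply_exclusions()` removes under-18 subjects, rows missing sex or age, and
unevaluable cores, attributing each removed row to exactly one reason (age
first) and logging rows and subjects per reason; counts always balance the
input. `transform_variables()` adds `sqrt_fraction = sqrt(percent/100)` and
natural logs of heart weight and BMI; missingness propagates and is handled
by listwise deletion (with a drop count) inside each model that uses the
variable.

`fit_mixed_model()` fits REML linear mixed models with crossed (not nested)
random intercepts for subject and TMA — crossed because replicate cores can
place one subject on several TMAs. Sex is coded female = 0, male = 1 and
disease uses treatment contrasts with Control as reference (the published
tables' row structure implies both; neither reference level is stated
explicitly, and age is taken in years untransformed, consistent with the
printed estimate scale). p-values use the normal approximation on t — the
"p.z" convention — with Satterthwaite degrees of freedom available behind
`df_method = "satterthwaite"`. Degenerate designs are reported, not hidden:
a grouping factor with one observed level, or a variance estimated at the
boundary, sets the `singular` flag while the variance component stays in the
output.

`compute_residuals()` offers two residual types because they answer
different questions. `"conditional"` residuals (observed minus fixed effects
minus all BLUPs) satisfy the least-squares orthogonality to the design
exactly, but shrink away any subject-level signal not in the model — a
disease shift would largely vanish into the subject intercepts.
`"adjusted"` residuals (the default) subtract the fixed effects and the TMA
intercepts only: repeated measures per individual are accounted for in
*estimating* the adjustment, but each subject's own deviation is retained,
so adjusted group comparisons (the residual-by-disease display) keep their
meaning. `run_model_suite()` packages the four standard analyses: age + sex
on everything; age + sex + disease on the first two TMAs; age + sex + log
heart weight; age + sex + an HCM indicator.

# Monte-Carlo design of the recovery checks

Parameter recovery is verified by refitting on many generated cohorts. Two
choices matter:

* **Problem sizes.** Recovery uses 600-subject cohorts and 200 replicate
  fits; image-level recovery uses 20 cores at 512×512 spanning <1%–92%
  mosaicism; the concordance fixture uses 7 uniform-cell cores and the
  replicate-variation check 200 duplicated subjects. These sizes put
  Monte-Carlo error well below the tolerances they are tested against while
  keeping a full run in minutes on one CPU.
* **Antithetic pairs.** The age effect (−0.00013 per year) is two orders of
  magnitude below its single-cohort standard error, so a naive 200-replicate
  mean cannot resolve a 10%-of-effect bias bound. `generate_cohort()`
  therefore takes `noise_sign = ±1`: the same seed redraws the design while
  mirroring every outcome-scale draw (subject and TMA intercepts,
  residuals). Averaging an antithetic pair cancels the noise term of the
  (nearly linear) estimator almost exactly — the pair mean of the sqrt
  outcome equals the fixed part exactly when no clipping occurs — leaving
  the bias estimate with a fraction of the naive variance. Coverage is
  unaffected: each replicate is marginally a proper draw.

# Known limitations

* The stain model is the clean two-stain Beer–Lambert idealisation; no
  stain normalisation across slides is attempted (out of scope).
* The automatic factor selection assumes a bimodal within-myocyte intensity
  distribution; cores with genuinely continuous intensity gradation will
  fall back on whatever split maximises separation, and the per-core log of
  selected factors should be reviewed as in the manual workflow.
* Percent mosaicism is area-based; per-cell counting exists only as the
  validation comparator, and no cell segmentation is performed.
* The pixel-based 50-px filter is resolution-dependent by construction;
  cores scanned at a very different magnification need the µm² override.
* Clipping of the sqrt-scale outcome at 0 introduces a small bias for
  parameter combinations far outside the defaults (very low intercepts with
  large SDs); at the defaults the clipped mass is negligible.
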
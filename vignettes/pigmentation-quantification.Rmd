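---
title: "Quantifying colony pigmentation from plate images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying colony pigmentation from plate images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

*Streptomyces coelicolor* responds to some interacting neighbour species by
producing red pigmented specialized metabolites (actinorhodin and
prodiginines), often concentrated along the patch edge facing the partner.
Scoring this by eye is unreliable: plate photographs vary in lighting, the
domed colony casts shadows on its own rim, and "how red is it" is not a
number. This package turns a cropped plate photograph of a single patch
into a reproducible, spatially resolved pigmentation profile, and bundles
the companion gene-selection procedures used to relate the pigmentation
phenotype to transcriptome changes.

## Pixel color distance in a normalized CIELAB frame

All color arithmetic happens in CIELAB (D65 white point, 2° observer,
standard sRGB transfer function; conversion by the `farver` package),
rescaled into a unit-diameter sphere: `lam = L*/100`,
`alp = a*/255`, `bet = b*/255`. Mid-gray (`L* = 50, a* = b* = 0`) is
the sphere center `(0.5, 0, 0)`.

For a pixel `X` and target color `Y` the distance is plain Euclidean,

d = sqrt((X_lam − Y_lam)² + (X_alp − Y_alp)² + (X_bet − Y_bet)²),

and is normalized by the target's maximum attainable distance,
`d_max = distance(target, center) + 0.5`, giving `d_s = d / d_max` in
[0, 1]. A target at the center has `d_max = 0.5`; a target on the sphere
surface has `d_max = 1`. Saturated sRGB corners can fall marginally
outside the sphere, so `d_s` is clamped into [0, 1].

Two conventions here were genuinely open and are worth stating:

* **The opponent-axis divisor.** `a*` and `b*` nominally span about
  −128..127 for 8-bit imagery; dividing by 255 maps the neutral axis to
  the sphere center while keeping the printed radius of 0.5 consistent
  with the printed center. The divisor is exposed as `ab_scale` in
  `srgb_to_lab()` for anyone who prefers 200 or 256.
* **The conversion backend.** `farver` agrees with a hand-written
  textbook sRGB→XYZ→L\*a\*b\* conversion to ~1e-5 per normalized
  coordinate (the test suite carries that textbook converter as an
  independent oracle). `grDevices::convertColor` disagrees with both by
  up to ~0.2 L\* units, so it is not used.

## Masking the patch

A pixel is background (agar) when `d_s` to the agar target color
(default `33393E`) is at most 0.15; everything else is foreground. Two
corrections follow, both defined on connected components:

1. **Noise removal** — foreground components smaller than 2% of the
   image are erased (bubbles, specks on the agar).
2. **Hole filling** — background components that do not touch the image
   border and are smaller than 20% of the image are reassigned to the
   patch (glare or dark spots inside the colony that happen to look like
   agar).

Both thresholds are strict "less than": a component of exactly the
threshold size survives. Foreground components use 8-connectivity and
background holes 4-connectivity — the standard dual pairing that avoids
a diagonal line being simultaneously connected and disconnecting. The
labeling itself is a small compiled breadth-first search
(`label_components()`); the finished mask must contain exactly one
component, and every correction is logged (`corrections_log()`).

## From pixels to a 200-breakpoint profile

Pigmentation of a foreground pixel is `p = 1 − d_s` against the pigment
target (default `803D33`, the red of heavily pigmented patches). The
profile is computed in a region of interest: a horizontal band spanning
the patch's bounding-box columns, vertically centered on the bounding
box midpoint, with height 20% (rounded) of the maximum patch height.
The band's columns are partitioned into 200 contiguous near-equal
breakpoints; per breakpoint the mean and pixel-level SD are recorded.
Breakpoint 1 is the patch edge facing the interacting strain; `flip`
mirrors the image when the partner sat on the right.

Two normalization steps make profiles comparable across images:

* **Effective pigmentation.** Unpigmented wild-type patches are not at
  `p = 0` — their beige surface sits near `p ≈ 0.34`. A baseline
  distribution `Pb` (per-breakpoint mean `p` over unpigmented isolated
  wild-type patches; twelve in the reference design) anchors the scale:
  `P_e = 0` below `Pb_min`, else `(P − Pb_min)/(1 − Pb_min)`. The
  packaged default baseline is flat at `Pb_min = 0.342`; recomputing it
  from matched wild-type images (`compute_baseline()`) is preferred and
  is what the analysis scripts do.
* **Spatial edge correction.** The patch rim is shadowed by the colony's
  three-dimensional shape, inflating apparent pigmentation toward the
  profile's ends. Per pixel, `P_f = P_e − (Pb_i − Pb_min)` with `i` the
  pixel's breakpoint, clamped at 0.

A subtlety of the correction as defined: the subtracted term is in raw
`P` units while `P_e` has been rescaled by `1/(1 − Pb_min)`, so for an
unpigmented patch a residual of about `0.52 × (Pb_i − Pb_min)` remains.
With realistic edge shading (baseline spatial variation ≲ 0.03) this
residual stays below 0.02 profile units, and the formula is kept exactly
as defined rather than silently re-scaled; the self-consistency test
pins this behaviour. The correction is applied per pixel, not per bin
mean — the two orders agree for the mean but not for the per-bin SD.

Empty breakpoints (possible only for degenerate patch shapes, since the
band spans the bounding box) are linearly interpolated from their
neighbours and flagged with `n_pixels = 0`. Profiles with fewer than 200
ROI columns are refused rather than silently coarsened.

## Replicates

`aggregate_profiles()` averages replicate profiles per breakpoint with
sample (n−1) SD; `select_representative()` returns the replicate whose
200-bin mean vector has the smallest Euclidean distance to the
aggregate mean (ties to the lowest index). Euclidean distance was chosen
because the similarity metric was otherwise unspecified and Euclidean
distance is what the transcriptome clustering uses. Averaging operates
directly on the baseline-normalized `P_f` profiles; no additional
per-replicate rescaling is applied before the mean. Profiles carry the
pixel-level per-bin SD and aggregates the replicate-level SD, so both
dispersion readings are available.

## Gene-selection procedures

The expression side consumes finished differential-expression tables
(gene id, log2 fold change, p-value) — it never recomputes the
differential test.

* `flag_de_2sd()` — a gene is called differentially expressed when its
  log2FC lies more than 2 SDs from the table's own mean log2FC and
  p < 0.05. Mean and SD are per table, making the rule shift-invariant;
  on a pure-null table the expected flagged fraction is
  2Φ(−2) × 0.05 ≈ 0.23%, which the suite verifies by simulation.
* `flag_de_threshold()` — boundary-inclusive |log2FC| ≥ t with p < 0.05;
  t = 2 (4-fold) for heatmap inclusion, t = 1.58 (3-fold) for calling
  regulated specialized-metabolite genes.
* `venn_shared_counts()` — exactly-k and ≥k flagged-gene counts over the
  union of gene universes; absent genes count as unflagged.
* `cluster_average_lfc()` and `compare_conditions()` — biosynthetic
  gene-cluster summaries (e.g. the packaged *lan* cluster,
  SCO6927–SCO6938) and a two-sample t-test between growth conditions.
  Welch's test is the default because equal variances were never
  asserted; a pooled-variance option exists. Stars follow
  p ≤ .05/.01/.001/.0001.
* `pca_and_cluster()` — PCA over the shared-gene log2FC matrix (one
  observation per comparison) and average-linkage hierarchical
  clustering on Euclidean distances. The linkage was unspecified;
  average linkage is the conventional default for expression profiles.

Raw p-values are used by default because the selection rules are stated
on raw p < 0.05; every rule takes `use_padj = TRUE` to switch to
adjusted values when the input table carries them.

## What the synthetic data does and does not emulate

`generate_plate()` renders a patch as a superellipse (exponent 4 — a
rounded rectangle, like a streaked patch; exponent 2 recovers an
ellipse) on agar of the target background color. Pixel colors inside the
patch are a linear-light convex blend of an unpigmented colony color and
the pigment target, weighted by a 1-D profile function of the normalized
horizontal position (step, ramp, first-quarter peak, flat). On top of
that: a quadratic radial vignette (default 6% luminance drop at the rim,
emulating rim shadowing), Gaussian channel noise (SD 2/255), small
colony-colored specks on the agar, and agar-colored interior holes. The
defaults mirror the reference imaging design: 12 isolated wild-type
patches define the baseline and 20 replicates per interaction condition.

Deliberate modelling choices:

* **Colony base color** `CCC3B2` scores `p ≈ 0.345`, matching the
  published unpigmented baseline minimum (0.342) so synthetic baselines
  land where real ones did.
* **Holes sit on the patch's upper/lower shoulders**, where specular
  glare on a domed colony actually concentrates. This also reflects a
  real limitation of the method: a filled hole is scored with the color
  it has, and dark glare inside the central profiling band would read as
  pigment. The method has no defence against that; neither does the
  simulation pretend to.
* **Resolution.** Default plates are 600×360 px with a 561-column patch,
  so each of the 200 breakpoints spans at least two full-height columns.
  Plate photographs in practice are multi-megapixel; profiles from
  patches barely 200 columns wide sit in a degenerate one-pixel-per-bin
  regime that the generator deliberately stays above. These sizes are
  also what the test suite and analysis scripts use.
* Blending happens in linear light (decoded sRGB), since mixing encoded
  values has no physical meaning; images are re-encoded and quantized to
  8 bits at the end, as a camera would.

The generator does not attempt photorealistic colony texture, specular
highlights inside the band, uneven illumination across the plate, or
camera-specific color response. Passing the recovery tests therefore
shows the pipeline is correct and well-calibrated under controlled
imaging, not that it is robust to arbitrary photography.

`generate_de_tables()` draws null log2FCs from N(0, 1) with uniform
p-values across 8000 genes (about the *S. coelicolor* genome size) and
plants regulated gene groups (by default five genes shifted +8 in all
four conditions and eight shifted +5 in three) with p-values below
1e-4. It emulates the *structure* of a multi-condition comparison, not
count-level noise, dispersion shrinkage, or p-value correlation.

Both generators are pure functions of their parameter objects: the same
seed gives bit-identical output, and the caller's RNG state is left
untouched.

## Numerical choices and degenerate inputs

* `d_s` and `P_f` are clamped into their defined ranges rather than
  allowed to leak out by floating error or saturated colors.
* Ties in representative selection go to the lowest replicate index.
* A mask whose corrections leave zero or several patches is an error
  naming the component count — never a silent pick.
* Patches under 5 px tall, ROIs narrower than the breakpoint count,
  empty tables (fewer than 3 genes for the 2-SD rule), and clusters with
  no genes in the table all fail loudly; the batch pipeline reports
  per-file failures and continues, failing only when every input fails.
* Zero-variance log2FC tables flag nothing (nothing is 2 SDs from the
  mean of a constant).

## Known limitations

* Actinorhodin and prodiginines both appear red at plate pH; the score
  is combined red pigmentation, not a concentration of either compound.
* The interacting partner colony must be cropped out beforehand; the
  pipeline assumes one patch per image.
* The spatial baseline correction subtracts raw-unit baseline structure
  from rescaled values (see above); with strong edge shading the
  residual grows proportionally.
* Selection rules inherit whatever multiple-testing behaviour the input
  p-values have.
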
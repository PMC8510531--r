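# pigmentr

Quantifies the spatial distribution of red pigmentation in *Streptomyces*
patches from plate photographs, and applies the companion gene-selection
rules to differential-expression tables. It is aimed at researchers
studying interspecies interactions who need "how pigmented is this patch,
where" as a reproducible number instead of a visual impression.

## The method

All color math happens in CIELAB normalized into a unit-diameter sphere
(λ = L\*/100, α = a\*/255, β = b\*/255; mid-gray at the center
(0.5, 0, 0)). For a pixel X and a target color c:

    d    = ||X − c||                 (Euclidean over λ, α, β)
    dmax = ||c − (0.5, 0, 0)|| + 0.5
    ds   = d / dmax ∈ [0, 1]

The pipeline for one image:

1. **Mask** — pixels with `ds ≤ 0.15` to the agar color `33393E` are
   background; foreground components under 2% of the image are removed as
   noise and interior background components under 20% are filled as holes,
   leaving exactly one patch.
2. **Score** — per-pixel pigmentation `p = 1 − ds` against the pigment
   target `803D33`.
3. **Profile** — inside a central band (20% of patch height, spanning the
   patch's width) the columns are split into 200 breakpoints. With a
   baseline distribution Pb from unpigmented wild-type patches
   (Pb_min = 0.342 packaged default):

       Pe = 0                         if p < Pb_min
       Pe = (p − Pb_min)/(1 − Pb_min) otherwise
       Pf = max(0, Pe − (Pb_i − Pb_min))   i = pixel's breakpoint

   Breakpoint 1 faces the interacting strain. `Pf ≥ 0.5` corresponds to
   easily visible pigmentation.
4. **Replicates** — per-breakpoint mean ± SD across replicates, plus the
   representative replicate (closest to the aggregate mean in Euclidean
   distance).

On the expression side: the 2-SD rule (|log2FC − mean| > 2·SD of the
table, p < 0.05), fixed thresholds (|log2FC| ≥ 2 or ≥ 1.58, p < 0.05),
multi-condition shared-gene counts, gene-cluster log2FC summaries with
Welch t-tests and star annotations, and PCA/hierarchical clustering of
comparisons. Seeded generators (`generate_plate()`,
`generate_de_tables()`) provide synthetic plates and expression tables
with known ground truth.

## Worked example

```r
library(pigmentr)

# 12 unpigmented wild-type patches define the baseline
wt <- lapply(1:12, function(s)
  generate_plate(plate_sim_params(profile_fn = profile_flat(0),
                                  seed = 100 + s)))
baseline <- compute_baseline(lapply(wt, function(p) raw_profile(p$image)))
baseline
#> baseline distribution: 200 breakpoints, Pb_min = 0.345 (from 12 images)

# an interaction patch with pigment concentrated on the facing edge
pl <- generate_plate(plate_sim_params(seed = 201))
prof <- extract_profile(pl$image, baseline = baseline)
which.max(prof$mean); round(max(prof$mean), 3)
#> [1] 25
#> [1] 0.725
round(cor(prof$mean, pl$truth_profile), 3)
#> [1] 0.997
```

The recomputed `Pb_min` (0.345) sits at the published unpigmented
baseline (0.342); the profile peaks at breakpoint 25 — inside the first
quarter of the patch, the wild-type interaction pattern — with a maximum
`Pf` of 0.73, i.e. strongly visible pigmentation, and tracks the
generator's planted spatial profile at r = 0.997.

The same workflow over full replicate sets, and the expression analyses,
are laid out as scripts:

```sh
Rscript analysis/01_simulate_plates.R       # 12 isolated + 20 interaction plates
Rscript analysis/02_pigmentation_profiles.R # baseline, profiles, aggregate
Rscript analysis/03_simulate_expression.R   # 4 DE tables with planted genes
Rscript analysis/04_gene_selection.R        # 2-SD flags, Venn, clusters, PCA
```

Each writes its tables under `results/`.

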
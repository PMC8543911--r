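# mtlatlas

Groupwise ex vivo MRI atlas construction and thickness–pathology mapping
for the medial temporal lobe (MTL), in R.

## The problem

The MTL — entorhinal cortex (ERC), transentorhinal cortex (BA35),
subiculum, CA fields, dentate gyrus and the thin SRLM layer — is the
earliest cortical target of neurofibrillary tau pathology. Given
high-resolution (0.2 mm) ex vivo T2-weighted MRI of autopsy specimens
with manual MTL/SRLM segmentations and semi-quantitative pathology
ratings (tau and TDP-43, ordinal scale {0, 0.5, 1, 2, 3} at ERC, DG and
CA), the analysis chain is:

1. **Groupwise atlas**: three-stage unbiased template construction —
   affine + shape registration on multi-label guide segmentations
   (collateral-sulcus banks labeled separately), an iterative unbiased
   shape-template loop with mean-deformation recentering, and
   artifact-masked intensity refinement. The atlas is a template image,
   a template segmentation, and a diffeomorphic transform pair per
   specimen.
2. **Consensus subregions**: per-specimen subregion labels warped to
   template space and fused by majority voting with a slight Markov
   random field (Potts) regularization, solved by ICM.
3. **Thickness**: Voronoi-skeleton (pruned medial axis) thickness
   computed in each specimen's native space and sampled at template
   surface vertices (MTL and SRLM surfaces), with artifact regions
   excluded.
4. **Statistics**: at each vertex an OLS model
   `thickness ~ tau + age (+ TDP-43)`, cluster-level familywise
   correction by Freedman–Lane permutation of the maximum cluster mass
   (sum of |t|), Bland–Altman agreement of ipsilateral vs contralateral
   ratings, and region-level NFT-density/thickness correlations.

Real specimen volumes cannot ship with a package, so `mtlatlas`
includes a seeded synthetic specimen generator: folded cortical-ribbon
phantoms with two collateral-sulcus fold types, prescribed ground-truth
thickness `T = T0 − beta_tau·tau·H − beta_age·(age − mean) + eps` with a
fixed entorhinal hotspot patch `H`, ordinal ratings from a latent
Gaussian copula correlated with age, and optional imaging artifacts.
Every stage is tested against independent oracles (analytic phantoms,
brute-force inscribed-ball thickness, explicit normal equations,
exhaustive majority voting).

## Worked example

```r
library(mtlatlas)

## a seeded cohort of 8 synthetic specimens at 48^3, 0.2 mm
cfg <- pipeline_config(out_dir = "demo",
                       cohort = list(n_specimens = 8L,
                                     grid_shape = c(48L, 48L, 48L)),
                       stats  = list(variant = "full_age_only",
                                     forming_threshold_p = 0.01,
                                     n_permutations = 200L),
                       seed = 1L)
report <- run_pipeline(cfg)
```

Console output from this exact run (seed 1):

```
stage simulate ok (3.7s)
stage build_atlas ok (71.8s)      # soft guide Dice 0.974 -> 0.976 -> 0.976
stage consensus ok (1.1s)
stage thickness ok (3.9s)         # mean valid vertex fraction 0.99
stage glm ok (3.7s)
stage agreement ok (0.0s)
```

The report (also written to `demo/report.json`) carries the guide-label
overlap (soft generalized Dice) after each atlas stage — non-decreasing
by construction — the fraction of template vertices with valid thickness
samples, the cluster table (cluster id, size, mass, permutation-corrected
p, dominant subregion), and the Bland–Altman summary. At this small
n = 8 no cluster reaches corrected significance (smallest corrected
p ≈ 0.48); the acceptance suite runs the stated 25-specimen
configuration, where the planted entorhinal hotspot cluster is detected
at corrected p < 0.05 with its centroid inside the patch.

Single stages are available as functions (`generate_cohort`,
`build_atlas`, `consensus_segmentation`, `extract_template_surfaces`,
`sample_specimen_thickness`, `fit_vertexwise_glm`,
`cluster_permutation_correction`, `bland_altman`, ...) and as CLI
subcommands:

```sh
Rscript inst/cli/mtlatlas.R simulate --n 29 --seed 7 --out cohort_dir
Rscript inst/cli/mtlatlas.R run-all --config cohort.json --out out_dir
```

Volumes are NIfTI-1 (`.nii.gz`, written/read by the package's own
minimal reader since no NIfTI package is available in the target
environment), deformation fields 5D vector NIfTI, affines 4×4 text,
meshes legacy-ASCII VTK polydata, tables CSV, configs/reports JSON.

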
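---
title: "Methods: groupwise MTL atlas construction and thickness-pathology mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: groupwise MTL atlas construction and thickness-pathology mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, numerical choices, and design
decisions behind `mtlatlas`. It states no empirical result that the test
suite does not itself compute.

## The scientific problem

Neurofibrillary tau pathology appears earliest in the medial temporal
lobe (MTL) — entorhinal cortex (ERC), transentorhinal cortex (BA35),
subiculum and CA1 — and is believed to drive local neurodegeneration.
High-resolution ex vivo T2-weighted MRI (0.2 mm isotropic) of autopsy
MTL specimens, combined with semi-quantitative pathologist ratings of
tau and TDP-43 severity, allows pointwise maps relating cortical
thickness to pathology burden. The chain required is substantial:
groupwise registration of very variable anatomy into an unbiased
template, consensus anatomical labeling, native-space thickness
measurement, and vertex-wise statistics with familywise-error control.
`mtlatlas` implements that chain end-to-end and, because real specimen
data cannot ship with a package, includes a fully seeded synthetic
specimen generator with known ground truth so every stage is testable.

## The synthetic specimen world

A specimen is a folded cortical sheet (the MTL gray ribbon, bent around
a collateral-sulcus valley) plus a thin stratum radiatum lacunosum
moleculare (SRLM) sheet, rasterized into a small isotropic grid (default
64^3 at 0.2 mm; tests use 48^3). The sheet is parameterized by
intrinsic coordinates `(u, v)` — `u` arc length across the fold, `v`
anterior-posterior — and local thickness, subregion labels (SUB, CA1-3,
DG, pre/parasubiculum, HATA, ERC, BA35, BA36, TE, TF/TH, SRLM) and the
pathology hotspot are all defined in `(u, v)`, so they correspond
across specimens regardless of individual fold geometry. Two fold types
are generated: type 1 with a deep continuous sulcus, and type 2 whose
anterior branch is much shallower, emulating the discontinuous sulcus
pattern that drives BA35 positional variability.

The thickness model at a boundary point with parameters `(u, v)` is

    T(u,v) = T0(u,v) - beta_tau * tau * H(u,v)
             - beta_age * (age - mean age) + eps(u,v)

with `T0(u,v) = 1.4 + 0.2 sin(pi u)` mm, `H` the fixed entorhinal
hotspot patch (`u` in [0.36, 0.52], `v` in [0.28, 0.72]), `tau` the
specimen's average ipsilateral tau rating, and `eps` a smooth random
field with exact pointwise SD `noise_sd_mm` (RBF mixture with
normalized weights, so the marginal variance is constant). Defaults
`beta_tau = 0.15` mm per rating unit and `noise_sd_mm = 0.1` mm are the
conditions under which the headline hotspot-recovery property is
stated. Configurations that would drive `T <= 0` anywhere are rejected
with the offending specimen id.

Two geometric constraints matter and were tuned once, on phantoms, not
on test outcomes:

* the sulcal valley is wide enough (Gaussian dip, sigma 9.5% of the
  grid) that the opposing banks never fuse — fused banks would make
  local thickness read the *pair* of banks and hide any thinning;
* the hotspot patch is large relative to the inscribed-ball scale, and
  analyses that quantify recovery of `beta_tau` evaluate the patch
  *core* (a one-voxel-scale margin removed), since the rim is
  partial-volume territory for any thickness estimator.

Ratings live on the ordinal scale {0, 0.5, 1, 2, 3} at three MTL
locations (ERC, DG, CA), two sides, two pathologies. They arise from a
latent Gaussian model: location latents share a per-specimen severity
factor (within-specimen correlation 0.9 — pathology is spatially
coherent within a brain) and load on age so that the cohort correlation
between age and mean tau rating hits the configurable target (default
0.61); the loading is de-attenuated analytically for the ordinal
quantization (attenuation constant 0.9). Marginals were chosen once to
emulate the published cohort summaries (mean ipsilateral tau about 1.5,
TDP-43 about 0.54). Contralateral ratings are the ipsilateral ones plus
a symmetric one-step ordinal jitter; a minority of specimens —
concentrated in those flagged FTLD — receive a coherent 2-3 step shift
toward the unclamped side of the scale, so the Bland-Altman asymmetry
analysis has signal (about 15% of cases with a >1-point average-rating
discrepancy, emulating the published 18%).

What the generator does **not** emulate: MR physics (intensities are
tissue-dependent means plus a smooth multiplicative bias and Gaussian
noise), histology appearance, extra-MTL anatomy, or anatomically
faithful subregion shapes. A green test therefore establishes that the
*computational chain* behaves as specified on geometry with the stated
statistical structure — not that the package reproduces any specific
real-data map.

## Registration

All transforms act on physical mm coordinates; affines follow the
resampling convention (fixed coordinates to moving coordinates);
deformation fields store mm displacements on the fixed grid and must
keep a strictly positive Jacobian.

**Affine.** Moment initialization (center of mass and principal axes of
the guide labels, translation-only fallback with a warning when the
second moments are near-spherical) followed by Nelder-Mead over
translation, rotation vector and log-scales on Gaussian-smoothed label
indicators. Two numerical details proved load-bearing: samples outside
the moving grid are clamped, not zero-filled (zero-filling makes the
objective discontinuous exactly at the identity for grid-filling
structures), and the half-resolution surrogate objective is followed by
a short full-resolution polish on a stride-2 subsample (the surrogate's
trilinear interpolation biases the optimum by ~0.3 voxel).

**Deformable.** A greedy diffeomorphic scheme: the metric force
(multi-label SSD over soft indicators of medial bank, lateral bank and
SRLM; or masked NCC for intensity) is fluid-smoothed, scaled to a
maximum step (default 0.4 voxel), composed into the total field, and
the total field is elastically smoothed. Steps that would drive the
Jacobian below a small positive margin, or increase the objective, are
rolled back with step halving (at most 5 times per level). Three pyramid
levels by default; when an initialization field is supplied only the
finest level runs, so the field is not degraded by downsampling.
Artifact-labeled regions still *guide* shape registration — each
artifact voxel is reassigned to its nearest guide structure when
building the soft channels — but are excluded from the intensity metric
and from thickness analysis, which is how ex vivo artifact labels are
meant to be used.

## Atlas construction

Stage 1 registers everybody (affine + shape) to a deterministic
reference: the specimen whose guide-label volume is closest to the
cohort median. Stage 2 iterates an unbiased template loop — average the
warped soft channels, re-register to the average, recenter by composing
with the inverse of the mean deformation — until the mean deformation
RMS drops below 0.5 voxel or 5 iterations; a final re-registration pass
recovers the interpolation loss of the recentering compose. Stage 3
refines correspondences with artifact-masked NCC registration against
the mean intensity template and rebuilds the template as the mean of
bias-normalized warped intensities.

The per-stage alignment metric recorded in the provenance is the mean
*soft* generalized Dice of each specimen's warped guide channels
against the channel mean ("leave-one-in"): hard-label argmax Dice of
the 2.5-voxel-thick SRLM fluctuates at the half-voxel level under the
shared recentering resample and masks genuine alignment changes. The
stage-wise monotonicity the pipeline promises is enforced
structurally: stage 2 selects the best candidate field set subject to
the unbiasedness tolerance, and any stage-3 refinement that lowers a
specimen's (or the cohort's) guide overlap is rolled back to its
stage-2 field, with the rollback recorded in the provenance.

Template guide labels are the voxel-wise argmax of the averaged warped
*unsmoothed* indicators — the smoothed channels would swallow the thin
SRLM sheet into the background.

**Consensus subregions.** Warped subregion labels (per-label soft
warping, inventory preserved; inter-block gaps carry an `unknown` label
excluded from voting) are fused by majority vote with a Potts/MRF prior
(6-connectivity), optimized by iterated conditional modes from the
plain-majority start with raster sweeps and lowest-id tie-breaks. Vote
fractions carry a +0.5 pseudo-count so that isolated unanimity can
still be absorbed at large weights. With weight 0 the result is exactly
the plain majority vote. "Slight regularization" is not quantified in
the source material; the default weight is 0.5 log 2 per face, below
the bound (about log(2V + 1)/6 for V voters) under which unanimous,
spatially coherent inputs are provably preserved.

## Thickness

Thickness follows the Voronoi-skeleton definition: medial elements of
the binary mask, each carrying an inscribed radius; a boundary point's
thickness is twice the radius of its associated element.

Numerical realization, all validated on analytic phantoms (slab,
spherical shell, prescribed-thickness ribbons, thin grooves) and
against a brute-force inscribed-ball oracle:

* **Inscribed radius.** The voxel EDT reaches background voxel centers
  — half a voxel beyond a flat surface, less on staircased curved ones —
  so radii are measured to the 0.5 iso-surface of the smoothed
  indicator (marching tetrahedra vertices), which is subvoxel-accurate
  on flat, tilted and curved surfaces alike.
* **Ridge extraction.** A voxel is a medial candidate when its EDT
  generator and a 6-neighbor's generator subtend a sufficient angle at
  the voxel (law of cosines; `prune_ratio` is the equivalent
  separation-per-spoke threshold, default 1.6, i.e. about 106 degrees),
  both spokes are close to the inscribed radius (staircase fakes under
  tangent surfaces have one short and one long spoke), the generator
  separation clears a 2-voxel floor, and the voxel's radius is not
  smaller than the neighbor's. Elements whose ball is contained in a
  larger element's ball are then removed (the medial axis consists of
  maximal balls). Pruning is monotone in `prune_ratio`.
* **Assignment.** Each boundary voxel considers the skeleton balls that
  reach it, drops those below 0.35 of the largest covering radius, and
  takes the largest-radius element within half a voxel of the nearest
  qualifying one. Pure nearest-element assignment is hijacked by small
  residual branches; pure max-ball assignment bleeds across genuine
  thickness steps and would render a planted thinning patch invisible
  (measured slope attenuation ~95%). The hybrid keeps both the analytic
  phantoms and the step-localization phantoms within half a voxel.

Per-specimen sampling warps template surface vertices (marching
tetrahedra on the smoothed template masks, lightly Laplacian-smoothed;
the two collateral-sulcus banks merged for the MTL surface so thickness
is not truncated at the artificial bank split) into native space,
computes thickness from the specimen's own mask, and takes the nearest
boundary point within a 3-voxel capture radius. Vertices landing in the
artifact-exclusion region or beyond the capture radius are invalid, not
extrapolated.

## Statistics

The per-specimen burden measure is the mean of the non-missing location
ratings for one side and pathology. Cohort variants mirror the study's
analyses: tau with age (and optionally TDP-43) as covariates, the
low-TDP subset (average TDP-43 < 1), the TDP-43 effect with age and tau
as covariates, and the contralateral-ratings variant; all apply the
age >= 59 filter and explicit id exclusions, and rank-deficient designs
fail loudly naming the offending column.

The vertex-wise GLM is available-case OLS per vertex (minimum
`p + 3` valid specimens), with the pathology column's t statistic and
two-sided p at per-vertex residual degrees of freedom. Cluster
correction thresholds the uncorrected p-map (default p < 0.01,
two-sided, exposed as a flag; no surface smoothing by default), forms
connected components on the surface graph, and scores them by mass
(sum of |t|). The null distribution of the maximum cluster mass comes
from Freedman-Lane permutation: residuals of the reduced model
(nuisance covariates only) are permuted, the reduced-model fit added
back, and the full model refit; with an intercept-only reduced model
this reduces exactly to permuting the outcome. Corrected
p = (1 + #{null max >= observed}) / (n_perm + 1), monotone in observed
mass by construction. Artifact-driven validity patterns are handled by
permuting coherently within each validity pattern (the global
permutation's induced order on the pattern's rows). Clusters are
reported with their dominant consensus-subregion tag so outputs read
anatomically.

Bland-Altman agreement uses differences of side-averaged ratings with
limits at mean +/- 2 SD; the asymmetry count uses a strict threshold
(|difference| > 1 by default) and whole-percent display rounding.
Region-level summaries correlate mean synthetic NFT density over a
region's voxel support with the median thickness over its surface
vertices, optionally partialling out age (residual-on-residual, df
n - 3).

## Reduced-scale testing choices

Everything is sized for minute-scale continuous testing: 48^3 grids,
cohorts of 5-25, 199-500 permutations. The familywise error simulation
runs the statistics stage on generator-model thickness at the vertex
level (100 null cohorts x 200 permutations) rather than 100 full
registration pipelines: registration and skeletonization are
deterministic given geometry and carry no information about the null
hypothesis machinery under test. The full pipeline's hotspot-recovery
property is tested once at the stated scale (25 specimens, 500
permutations).

## Known limitations

* The registration parameter schedule is own-tuned on phantoms; no
  claim of equivalence with any published schedule is made.
* Thickness is quantized at the 0.2 mm working resolution; recovery of
  a planted thinning rate is accurate to ~15% (bias, not variance),
  dominated by partial-volume effects at patch rims.
* The consensus MRF uses ICM, which finds a local optimum adequate for
  slight regularization, not a global one.
* The printed cohort summary numbers of the source study rely on its
  supplementary per-specimen table, which is not redistributable here;
  the generator's stated world emulates the published summary scale and
  the tests check that emulation, not the original data.
* Anisotropic voxels are supported by the volume containers and I/O but
  not by the skeleton-thickness chain, which assumes isotropic spacing.
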
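---
title: "Estimating body composition from 3D body scans: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating body composition from 3D body scans: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`morphocomp` estimates ten body-composition variables (total and regional
fat and lean masses, visceral fat mass, percent body fat) from 3D optical
surface scans. This vignette explains the models, their assumptions, the
parameters that matter, and the choices made where the design was open.

## Why fixed topology

Every algorithm downstream of mesh I/O assumes *topology constancy*: all
meshes share one vertex ordering and face array, so vertex *i* is the same
anatomical location on every subject. Raw scans do not satisfy this, so the
remeshing stage maps each scan onto a template:

1. a sparse correspondence matrix **C** with exactly one unit entry per row
   selects, for each template vertex, the nearest source vertex (Euclidean,
   ties to the lowest index — deterministic);
2. the rough mapping `C %*% source_vertices` is refined by an explicit
   nonrigid iteration: each vertex moves a fraction `step` toward its
   closest point on the source surface, blended with a uniform-Laplacian
   term weighted by `smoothness`. With `smoothness = 0` the mean
   closest-point distance is non-increasing by construction.

Closest points are computed against source *vertices* rather than triangle
interiors: on the scan densities this package targets the difference is
well below the refinement step size, and vertex mode is deterministic and
fast. The refinement is deliberately simple — an affine-per-vertex
optimizer would track sharp creases better, and this is a known fidelity
gap. QC after templating flags the failure modes that matter in practice:
collapsed regions (near-zero-area faces), stretched bridges (max/median
edge ratio), and fragmented surfaces (component count). Default thresholds
(degenerate fraction ≤ 0.1%, edge ratio ≤ 20, exactly 1 component) are
package choices; tune them per scanner.

## The graph-convolutional autoencoder

On an irregular mesh graph there is no canonical neighbour ordering, so a
convolution kernel cannot assign one weight matrix per kernel position.
Instead each (node, neighbour-slot) pair mixes `M` shared basis matrices:

$$W_{i,j} = \sum_{k=1}^{M} \alpha_{i,j,k} B_k, \qquad
  y_i = \sum_{j} W_{i,j}^{\top} x_{i,j} + b$$

with neighbourhoods given by the 2-ring of each center vertex. `M = 37` is
the production default; the basis count trades parameter sharing against
spatial specificity and is freely configurable. The implementation
vectorizes the sum as $y_i = \sum_k B_k^\top \bigl(\sum_j \alpha_{i,j,k}
x_{i,j}\bigr) + b$, which turns every aggregation into a sparse
matrix–dense matrix product with a frozen sparsity pattern; a testthat
oracle re-derives the output from the literal two-equation form on random
graphs to 1e-10.

**Hierarchy.** Pooling structure is precomputed once per template: centers
are chosen greedily in ascending vertex index, accepting a vertex iff its
graph distance to every accepted center is at least `stride` (2);
neighbourhoods are the `radius`-rings (2) of each center; two centers are
adjacent at the next level iff their neighbourhoods overlap; unpooling is
the transposed membership normalized per fine vertex. Greedy ascending
order is a package decision made for determinism — the selection order of
the original architecture is unpublished, so exact per-level counts are not
a comparison surface, only the ~4× shrinkage per level.

**Architecture.** One full-resolution convolution lifts the 3 coordinate
channels to the first feature depth, then one pooled convolution per
hierarchy level down to the bottleneck (n_L nodes × f channels); the
decoder mirrors with untied weights (unpool, then a within-level
convolution), ending in a linear convolution back to 3 channels. Hidden
layers use tanh; the bottleneck and output are linear so the latent space
and coordinates are unbounded. These activation placements are package
choices; the source architecture leaves them unspecified.

**Training.** Inputs are centered on the training mean mesh and divided by
one global scalar (the RMS centered coordinate), so the optimizer sees O(1)
values; the loss is the mean per-vertex *Euclidean* distance (the same
definition `vertex_mae` reports, in mm after un-scaling). Per-coordinate
absolute error would be the other reading of "geometric MAE"; Euclidean
per-vertex is the convention of surface-error heatmaps and is used
everywhere here. Optimization is Adam (the optimizer is unnamed in the
source; Adam with default moments is fixed here) at learning rate 1e-4 and
batch size 16 by default; weights initialize from a scaled uniform
distribution with α set to 1/|neighbourhood| and zero biases, fully seeded.
After every epoch the evaluation set is reconstructed and the returned
model is the state with minimum evaluation loss — epoch selection against
overfitting. `pretrain_finetune` runs the two-corpus schedule: stage 1 on a
pose-varied corpus with an internal 80/20 split, stage 2 resuming on the
identity-varied corpus.

## The linear baseline

`fit_pca` takes the SVD of the centered `n × 3V` flattened vertex matrix
(numerically stabler than the covariance eigendecomposition) with the sign
of each component fixed by its largest-magnitude entry. Baselines are built
at the same `d` values as the autoencoder's flattened latent sizes so the
linear/nonlinear comparison holds capacity constant. No Procrustes
alignment or vertex weighting precedes PCA: inputs are already
template-registered.

## Composition regression

Features are `[shape features..., height, weight, age]`, z-scored with
training-set statistics — dot-product kernels are scale-sensitive and
millimetre-scale vertex coordinates would otherwise drown the
demographics. Columns with no training variation are dropped from the fit:
on a synthetic cohort whose shapes live on a low-dimensional manifold, PCA
directions beyond the effective rank have numerically zero training
variance, and a retest scan's noise along such a direction would otherwise
be amplified by the z-scoring into arbitrarily large feature values.

The regressor is GPR with the squared dot-product kernel

$$k(x, x') = \left(\sigma_0^2 + \tfrac{x \cdot x'}{p}\right)^2$$

whose predictive mean is mean-centered kernel ridge regression — exactly
ridge in the quadratic polynomial feature space of the inputs. The
quadratic form encodes the working assumption that composition is
nonlinear but monotone in overall size and girth measures. Two numerical
choices are the package's own, as the source leaves regularization
unstated: the dot product is averaged over the `p` feature dimensions
(the same 1/p normalization kernlab and scikit-learn kernels default to),
so kernel scale does not grow with feature count; and the noise term
defaults to `alpha = 0.1` on z-scored features. With the unnormalized
kernel and a near-zero alpha, the quadratic interpolant memorizes training
noise — near-zero training error, test error worse than the linear
baseline, the classic overfitting symptom — and the defaults are chosen to
sit on the generalizing side of that trade-off. Both are configurable;
marginal-likelihood optimization is deliberately off for determinism.
Models are fit per sex, one independent model per target variable; OLS
(intercept included, minimum-norm pseudoinverse when p ≥ n) is the linear
reference, and a demographics-only GPR ([height, weight, age], no shape)
is the floor every shape feature must beat.

## Evaluation statistics

- `rmse`, `r_squared` (1 − SS_res/SS_tot, not a squared correlation).
- `normalized_rmse`: 100 × RMSE / RMSE(PCA-OLS) per target — below 100%
  means the permutation beats the fully linear pipeline.
- Test–retest precision from same-day duplicate scans: per-subject SD
  |m₁ − m₂|/√2, pooled as RMS; `rms_cv_percent` divides by the grand mean
  of all 2n measurements (%CV); `repeat_rmse` reports the same precision
  error in the variable's units — used for percent fat, where a CV of a
  percentage is not conventional. The /2n convention (precision error, not
  plain pairwise RMSE) is flagged here because "RMSE between trial 1 and
  trial 2" admits both readings; the chosen one is consistent with the %CV
  column and differs from plain RMSE by exactly √2 (asserted in tests).
- `ablation_report` enforces identical train/test membership across all
  permutations — the controlled-comparison contract — and errors otherwise.

## The synthetic cohort

Restricted scan + DXA cohorts cannot be bundled, so tests and the
acceptance script run on a procedural stand-in:

- **Template**: a subdivided icosahedron (V = 10·4^s + 2) deformed by fixed
  smooth fields into a vertically elongated, waist-tapered body with paired
  lower bulges. It is a closed, clean, fixed-topology mesh about 1.7 m
  tall — body-*like*, not anatomical; topology constancy is the property
  the pipeline actually needs.
- **Morphs**: five positive factors (overall scale, trunk girth, limb
  girth, adiposity, stature), Gaussian around 1 with SDs (0.06, 0.12,
  0.10, 0.25, 0.05), drive smooth radial displacement fields. Height is
  the vertical extent; weight is the enclosed mesh volume times a fixed
  tissue density (0.985 g/cm³), so weight–volume correlation is exact.
- **Composition functions**: sex-specific, monotone increasing in every
  morph factor on the sampled domain (checked by finite differences), with
  genuine quadratic and interaction terms — fat fraction carries an a²
  term comparable to its linear term, and fat mass is fat fraction ×
  weight, an irreducible product. This curvature is what makes the
  GPR-versus-OLS comparison informative: a cohort whose composition were
  linear in shape would show nothing. Per-target Gaussian measurement
  noise emulates reference-method precision (e.g. 0.5 kg on total fat).
- **Retest pairs**: a smooth low-frequency pose field (default 8 mm) plus
  per-vertex noise (2 mm), seeded per subject.
- **Pretraining corpus**: few identities × many large pose deformations
  (40 mm bends) — shape diversity from articulation, not identity.

What passing tests on this cohort do **not** show: robustness to scan
holes, clothing, pose articulation with joints, segmentation errors, or
real anthropometric covariance between morphs. The generator's value is
that ground truth is known exactly, so recovery, monotonicity,
determinism, and the qualitative orderings (shape beats demographics, GPR
beats OLS under curvature, pretraining helps under a tight finetune
budget) are decidable.

## Problem sizes and numerical choices

The test suite and `scripts/acceptance.R` use scaled-down templates
(42- and 162-vertex) and cohorts (60–300 subjects), with basis counts and
channel lists (M = 8, channels 8/16 or 4/8, bottleneck ≤ 64 flat) matched
to those scales, and a learning rate of 2e-3 — small meshes tolerate and
reward a larger step than the production default. These sizes were chosen
as the smallest at which each qualitative effect is stable across seeds.
Other fixed numerics: nearest-neighbour ties always break to the lowest
index; hierarchy centers are selected in ascending index order; PCA signs
follow the largest-magnitude entry; degenerate faces are those with area
below 1e-9 mm²; the GPR solve is a Cholesky factorization of K + αI, which
is positive definite for any α > 0.

## Known limitations

- The nonrigid refinement is a simplified closest-point scheme, not an
  affine-per-vertex optimizer; it assumes source and template are already
  roughly aligned (no rigid pre-registration is provided).
- The autoencoder learns no invariances: a rigidly translated mesh encodes
  differently. Real pipelines should normalize pose and position upstream.
- Pure-R training is practical to a few hundred vertices and subjects;
  production-scale meshes (thousands of vertices, 10⁴ scans) need a GPU
  implementation of the same architecture.
- The per-sex models require both sexes in training data and cannot
  estimate subjects outside the binary labels the reference cohorts used.
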
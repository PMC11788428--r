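# morphocomp

Body composition estimation from 3D optical (3DO) body scans.

3DO surface scanners are cheap, fast and radiation-free, but they only see
the body's outer surface. `morphocomp` implements an end-to-end pipeline
that turns fixed-topology body meshes into estimates of ten DXA-style body
composition variables (total/regional fat and lean masses, visceral fat,
percent fat), for researchers evaluating shape-based body composition
models and for methodologists studying how shape representations and
regressors interact.

## The pipeline

1. **Topology standardization** (`solve_nn_correspondence`,
   `nonrigid_refine`, `qc_mesh`): a sparse correspondence matrix **C**
   (one nearest source vertex per template vertex) maps any roughly aligned
   scan onto a fixed template topology; an explicit nonrigid refinement
   (closest-point pull blended with uniform-Laplacian smoothing) maximizes
   surface-to-surface alignment, and QC flags collapsed or fragmented
   results.

2. **Shape encoding** — two interchangeable models at matched parameter
   count *d*:
   - a **graph-convolutional autoencoder** (`train_autoencoder`,
     `encode`, `decode`): spatial convolutions on the mesh graph where each
     neighbour's weight matrix is a learned mixture of *M* shared basis
     matrices, W_ij = Σ_k α_ijk B_k, y_i = Σ_j W_ijᵀ x_ij + b, over a
     precomputed pooling hierarchy (`build_hierarchy`, kernel radius 2,
     stride 2), trained with a per-vertex Euclidean MAE loss and optional
     pose-set pretraining (`pretrain_finetune`);
   - a **PCA shape model** (`fit_pca`), the linear baseline.

3. **Composition regression** (`fit_per_sex`, `fit_gpr`, `fit_ols`): shape
   features concatenated with [height, weight, age], z-scored, and mapped
   to each composition variable by Gaussian-process regression with a
   squared dot-product kernel k(x,x′) = (σ₀² + x·x′/p)² — equivalently,
   ridge regression in the quadratic polynomial feature space — or by OLS.
   Separate models per sex.

4. **Evaluation** (`ablation_report`, `rmse`, `r_squared`,
   `rms_cv_percent`, `repeat_rmse`): a controlled permutation grid where
   each row changes exactly one component, with RMSE normalized to the
   fully linear PCA-OLS row, plus duplicate-scan test–retest precision
   (RMS within-pair SD and Glüer-style %CV).

Because real scan + DXA cohorts are restricted, the package ships a
synthetic humanoid cohort generator (`synthetic_spec`,
`sample_population`, `make_retest_pair`, `make_pretrain_set`) with known
latent morphology and a monotone-nonlinear composition function, so every
stage is testable end to end.

## Worked example

```r
library(morphocomp)

cfg <- experiment_config(
  spec = synthetic_spec(n_subjects = 60, subdivision = 1),
  ae = ae_config(channels = c(4L, 8L), bottleneck_channels = 4L,
                 basis_size = 8L, learning_rate = 2e-3, batch_size = 8L),
  ae_epochs = 8, pca_d = 8, seed = 3,
  targets = c("total_fat_mass", "percent_fat"))
res <- run_experiment(cfg)
res$grid
#> # A tibble: 10 x 7
#>    model    extractor regressor target             n  rmse normalized_pct
#>  1 baseline none      GPR       total_fat_mass    12 4.05           266.
#>  3 PCA-OLS  PCA       OLS       total_fat_mass    12 1.52           100
#>  5 PCA-GPR  PCA       GPR       total_fat_mass    12 0.983           64.5
#>  7 Mesh-GPR Mesh      GPR       total_fat_mass    12 0.924           60.6
#>  ...
```

Reading the grid: each row is one pipeline permutation evaluated on the
same held-out subjects. `rmse` is the prediction error against the
cohort's reference composition values (kg, or percentage points for
percent fat); `normalized_pct` rescales it so the fully linear PCA-OLS
model is 100% — the PCA-GPR row at 64.5% means swapping OLS for the
quadratic-kernel GPR removed a third of the error on this cohort, while
the demographics-only baseline (no shape at all) has 2.7× the error.
`res$precision` reports the same models' test–retest stability on
duplicate scans, and `res$recon` the shape models' held-out reconstruction
MAE in millimetres.

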
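test_that("template vertex counts follow the icosphere formula and are deterministic", {
  expect_equal(nrow(make_template(0L)$vertices), 12L)
  expect_equal(nrow(make_template(1L)$vertices), 42L)   # 10*4 + 2
  expect_equal(nrow(make_template(2L)$vertices), 162L)  # 10*16 + 2
  expect_identical(make_template(2L), make_template(2L))
  # closed and clean
  expect_true(qc_mesh(make_template(2L))$pass)
})

test_that("the cohort is reproducible and morphs drive measurable shape change", {
  spec <- synthetic_spec(n_subjects = 12L, subdivision = 1L, seed = 21L)
  a <- sample_population(spec)
  b <- sample_population(spec)
  expect_identical(a$records, b$records)
  expect_identical(a$meshes[[5L]]$vertices, b$meshes[[5L]]$vertices)
  expect_identical(a$truth, b$truth)
  # all meshes share the template topology
  for (m in a$meshes) expect_identical(m$faces, a$template$faces)
})

test_that("zero morph variation and zero noise collapse the cohort onto the template", {
  spec <- synthetic_spec(n_subjects = 5L, subdivision = 1L, seed = 1L,
                         morph_sd = c(scale = 0, trunk = 0, limb = 0,
                                      adiposity = 0, stature = 0),
                         composition_noise_sd = stats::setNames(
                           rep(0, 10L), composition_targets()))
  pop <- sample_population(spec)
  for (m in pop$meshes) {
    expect_equal(vertex_mae(m, pop$meshes[[1L]]), 0)
  }
  for (s in c("male", "female")) {
    tg <- pop$records$total_fat_mass[pop$records$sex == s]
    if (length(tg) > 1L) expect_equal(diff(range(tg)), 0)
  }
})

test_that("the composition function is monotone in every morph parameter", {
  template <- make_template(1L)
  base <- c(scale = 1, trunk = 1, limb = 1, adiposity = 1, stature = 1)
  density <- 0.985e-6
  eval_targets <- function(m, sex) {
    v <- morphocomp:::apply_morphs(template, m)
    mesh <- triangle_mesh(v, template$faces)
    h <- (max(v[, 2]) - min(v[, 2])) / 10
    w <- morphocomp:::mesh_volume(mesh) * density
    morphocomp:::composition_truth(m, sex, h, w)
  }
  grid <- seq(0.7, 1.4, by = 0.1)
  for (sex in c("male", "female")) {
    for (param in names(base)) {
      vals <- sapply(grid, function(g) {
        m <- base; m[param] <- g
        eval_targets(m, sex)
      })
      for (tg in rownames(vals)) {
        d <- diff(vals[tg, ])
        expect_true(all(d >= -1e-9),
                    info = sprintf("%s not monotone in %s (%s)", tg, param, sex))
      }
    }
  }
  # doubling adiposity strictly increases fat mass
  lo <- eval_targets(base, "male")
  m2 <- base; m2["adiposity"] <- 2
  hi <- eval_targets(m2, "male")
  expect_gt(hi[["total_fat_mass"]], lo[["total_fat_mass"]])
})

test_that("morph samples match the spec distributions and weight tracks volume", {
  spec <- synthetic_spec(n_subjects = 1000L, subdivision = 0L, seed = 31L)
  pop <- sample_population(spec)
  for (p in names(spec$morph_mean)) {
    expect_lt(abs(mean(pop$truth[[p]]) - spec$morph_mean[[p]]),
              4 * spec$morph_sd[[p]] / sqrt(1000))
    expect_lt(abs(sd(pop$truth[[p]]) - spec$morph_sd[[p]]),
              0.15 * spec$morph_sd[[p]] + 1e-9)
  }
  vols <- vapply(pop$meshes, morphocomp:::mesh_volume, numeric(1))
  expect_gt(cor(vols, pop$records$weight_kg), 0.9)
})

test_that("retest pairs are seed-stable perturbations at the configured scale", {
  spec <- synthetic_spec(n_subjects = 2L, subdivision = 1L, seed = 41L)
  pop <- sample_population(spec)
  m <- pop$meshes[[1L]]
  r1 <- make_retest_pair(m, spec, 7L)
  r2 <- make_retest_pair(m, spec, 7L)
  expect_identical(r1$vertices, r2$vertices)
  r3 <- make_retest_pair(m, spec, 8L)
  expect_gt(vertex_mae(r1, r3), 0)
  # perturbation magnitude within 3x the configured scales
  scale <- spec$pose_jitter_mm + spec$retest_noise_sd_mm
  expect_lt(vertex_mae(m, r1), 3 * scale)
  expect_gt(vertex_mae(m, r1), 0)
  # zero jitter and noise reproduce the input
  spec0 <- spec
  spec0$pose_jitter_mm <- 0
  spec0$retest_noise_sd_mm <- 0
  expect_equal(make_retest_pair(m, spec0, 7L)$vertices, m$vertices)
})

test_that("the pretraining corpus has few identities and many poses", {
  spec <- synthetic_spec(subdivision = 1L, seed = 51L)
  pre <- make_pretrain_set(spec, n_individuals = 2L, n_poses = 20L)
  expect_length(pre$meshes, 40L)
  expect_equal(sort(unique(pre$identity)), 1:2)
  for (m in pre$meshes) expect_identical(m$faces, pre$template$faces)
  # within-identity distances smaller than between-identity on average
  mae_mat <- matrix(0, 40L, 40L)
  for (i in 1:39) for (j in (i + 1):40) {
    mae_mat[i, j] <- mae_mat[j, i] <- vertex_mae(pre$meshes[[i]], pre$meshes[[j]])
  }
  same <- outer(pre$identity, pre$identity, `==`) & upper.tri(mae_mat)
  diff_id <- outer(pre$identity, pre$identity, `!=`) & upper.tri(mae_mat)
  expect_lt(mean(mae_mat[same]), mean(mae_mat[diff_id]))
})

test_that("the spec constructor rejects invalid settings", {
  expect_error(synthetic_spec(n_subjects = 0L), ">= 1")
  expect_error(synthetic_spec(retest_noise_sd_mm = -1), ">= 0")
})
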
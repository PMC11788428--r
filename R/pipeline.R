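# End-to-end experiment runner on a synthetic cohort: simulate ->
# hierarchy -> train autoencoder & fit PCA -> regress all permutations ->
# evaluate accuracy and test-retest precision. One global seed fans out to
# fixed per-stage seeds so stages can be rerun in isolation; every
# permutation shares identical train/test membership.

#' Experiment configuration
#'
#' @param spec a [synthetic_spec()] describing the cohort.
#' @param ae an [ae_config()] for the shape autoencoder.
#' @param levels hierarchy depth (must equal `length(ae$channels)`).
#' @param pca_d PCA component count (defaults to the autoencoder's
#'   flattened latent size, for the matched-parameter comparison).
#' @param ae_layer which encoder layer feeds the 3DAE-GPR row
#'   (`"bottleneck"` or a 0-based level index).
#' @param targets composition variables to evaluate.
#' @param test_fraction held-out test share (default 0.2).
#' @param eval_fraction share of the training half used for epoch selection.
#' @param ae_epochs training epochs (defaults to `ae$finetune_epochs`).
#' @param with_pretrain also run the pose-pretraining stage first.
#' @param gpr_args arguments passed to [fit_gpr()].
#' @param seed global experiment seed.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(spec = synthetic_spec(),
                              ae = ae_config(channels = c(8L, 16L),
                                             bottleneck_channels = 4L,
                                             basis_size = 8L,
                                             learning_rate = 2e-3),
                              levels = length(ae$channels),
                              pca_d = NULL,
                              ae_layer = "bottleneck",
                              targets = composition_targets(),
                              test_fraction = 0.2,
                              eval_fraction = 0.2,
                              ae_epochs = 60L,
                              with_pretrain = FALSE,
                              gpr_args = list(),
                              seed = 1L) {
  structure(list(spec = spec, ae = ae, levels = as.integer(levels),
                 pca_d = pca_d, ae_layer = ae_layer, targets = targets,
                 test_fraction = test_fraction, eval_fraction = eval_fraction,
                 ae_epochs = as.integer(ae_epochs),
                 with_pretrain = isTRUE(with_pretrain),
                 gpr_args = gpr_args, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run the full synthetic experiment
#'
#' @param config an [experiment_config()].
#' @param out_dir optional directory; when given, the grid, precision
#'   report, training history and config are written as CSV/YAML files.
#' @param verbose print stage progress.
#' @return list: `grid` (ablation tibble), `precision` (tibble),
#'   `recon` (tibble of shape-model test MAEs), `history`, `splits`,
#'   `population`, `ae_model`, `pca_model`.
#' @export
run_experiment <- function(config, out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  spec <- config$spec
  spec$seed <- config$seed  # single global seed fans out per stage
  say("stage=simulate n=%d", spec$n_subjects)
  pop <- sample_population(spec)
  n <- spec$n_subjects

  set.seed(config$seed + 100L)
  n_test <- max(1L, round(config$test_fraction * n))
  test_idx <- sort(sample.int(n, n_test))
  train_idx <- setdiff(seq_len(n), test_idx)
  n_eval <- max(1L, round(config$eval_fraction * length(train_idx)))
  eval_idx <- sort(sample(train_idx, n_eval))
  fit_idx <- setdiff(train_idx, eval_idx)

  say("stage=hierarchy levels=%d", config$levels)
  adj <- vertex_adjacency(pop$template)
  hier <- build_hierarchy(adj, config$levels, radius = config$ae$radius,
                          stride = config$ae$stride)

  say("stage=train-ae epochs=%d", config$ae_epochs)
  ae_cfg <- config$ae
  ae_cfg$seed <- config$seed + 200L
  if (config$with_pretrain) {
    pre <- make_pretrain_set(spec)
    run <- pretrain_finetune(pre$meshes, pop$meshes[fit_idx],
                             pop$meshes[eval_idx], ae_cfg, hier, pop$template)
    ae_model <- run$model
    history <- run$finetune_history
  } else {
    run <- train_autoencoder(pop$meshes[fit_idx], pop$meshes[eval_idx],
                             ae_cfg, hier, pop$template,
                             epochs = config$ae_epochs)
    ae_model <- run$model
    history <- run$history
  }

  d <- if (is.null(config$pca_d)) {
    min(ae_latent_size(ae_model), length(train_idx) - 1L)
  } else config$pca_d
  say("stage=fit-pca d=%d", d)
  pca_model <- fit_pca(pop$meshes[train_idx], d)

  say("stage=features layer=%s", as.character(config$ae_layer))
  mesh_feats <- t(vapply(pop$meshes, function(m) as.numeric(t(m$vertices)),
                         numeric(3L * nrow(pop$template$vertices))))
  pca_feats <- t(vapply(pop$meshes, function(m) pca_encode(pca_model, m),
                        numeric(d)))
  ae_feats <- t(vapply(pop$meshes,
                       function(m) extract_features(ae_model, m, config$ae_layer),
                       numeric(length(extract_features(ae_model, pop$meshes[[1L]],
                                                       config$ae_layer)))))
  feature_sets <- list(PCA = pca_feats, Mesh = mesh_feats, `3DAE` = ae_feats)

  say("stage=regress permutations=%d", 2L + 2L * length(feature_sets))
  grid <- ablation_report(pop$records, feature_sets, train_idx, test_idx,
                          targets = config$targets,
                          gpr_args = config$gpr_args)

  say("stage=reconstruction")
  recon <- tibble::tibble(
    model = c("3DAE", "PCA", "mean-mesh"),
    test_mae_mm = c(
      mean(vapply(pop$meshes[test_idx],
                  function(m) vertex_mae(m, reconstruct(m, ae_model)),
                  numeric(1))),
      mean(vapply(pop$meshes[test_idx],
                  function(m) vertex_mae(m$vertices, pca_reconstruct(pca_model, m)),
                  numeric(1))),
      {
        mean_mesh <- Reduce(`+`, lapply(pop$meshes[train_idx], `[[`, "vertices")) /
          length(train_idx)
        mean(vapply(pop$meshes[test_idx],
                    function(m) vertex_mae(m$vertices, mean_mesh), numeric(1)))
      }))

  say("stage=precision pairs=%d", length(test_idx))
  precision <- precision_report(pop, ae_model, pca_model, config,
                                train_idx, test_idx)

  out <- list(grid = grid, precision = precision, recon = recon,
              history = history, config = config,
              splits = list(fit = fit_idx, eval = eval_idx,
                            train = train_idx, test = test_idx),
              population = pop, ae_model = ae_model, pca_model = pca_model)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(grid, file.path(out_dir, "grid.csv"), row.names = FALSE)
    utils::write.csv(precision, file.path(out_dir, "precision.csv"),
                     row.names = FALSE)
    utils::write.csv(recon, file.path(out_dir, "reconstruction.csv"),
                     row.names = FALSE)
    if (!is.null(history)) {
      utils::write.csv(history, file.path(out_dir, "history.csv"),
                       row.names = FALSE)
    }
    yaml::write_yaml(config_to_list(config), file.path(out_dir, "config.yaml"))
  }
  out
}

# test-retest precision of predicted composition: duplicate scans of each
# test subject pushed through the fitted shape+regression models
precision_report <- function(pop, ae_model, pca_model, config,
                             train_idx, test_idx) {
  records <- pop$records
  retest <- lapply(test_idx, function(i) {
    make_retest_pair(pop$meshes[[i]], config$spec,
                     subject_seed = config$seed + 300L + i)
  })
  d <- nrow(pca_model$components)
  featurize <- function(meshes, kind) {
    switch(kind,
           `3DAE` = t(vapply(meshes, function(m)
             extract_features(ae_model, m, "bottleneck"),
             numeric(ae_latent_size(ae_model)))),
           PCA = t(vapply(meshes, function(m) pca_encode(pca_model, m),
                          numeric(d))))
  }
  models_for <- function(kind, regressor, target) {
    feats <- featurize(pop$meshes, kind)
    sexes <- c("male", "female")
    stats::setNames(lapply(sexes, function(s) {
      itr <- train_idx[records$sex[train_idx] == s]
      do.call(fit_composition_model,
              c(list(records[itr, , drop = FALSE],
                     feats[itr, , drop = FALSE], target, regressor),
                if (regressor == "GPR") config$gpr_args))
    }), sexes)
  }
  rows <- list()
  for (perm in list(c("3DAE", "GPR"), c("PCA", "GPR"), c("PCA", "OLS"))) {
    kind <- perm[1L]; regressor <- perm[2L]
    f1 <- featurize(pop$meshes[test_idx], kind)
    f2 <- featurize(retest, kind)
    for (target in c("visceral_fat_mass", "percent_fat")) {
      mods <- models_for(kind, regressor, target)
      te <- records[test_idx, , drop = FALSE]
      p1 <- numeric(nrow(te)); p2 <- numeric(nrow(te))
      for (s in c("male", "female")) {
        ii <- which(te$sex == s)
        if (!length(ii)) next
        p1[ii] <- predict(mods[[s]], te[ii, , drop = FALSE], f1[ii, , drop = FALSE])
        p2[ii] <- predict(mods[[s]], te[ii, , drop = FALSE], f2[ii, , drop = FALSE])
      }
      pairs <- tibble::tibble(m1 = p1, m2 = p2)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        model = paste(kind, regressor, sep = "-"), target = target,
        n = nrow(pairs),
        cv_percent = if (target == "percent_fat") NA_real_ else rms_cv_percent(pairs),
        repeat_rmse = repeat_rmse(pairs))
    }
  }
  dplyr::bind_rows(rows)
}

config_to_list <- function(config) {
  list(seed = config$seed,
       n_subjects = config$spec$n_subjects,
       subdivision = config$spec$subdivision,
       levels = config$levels,
       channels = config$ae$channels,
       bottleneck_channels = config$ae$bottleneck_channels,
       basis_size = config$ae$basis_size,
       learning_rate = config$ae$learning_rate,
       batch_size = config$ae$batch_size,
       ae_epochs = config$ae_epochs,
       ae_layer = as.character(config$ae_layer),
       test_fraction = config$test_fraction,
       eval_fraction = config$eval_fraction,
       with_pretrain = config$with_pretrain,
       targets = config$targets)
}
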
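# Controlled model-permutation grid: every row changes exactly one pipeline
# component (feature extractor or regressor) while all rows share identical
# train/test membership, and each cell's RMSE is also reported normalized to
# the fully linear PCA-OLS row.

#' Build the ablation grid over extractors and regressors
#'
#' Trains and evaluates every (extractor, regressor) permutation on
#' identical train/test membership and reports per-target RMSE plus RMSE
#' normalized to the `PCA-OLS` row (100% = the fully linear baseline; below
#' 100% = lower error).
#'
#' @param records subject tibble ([sample_population()] format).
#' @param feature_sets named list of `n x d` feature matrices aligned with
#'   `records` rows; must contain an entry named `"PCA"` (the normalization
#'   anchor is the `PCA` + `OLS` permutation). A `"none"` entry of 0 columns
#'   is added automatically for the demographics baseline.
#' @param train_idx,test_idx disjoint row indices shared by every
#'   permutation.
#' @param targets composition variable names (default all ten).
#' @param per_sex fit separate models per sex (default TRUE).
#' @param gpr_args list of arguments passed to [fit_gpr()].
#' @return an `ablation_grid` tibble: model, extractor, regressor, target,
#'   n, rmse, normalized_pct.
#' @export
ablation_report <- function(records, feature_sets, train_idx, test_idx,
                            targets = composition_targets(),
                            per_sex = TRUE, gpr_args = list()) {
  if (length(intersect(train_idx, test_idx)) > 0L) {
    stop("train and test membership overlap: controlled comparison violated")
  }
  if (!"PCA" %in% names(feature_sets)) {
    stop("feature_sets must contain a 'PCA' entry (the normalization baseline)")
  }
  for (nm in names(feature_sets)) {
    if (nrow(as.matrix(feature_sets[[nm]])) != nrow(records)) {
      stop(sprintf("feature set '%s' rows do not match records", nm))
    }
  }
  perms <- dplyr::bind_rows(
    tibble::tibble(model = "baseline", extractor = "none", regressor = "GPR"),
    tidyr::expand_grid(extractor = names(feature_sets),
                       regressor = c("OLS", "GPR")) |>
      dplyr::filter(.data$extractor == "PCA" | .data$regressor == "GPR") |>
      dplyr::mutate(model = paste(.data$extractor, .data$regressor, sep = "-"))
  )
  feature_sets <- c(feature_sets,
                    list(none = matrix(numeric(0), nrow(records), 0L)))
  rows <- purrr::pmap_dfr(perms, function(model, extractor, regressor) {
    feats <- as.matrix(feature_sets[[extractor]])
    purrr::map_dfr(targets, function(tg) {
      res <- fit_eval_permutation(records, feats, train_idx, test_idx, tg,
                                  regressor, per_sex, gpr_args)
      tibble::tibble(model = model, extractor = extractor,
                     regressor = regressor, target = tg,
                     n = res$n, rmse = res$rmse)
    })
  })
  base <- rows |> dplyr::filter(.data$model == "PCA-OLS") |>
    dplyr::select("target", baseline_rmse = "rmse")
  out <- rows |> dplyr::left_join(base, by = "target") |>
    dplyr::mutate(normalized_pct = 100 * .data$rmse / .data$baseline_rmse) |>
    dplyr::select(-"baseline_rmse")
  class(out) <- c("ablation_grid", class(out))
  out
}

# one (features, regressor, target) permutation: pooled-test RMSE over the
# per-sex (or pooled) models
fit_eval_permutation <- function(records, feats, train_idx, test_idx, target,
                                 regressor, per_sex, gpr_args) {
  tr <- records[train_idx, , drop = FALSE]
  te <- records[test_idx, , drop = FALSE]
  ftr <- feats[train_idx, , drop = FALSE]
  fte <- feats[test_idx, , drop = FALSE]
  pred <- numeric(nrow(te))
  if (per_sex) {
    for (s in c("male", "female")) {
      itr <- which(tr$sex == s)
      ite <- which(te$sex == s)
      if (length(itr) == 0L) stop(sprintf("no %s training records", s))
      cm <- do.call(fit_composition_model,
                    c(list(tr[itr, , drop = FALSE], ftr[itr, , drop = FALSE],
                           target, regressor), if (regressor == "GPR") gpr_args))
      if (length(ite)) {
        pred[ite] <- predict(cm, te[ite, , drop = FALSE],
                             fte[ite, , drop = FALSE])
      }
    }
  } else {
    cm <- do.call(fit_composition_model,
                  c(list(tr, ftr, target, regressor),
                    if (regressor == "GPR") gpr_args))
    pred <- predict(cm, te, fte)
  }
  list(rmse = rmse(pred, te[[target]]), n = nrow(te))
}

#' Plot an ablation grid
#' @param object an `ablation_grid`.
#' @param ... unused.
#' @return a ggplot tile map of normalized RMSE (model x target).
#' @method autoplot ablation_grid
#' @export
autoplot.ablation_grid <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$target, y = .data$model,
                               fill = .data$normalized_pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.0f%%", .data$normalized_pct)), size = 3) +
    ggplot2::scale_fill_gradient2(midpoint = 100, low = "#2166ac",
                                  mid = "white", high = "#b2182b",
                                  name = "% of PCA-OLS RMSE") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
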
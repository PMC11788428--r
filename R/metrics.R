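# Accuracy and test-retest precision statistics: RMSE against reference
# measurements, RMSE normalized to the fully linear PCA-OLS baseline,
# coefficient of determination, and duplicate-scan precision (RMS
# within-pair SD and the Gluer-style %CV).

#' Root-mean-squared error
#' @param pred,ref equal-length numeric vectors (target units).
#' @return scalar RMSE.
#' @export
rmse <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("pred and ref lengths differ")
  if (length(pred) < 1L) stop("need at least one pair")
  sqrt(mean((pred - ref)^2))
}

#' RMSE normalized to a baseline model (percent)
#'
#' `100 x model / baseline`; values below 100% mean lower error than the
#' baseline (conventionally the fully linear PCA-OLS column).
#'
#' @param model_rmse,baseline_rmse positive scalars in the same units.
#' @return percent.
#' @export
normalized_rmse <- function(model_rmse, baseline_rmse) {
  if (baseline_rmse <= 0) stop("baseline RMSE must be > 0")
  100 * model_rmse / baseline_rmse
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` (not a squared correlation): can be negative for
#' models worse than predicting the reference mean.
#'
#' @param pred,ref equal-length vectors; `ref` must not be constant.
#' @return scalar `<= 1`.
#' @export
r_squared <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("pred and ref lengths differ")
  if (length(ref) < 2L) stop("need at least two pairs")
  ss_tot <- sum((ref - mean(ref))^2)
  if (ss_tot == 0) stop("reference is constant; R^2 undefined")
  1 - sum((pred - ref)^2) / ss_tot
}

check_pairs <- function(pairs) {
  need <- c("m1", "m2")
  if (!all(need %in% names(pairs))) {
    stop("pairs must have columns m1 and m2 (the duplicate measurements)")
  }
  if (nrow(pairs) < 1L) stop("need at least one pair")
  if (any(!is.finite(pairs$m1)) || any(!is.finite(pairs$m2))) {
    stop("non-finite measurement in pairs")
  }
  invisible(pairs)
}

#' Test-retest precision as RMS coefficient of variation (percent)
#'
#' Duplicate-scan precision in the Gluer sense: per-subject SD is
#' `|m1 - m2| / sqrt(2)`, the RMS-SD pools subjects as
#' `sqrt(sum SD_i^2 / n)`, and %CV divides by the grand mean of all `2n`
#' measurements.
#'
#' @param pairs data frame with columns `m1`, `m2` (same variable, same
#'   device, same day).
#' @return percent CV.
#' @export
rms_cv_percent <- function(pairs) {
  check_pairs(pairs)
  gm <- mean(c(pairs$m1, pairs$m2))
  if (gm <= 0) stop("grand mean must be > 0 for %CV")
  sd_i2 <- (pairs$m1 - pairs$m2)^2 / 2
  100 * sqrt(mean(sd_i2)) / gm
}

#' Test-retest precision as RMS within-pair SD (target units)
#'
#' `sqrt( sum (m1 - m2)^2 / (2n) )` — the precision error underlying %CV,
#' reported in the variable's own units (used for percent-fat precision,
#' where a CV of a percentage is not conventional).
#'
#' @param pairs data frame with columns `m1`, `m2`.
#' @return scalar precision error.
#' @export
repeat_rmse <- function(pairs) {
  check_pairs(pairs)
  sqrt(sum((pairs$m1 - pairs$m2)^2) / (2 * nrow(pairs)))
}

#' Evaluate a set of fitted composition models on a test split
#'
#' @param models named list of `composition_model`s (e.g. per sex).
#' @param records test subject tibble.
#' @param features aligned shape features for the test rows.
#' @param target composition variable name.
#' @return tibble: sex, n, rmse, r_squared.
#' @export
evaluate_models <- function(models, records, features, target) {
  features <- as.matrix(features)
  purrr::map_dfr(names(models), function(s) {
    idx <- which(records$sex == s)
    if (length(idx) == 0L) {
      return(tibble::tibble(sex = s, n = 0L, rmse = NA_real_,
                            r_squared = NA_real_))
    }
    pred <- predict(models[[s]], records[idx, , drop = FALSE],
                    features[idx, , drop = FALSE])
    ref <- records[[target]][idx]
    tibble::tibble(sex = s, n = length(idx), rmse = rmse(pred, ref),
                   r_squared = r_squared(pred, ref))
  })
}
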
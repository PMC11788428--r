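# Body-composition regression: shape features plus [height, weight, age]
# mapped to each of the ten DXA-style composition variables, per sex, by
# ordinary least squares or Gaussian-process regression with a squared
# dot-product kernel k(x, x') = (sigma0^2 + x.x')^2. The squared dot-product
# kernel encodes the assumption that composition is nonlinear but monotone
# in shape: it is exactly ridge regression in the quadratic polynomial
# feature space of the inputs.

#' The ten body-composition target variables
#'
#' Masses in kg; `percent_fat` in percent of body mass.
#' @return character vector of target names.
#' @export
composition_targets <- function() {
  c("total_fat_mass", "total_lean_mass", "visceral_fat_mass",
    "arm_lean_mass", "leg_lean_mass", "percent_fat",
    "trunk_fat_mass", "trunk_lean_mass", "arm_fat_mass", "leg_fat_mass")
}

#' Fit per-feature standardization statistics
#'
#' Columns with (numerically) zero training variance get sd 1 so they
#' standardize to their deviation from the training mean rather than
#' exploding; `keep` flags the columns with genuine variation, which is what
#' the regression fits should use (a direction the training set never
#' explores carries no signal, only amplified noise).
#'
#' @param X `n x p` training feature matrix.
#' @return list of per-column `mean`, `sd`, and logical `keep`.
#' @export
feature_stats <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  tol <- 1e-8 * max(c(sd[is.finite(sd)], 1))
  keep <- is.finite(sd) & sd > tol
  sd[!keep] <- 1
  list(mean = mu, sd = sd, keep = keep)
}

#' Assemble a regression feature vector
#'
#' Concatenates `[shape_features..., height, weight, age]` and, when
#' training-set standardization statistics are supplied, z-scores every
#' dimension. Dot-product kernels are scale-sensitive, so standardization
#' keeps millimetre-scale shape features from drowning the demographics.
#'
#' @param shape_features numeric vector (may be empty for the
#'   demographics-only baseline) or an `n x d` matrix.
#' @param height cm; `weight` kg; `age` years (scalars or length-n vectors).
#' @param stats optional [feature_stats()] of the assembled training matrix.
#' @return numeric vector (or matrix for matrix input), length `d + 3`.
#' @export
assemble_features <- function(shape_features, height, weight, age, stats = NULL) {
  if (is.matrix(shape_features) || length(height) > 1L) {
    sf <- if (is.null(shape_features) || length(shape_features) == 0L) {
      matrix(numeric(0), nrow = length(height), ncol = 0L)
    } else as.matrix(shape_features)
    X <- cbind(sf, height = height, weight = weight, age = age)
  } else {
    X <- matrix(c(as.numeric(shape_features), height, weight, age), nrow = 1L)
  }
  if (any(!is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite feature at dimension %d", bad[2L]))
  }
  if (!is.null(stats)) {
    X <- sweep(sweep(X, 2L, stats$mean), 2L, stats$sd, `/`)
  }
  if (nrow(X) == 1L && !is.matrix(shape_features) && length(height) == 1L) {
    as.numeric(X)
  } else X
}

#' Ordinary least squares with minimum-norm fallback
#'
#' Intercept-augmented least squares. When `p + 1 > n` (more parameters
#' than observations) the minimum-norm solution via SVD pseudoinverse is
#' returned.
#'
#' @param X `n x p` feature matrix.
#' @param y length-n target vector.
#' @return `regression_model` of kind `"OLS"`.
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X rows and y length differ")
  if (nrow(X) < 1L) stop("need at least one observation")
  A <- cbind(1, X)
  beta <- pinv_solve(A, y)
  structure(list(kind = "OLS", intercept = beta[1L], coef = beta[-1L],
                 p = ncol(X)),
            class = "regression_model")
}

# minimum-norm least squares via SVD with relative tolerance
pinv_solve <- function(A, y, rtol = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > rtol * sv$d[1L]
  as.numeric(sv$v[, keep, drop = FALSE] %*%
               ((crossprod(sv$u[, keep, drop = FALSE], y)) / sv$d[keep]))
}

#' Gaussian-process regression with a dot-product kernel
#'
#' Kernel `k(x, x') = (sigma0^2 + x . x' / p)^degree` (degree 2 by default,
#' the squared dot-product kernel; the dot product is averaged over the `p`
#' feature dimensions so the kernel scale is independent of feature count,
#' the same `1/p` normalization other kernel implementations default to).
#' Targets are mean-centered internally; the predictive mean is
#' `ybar + k*' (K + alpha I)^{-1} (y - ybar)`, solved by Cholesky
#' factorization.
#'
#' @param X `n x p` feature matrix (standardize first; see
#'   [assemble_features()]).
#' @param y length-n targets.
#' @param sigma0_sq kernel offset `sigma0^2 >= 0` (default 1).
#' @param noise_alpha regularization `alpha > 0` added to the kernel
#'   diagonal (default 0.1, suited to z-scored features; training noise is
#'   otherwise interpolated).
#' @param degree kernel exponent (2 = squared dot product; 1 = linear).
#' @return `regression_model` of kind `"GPR"`.
#' @export
fit_gpr <- function(X, y, sigma0_sq = 1, noise_alpha = 0.1, degree = 2L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X rows and y length differ")
  if (nrow(X) < 1L) stop("need at least one observation")
  if (sigma0_sq < 0) stop("sigma0_sq must be >= 0")
  if (noise_alpha <= 0) stop("noise_alpha must be > 0")
  p_scale <- max(1L, ncol(X))
  K <- (sigma0_sq + tcrossprod(X) / p_scale)^degree
  ybar <- mean(y)
  n <- nrow(X)
  Kr <- K + diag(noise_alpha, n)
  ch <- tryCatch(chol(Kr), error = function(e) {
    stop(sprintf("kernel system not positive definite (condition ~ %.3g): %s",
                 kappa(Kr), conditionMessage(e)))
  })
  dual <- backsolve(ch, forwardsolve(t(ch), y - ybar))
  structure(list(kind = "GPR", X_train = X, dual = dual, ybar = ybar,
                 sigma0_sq = sigma0_sq, noise_alpha = noise_alpha,
                 degree = as.integer(degree), p = ncol(X),
                 p_scale = p_scale),
            class = "regression_model")
}

#' @export
print.regression_model <- function(x, ...) {
  if (x$kind == "OLS") {
    cat(sprintf("<regression_model OLS: p=%d>\n", x$p))
  } else {
    cat(sprintf("<regression_model GPR: p=%d, n=%d, (sigma0^2 + x.x')^%d, alpha=%g>\n",
                x$p, nrow(x$X_train), x$degree, x$noise_alpha))
  }
  invisible(x)
}

#' Predict from a fitted regression model
#' @param object a `regression_model`.
#' @param X `m x p` feature matrix (or length-p vector).
#' @param ... unused.
#' @return length-m numeric predictions in target units.
#' @export
predict.regression_model <- function(object, X, ...) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (ncol(X) != object$p) {
    stop(sprintf("model expects %d features, got %d", object$p, ncol(X)))
  }
  if (object$kind == "OLS") {
    as.numeric(object$intercept + X %*% object$coef)
  } else {
    Ks <- (object$sigma0_sq +
             tcrossprod(X, object$X_train) / object$p_scale)^object$degree
    as.numeric(object$ybar + Ks %*% object$dual)
  }
}

#' Fit one model per sex
#'
#' @param records a subject tibble (see [sample_population()]) with columns
#'   `sex`, `height_cm`, `weight_kg`, `age_years` and the target column.
#' @param features `n x d` shape-feature matrix aligned with `records` rows
#'   (0 columns for the demographics-only baseline).
#' @param target name of the composition variable to fit.
#' @param method `"GPR"` or `"OLS"`.
#' @param ... passed to [fit_gpr()].
#' @return list with elements `male` and `female`, each a list
#'   `model`, `stats` (feature standardization), `target`, `method`.
#' @export
fit_per_sex <- function(records, features, target, method = c("GPR", "OLS"), ...) {
  method <- match.arg(method)
  features <- as.matrix(features)
  if (nrow(features) != nrow(records)) stop("features and records row mismatch")
  if (!target %in% names(records)) stop(sprintf("no target column '%s'", target))
  out <- list()
  for (s in c("male", "female")) {
    idx <- which(records$sex == s)
    if (length(idx) == 0L) stop(sprintf("no %s records", s))
    out[[s]] <- fit_composition_model(records[idx, , drop = FALSE],
                                      features[idx, , drop = FALSE],
                                      target, method, ...)
  }
  out
}

# single-sex (or pooled) fit with standardization baked in; columns without
# training variation are dropped from the fit entirely
fit_composition_model <- function(records, features, target, method, ...) {
  Xraw <- assemble_features(features, records$height_cm, records$weight_kg,
                            records$age_years)
  st <- feature_stats(Xraw)
  X <- sweep(sweep(Xraw, 2L, st$mean), 2L, st$sd, `/`)[, st$keep, drop = FALSE]
  y <- records[[target]]
  model <- if (method == "OLS") fit_ols(X, y) else fit_gpr(X, y, ...)
  structure(list(model = model, stats = st, target = target, method = method),
            class = "composition_model")
}

#' Predict body composition for new subjects
#' @param object a `composition_model` from [fit_per_sex()] /
#'   [baseline_demographics_model()].
#' @param records subject tibble rows to predict for.
#' @param features aligned shape-feature matrix (0 columns for baseline).
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.composition_model <- function(object, records, features, ...) {
  features <- as.matrix(features)
  X <- assemble_features(features, records$height_cm, records$weight_kg,
                         records$age_years, stats = object$stats)
  predict(object$model, X[, object$stats$keep, drop = FALSE])
}

#' Demographics-only baseline model
#'
#' GPR from `[height, weight, age]` alone, without any shape conditioning —
#' the floor that any useful shape feature must beat.
#'
#' @param records subject tibble.
#' @param target composition variable name.
#' @param ... passed to [fit_gpr()].
#' @return a `composition_model`.
#' @export
baseline_demographics_model <- function(records, target, ...) {
  fit_composition_model(records,
                        matrix(numeric(0), nrow = nrow(records), ncol = 0L),
                        target, "GPR", ...)
}

#' Tidy a regression model
#' @param x a `regression_model`.
#' @param ... unused.
#' @return for OLS, tibble of term/estimate; for GPR, tibble of
#'   training-point dual coefficients.
#' @method tidy regression_model
#' @export
tidy.regression_model <- function(x, ...) {
  if (x$kind == "OLS") {
    tibble::tibble(term = c("(Intercept)", paste0("x", seq_along(x$coef))),
                   estimate = c(x$intercept, x$coef))
  } else {
    tibble::tibble(term = paste0("dual", seq_along(x$dual)),
                   estimate = x$dual)
  }
}

#' One-row summary of a regression model
#' @param x a `regression_model`.
#' @param ... unused.
#' @return tibble with kind, p, and (GPR) kernel settings.
#' @method glance regression_model
#' @export
glance.regression_model <- function(x, ...) {
  tibble::tibble(kind = x$kind, p = x$p,
                 n_train = if (x$kind == "GPR") nrow(x$X_train) else NA_integer_,
                 sigma0_sq = if (x$kind == "GPR") x$sigma0_sq else NA_real_,
                 noise_alpha = if (x$kind == "GPR") x$noise_alpha else NA_real_,
                 degree = if (x$kind == "GPR") x$degree else 1L)
}
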
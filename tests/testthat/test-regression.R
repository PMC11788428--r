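test_that("assemble_features concatenates demographics and standardizes", {
  v <- assemble_features(numeric(0), 170, 70, 30)
  expect_equal(v, c(170, 70, 30))
  v2 <- assemble_features(c(1, 2, 3, 4), 170, 70, 30)
  expect_length(v2, 7L)
  expect_equal(v2[5:7], c(170, 70, 30))
  expect_error(assemble_features(c(1, NA), 170, 70, 30), "dimension 2")
  set.seed(1)
  Xs <- matrix(rnorm(40), 10, 4)
  Xa <- assemble_features(Xs, runif(10, 150, 190), runif(10, 50, 100),
                          runif(10, 20, 60))
  st <- feature_stats(Xa)
  Z <- assemble_features(Xs, Xa[, 5], Xa[, 6], Xa[, 7], stats = st)
  expect_equal(unname(colMeans(Z)), rep(0, 7L), tolerance = 1e-12)
  expect_equal(unname(apply(Z, 2, sd)), rep(1, 7L), tolerance = 1e-12)
})

test_that("OLS recovers an exact line and linear systems", {
  m <- fit_ols(matrix(c(0, 1, 2), 3), c(1, 3, 5))
  expect_equal(m$intercept, 1, tolerance = 1e-10)
  expect_equal(unname(m$coef), 2, tolerance = 1e-10)
  set.seed(2)
  X <- matrix(rnorm(100), 20, 5)
  beta <- rnorm(5)
  y <- 3 + X %*% beta
  m2 <- fit_ols(X, y)
  expect_lt(max(abs(predict(m2, X) - y)), 1e-8)
  # matches lm() on n > p data as an independent implementation
  lmfit <- lm(y ~ X)
  expect_equal(unname(m2$coef), unname(coef(lmfit)[-1L]), tolerance = 1e-8)
  # constant y is a valid constant model
  m3 <- fit_ols(X, rep(4, 20))
  expect_equal(predict(m3, X), rep(4, 20), tolerance = 1e-8)
})

test_that("underdetermined OLS returns the minimum-norm pseudoinverse solution", {
  set.seed(3)
  X <- matrix(rnorm(5 * 12), 5, 12)
  y <- rnorm(5)
  m <- fit_ols(X, y)
  expect_lt(max(abs(predict(m, X) - y)), 1e-8)  # interpolates
  A <- cbind(1, X)
  sv <- svd(A)
  beta_pinv <- sv$v %*% diag(1 / sv$d) %*% t(sv$u) %*% y
  expect_equal(c(m$intercept, m$coef), as.numeric(beta_pinv), tolerance = 1e-8)
  # minimum norm among random interpolating solutions
  ns <- svd(A, nv = 13)$v[, 6:13]  # null space
  for (rep in 1:5) {
    alt <- as.numeric(beta_pinv) + as.numeric(ns %*% rnorm(8))
    expect_gte(sum(alt^2), sum(beta_pinv^2) - 1e-10)
  }
})

test_that("GPR interpolates training data as noise vanishes", {
  set.seed(4)
  X <- matrix(rnorm(30), 10, 3)
  y <- rnorm(10)
  m <- fit_gpr(X, y, noise_alpha = 1e-10)
  expect_lt(max(abs(predict(m, X) - y)), 1e-4)
})

test_that("GPR predictive mean matches the dense-solve oracle", {
  set.seed(5)
  for (rep in 1:10) {
    n <- 20L; p <- 3L
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    Xs <- matrix(rnorm(5L * p), 5L, p)
    s0 <- runif(1, 0.5, 2)
    al <- runif(1, 1e-3, 1e-1)
    m <- fit_gpr(X, y, sigma0_sq = s0, noise_alpha = al)
    K <- (s0 + X %*% t(X) / p)^2
    cc <- solve(K + al * diag(n), y - mean(y))
    oracle <- mean(y) + (s0 + Xs %*% t(X) / p)^2 %*% cc
    expect_equal(predict(m, Xs), as.numeric(oracle), tolerance = 1e-8)
  }
})

test_that("squared dot-product GPR equals ridge in the explicit quadratic feature space", {
  # phi(x) = all degree <= 2 monomials of (sigma0, x / sqrt(p)), scaled so
  # that phi(x) . phi(x') = (sigma0^2 + x.x'/p)^2
  quad_map <- function(X, s0) {
    p <- ncol(X)
    t(apply(X, 1L, function(x) {
      z <- c(sqrt(s0), x / sqrt(p))
      outer(z, z)[upper.tri(diag(length(z)), diag = TRUE)] *
        ifelse(upper.tri(diag(length(z)), diag = TRUE)[
          upper.tri(diag(length(z)), diag = TRUE)] &
            !diag(length(z))[upper.tri(diag(length(z)), diag = TRUE)],
          sqrt(2), 1)
    }))
  }
  set.seed(6)
  for (p in 2:4) {
    n <- 15L
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    s0 <- 1.3
    al <- 0.05
    m <- fit_gpr(X, y, sigma0_sq = s0, noise_alpha = al)
    Phi <- quad_map(X, s0)
    yc <- y - mean(y)
    w <- solve(crossprod(Phi) + al * diag(ncol(Phi)), crossprod(Phi, yc))
    Xs <- matrix(rnorm(4L * p), 4L, p)
    ridge_pred <- mean(y) + quad_map(Xs, s0) %*% w
    expect_equal(predict(m, Xs), as.numeric(ridge_pred), tolerance = 1e-8)
  }
})

test_that("linear-kernel GPR converges to OLS on well-conditioned data", {
  set.seed(7)
  X <- scale(matrix(rnorm(200), 50, 4))
  y <- as.numeric(2 + X %*% c(1, -0.5, 0.3, 2) + rnorm(50, sd = 0.1))
  gpr <- fit_gpr(X, y, sigma0_sq = 1, noise_alpha = 1e-8, degree = 1L)
  ols <- fit_ols(X, y)
  Xs <- matrix(rnorm(40), 10, 4)
  expect_equal(predict(gpr, Xs), predict(ols, Xs), tolerance = 1e-3)
})

test_that("GPR agrees with kernlab's polydot gausspr as an independent implementation", {
  skip_if_not_installed("kernlab")
  set.seed(8)
  n <- 25L
  X <- matrix(rnorm(n * 3L), n, 3L)
  y <- rnorm(n)
  al <- 0.05
  m <- fit_gpr(X, y, sigma0_sq = 1, noise_alpha = al)
  kl <- kernlab::gausspr(X, y, kernel = kernlab::polydot(degree = 2,
                                                         scale = 1 / 3,
                                                         offset = 1),
                         var = al, scaled = FALSE)
  Xs <- matrix(rnorm(15L), 5L, 3L)
  # kernlab does not center targets, so agreement is approximate
  expect_equal(predict(m, Xs), as.numeric(kernlab::predict(kl, Xs)),
               tolerance = 2e-2)
})

test_that("per-sex fitting is sex-local and order-invariant", {
  spec <- synthetic_spec(n_subjects = 60L, subdivision = 1L, seed = 11L)
  pop <- sample_population(spec)
  feats <- as.matrix(pop$truth[, -1L])
  fits <- fit_per_sex(pop$records, feats, "total_fat_mass", method = "GPR")
  expect_named(fits, c("male", "female"))
  # permuting record order leaves each sex's model unchanged
  set.seed(1)
  perm <- sample.int(nrow(pop$records))
  fits2 <- fit_per_sex(pop$records[perm, ], feats[perm, , drop = FALSE],
                       "total_fat_mass", method = "GPR")
  for (s in c("male", "female")) {
    idx <- which(pop$records$sex == s)
    p1 <- predict(fits[[s]], pop$records[idx, ], feats[idx, , drop = FALSE])
    p2 <- predict(fits2[[s]], pop$records[idx, ], feats[idx, , drop = FALSE])
    expect_equal(p1, p2, tolerance = 1e-8)
  }
  only_m <- pop$records[pop$records$sex == "male", ]
  expect_error(fit_per_sex(only_m, feats[pop$records$sex == "male", , drop = FALSE],
                           "total_fat_mass"), "female")
})

test_that("demographics-only baseline is beaten by shape-informed models", {
  spec <- synthetic_spec(n_subjects = 200L, subdivision = 1L, seed = 12L)
  pop <- sample_population(spec)
  test_idx <- 161:200
  train_idx <- 1:160
  feats <- as.matrix(pop$truth[, -1L])  # true morphs: ideal shape features
  target <- "percent_fat"
  tr <- pop$records[train_idx, ]
  base <- baseline_demographics_model(tr, target)
  shaped <- morphocomp:::fit_composition_model(tr, feats[train_idx, ], target, "GPR")
  te <- pop$records[test_idx, ]
  base_rmse <- rmse(predict(base, te, matrix(numeric(0), nrow(te), 0L)),
                    te[[target]])
  shaped_rmse <- rmse(predict(shaped, te, feats[test_idx, ]), te[[target]])
  expect_lt(shaped_rmse, base_rmse)
  # a target that is a pure function of height/weight is nailed by demographics
  tr2 <- tr
  tr2$total_lean_mass <- 0.4 * tr2$weight_kg + 0.1 * tr2$height_cm
  te2 <- te
  te2$total_lean_mass <- 0.4 * te2$weight_kg + 0.1 * te2$height_cm
  base2 <- baseline_demographics_model(tr2, "total_lean_mass")
  pred2 <- predict(base2, te2, matrix(numeric(0), nrow(te2), 0L))
  expect_lt(rmse(pred2, te2$total_lean_mass), 0.5)
})
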
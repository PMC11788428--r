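test_that("encoder produces the contracted feature-map shapes", {
  s <- tiny_ae_setup()
  model <- build_autoencoder(s$hier, s$cfg, s$template)
  lat <- encode(s$template, model)
  expect_equal(dim(lat$levels[[1L]]), c(s$hier$n[1L], 4L))
  expect_equal(dim(lat$levels[[2L]]), c(s$hier$n[2L], 8L))
  expect_equal(dim(lat$bottleneck), c(s$hier$n[3L], 4L))
  expect_length(lat$flat_bottleneck, ae_latent_size(model))
  # extract_features flattens each level row-major
  expect_length(extract_features(model, s$template, 0L), s$hier$n[1L] * 4L)
  expect_length(extract_features(model, s$template, 1L), s$hier$n[2L] * 8L)
  expect_identical(extract_features(model, s$template, "bottleneck"),
                   lat$flat_bottleneck)
  expect_error(extract_features(model, s$template, 7L), "layer must be")
})

test_that("inference is deterministic and sensitive to rigid translation", {
  s <- tiny_ae_setup()
  model <- build_autoencoder(s$hier, s$cfg, s$template)
  f1 <- extract_features(model, s$template, "bottleneck")
  f2 <- extract_features(model, s$template, "bottleneck")
  expect_identical(f1, f2)
  moved <- s$template
  moved$vertices <- moved$vertices + rep(c(10, 0, 0), each = nrow(moved$vertices))
  f3 <- extract_features(model, moved, "bottleneck")
  expect_gt(sqrt(sum((f1 - f3)^2)), 0)  # no built-in translation invariance
  # decode determinism and fixed output for the zero latent
  z <- matrix(0, s$hier$n[3L], 4L)
  expect_identical(decode(z, model), decode(z, model))
  expect_error(decode(matrix(0, 2L, 9L), model), "shape")
  wrong_v <- triangle_mesh(matrix(0, 10L, 3L), matrix(c(0L, 1L, 2L), 1L))
  expect_error(encode(wrong_v, model), "expects 42")
})

test_that("training memorizes a single repeated mesh", {
  s <- tiny_ae_setup()
  spec <- synthetic_spec(n_subjects = 1L, subdivision = 1L, seed = 4L)
  mesh <- sample_population(spec)$meshes[[1L]]
  run <- train_autoencoder(rep(list(mesh), 20L), list(mesh), s$cfg,
                           s$hier, s$template, epochs = 150L)
  expect_lt(min(run$history$eval_mae_mm), 0.01 * bbox_diagonal(mesh))
})

test_that("trained reconstruction beats the mean-mesh baseline on held-out data", {
  s <- tiny_ae_setup()
  spec <- synthetic_spec(n_subjects = 60L, subdivision = 1L, seed = 2L)
  pop <- sample_population(spec)
  train <- pop$meshes[1:45]
  heldout <- pop$meshes[46:60]
  run <- train_autoencoder(train, heldout, s$cfg, s$hier, s$template,
                           epochs = 40L)
  mean_mesh <- Reduce(`+`, lapply(train, `[[`, "vertices")) / length(train)
  baseline <- mean(vapply(heldout, function(m) vertex_mae(m$vertices, mean_mesh),
                          numeric(1)))
  ae_mae <- mean(vapply(heldout, function(m)
    vertex_mae(m, reconstruct(m, run$model)), numeric(1)))
  expect_lt(ae_mae, baseline)
  # history contract: returned model is the best-eval-epoch state
  expect_equal(attr(run$history, "best_epoch"),
               run$history$epoch[which.min(run$history$eval_mae_mm)])
  expect_equal(nrow(run$history), 40L)
})

test_that("training is reproducible under a fixed seed", {
  s <- tiny_ae_setup(seed = 9L)
  spec <- synthetic_spec(n_subjects = 12L, subdivision = 1L, seed = 3L)
  pop <- sample_population(spec)
  run1 <- train_autoencoder(pop$meshes[1:9], pop$meshes[10:12], s$cfg,
                            s$hier, s$template, epochs = 4L)
  run2 <- train_autoencoder(pop$meshes[1:9], pop$meshes[10:12], s$cfg,
                            s$hier, s$template, epochs = 4L)
  expect_identical(run1$history$train_mae_mm, run2$history$train_mae_mm)
  expect_identical(run1$model$params, run2$model$params)
})

test_that("training rejects empty sets and zero finetune epochs is a no-op", {
  s <- tiny_ae_setup()
  spec <- synthetic_spec(n_subjects = 8L, subdivision = 1L)
  pop <- sample_population(spec)
  expect_error(train_autoencoder(list(), pop$meshes[1:2], s$cfg, s$hier,
                                 s$template), "empty")
  expect_error(train_autoencoder(pop$meshes[1:2], list(), s$cfg, s$hier,
                                 s$template), "empty")
  expect_error(pretrain_finetune(list(), pop$meshes[1:4], pop$meshes[5:6],
                                 s$cfg, s$hier, s$template), "empty")
  cfg <- s$cfg
  cfg$pretrain_epochs <- 2L
  cfg$finetune_epochs <- 0L
  out <- pretrain_finetune(pop$meshes[1:6], pop$meshes[7:8], pop$meshes[7:8],
                           cfg, s$hier, s$template)
  expect_null(out$finetune_history)
  expect_equal(nrow(out$pretrain_history), 2L)
})

test_that("whole-network gradients agree with finite differences", {
  # spot-check a handful of parameters through the full forward/backward
  s <- tiny_ae_setup()
  model <- build_autoencoder(s$hier, s$cfg, s$template)
  model$norm$scale <- 100
  set.seed(31)
  X <- matrix(rnorm(42L * 3L), 42L, 3L)
  caches <- morphocomp:::make_run_caches(model, 1L)
  loss_fn <- function(m) {
    st <- morphocomp:::ae_forward(m, X, 1L, caches, keep = FALSE)
    morphocomp:::euclid_loss(st$Yhat, X * 0)$loss
  }
  st <- morphocomp:::ae_forward(model, X, 1L, caches, keep = TRUE)
  lo <- morphocomp:::euclid_loss(st$Yhat, X * 0)
  grads <- morphocomp:::ae_backward(model, st, lo$dY, 1L, caches)
  eps <- 1e-6
  checks <- list(list("enc", 1L, "basis", 2L, 3L), list("enc", 2L, "alpha", 5L, NULL),
                 list("dec", 1L, "bias", 1L, NULL), list("dec", 3L, "basis", 1L, 3L),
                 list("enc", 3L, "alpha", 2L, NULL), list("dec", 2L, "bias", 2L, NULL))
  for (ch in checks) {
    side <- ch[[1L]]; layer <- ch[[2L]]; what <- ch[[3L]]
    i1 <- ch[[4L]]; i2 <- ch[[5L]]
    get_set <- function(m, val = NULL) {
      p <- m$params[[side]][[layer]]
      if (what == "basis") {
        if (is.null(val)) return(p$basis[[1L]][i1, i2])
        p$basis[[1L]][i1, i2] <- val
      } else if (what == "alpha") {
        if (is.null(val)) return(p$alpha[i1, 1L])
        p$alpha[i1, 1L] <- val
      } else {
        if (is.null(val)) return(p$bias[i1])
        p$bias[i1] <- val
      }
      m$params[[side]][[layer]] <- p
      m
    }
    base <- get_set(model)
    num <- (loss_fn(get_set(model, base + eps)) -
              loss_fn(get_set(model, base - eps))) / (2 * eps)
    g <- grads[[side]][[layer]]
    ana <- if (what == "basis") g$dB[[1L]][i1, i2]
    else if (what == "alpha") g$dalpha[i1, 1L]
    else g$dbias[i1]
    expect_equal(ana, num, tolerance = 1e-4)
  }
})
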
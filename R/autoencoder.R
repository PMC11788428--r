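# Graph-convolutional mesh autoencoder (3DAE).
#
# Encoder: one full-resolution basis-decomposed convolution on the template
# graph, then one pooled convolution per hierarchy level; the deepest map is
# the bottleneck (n_L nodes x f channels). Decoder mirrors the encoder with
# untied weights: unpool (membership-normalized scatter) followed by a
# within-level convolution, ending in a linear convolution back to 3
# coordinate channels. Hidden convolutions use tanh; the bottleneck and the
# output layer are linear. Input meshes are centered on the training-set
# mean mesh and scaled by one global scalar so coordinates are O(1); the
# training loss is the mean per-vertex Euclidean distance on normalized
# coordinates, reported in millimetres after un-scaling.

#' Autoencoder configuration
#'
#' @param channels per-level channel counts for the encoder levels above the
#'   bottleneck (default `c(16, 32, 64, 128)`; the hierarchy must have
#'   `length(channels)` pooled levels).
#' @param bottleneck_channels channel depth `f` of the deepest layer; the
#'   flattened latent size is `bottleneck nodes x f`.
#' @param radius,stride hierarchy/kernel geometry (default 2 and 2).
#' @param basis_size number `M` of shared basis matrices per layer
#'   (default 37).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param batch_size minibatch size (default 16).
#' @param pretrain_epochs,finetune_epochs stage lengths for
#'   [pretrain_finetune()] (defaults 200 and 400).
#' @param seed integer seed controlling initialization and batch shuffling.
#' @return an `ae_config` list.
#' @export
ae_config <- function(channels = c(16L, 32L, 64L, 128L),
                      bottleneck_channels = 8L,
                      radius = 2L, stride = 2L,
                      basis_size = 37L,
                      learning_rate = 1e-4,
                      batch_size = 16L,
                      pretrain_epochs = 200L,
                      finetune_epochs = 400L,
                      seed = 1L) {
  cfg <- list(channels = as.integer(channels),
              bottleneck_channels = as.integer(bottleneck_channels),
              radius = as.integer(radius), stride = as.integer(stride),
              basis_size = as.integer(basis_size),
              learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              pretrain_epochs = as.integer(pretrain_epochs),
              finetune_epochs = as.integer(finetune_epochs),
              seed = as.integer(seed))
  if (any(c(cfg$channels, cfg$bottleneck_channels, cfg$basis_size,
            cfg$batch_size) < 1L)) {
    stop("all channel, basis and batch counts must be positive")
  }
  structure(cfg, class = "ae_config")
}

# One layer's static structure: neighbourhood slot vectors at its level.
ae_layer_plan <- function(neighborhoods, n_in, n_out) {
  fl <- flatten_neighborhoods(neighborhoods)
  list(slot_src = fl$slot_src, slot_out = fl$slot_out,
       n_slots = fl$n_slots, n_in = n_in, n_out = n_out)
}

# Full architecture plan from a hierarchy: per-layer neighbourhood structure
# for encoder and decoder, plus unpool maps.
ae_architecture <- function(hierarchy, config) {
  L <- hierarchy$n_levels
  if (length(config$channels) != L) {
    stop(sprintf("config has %d channel entries but hierarchy has %d levels",
                 length(config$channels), L))
  }
  chans <- c(config$channels, config$bottleneck_channels)  # levels 0..L
  ring_nbhd <- function(level) {
    nb <- hierarchy$level_adj[[level + 1L]]
    lapply(seq_along(nb), function(v) ring_set(nb, v, hierarchy$radius))
  }
  enc <- vector("list", L + 1L)
  # layer 1: full-resolution conv on the level-0 graph, 3 -> chans[1]
  enc[[1L]] <- c(ae_layer_plan(ring_nbhd(0L), hierarchy$n[1L], hierarchy$n[1L]),
                 list(I = 3L, O = chans[1L], level = 0L, act = "tanh"))
  for (l in seq_len(L)) {
    act <- if (l == L) "linear" else "tanh"  # bottleneck is linear
    enc[[l + 1L]] <- c(ae_layer_plan(hierarchy$neighborhoods[[l]],
                                     hierarchy$n[l], hierarchy$n[l + 1L]),
                       list(I = chans[l], O = chans[l + 1L], level = l, act = act))
  }
  dec <- vector("list", L + 1L)
  for (i in seq_len(L)) {
    l <- L - i + 1L  # unpool level l -> l-1, conv at level l-1
    dec[[i]] <- c(ae_layer_plan(ring_nbhd(l - 1L),
                                hierarchy$n[l], hierarchy$n[l]),
                  list(I = chans[l + 1L], O = chans[l], level = l - 1L,
                       act = "tanh", unpool_level = l))
  }
  # final linear conv at level 0: chans[1] -> 3
  dec[[L + 1L]] <- c(ae_layer_plan(ring_nbhd(0L), hierarchy$n[1L], hierarchy$n[1L]),
                     list(I = chans[1L], O = 3L, level = 0L, act = "linear",
                          unpool_level = NA_integer_))
  # unpool structure per level: member slot -> coarse node, with 1/count norm
  unpool <- vector("list", L)
  for (l in seq_len(L)) {
    up <- hierarchy$upmap[[l]]
    counts <- lengths(up)
    if (any(counts == 0L)) stop("upmap leaves a vertex uncovered")
    unpool[[l]] <- list(fine = rep.int(seq_along(up), counts),
                        coarse = unlist(up, use.names = FALSE),
                        weight = rep.int(1 / counts, counts),
                        n_fine = length(up), n_coarse = hierarchy$n[l + 1L])
  }
  list(enc = enc, dec = dec, unpool = unpool, chans = chans, L = L)
}

init_kernel_params <- function(plan, M) {
  I <- plan$I; O <- plan$O
  a <- sqrt(6 / (I + O)) / sqrt(M)
  basis <- lapply(seq_len(M), function(k) {
    matrix(stats::runif(I * O, -a, a), I, O)
  })
  nb_sizes <- tabulate(plan$slot_out, nbins = plan$n_out)
  alpha <- matrix(rep.int(1 / nb_sizes[plan$slot_out], M),
                  plan$n_slots, M)
  list(basis = basis, alpha = alpha, bias = numeric(O))
}

#' Build an untrained mesh autoencoder
#'
#' @param hierarchy a `graph_hierarchy` built on the template.
#' @param config an [ae_config()]; `length(config$channels)` must equal the
#'   hierarchy's level count.
#' @param template the template [triangle_mesh] (topology reference).
#' @return object of class `mesh_autoencoder` (untrained: normalization is
#'   fitted during training).
#' @export
build_autoencoder <- function(hierarchy, config, template) {
  stopifnot_mesh(template)
  if (nrow(template$vertices) != hierarchy$n[1L]) {
    stop(sprintf("template has %d vertices but hierarchy level 0 has %d",
                 nrow(template$vertices), hierarchy$n[1L]))
  }
  arch <- ae_architecture(hierarchy, config)
  set.seed(config$seed)
  M <- config$basis_size
  params <- list(enc = lapply(arch$enc, init_kernel_params, M = M),
                 dec = lapply(arch$dec, init_kernel_params, M = M))
  structure(list(config = config, hierarchy = hierarchy, arch = arch,
                 params = params, template_v = hierarchy$n[1L],
                 faces = template$faces,
                 norm = list(mean_mesh = matrix(0, hierarchy$n[1L], 3L),
                             scale = 1),
                 trained = FALSE),
            class = "mesh_autoencoder")
}

#' @export
print.mesh_autoencoder <- function(x, ...) {
  np <- ae_n_params(x)
  cat(sprintf("<mesh_autoencoder: V=%d, levels %s, bottleneck %d x %d = %d, M=%d, %s; %d parameters>\n",
              x$template_v, paste(x$hierarchy$n, collapse = "->"),
              x$hierarchy$n[x$arch$L + 1L], x$config$bottleneck_channels,
              ae_latent_size(x), x$config$basis_size,
              if (x$trained) "trained" else "untrained", np))
  invisible(x)
}

#' Flattened bottleneck size of an autoencoder
#' @param model a `mesh_autoencoder`.
#' @return integer: bottleneck nodes x bottleneck channels.
#' @export
ae_latent_size <- function(model) {
  model$hierarchy$n[model$arch$L + 1L] * model$config$bottleneck_channels
}

ae_n_params <- function(model) {
  count1 <- function(p) sum(lengths(lapply(p$basis, as.numeric))) +
    length(p$alpha) + length(p$bias)
  sum(vapply(model$params$enc, count1, numeric(1))) +
    sum(vapply(model$params$dec, count1, numeric(1)))
}

# ---- batched forward / backward -------------------------------------------

# Replicate a layer plan for batch size B: slots address stacked blocks.
batch_plan <- function(plan, B) {
  if (B == 1L) {
    return(list(slot_src = plan$slot_src, slot_out = plan$slot_out,
                slot_id = seq_len(plan$n_slots),
                n_in = plan$n_in, n_out = plan$n_out))
  }
  off_in <- rep(seq(0L, by = plan$n_in, length.out = B), each = plan$n_slots)
  off_out <- rep(seq(0L, by = plan$n_out, length.out = B), each = plan$n_slots)
  list(slot_src = rep.int(plan$slot_src, B) + off_in,
       slot_out = rep.int(plan$slot_out, B) + off_out,
       slot_id = rep.int(seq_len(plan$n_slots), B),
       n_in = plan$n_in * B, n_out = plan$n_out * B)
}

batch_unpool_plan <- function(up, B) {
  if (B == 1L) return(up)
  ns <- length(up$fine)
  off_f <- rep(seq(0L, by = up$n_fine, length.out = B), each = ns)
  off_c <- rep(seq(0L, by = up$n_coarse, length.out = B), each = ns)
  list(fine = rep.int(up$fine, B) + off_f,
       coarse = rep.int(up$coarse, B) + off_c,
       weight = rep.int(up$weight, B),
       n_fine = up$n_fine * B, n_coarse = up$n_coarse * B)
}

apply_act <- function(x, act) if (act == "tanh") tanh(x) else x
act_grad <- function(y, act) if (act == "tanh") 1 - y * y else 1

# Training hot path: each layer's scatter/gather structure is frozen into
# sparse-matrix patterns once per (layer, batch size); per step only the @x
# slot is refilled from the current alpha, so every aggregation is a sparse
# BLAS product rather than an R-level rowsum.
conv_layer_forward <- function(X, plan, params, B, cache, keep = TRUE) {
  M <- length(params$basis)
  I <- plan$I
  O <- plan$O
  W <- cache$W_tpl
  Y <- matrix(rep(params$bias, each = cache$n_out_b), cache$n_out_b, O)
  S <- if (keep) vector("list", M) else NULL
  for (k in seq_len(M)) {
    W@x <- params$alpha[cache$slot_id_b, k][cache$perm_f]
    agg <- as.matrix(W %*% X)
    Y <- Y + agg %*% params$basis[[k]]
    if (keep) S[[k]] <- agg
  }
  A <- apply_act(Y, plan$act)
  fwd <- if (keep) list(S = S, Xs = X[cache$slot_src_b, , drop = FALSE]) else NULL
  list(A = A, fwd = fwd)
}

conv_layer_backward <- function(dZ, plan, params, cache, fwd) {
  M <- length(params$basis)
  I <- plan$I
  O <- plan$O
  # stacked transposed bases: one dense matmul gives every dAgg_k
  Bt_stack <- do.call(cbind, lapply(params$basis, t))       # O x (I*M)
  dAgg_all <- dZ %*% Bt_stack                               # n_out_b x (I*M)
  G <- dAgg_all[cache$slot_out_b, , drop = FALSE]           # one big gather
  E <- G * fwd$Xs[, rep.int(seq_len(I), M), drop = FALSE]
  dalpha <- as.matrix(cache$P_id %*% (E %*% cache$KR))      # n_slots x M
  dB <- vector("list", M)
  dX <- NULL
  Wt <- cache$Wt_tpl
  for (k in seq_len(M)) {
    dB[[k]] <- crossprod(fwd$S[[k]], dZ)
    Wt@x <- params$alpha[cache$slot_id_b, k][cache$perm_b]
    dAk <- dAgg_all[, (k - 1L) * I + seq_len(I), drop = FALSE]
    dX <- if (is.null(dX)) as.matrix(Wt %*% dAk) else dX + as.matrix(Wt %*% dAk)
  }
  list(dB = dB, dalpha = dalpha, dbias = colSums(dZ), dX = dX)
}

make_run_caches <- function(model, B) {
  mk <- function(plan) {
    bp <- batch_plan(plan, B)
    ns <- length(bp$slot_src)
    Wp <- Matrix::sparseMatrix(i = bp$slot_out, j = bp$slot_src,
                               x = seq_len(ns), dims = c(bp$n_out, bp$n_in))
    Wtp <- Matrix::sparseMatrix(i = bp$slot_src, j = bp$slot_out,
                                x = seq_len(ns), dims = c(bp$n_in, bp$n_out))
    P_id <- Matrix::sparseMatrix(i = bp$slot_id, j = seq_len(ns), x = 1,
                                 dims = c(plan$n_slots, ns))
    I <- plan$I
    M <- model$config$basis_size
    KR <- matrix(0, I * M, M)
    for (k in seq_len(M)) KR[(k - 1L) * I + seq_len(I), k] <- 1
    list(W_tpl = Wp, perm_f = as.integer(Wp@x),
         Wt_tpl = Wtp, perm_b = as.integer(Wtp@x),
         P_id = P_id, KR = KR,
         slot_src_b = bp$slot_src, slot_out_b = bp$slot_out,
         slot_id_b = bp$slot_id,
         n_in_b = bp$n_in, n_out_b = bp$n_out)
  }
  mku <- function(up) {
    bu <- batch_unpool_plan(up, B)
    # membership-normalized unpool as a single sparse map and its transpose
    bu$U <- Matrix::sparseMatrix(i = bu$fine, j = bu$coarse, x = bu$weight,
                                 dims = c(bu$n_fine, bu$n_coarse))
    bu$Ut <- Matrix::t(bu$U)
    bu
  }
  list(enc = lapply(model$arch$enc, mk),
       dec = lapply(model$arch$dec, mk),
       unpool = lapply(model$arch$unpool, mku),
       B = B)
}

# Forward through the whole network on a stacked batch X ((B*V) x 3,
# normalized coordinates). Returns activations needed for backprop.
ae_forward <- function(model, X, B, caches, keep = TRUE) {
  arch <- model$arch
  L <- arch$L
  enc_acts <- vector("list", L + 1L)
  enc_fwd <- vector("list", L + 1L)
  A <- X
  for (i in seq_along(arch$enc)) {
    out <- conv_layer_forward(A, arch$enc[[i]], model$params$enc[[i]], B,
                              caches$enc[[i]], keep = keep)
    A <- out$A
    enc_acts[[i]] <- A
    if (keep) enc_fwd[[i]] <- out$fwd
  }
  bottleneck <- A
  dec_acts <- vector("list", L + 1L)
  dec_fwd <- vector("list", L + 1L)
  dec_in <- vector("list", L + 1L)
  for (i in seq_along(arch$dec)) {
    plan <- arch$dec[[i]]
    if (!is.na(plan$unpool_level)) {
      A <- as.matrix(caches$unpool[[plan$unpool_level]]$U %*% A)
    }
    if (keep) dec_in[[i]] <- A
    out <- conv_layer_forward(A, plan, model$params$dec[[i]], B,
                              caches$dec[[i]], keep = keep)
    A <- out$A
    dec_acts[[i]] <- A
    if (keep) dec_fwd[[i]] <- out$fwd
  }
  list(Yhat = A, bottleneck = bottleneck, enc_acts = enc_acts,
       enc_fwd = enc_fwd, dec_acts = dec_acts, dec_fwd = dec_fwd,
       dec_in = dec_in, X = X)
}

# Backward pass: gradient of the mean per-vertex Euclidean loss wrt all
# parameters. dY0 is dLoss/dYhat.
ae_backward <- function(model, state, dY0, B, caches) {
  arch <- model$arch
  L <- arch$L
  grads <- list(enc = vector("list", L + 1L), dec = vector("list", L + 1L))
  dA <- dY0
  for (i in rev(seq_along(arch$dec))) {
    plan <- arch$dec[[i]]
    dZ <- dA * act_grad(state$dec_acts[[i]], plan$act)
    bw <- conv_layer_backward(dZ, plan, model$params$dec[[i]],
                              caches$dec[[i]], state$dec_fwd[[i]])
    grads$dec[[i]] <- bw
    dA <- bw$dX
    if (!is.na(plan$unpool_level)) {
      # unpool transpose: scatter fine grads back to coarse nodes
      dA <- as.matrix(caches$unpool[[plan$unpool_level]]$Ut %*% dA)
    }
  }
  for (i in rev(seq_along(arch$enc))) {
    plan <- arch$enc[[i]]
    dZ <- dA * act_grad(state$enc_acts[[i]], plan$act)
    bw <- conv_layer_backward(dZ, plan, model$params$enc[[i]],
                              caches$enc[[i]], state$enc_fwd[[i]])
    grads$enc[[i]] <- bw
    dA <- bw$dX
  }
  grads
}

# Mean per-vertex Euclidean loss and its gradient on stacked batches.
euclid_loss <- function(Yhat, Target) {
  D <- Yhat - Target
  r <- sqrt(rowSums(D * D))
  n <- nrow(D)
  safe <- pmax(r, 1e-12)
  list(loss = mean(r), dY = D / safe / n)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(p) {
    list(basis = lapply(p$basis, function(b) b * 0),
         alpha = p$alpha * 0, bias = p$bias * 0)
  }
  list(m = list(enc = lapply(params$enc, zero_like),
                dec = lapply(params$dec, zero_like)),
       v = list(enc = lapply(params$enc, zero_like),
                dec = lapply(params$dec, zero_like)),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  for (side in c("enc", "dec")) {
    for (i in seq_along(params[[side]])) {
      g <- if (side == "enc") grads$enc[[i]] else grads$dec[[i]]
      pr <- params[[side]][[i]]
      mo <- opt$m[[side]][[i]]; vo <- opt$v[[side]][[i]]
      for (k in seq_along(pr$basis)) {
        u <- upd(pr$basis[[k]], g$dB[[k]], mo$basis[[k]], vo$basis[[k]])
        pr$basis[[k]] <- u$p; mo$basis[[k]] <- u$m; vo$basis[[k]] <- u$v
      }
      u <- upd(pr$alpha, g$dalpha, mo$alpha, vo$alpha)
      pr$alpha <- u$p; mo$alpha <- u$m; vo$alpha <- u$v
      u <- upd(pr$bias, g$dbias, mo$bias, vo$bias)
      pr$bias <- u$p; mo$bias <- u$m; vo$bias <- u$v
      params[[side]][[i]] <- pr
      opt$m[[side]][[i]] <- mo; opt$v[[side]][[i]] <- vo
    }
  }
  list(params = params, opt = opt)
}

# ---- training --------------------------------------------------------------

meshes_to_array <- function(meshes, V) {
  mats <- lapply(meshes, function(m) {
    vm <- if (is_triangle_mesh(m)) m$vertices else as.matrix(m)
    if (nrow(vm) != V) stop(sprintf("mesh has %d vertices; template expects %d",
                                    nrow(vm), V))
    vm
  })
  mats
}

ae_eval_loss <- function(model, mats, caches_by_B, max_B) {
  n <- length(mats)
  total <- 0
  i <- 1L
  while (i <= n) {
    idx <- i:min(i + max_B - 1L, n)
    B <- length(idx)
    key <- as.character(B)
    if (is.null(caches_by_B[[key]])) caches_by_B[[key]] <- make_run_caches(model, B)
    X <- normalize_stack(model, mats[idx])
    st <- ae_forward(model, X, B, caches_by_B[[key]], keep = FALSE)
    D <- st$Yhat - X
    total <- total + sum(sqrt(rowSums(D * D)))
    i <- i + B
  }
  (total / (n * model$template_v)) * model$norm$scale  # mm
}

normalize_stack <- function(model, mats) {
  B <- length(mats)
  X <- do.call(rbind, mats)
  mean_rep <- model$norm$mean_mesh[rep(seq_len(model$template_v), B), ]
  (X - mean_rep) / model$norm$scale
}

denormalize <- function(model, Y) {
  Y * model$norm$scale + model$norm$mean_mesh
}

#' Train a mesh autoencoder
#'
#' Minimizes the mean per-vertex Euclidean reconstruction error with Adam
#' mini-batch gradient descent. After every epoch the evaluation set is
#' reconstructed and its loss recorded; the returned model carries the
#' parameters from the epoch with minimum evaluation loss.
#'
#' @param train,eval lists of [triangle_mesh] (or `V x 3` matrices) in the
#'   template topology; disjoint sets.
#' @param config an [ae_config()].
#' @param hierarchy a `graph_hierarchy` for the template.
#' @param template the template [triangle_mesh].
#' @param init optional `mesh_autoencoder` whose parameters (and
#'   normalization) seed training, e.g. a pretrained model.
#' @param epochs number of epochs (defaults to `config$finetune_epochs`).
#' @param verbose print per-epoch `epoch,train_mae_mm,eval_mae_mm` lines.
#' @return list with `model` (a trained `mesh_autoencoder`) and `history`
#'   (tibble: epoch, train_mae_mm, eval_mae_mm, best flag).
#' @export
train_autoencoder <- function(train, eval, config, hierarchy, template,
                              init = NULL, epochs = NULL, verbose = FALSE) {
  if (length(train) == 0L) stop("training set is empty")
  if (length(eval) == 0L) stop("evaluation set is empty")
  if (is.null(epochs)) epochs <- config$finetune_epochs
  epochs <- as.integer(epochs)
  model <- if (is.null(init)) build_autoencoder(hierarchy, config, template) else init
  V <- model$template_v
  train_mats <- meshes_to_array(train, V)
  eval_mats <- meshes_to_array(eval, V)
  if (is.null(init)) {
    # fit normalization on the training set
    mean_mesh <- Reduce(`+`, train_mats) / length(train_mats)
    centered_sd <- sqrt(mean(vapply(train_mats,
                                    function(m) mean((m - mean_mesh)^2),
                                    numeric(1))))
    model$norm <- list(mean_mesh = mean_mesh,
                       scale = if (centered_sd > 0) centered_sd else 1)
  }
  set.seed(config$seed + 1L)
  n <- length(train_mats)
  Bmax <- min(config$batch_size, n)
  caches_by_B <- new.env(parent = emptyenv())
  opt <- adam_init(model$params)
  history <- tibble::tibble(epoch = integer(0), train_mae_mm = numeric(0),
                            eval_mae_mm = numeric(0))
  best_loss <- Inf
  best_params <- model$params
  best_epoch <- 0L
  if (epochs > 0L) {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      i <- 1L
      while (i <= n) {
        idx <- ord[i:min(i + Bmax - 1L, n)]
        B <- length(idx)
        key <- as.character(B)
        if (is.null(caches_by_B[[key]])) caches_by_B[[key]] <- make_run_caches(model, B)
        caches <- caches_by_B[[key]]
        X <- normalize_stack(model, train_mats[idx])
        st <- ae_forward(model, X, B, caches, keep = TRUE)
        lo <- euclid_loss(st$Yhat, X)
        if (!is.finite(lo$loss)) {
          stop(sprintf("NaN/Inf loss at epoch %d; lower the learning rate", ep))
        }
        grads <- ae_backward(model, st, lo$dY, B, caches)
        stepped <- adam_step(model$params, grads, opt, config$learning_rate)
        model$params <- stepped$params
        opt <- stepped$opt
        ep_loss <- ep_loss + lo$loss * B
        i <- i + B
      }
      train_mae <- (ep_loss / n) * model$norm$scale
      eval_mae <- ae_eval_loss(model, eval_mats, caches_by_B, Bmax)
      history <- tibble::add_row(history, epoch = ep, train_mae_mm = train_mae,
                                 eval_mae_mm = eval_mae)
      if (eval_mae < best_loss) {
        best_loss <- eval_mae
        best_params <- model$params
        best_epoch <- ep
      }
      if (verbose) cat(sprintf("%d,%.6f,%.6f\n", ep, train_mae, eval_mae))
    }
    model$params <- best_params
  }
  model$trained <- TRUE
  history$best <- history$epoch == best_epoch
  attr(history, "best_epoch") <- best_epoch
  class(history) <- c("ae_history", class(history))
  list(model = model, history = history)
}

#' Pretrain on one corpus, then finetune on another
#'
#' Stage 1 trains from random initialization on the pretraining set, holding
#' out 20% of it (seeded split) as the stage's own evaluation set. Stage 2
#' resumes from the stage-1 parameters on the finetuning set, with model
#' selection on `eval_set`.
#'
#' @param pretrain_set,finetune_set,eval_set disjoint mesh lists.
#' @param config an [ae_config()]; stage lengths come from
#'   `pretrain_epochs` / `finetune_epochs`.
#' @inheritParams train_autoencoder
#' @return list: `model`, `pretrain_history`, `finetune_history`.
#' @export
pretrain_finetune <- function(pretrain_set, finetune_set, eval_set,
                              config, hierarchy, template, verbose = FALSE) {
  if (length(pretrain_set) == 0L) stop("pretraining set is empty")
  set.seed(config$seed + 2L)
  n <- length(pretrain_set)
  n_eval <- max(1L, floor(0.2 * n))
  eval_idx <- sample.int(n, n_eval)
  s1 <- train_autoencoder(pretrain_set[-eval_idx], pretrain_set[eval_idx],
                          config, hierarchy, template,
                          epochs = config$pretrain_epochs, verbose = verbose)
  if (config$finetune_epochs == 0L) {
    return(list(model = s1$model, pretrain_history = s1$history,
                finetune_history = NULL))
  }
  s2 <- train_autoencoder(finetune_set, eval_set, config, hierarchy, template,
                          init = s1$model, epochs = config$finetune_epochs,
                          verbose = verbose)
  list(model = s2$model, pretrain_history = s1$history,
       finetune_history = s2$history)
}

# ---- inference -------------------------------------------------------------

#' Encode a mesh into per-level latent features
#'
#' @param mesh a [triangle_mesh] (or `V x 3` matrix) in the model's template
#'   topology.
#' @param model a trained `mesh_autoencoder`.
#' @return object of class `latent_features`: list `levels` (per-level
#'   `n_l x c_l` activation matrices, level 0 first), `bottleneck`
#'   (`n_L x f` matrix), `flat_bottleneck` (row-major flattened vector).
#' @export
encode <- function(mesh, model) {
  vm <- if (is_triangle_mesh(mesh)) mesh$vertices else as.matrix(mesh)
  if (nrow(vm) != model$template_v) {
    stop(sprintf("mesh has %d vertices; model expects %d",
                 nrow(vm), model$template_v))
  }
  caches <- make_run_caches(model, 1L)
  X <- (vm - model$norm$mean_mesh) / model$norm$scale
  arch <- model$arch
  A <- X
  levels <- vector("list", arch$L + 1L)
  for (i in seq_along(arch$enc)) {
    out <- conv_layer_forward(A, arch$enc[[i]], model$params$enc[[i]], 1L,
                              caches$enc[[i]], keep = FALSE)
    A <- out$A
    levels[[i]] <- A
  }
  structure(list(levels = levels[seq_len(arch$L)], bottleneck = A,
                 flat_bottleneck = as.numeric(t(A))),
            class = "latent_features")
}

#' @export
print.latent_features <- function(x, ...) {
  shp <- vapply(x$levels, function(m) sprintf("%dx%d", nrow(m), ncol(m)), "")
  cat(sprintf("<latent_features: levels %s; bottleneck %dx%d>\n",
              paste(shp, collapse = ", "), nrow(x$bottleneck), ncol(x$bottleneck)))
  invisible(x)
}

#' Decode a bottleneck array back to vertex coordinates
#'
#' @param latent `n_L x f` bottleneck matrix (or its row-major flattening).
#' @param model a trained `mesh_autoencoder`.
#' @return `V x 3` vertex coordinate matrix in millimetres.
#' @export
decode <- function(latent, model) {
  nL <- model$hierarchy$n[model$arch$L + 1L]
  f <- model$config$bottleneck_channels
  if (is.null(dim(latent))) {
    if (length(latent) != nL * f) {
      stop(sprintf("latent length %d does not match bottleneck %d x %d",
                   length(latent), nL, f))
    }
    latent <- matrix(latent, nL, f, byrow = TRUE)
  }
  if (nrow(latent) != nL || ncol(latent) != f) {
    stop(sprintf("latent shape %dx%d does not match bottleneck %dx%d",
                 nrow(latent), ncol(latent), nL, f))
  }
  caches <- make_run_caches(model, 1L)
  arch <- model$arch
  A <- latent
  for (i in seq_along(arch$dec)) {
    plan <- arch$dec[[i]]
    if (!is.na(plan$unpool_level)) {
      A <- as.matrix(caches$unpool[[plan$unpool_level]]$U %*% A)
    }
    out <- conv_layer_forward(A, plan, model$params$dec[[i]], 1L,
                              caches$dec[[i]], keep = FALSE)
    A <- out$A
  }
  denormalize(model, A)
}

#' Reconstruct a mesh through the autoencoder
#' @param mesh input [triangle_mesh].
#' @param model trained `mesh_autoencoder`.
#' @return a [triangle_mesh] of the reconstruction.
#' @export
reconstruct <- function(mesh, model) {
  lat <- encode(mesh, model)
  triangle_mesh(decode(lat$bottleneck, model), model$faces,
                name = paste0(if (is_triangle_mesh(mesh)) mesh$name else "mesh",
                              "_recon"))
}

#' Extract a flat feature vector from one layer of the encoder
#'
#' @param model trained `mesh_autoencoder`.
#' @param mesh input mesh.
#' @param layer integer encoder level (0-based: level 0 is the
#'   full-resolution feature map) or `"bottleneck"`.
#' @return numeric vector: row-major flattening of the chosen `n_l x c_l`
#'   activation map.
#' @export
extract_features <- function(model, mesh, layer = "bottleneck") {
  lat <- encode(mesh, model)
  L <- model$arch$L
  if (identical(layer, "bottleneck")) return(lat$flat_bottleneck)
  layer <- suppressWarnings(as.integer(layer))
  if (is.na(layer) || layer < 0L || layer > L - 1L) {
    stop(sprintf("layer must be 0..%d or \"bottleneck\"", L - 1L))
  }
  as.numeric(t(lat$levels[[layer + 1L]]))
}

# ---- broom-style methods ---------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of an autoencoder run
#' @param x an `ae_history` tibble from [train_autoencoder()].
#' @param ... unused.
#' @return a long tibble: epoch, set (train/eval), mae_mm.
#' @method tidy ae_history
#' @export
tidy.ae_history <- function(x, ...) {
  tibble::tibble(epoch = rep(x$epoch, 2L),
                 set = rep(c("train", "eval"), each = nrow(x)),
                 mae_mm = c(x$train_mae_mm, x$eval_mae_mm))
}

#' One-row summary of a training run
#' @param x an `ae_history`.
#' @param ... unused.
#' @return tibble: epochs, best_epoch, best_eval_mae_mm, final_train_mae_mm.
#' @method glance ae_history
#' @export
glance.ae_history <- function(x, ...) {
  be <- attr(x, "best_epoch")
  tibble::tibble(epochs = nrow(x),
                 best_epoch = be,
                 best_eval_mae_mm = if (nrow(x)) min(x$eval_mae_mm) else NA_real_,
                 final_train_mae_mm = if (nrow(x)) x$train_mae_mm[nrow(x)] else NA_real_)
}

#' Plot a training history
#' @param object an `ae_history`.
#' @param ... unused.
#' @return a ggplot of train/eval MAE per epoch, best epoch marked.
#' @method autoplot ae_history
#' @export
autoplot.ae_history <- function(object, ...) {
  df <- tidy.ae_history(object)
  be <- attr(object, "best_epoch")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$mae_mm,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = be, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "epoch", y = "reconstruction MAE (mm)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
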
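# Basis-decomposed spatial graph convolution.
#
# On an irregular graph there is no one-to-one correspondence between
# neighbour positions and kernel indices, so the per-neighbour weight matrix
# W_{i,j} is expressed as a learned mixture of M shared basis matrices:
#     W_{i,j} = sum_k alpha_{i,j,k} B_k
# and the output feature at node i is
#     y_i = sum_j W_{i,j}^T x_{i,j} + b.
# Swapping the summation order gives the vectorized form used here:
#     y_i = sum_k B_k^T ( sum_j alpha_{i,j,k} x_{i,j} ) + b
# which reduces to M grouped row-sums plus M small matrix products.

#' Construct a convolution kernel
#'
#' @param basis list of `M` matrices, each `I x O` (input x output channels).
#' @param alpha numeric matrix with one row per (output node, neighbour slot)
#'   pair — rows ordered as the flattened neighbourhood lists — and `M`
#'   columns of mixing coefficients.
#' @param bias length-`O` bias vector.
#' @return object of class `conv_kernel`.
#' @export
conv_kernel <- function(basis, alpha, bias) {
  if (!is.list(basis) || length(basis) < 1L) stop("basis must be a non-empty list")
  dims <- dim(basis[[1L]])
  if (!all(vapply(basis, function(b) identical(dim(b), dims), logical(1L)))) {
    stop("all basis matrices must share the same I x O shape")
  }
  alpha <- as.matrix(alpha)
  if (ncol(alpha) != length(basis)) {
    stop(sprintf("alpha must have M = %d columns, got %d", length(basis), ncol(alpha)))
  }
  if (length(bias) != dims[2L]) {
    stop(sprintf("bias must have length O = %d", dims[2L]))
  }
  structure(list(basis = lapply(basis, function(b) {
    b <- as.matrix(b); storage.mode(b) <- "double"; b
  }), alpha = alpha, bias = as.numeric(bias),
  I = dims[1L], O = dims[2L], M = length(basis)),
  class = "conv_kernel")
}

#' @export
print.conv_kernel <- function(x, ...) {
  cat(sprintf("<conv_kernel: %d -> %d channels, M = %d basis matrices, %d slots>\n",
              x$I, x$O, x$M, nrow(x$alpha)))
  invisible(x)
}

# Flatten neighbourhood lists into slot vectors.
#   slot_src: input-node index per slot; slot_out: output-node index per slot.
flatten_neighborhoods <- function(neighborhoods) {
  list(slot_src = unlist(neighborhoods, use.names = FALSE),
       slot_out = rep.int(seq_along(neighborhoods), lengths(neighborhoods)),
       n_out = length(neighborhoods),
       n_slots = sum(lengths(neighborhoods)))
}

#' Basis-decomposed graph convolution
#'
#' Applies the shared-basis convolution to a feature matrix: output node `i`
#' receives `sum_j W_{i,j}^T x_{i,j} + b` where each `W_{i,j}` is the
#' alpha-weighted mixture of the kernel's `M` basis matrices and `j` runs
#' over that node's neighbourhood slots.
#'
#' @param features `n_in x I` feature matrix.
#' @param neighborhoods list with one integer vector of 1-based input-node
#'   indices per output node.
#' @param kernel a [conv_kernel]; `nrow(alpha)` must equal the total slot
#'   count of `neighborhoods`.
#' @return `n_out x O` output feature matrix.
#' @export
vc_conv <- function(features, neighborhoods, kernel) {
  if (!inherits(kernel, "conv_kernel")) stop("kernel must be a conv_kernel")
  features <- as.matrix(features)
  if (ncol(features) != kernel$I) {
    stop(sprintf("feature channels (%d) do not match kernel I (%d)",
                 ncol(features), kernel$I))
  }
  fl <- flatten_neighborhoods(neighborhoods)
  if (fl$n_slots != nrow(kernel$alpha)) {
    stop(sprintf("kernel alpha has %d rows but neighbourhoods have %d slots",
                 nrow(kernel$alpha), fl$n_slots))
  }
  if (fl$n_slots > 0L && (min(fl$slot_src) < 1L || max(fl$slot_src) > nrow(features))) {
    stop("neighbourhood index out of range of the feature matrix")
  }
  conv_forward(features, fl$slot_src, fl$slot_out, fl$n_out,
               kernel$alpha, kernel$basis, kernel$bias)$Y
}

# Vectorized forward pass shared by vc_conv and the autoencoder.
# X: (n_rows x I); slot_src/slot_out may address batched blocks.
# Returns Y and the per-basis aggregates S (kept for the backward pass).
# `grp` may carry a precomputed grouping factor (training hot path).
conv_forward <- function(X, slot_src, slot_out, n_out, alpha, basis, bias,
                         keep_aggregates = TRUE, grp = NULL) {
  I <- ncol(X)
  O <- length(bias)
  M <- length(basis)
  Xs <- X[slot_src, , drop = FALSE]
  if (is.null(grp)) grp <- factor(slot_out, levels = seq_len(n_out))
  Y <- matrix(rep(bias, each = n_out), n_out, O)
  S <- if (keep_aggregates) vector("list", M) else NULL
  for (k in seq_len(M)) {
    agg <- rowsum(Xs * alpha[, k], grp)  # n_out x I, zero rows for empty groups
    Y <- Y + agg %*% basis[[k]]
    if (keep_aggregates) S[[k]] <- agg
  }
  dimnames(Y) <- NULL
  list(Y = Y, S = S, Xs = Xs)
}

# Backward pass. dY: (n_out x O). Returns gradients for basis, alpha
# (accumulated onto the shared n_alpha rows via slot_id — identity when
# unbatched), bias, and the input features. `alpha_slots` is the per-slot
# (possibly batch-replicated) coefficient matrix used in the forward pass.
conv_backward <- function(dY, slot_src, slot_out, slot_id, n_in, n_alpha,
                          alpha_slots, basis, fwd, grp_id = NULL,
                          grp_src = NULL) {
  I <- ncol(fwd$Xs)
  M <- length(basis)
  dB <- vector("list", M)
  dalpha <- matrix(0, n_alpha, M)
  dXs <- matrix(0, length(slot_src), I)
  Xs <- fwd$Xs
  if (is.null(grp_id)) grp_id <- factor(slot_id, levels = seq_len(n_alpha))
  for (k in seq_len(M)) {
    dB[[k]] <- crossprod(fwd$S[[k]], dY)          # I x O
    dAgg <- dY %*% t(basis[[k]])                  # n_out x I
    dAgg_s <- dAgg[slot_out, , drop = FALSE]      # per-slot
    da <- rowSums(Xs * dAgg_s)
    dalpha[, k] <- rowsum(da, grp_id)
    dXs <- dXs + alpha_slots[, k] * dAgg_s
  }
  if (is.null(grp_src)) grp_src <- factor(slot_src, levels = seq_len(n_in))
  dX <- rowsum(dXs, grp_src)
  dimnames(dX) <- NULL
  list(dB = dB, dalpha = dalpha, dbias = colSums(dY), dX = dX)
}
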
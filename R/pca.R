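# Linear shape-model baseline: PCA on flattened vertex coordinates,
# matched in parameter count (d) to the autoencoder's latent sizes so the
# linear and nonlinear shape spaces can be compared at equal capacity.

#' Fit a PCA shape model
#'
#' SVD of the centered, flattened (`n x 3V`) vertex matrix; the top `d`
#' right-singular directions become the components. Deterministic up to
#' component sign, which is fixed by making each component's
#' largest-magnitude entry positive.
#'
#' @param meshes list of [triangle_mesh] (or `V x 3` matrices) sharing one
#'   topology; at least 2.
#' @param d number of components, `d <= length(meshes) - 1`.
#' @return object of class `pca_shape_model`: `mean` (3V vector, mm),
#'   `components` (`d x 3V`, orthonormal rows), `explained_variance`
#'   (length-`d`, non-increasing), `V` (vertex count), `faces`.
#' @export
fit_pca <- function(meshes, d) {
  if (length(meshes) < 2L) stop("need at least 2 meshes")
  d <- as.integer(d)
  n <- length(meshes)
  if (d > n - 1L) stop(sprintf("d = %d too large; max d is n - 1 = %d", d, n - 1L))
  if (d < 1L) stop("d must be >= 1")
  faces <- if (is_triangle_mesh(meshes[[1L]])) meshes[[1L]]$faces else NULL
  flat <- t(vapply(meshes, function(m) {
    vm <- if (is_triangle_mesh(m)) m$vertices else as.matrix(m)
    as.numeric(t(vm))  # row-major: (x1,y1,z1,x2,...)
  }, numeric(3L * nrow(if (is_triangle_mesh(meshes[[1L]])) meshes[[1L]]$vertices
                       else as.matrix(meshes[[1L]])))))
  mu <- colMeans(flat)
  Xc <- sweep(flat, 2L, mu)
  sv <- svd(Xc, nu = 0L, nv = d)
  comps <- t(sv$v)  # d x 3V
  # sign convention: largest-magnitude entry of each component positive
  for (i in seq_len(d)) {
    j <- which.max(abs(comps[i, ]))
    if (comps[i, j] < 0) comps[i, ] <- -comps[i, ]
  }
  structure(list(mean = mu, components = comps,
                 explained_variance = sv$d[seq_len(d)]^2 / (n - 1L),
                 V = length(mu) / 3L, faces = faces),
            class = "pca_shape_model")
}

#' @export
print.pca_shape_model <- function(x, ...) {
  cat(sprintf("<pca_shape_model: V=%d, d=%d components>\n",
              x$V, nrow(x$components)))
  invisible(x)
}

#' Project a mesh onto the PCA shape space
#' @param model a `pca_shape_model`.
#' @param mesh a [triangle_mesh] or `V x 3` matrix in the model topology.
#' @return length-`d` coefficient vector.
#' @export
pca_encode <- function(model, mesh) {
  vm <- if (is_triangle_mesh(mesh)) mesh$vertices else as.matrix(mesh)
  flat <- as.numeric(t(vm))
  if (length(flat) != length(model$mean)) {
    stop(sprintf("mesh has %d coordinates; model expects %d",
                 length(flat), length(model$mean)))
  }
  as.numeric(model$components %*% (flat - model$mean))
}

#' Reconstruct vertices from PCA coefficients
#' @param model a `pca_shape_model`.
#' @param coeffs length-`d` coefficient vector.
#' @return `V x 3` vertex coordinate matrix (mm).
#' @export
pca_decode <- function(model, coeffs) {
  if (length(coeffs) != nrow(model$components)) {
    stop(sprintf("expected %d coefficients, got %d",
                 nrow(model$components), length(coeffs)))
  }
  flat <- model$mean + as.numeric(crossprod(model$components, coeffs))
  matrix(flat, ncol = 3L, byrow = TRUE)
}

#' PCA reconstruction of a mesh at the model's rank
#' @param model a `pca_shape_model`.
#' @param mesh input mesh.
#' @return `V x 3` reconstructed vertices.
#' @export
pca_reconstruct <- function(model, mesh) {
  pca_decode(model, pca_encode(model, mesh))
}

#' Tidy a PCA shape model
#' @param x a `pca_shape_model`.
#' @param ... unused.
#' @return tibble: component, explained_variance, cumulative fraction.
#' @method tidy pca_shape_model
#' @export
tidy.pca_shape_model <- function(x, ...) {
  ev <- x$explained_variance
  tibble::tibble(component = seq_along(ev),
                 explained_variance = ev,
                 cumulative_fraction = cumsum(ev) / sum(ev))
}

#' One-row summary of a PCA shape model
#' @param x a `pca_shape_model`.
#' @param ... unused.
#' @return tibble: d, n_vertices, total_variance.
#' @method glance pca_shape_model
#' @export
glance.pca_shape_model <- function(x, ...) {
  tibble::tibble(d = nrow(x$components), n_vertices = x$V,
                 total_variance = sum(x$explained_variance))
}
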
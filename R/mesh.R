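#' Triangle mesh with fixed template topology
#'
#' The atomic shape object of the package: a `V x 3` matrix of vertex
#' coordinates in millimetres plus an `F x 3` integer matrix of 0-based
#' vertex indices with fixed winding. All meshes in one dataset must share
#' an identical face array (topology constancy), so that vertex `i` is
#' anatomically comparable across subjects.
#'
#' @param vertices numeric `V x 3` matrix, millimetres.
#' @param faces integer `F x 3` matrix of 0-based vertex indices.
#' @param name free-text identifier.
#' @return an object of class `triangle_mesh` with elements `vertices`,
#'   `faces`, `name`.
#' @export
triangle_mesh <- function(vertices, faces, name = "mesh") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be a V x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an F x 3 matrix")
  v <- nrow(vertices)
  if (nrow(faces) > 0L) {
    if (any(faces < 0L) || any(faces >= v)) {
      bad <- which(faces < 0L | faces >= v)[1L]
      stop(sprintf("face index %d out of range [0, %d)", faces[bad], v))
    }
    if (any(faces[, 1L] == faces[, 2L] | faces[, 1L] == faces[, 3L] |
              faces[, 2L] == faces[, 3L])) {
      stop("a face repeats a vertex index")
    }
  }
  structure(list(vertices = vertices, faces = faces, name = as.character(name)),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh '%s': %d vertices, %d faces>\n",
              x$name, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' @export
format.triangle_mesh <- function(x, ...) {
  sprintf("triangle_mesh(%s, V=%d, F=%d)", x$name, nrow(x$vertices), nrow(x$faces))
}

is_triangle_mesh <- function(x) inherits(x, "triangle_mesh")

stopifnot_mesh <- function(mesh) {
  if (!is_triangle_mesh(mesh)) stop("expected a triangle_mesh")
  invisible(mesh)
}

#' Check that two meshes share the same topology
#'
#' @param a,b triangle meshes.
#' @return `TRUE` invisibly; errors if the face arrays differ.
#' @export
check_same_topology <- function(a, b) {
  stopifnot_mesh(a); stopifnot_mesh(b)
  if (nrow(a$vertices) != nrow(b$vertices)) {
    stop(sprintf("vertex count mismatch: %d vs %d", nrow(a$vertices), nrow(b$vertices)))
  }
  if (nrow(a$faces) != nrow(b$faces) || any(a$faces != b$faces)) {
    stop("face arrays differ: meshes are not in the same template topology")
  }
  invisible(TRUE)
}

#' Bounding-box diagonal of a mesh (millimetres)
#' @param mesh a triangle mesh.
#' @return scalar diagonal length.
#' @export
bbox_diagonal <- function(mesh) {
  stopifnot_mesh(mesh)
  rng <- apply(mesh$vertices, 2L, range)
  sqrt(sum((rng[2L, ] - rng[1L, ])^2))
}

#' Vertex adjacency from shared face edges
#'
#' Undirected, deduplicated neighbour lists: `j` is a neighbour of `i` iff
#' some face contains the edge `{i, j}`. Symmetric by construction, no
#' self-loops.
#'
#' @param mesh a triangle mesh.
#' @return object of class `vertex_adjacency`: a list with `neighbors`
#'   (list of 1-based integer vectors, one per vertex, sorted) and `n_vertices`.
#' @export
vertex_adjacency <- function(mesh) {
  stopifnot_mesh(mesh)
  v <- nrow(mesh$vertices)
  f <- mesh$faces + 1L  # 1-based
  # every face contributes its three undirected edges
  i <- c(f[, 1L], f[, 2L], f[, 2L], f[, 3L], f[, 3L], f[, 1L])
  j <- c(f[, 2L], f[, 1L], f[, 3L], f[, 2L], f[, 1L], f[, 3L])
  nb <- split(j, factor(i, levels = seq_len(v)))
  nb <- lapply(nb, function(x) sort(unique(x)))
  names(nb) <- NULL
  structure(list(neighbors = nb, n_vertices = v), class = "vertex_adjacency")
}

#' @export
print.vertex_adjacency <- function(x, ...) {
  deg <- lengths(x$neighbors)
  cat(sprintf("<vertex_adjacency: %d vertices, degree %d-%d>\n",
              x$n_vertices, min(deg), max(deg)))
  invisible(x)
}

#' k-ring neighbourhood of a vertex
#'
#' All vertices at graph distance at most `k` from `center` (inclusive of the
#' center itself), by breadth-first expansion.
#'
#' @param adj a `vertex_adjacency`.
#' @param center 1-based vertex index.
#' @param k nonnegative ring radius.
#' @return sorted integer vector of 1-based vertex indices.
#' @export
k_ring <- function(adj, center, k) {
  if (!inherits(adj, "vertex_adjacency")) stop("adj must be a vertex_adjacency")
  center <- as.integer(center)
  if (center < 1L || center > adj$n_vertices) {
    stop(sprintf("center %d out of range [1, %d]", center, adj$n_vertices))
  }
  if (k < 0) stop("k must be nonnegative")
  seen <- logical(adj$n_vertices)
  seen[center] <- TRUE
  frontier <- center
  depth <- 0L
  while (depth < k && length(frontier) > 0L) {
    nxt <- unique(unlist(adj$neighbors[frontier], use.names = FALSE))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
    depth <- depth + 1L
  }
  which(seen)
}

# BFS distances from a source, capped at `max_depth` (Inf beyond); internal.
bfs_distances <- function(neighbors, source, max_depth = Inf) {
  n <- length(neighbors)
  dist <- rep(Inf, n)
  dist[source] <- 0
  frontier <- source
  d <- 0
  while (length(frontier) > 0L && d < max_depth) {
    nxt <- unique(unlist(neighbors[frontier], use.names = FALSE))
    nxt <- nxt[!is.finite(dist[nxt])]
    d <- d + 1
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Mean per-vertex Euclidean error between two meshes (millimetres)
#'
#' The geometric mean-absolute-error used throughout: the mean over vertices
#' of the Euclidean distance between paired vertex positions. Requires
#' identical vertex counts (fixed topology).
#'
#' @param a,b triangle meshes (or bare `V x 3` matrices) with equal V.
#' @return scalar MAE in millimetres.
#' @export
vertex_mae <- function(a, b) {
  va <- if (is_triangle_mesh(a)) a$vertices else as.matrix(a)
  vb <- if (is_triangle_mesh(b)) b$vertices else as.matrix(b)
  if (nrow(va) != nrow(vb) || ncol(va) != 3L || ncol(vb) != 3L) {
    stop(sprintf("vertex array shape mismatch: %dx%d vs %dx%d",
                 nrow(va), ncol(va), nrow(vb), ncol(vb)))
  }
  d <- va - vb
  mean(sqrt(rowSums(d * d)))
}
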
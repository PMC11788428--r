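# Multi-level graph pooling structure for the mesh autoencoder.
#
# Level 0 is the template graph. At each level l >= 1, center vertices are
# chosen greedily in ascending index order, accepting a vertex iff its graph
# distance to every previously accepted center is >= stride; each center's
# neighbourhood is the radius-ring around it in the level-(l-1) graph, and
# level-l adjacency connects two centers iff their neighbourhoods overlap.
# Pooling averages a neighbourhood onto its center; unpooling distributes a
# center's value back to its members, normalized per member by how many
# neighbourhoods contain it.

#' Build the graph pooling hierarchy
#'
#' @param adj a [vertex_adjacency] for the template (level-0) graph; must be
#'   connected.
#' @param levels number of pooled levels to build (>= 1).
#' @param radius neighbourhood ring radius (default 2, the convolution kernel
#'   radius).
#' @param stride minimum pairwise graph distance between accepted centers
#'   (default 2).
#' @return object of class `graph_hierarchy`: list with `n_levels`, `radius`,
#'   `stride`, `n` (vertex counts per level, level 0 first), and per-level
#'   lists `centers` (indices into the previous level), `neighborhoods`
#'   (lists of previous-level vertex indices), `upmap` (per previous-level
#'   vertex, the level-l nodes containing it), `level_adj` (adjacency at each
#'   level, level 0 = input).
#' @export
build_hierarchy <- function(adj, levels, radius = 2L, stride = 2L) {
  if (!inherits(adj, "vertex_adjacency")) stop("adj must be a vertex_adjacency")
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1")
  comp <- count_components(adj)
  if (comp != 1L) stop(sprintf("graph must be connected (found %d components)", comp))

  level_adj <- vector("list", levels + 1L)
  level_adj[[1L]] <- adj$neighbors
  n <- integer(levels + 1L)
  n[1L] <- adj$n_vertices
  centers <- vector("list", levels)
  neighborhoods <- vector("list", levels)
  upmap <- vector("list", levels)

  for (l in seq_len(levels)) {
    prev <- level_adj[[l]]
    np <- length(prev)
    if (np == 1L) {
      stop(sprintf("level %d cannot pool a single-vertex graph; achievable depth is %d",
                   l, l - 1L))
    }
    sel <- select_centers(prev, stride)
    nbhd <- lapply(sel, function(c) ring_set(prev, c, radius))
    # full coverage: every previous-level vertex must appear in >= 1 neighbourhood
    covered <- logical(np)
    covered[unlist(nbhd, use.names = FALSE)] <- TRUE
    if (!all(covered)) {
      # assign each uncovered vertex to the neighbourhood of the graph-nearest
      # center (can occur on stringy graphs when radius < stride coverage gap)
      for (v in which(!covered)) {
        d <- bfs_distances(prev, v)
        best <- which.min(d[sel])
        nbhd[[best]] <- sort(c(nbhd[[best]], v))
      }
    }
    memb_flat <- unlist(nbhd, use.names = FALSE)
    memb_node <- rep.int(seq_along(sel), lengths(nbhd))
    up <- split(memb_node, factor(memb_flat, levels = seq_len(np)))
    names(up) <- NULL
    # level-l adjacency: two centers adjacent iff neighbourhoods share a vertex
    new_adj <- overlap_adjacency(nbhd, np, length(sel))
    centers[[l]] <- sel
    neighborhoods[[l]] <- nbhd
    upmap[[l]] <- up
    level_adj[[l + 1L]] <- new_adj
    n[l + 1L] <- length(sel)
  }
  structure(list(n_levels = levels, radius = as.integer(radius),
                 stride = as.integer(stride), n = n, centers = centers,
                 neighborhoods = neighborhoods, upmap = upmap,
                 level_adj = level_adj),
            class = "graph_hierarchy")
}

# Greedy ascending-index center selection with BFS distance >= stride to all
# previously accepted centers.
select_centers <- function(neighbors, stride) {
  np <- length(neighbors)
  blocked <- logical(np)  # within distance < stride of an accepted center
  sel <- integer(0)
  for (v in seq_len(np)) {
    if (blocked[v]) next
    sel <- c(sel, v)
    # block everything at distance < stride from v
    if (stride > 1L) {
      near <- ring_set(neighbors, v, stride - 1L)
      blocked[near] <- TRUE
    } else {
      blocked[v] <- TRUE
    }
  }
  sel
}

# vertices at graph distance <= radius from center (ring set, center included)
ring_set <- function(neighbors, center, radius) {
  seen <- logical(length(neighbors))
  seen[center] <- TRUE
  frontier <- center
  d <- 0L
  while (d < radius && length(frontier)) {
    nxt <- unique(unlist(neighbors[frontier], use.names = FALSE))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
    d <- d + 1L
  }
  which(seen)
}

overlap_adjacency <- function(nbhd, n_prev, n_new) {
  memb_flat <- unlist(nbhd, use.names = FALSE)
  memb_node <- rep.int(seq_len(n_new), lengths(nbhd))
  by_vertex <- split(memb_node, factor(memb_flat, levels = seq_len(n_prev)))
  adj_sets <- vector("list", n_new)
  for (g in by_vertex) {
    if (length(g) < 2L) next
    for (a in g) adj_sets[[a]] <- c(adj_sets[[a]], g)
  }
  lapply(seq_len(n_new), function(i) {
    s <- unique(adj_sets[[i]])
    sort(s[s != i])
  })
}

#' @export
print.graph_hierarchy <- function(x, ...) {
  cat(sprintf("<graph_hierarchy: radius %d, stride %d; sizes %s>\n",
              x$radius, x$stride, paste(x$n, collapse = " -> ")))
  invisible(x)
}

#' Feature-map shape at a hierarchy level
#'
#' Returns the `(node count, channel count)` of the feature map a mesh
#' autoencoder produces at the given level. Level 0 is the full-resolution
#' template; the deepest level is the bottleneck, whose flattened size is
#' `node count x channels`.
#'
#' @param h a `graph_hierarchy`, or an integer vector of per-level node
#'   counts (level 0 first).
#' @param channels per-level channel counts (level 0 first, bottleneck last).
#' @param level 0-based level index.
#' @return integer vector `c(nodes, channels)`.
#' @export
level_feature_shape <- function(h, channels, level) {
  n <- if (inherits(h, "graph_hierarchy")) h$n else as.integer(h)
  level <- as.integer(level)
  if (level < 0L || level > length(n) - 1L) {
    stop(sprintf("level %d out of range [0, %d]", level, length(n) - 1L))
  }
  if (length(channels) != length(n)) {
    stop(sprintf("channels must have one entry per level (%d), got %d",
                 length(n), length(channels)))
  }
  c(nodes = n[level + 1L], channels = as.integer(channels[level + 1L]))
}

#' Serialize a hierarchy to JSON
#' @param h a `graph_hierarchy`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_hierarchy <- function(h, path) {
  obj <- list(n_levels = h$n_levels, radius = h$radius, stride = h$stride,
              n = h$n, centers = h$centers, neighborhoods = h$neighborhoods,
              upmap = h$upmap, level_adj = h$level_adj)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a hierarchy back from JSON
#' @param path JSON path written by [write_hierarchy()].
#' @return a `graph_hierarchy`.
#' @export
read_hierarchy <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  ints <- function(x) as.integer(unlist(x))
  int_list <- function(x) lapply(x, ints)
  nested <- function(x) lapply(x, int_list)
  structure(list(n_levels = ints(obj$n_levels),
                 radius = ints(obj$radius),
                 stride = ints(obj$stride),
                 n = ints(obj$n),
                 centers = int_list(obj$centers),
                 neighborhoods = nested(obj$neighborhoods),
                 upmap = nested(obj$upmap),
                 level_adj = nested(obj$level_adj)),
            class = "graph_hierarchy")
}
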
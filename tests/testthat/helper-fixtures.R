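# Shared fixtures and independent oracles, all built in code.

# regular tetrahedron: smallest closed triangle mesh
tetrahedron_mesh <- function() {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * 100
  f <- rbind(c(0L, 1L, 2L), c(0L, 3L, 1L), c(0L, 2L, 3L), c(1L, 3L, 2L))
  triangle_mesh(v, f, name = "tetra")
}

single_triangle_mesh <- function() {
  triangle_mesh(rbind(c(0, 0, 0), c(100, 0, 0), c(0, 100, 0)),
                rbind(c(0L, 1L, 2L)), name = "tri")
}

# random valid triangle soup on n vertices (connectivity not guaranteed;
# used where only face/edge bookkeeping matters)
random_mesh <- function(n_vertices = 20L, n_faces = 30L, seed = 1L) {
  set.seed(seed)
  v <- matrix(stats::rnorm(n_vertices * 3L, sd = 50), n_vertices, 3L)
  f <- t(replicate(n_faces, sample.int(n_vertices, 3L) - 1L))
  triangle_mesh(v, f, name = sprintf("rand%d", seed))
}

# random connected graph as a neighbour list (spanning tree + extra edges)
random_connected_graph <- function(n, extra_edges = n, seed = 1L) {
  set.seed(seed)
  nb <- vector("list", n)
  add_edge <- function(nb, a, b) {
    nb[[a]] <- union(nb[[a]], b)
    nb[[b]] <- union(nb[[b]], a)
    nb
  }
  for (v in 2:n) nb <- add_edge(nb, v, sample.int(v - 1L, 1L))
  for (k in seq_len(extra_edges)) {
    ab <- sample.int(n, 2L)
    if (ab[1L] != ab[2L]) nb <- add_edge(nb, ab[1L], ab[2L])
  }
  lapply(nb, sort)
}

adjacency_from_neighbors <- function(nb) {
  structure(list(neighbors = nb, n_vertices = length(nb)),
            class = "vertex_adjacency")
}

# oracle: undirected edge set by brute-force face enumeration
edges_from_faces <- function(faces) {
  e <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  unique(e)
}

# oracle: BFS distances on a neighbour list (independent of package BFS code)
oracle_bfs <- function(nb, src) {
  n <- length(nb)
  d <- rep(Inf, n)
  d[src] <- 0
  q <- src
  while (length(q)) {
    v <- q[1L]; q <- q[-1L]
    for (w in nb[[v]]) {
      if (d[w] > d[v] + 1) {
        d[w] <- d[v] + 1
        q <- c(q, w)
      }
    }
  }
  d
}

# oracle: the two-equation convolution expansion — materialize every W_{i,j}
# from the basis mixture, then accumulate y_i = sum_j W_{i,j}^T x_{i,j} + b
oracle_conv <- function(features, neighborhoods, kernel) {
  O <- length(kernel$bias)
  Y <- matrix(0, length(neighborhoods), O)
  slot <- 0L
  for (i in seq_along(neighborhoods)) {
    yi <- kernel$bias
    for (j in neighborhoods[[i]]) {
      slot <- slot + 1L
      W <- Reduce(`+`, Map(function(a, B) a * B,
                           as.list(kernel$alpha[slot, ]), kernel$basis))
      yi <- yi + as.numeric(t(W) %*% features[j, ])
    }
    Y[i, ] <- yi
  }
  Y
}

random_kernel <- function(neighborhoods, I, O, M, seed = 1L) {
  set.seed(seed)
  n_slots <- sum(lengths(neighborhoods))
  conv_kernel(basis = lapply(seq_len(M), function(k) matrix(rnorm(I * O), I, O)),
              alpha = matrix(rnorm(n_slots * M), n_slots, M),
              bias = rnorm(O))
}

# small shared training setup for autoencoder tests
tiny_ae_setup <- function(seed = 1L) {
  template <- make_template(1L)  # 42 vertices
  adj <- vertex_adjacency(template)
  hier <- build_hierarchy(adj, 2L)
  cfg <- ae_config(channels = c(4L, 8L), bottleneck_channels = 4L,
                   basis_size = 4L, learning_rate = 2e-3, batch_size = 8L,
                   seed = seed)
  list(template = template, hier = hier, cfg = cfg)
}
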
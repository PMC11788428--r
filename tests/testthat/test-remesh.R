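test_that("self-correspondence is the identity selection", {
  m <- tetrahedron_mesh()
  cmap <- solve_nn_correspondence(m, m)
  expect_equal(as.matrix(cmap$C), diag(4), ignore_attr = TRUE)
  expect_equal(apply_correspondence(cmap, m$vertices), m$vertices,
               ignore_attr = TRUE)
})

test_that("nearest-neighbour correspondence matches the all-pairs oracle", {
  set.seed(11)
  src <- triangle_mesh(matrix(rnorm(150, sd = 40), 50, 3),
                       matrix(c(0L, 1L, 2L), 1), name = "src")
  tgt <- triangle_mesh(matrix(rnorm(60, sd = 40), 20, 3),
                       matrix(c(0L, 1L, 2L), 1), name = "tgt")
  cmap <- solve_nn_correspondence(src, tgt)
  # O(V^2) oracle
  d2 <- as.matrix(stats::dist(rbind(tgt$vertices, src$vertices)))[1:20, 21:70]
  oracle <- apply(d2, 1L, which.min)
  got <- apply(as.matrix(cmap$C), 1L, which.max)
  expect_equal(unname(got), unname(oracle))
  # contract: exactly one nonzero of value 1 per row
  expect_true(all(Matrix::rowSums(cmap$C) == 1))
  expect_true(all(Matrix::rowSums(cmap$C != 0) == 1))
})

test_that("equidistant sources break ties to the lowest index", {
  src <- triangle_mesh(rbind(c(-100, 0, 0), c(100, 0, 0), c(0, 500, 0)),
                       matrix(c(0L, 1L, 2L), 1), name = "src")
  tgt <- triangle_mesh(rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0)),
                       matrix(c(0L, 1L, 2L), 1), name = "tgt")
  cmap <- solve_nn_correspondence(src, tgt)
  expect_true(all(apply(as.matrix(cmap$C), 1L, which.max) == 1L))
})

test_that("apply_correspondence is linear and shape-checked", {
  m <- tetrahedron_mesh()
  cmap <- solve_nn_correspondence(m, m)
  expect_equal(apply_correspondence(cmap, m$vertices * 2), m$vertices * 2,
               ignore_attr = TRUE)
  # constant selection: every row picks source vertex 3 (0-based idx 2)
  C <- Matrix::sparseMatrix(i = 1:4, j = rep(3L, 4L), x = 1, dims = c(4L, 4L))
  out <- apply_correspondence(C, m$vertices)
  expect_true(all(apply(out, 1L, function(r) all(r == m$vertices[3L, ]))))
  expect_error(apply_correspondence(cmap, m$vertices[1:3, ]), "source vertices")
})

test_that("refinement is a fixed point on its own reference and respects iterations = 0", {
  m <- make_template(1L)
  out0 <- nonrigid_refine(m, m, iterations = 0L)
  expect_equal(out0$vertices, m$vertices)
  out <- nonrigid_refine(m, m, iterations = 5L, smoothness = 0)
  expect_lt(vertex_mae(out, m), 1e-9)
  expect_error(nonrigid_refine(m, m, iterations = -1L), ">= 0")
})

test_that("closest-point distance decreases monotonically toward a translated copy", {
  m <- make_template(1L)
  ref <- m
  ref$vertices <- m$vertices + rep(c(2, 0, 0), each = nrow(m$vertices))
  out <- nonrigid_refine(m, ref, iterations = 50L, smoothness = 0, step = 0.5)
  trace <- attr(out, "distance_trace")
  expect_true(all(diff(trace) <= 1e-9))
  expect_lt(trace[length(trace)], 0.1 * trace[1L])
})

test_that("QC passes clean meshes and flags collapsed or split geometry", {
  tpl <- make_template(2L)
  expect_true(qc_mesh(tpl)$pass)

  collapsed <- tpl
  low <- which(collapsed$vertices[, 2L] < -600)  # collapse a 'limb' region
  collapsed$vertices[low, ] <- rep(colMeans(tpl$vertices[low, , drop = FALSE]),
                                   each = length(low))
  rep_qc <- qc_mesh(collapsed)
  # direct zero-area face count oracle
  f <- collapsed$faces + 1L
  n_zero <- sum(apply(f, 1L, function(fi) {
    e1 <- collapsed$vertices[fi[2L], ] - collapsed$vertices[fi[1L], ]
    e2 <- collapsed$vertices[fi[3L], ] - collapsed$vertices[fi[1L], ]
    cr <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    0.5 * sqrt(sum(cr^2)) < 1e-9
  }))
  expect_gt(n_zero, 0L)
  expect_equal(rep_qc$degenerate_face_fraction, n_zero / nrow(f))
  expect_false(rep_qc$pass)

  two <- tetrahedron_mesh()
  far <- tetrahedron_mesh()
  combined <- triangle_mesh(rbind(two$vertices, far$vertices + 1000),
                            rbind(two$faces, far$faces + 4L), name = "two")
  rep2 <- qc_mesh(combined)
  expect_equal(rep2$component_count, 2L)
  expect_false(rep2$pass)
})

test_that("end-to-end remeshing standardizes a finer source onto the template", {
  tpl <- make_template(1L)
  src <- make_template(2L)  # same underlying surface, different topology
  res <- remesh_to_template(src, tpl, iterations = 20L, smoothness = 0.05)
  expect_identical(res$mesh$faces, tpl$faces)
  # refined mesh hugs the source surface: mean closest-point distance small
  # relative to body scale
  trace <- attr(res$mesh, "distance_trace")
  expect_lt(trace[length(trace)], 10)  # mm, on a ~1700 mm body
  expect_true(res$qc$pass)
})
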
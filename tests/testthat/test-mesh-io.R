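test_that("triangle_mesh validates faces against the vertex array", {
  expect_error(triangle_mesh(diag(3), rbind(c(0L, 1L, 9L))), "out of range")
  expect_error(triangle_mesh(diag(3), rbind(c(0L, 1L, 1L))), "repeats")
  m <- tetrahedron_mesh()
  expect_equal(nrow(m$vertices), 4L)
  expect_equal(nrow(m$faces), 4L)
})

test_that("OBJ read parses a tetrahedron and flags bad indices", {
  path <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("# comment", "v 100 100 100", "v 100 -100 -100",
               "v -100 100 -100", "v -100 -100 100",
               "f 1 2 3", "f 1 4 2", "f 1 3 4", "f 2 4 3"), path)
  m <- read_mesh(path)
  expect_equal(nrow(m$vertices), 4L)
  expect_equal(nrow(m$faces), 4L)
  expect_equal(min(m$faces), 0L)

  bad <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "v 0 0 1", "f 1 2 10"), bad)
  expect_error(suppressWarnings(read_mesh(bad)), "vertex 10 of 4")

  junk <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 zebra", "f 1 1 1"), junk)
  expect_error(read_mesh(junk), "line 1")
})

test_that("write/read roundtrips preserve vertices and faces", {
  m <- random_mesh(n_vertices = 25L, n_faces = 40L, seed = 7L)
  m$vertices <- m$vertices + 500  # keep bbox diagonal >> units heuristic
  for (spec in list(list(ext = ".obj", binary = FALSE),
                    list(ext = ".ply", binary = FALSE),
                    list(ext = ".ply", binary = TRUE))) {
    path <- withr::local_tempfile(fileext = spec$ext)
    write_mesh(m, path, binary = spec$binary)
    back <- read_mesh(path)
    expect_equal(back$vertices, m$vertices, tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_identical(back$faces, m$faces)
  }
})

test_that("metre-scaled files are detected and rescaled to millimetres", {
  m <- tetrahedron_mesh()
  m$vertices <- m$vertices / 1000  # metres
  path <- withr::local_tempfile(fileext = ".obj")
  write_mesh(m, path)
  expect_warning(back <- read_mesh(path), "metres")
  expect_equal(back$vertices, m$vertices * 1000, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("vertex adjacency matches brute-force edge enumeration", {
  for (seed in 1:5) {
    m <- random_mesh(n_vertices = 15L, n_faces = 25L, seed = seed)
    adj <- vertex_adjacency(m)
    oracle <- edges_from_faces(m$faces + 1L)
    for (v in seq_len(15L)) {
      expected <- sort(unique(c(oracle[oracle[, 1L] == v, 2L],
                                oracle[oracle[, 2L] == v, 1L])))
      expect_identical(adj$neighbors[[v]], as.integer(expected))
    }
    # symmetry and no self-loops
    for (v in seq_len(15L)) {
      expect_false(v %in% adj$neighbors[[v]])
      for (w in adj$neighbors[[v]]) expect_true(v %in% adj$neighbors[[w]])
    }
  }
})

test_that("adjacency of the elementary meshes is as expected", {
  adj <- vertex_adjacency(tetrahedron_mesh())
  expect_true(all(lengths(adj$neighbors) == 3L))  # K4
  adj2 <- vertex_adjacency(single_triangle_mesh())
  expect_true(all(lengths(adj2$neighbors) == 2L))
})

test_that("k_ring equals depth-truncated BFS", {
  m <- tetrahedron_mesh()
  adj <- vertex_adjacency(m)
  expect_identical(k_ring(adj, 2L, 0L), 2L)            # k = 0 -> center only
  expect_identical(k_ring(adj, 1L, 1L), 1:4)           # K4 diameter 1
  expect_error(k_ring(adj, 9L, 1L), "out of range")

  tpl <- make_template(2L)
  adj <- vertex_adjacency(tpl)
  for (center in c(1L, 50L, 162L)) {
    d <- oracle_bfs(adj$neighbors, center)
    for (k in 0:2) {
      expect_identical(k_ring(adj, center, k), which(d <= k))
    }
  }
})

test_that("vertex_mae is the mean per-vertex Euclidean distance", {
  m <- tetrahedron_mesh()
  expect_equal(vertex_mae(m, m), 0)
  shifted <- m
  shifted$vertices <- m$vertices + rep(c(1, 0, 0), each = 4L)
  expect_equal(vertex_mae(m, shifted), 1)
  shifted$vertices <- m$vertices + rep(c(3, 4, 0), each = 4L)
  expect_equal(vertex_mae(m, shifted), 5)
  expect_error(vertex_mae(m$vertices, single_triangle_mesh()$vertices),
               "mismatch")
})

test_that("vertex_mae behaves as a metric on random triples", {
  set.seed(42)
  for (rep in 1:20) {
    a <- matrix(rnorm(30), 10, 3)
    b <- matrix(rnorm(30), 10, 3)
    c_ <- matrix(rnorm(30), 10, 3)
    expect_equal(vertex_mae(a, b), vertex_mae(b, a))
    expect_gte(vertex_mae(a, b) + vertex_mae(b, c_), vertex_mae(a, c_) - 1e-12)
    expect_gt(vertex_mae(a, b), 0)
  }
})

test_that("manifest reading enforces the split vocabulary", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,mesh_path,split", "a,a.ply,finetune", "b,b.ply,test"), path)
  mf <- read_manifest(path)
  expect_equal(nrow(mf), 2L)
  writeLines(c("id,mesh_path,split", "a,a.ply,banana"), path)
  expect_error(read_manifest(path), "banana")
})
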
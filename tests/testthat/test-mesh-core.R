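test_that("mesh construction enforces the structural invariants", {
  expect_s3_class(tetra_mesh(), "triangle_mesh")
  expect_error(triangle_mesh(matrix(0, 4, 3), rbind(c(1, 2, 9))),
               "out-of-range")
  expect_error(triangle_mesh(matrix(rnorm(12), 4, 3), rbind(c(1, 1, 2))),
               "same vertex twice")
  v <- matrix(rnorm(12), 4, 3)
  v[2, 1] <- NA
  expect_error(triangle_mesh(v, rbind(c(1, 2, 3))), "finite")
})

test_that("PLY round-trips preserve geometry, connectivity and scalar fields", {
  m <- tetra_mesh()
  for (binary in c(FALSE, TRUE)) {
    p <- tempfile(fileext = ".ply")
    write_mesh(m, p, binary = binary)
    r <- read_mesh(p)
    tol <- if (binary) 1e-6 else 1e-12
    expect_lt(max(abs(r$vertices - m$vertices)), tol)
    expect_identical(r$faces, m$faces)
    unlink(p)
  }
  # 1000-vertex synthetic radius, binary
  big <- remesh_copy(small_template()$mesh, 1000, seed = 5)
  p <- tempfile(fileext = ".ply")
  write_mesh(big, p, binary = TRUE)
  r <- read_mesh(p)
  expect_lt(max(abs(r$vertices - big$vertices)), 1e-3) # float32 storage
  expect_identical(r$faces, big$faces)
  # scalar field round-trip (both dialects)
  m$scalar <- c(0.5, 1, 2, 4)
  for (binary in c(FALSE, TRUE)) {
    write_mesh(m, p, binary = binary)
    r <- read_mesh(p)
    expect_lt(max(abs(r$scalar - m$scalar)), 1e-6)
  }
  unlink(p)
})

test_that("PLY with an out-of-range face index is rejected", {
  p <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0",
               "element vertex 4",
               "property double x", "property double y", "property double z",
               "element face 1",
               "property list uchar int vertex_indices",
               "end_header",
               "0 0 0", "1 0 0", "0 1 0", "0 0 1",
               "3 0 1 9"), p)
  expect_error(read_mesh(p), "out-of-range")
  unlink(p)
})

test_that("STL round-trips weld duplicated corner records into shared vertices", {
  m <- tetra_mesh()
  for (binary in c(FALSE, TRUE)) {
    p <- tempfile(fileext = ".stl")
    write_mesh(m, p, binary = binary)
    r <- read_mesh(p)
    # 4 faces x 3 unwelded corners collapse back to 4 unique vertices
    expect_identical(n_vertices(r), 4L)
    expect_identical(n_faces(r), 4L)
    # same vertex set (order may differ)
    key <- function(v) sort(apply(round(v, 9), 1, paste, collapse = ","))
    expect_identical(key(r$vertices), key(m$vertices))
    unlink(p)
  }
})

test_that("OBJ round-trips preserve vertices and faces", {
  m <- tetra_mesh()
  p <- tempfile(fileext = ".obj")
  write_mesh(m, p)
  r <- read_mesh(p)
  expect_lt(max(abs(r$vertices - m$vertices)), 1e-12)
  expect_identical(r$faces, m$faces)
  unlink(p)
})

test_that("scalar fields export to CSV", {
  m <- tetra_mesh()
  m$scalar <- 1:4 / 2
  p <- tempfile(fileext = ".csv")
  write_scalar_csv(m, p)
  d <- read.csv(p)
  expect_equal(d$value, m$scalar)
  expect_equal(d$vertex_index, 1:4)
  unlink(p)
})

test_that("mirroring negates X, preserves orientation, and is an involution", {
  m <- small_template()$mesh
  mm <- mirror_mesh(m)
  expect_equal(mm$vertices[, 1], -m$vertices[, 1])
  expect_equal(mm$vertices[, 2:3], m$vertices[, 2:3])
  # signed volume preserved in magnitude and sign by the winding flip
  expect_equal(signed_volume(mm), signed_volume(m), tolerance = 1e-12)
  m2 <- mirror_mesh(mm)
  expect_identical(m2$vertices, m$vertices)
  expect_identical(m2$faces, m$faces)
  # single vertex sanity
  one <- triangle_mesh(rbind(c(1, 2, 3), c(0, 1, 0), c(0, 0, 1)),
                       rbind(c(1, 2, 3)))
  expect_equal(mirror_mesh(one)$vertices[1, ], c(-1, 2, 3))
})

test_that("cut_by_length_fraction partitions vertices at the stated Y level", {
  # 11 vertices on a line at Y = 0, 10, ..., 100
  v <- cbind(0, seq(0, 100, 10), 0)
  v <- rbind(v, c(1, 0, 0), c(0, 0, 1))     # make valid faces possible
  m <- triangle_mesh(v, rbind(c(1, 12, 13)))
  cuts <- cut_by_length_fraction(m, "y", 0.88)
  expect_setequal(cuts$proximal$indices, c(which(v[, 2] <= 88)))
  expect_setequal(cuts$distal$indices, which(v[, 2] > 88))
  # partition property on a synthetic radius
  tm <- small_template()$mesh
  cuts <- cut_by_length_fraction(tm, "y", 0.88)
  expect_identical(sort(c(cuts$proximal$indices, cuts$distal$indices)),
                   seq_len(n_vertices(tm)))
  expect_length(intersect(cuts$proximal$indices, cuts$distal$indices), 0)
  # half-cut of a Y-symmetric mesh balances up to boundary ties
  sym <- triangle_mesh(cbind(c(1, 0, 0, 1, 0, 0), c(0, 0, 0, 1, 1, 1),
                             c(0, 1, 0, 0, 1, 0)),
                       rbind(c(1, 2, 3), c(4, 5, 6)))
  cs <- cut_by_length_fraction(sym, "y", 0.5)
  expect_identical(length(cs$proximal$indices), length(cs$distal$indices))
  expect_error(cut_by_length_fraction(tm, "y", 1.2), "between 0 and 1")
  expect_error(cut_by_length_fraction(tm, "y", 0), "between 0 and 1")
})

test_that("closest_point_on_surface matches the exhaustive per-triangle oracle", {
  m <- decimate_mesh(small_template()$mesh, 30)  # <= 100 triangles
  expect_lte(n_faces(m), 100)
  set.seed(7)
  q <- matrix(rnorm(60, sd = 60), 20, 3)
  cp <- closest_point_on_surface(m, q)
  for (i in seq_len(nrow(q))) {
    bf <- bf_closest_point_mesh(m, q[i, ])
    expect_lt(abs(cp$distance[i] - bf$distance), 1e-9)
  }
  # query at a vertex returns it at distance 0
  cp0 <- closest_point_on_surface(m, m$vertices[5, ])
  expect_lt(cp0$distance, 1e-12)
  # perpendicular foot above a single triangle
  tri <- triangle_mesh(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0)),
                       rbind(c(1, 2, 3)))
  cp1 <- closest_point_on_surface(tri, c(0.5, 0.5, 3))
  expect_equal(cp1$point[1, ], c(0.5, 0.5, 0), tolerance = 1e-12)
  expect_equal(cp1$distance, 3, tolerance = 1e-12)
})

test_that("decimation respects the vertex budget and stays near the surface", {
  # ~5000-vertex sphere decimated to 500
  sph <- sphere_mesh(5000)
  dec <- decimate_mesh(sph, 500)
  expect_lte(n_vertices(dec), 500)
  radial_err <- abs(sqrt(rowSums(dec$vertices^2)) - 1)
  expect_lt(mean(radial_err), 0.01)
  # one-sided distance to the input under 1% of the bbox diagonal
  d <- closest_point_on_surface(sph, dec$vertices)$distance
  expect_lt(max(d), 0.01 * bbox_diagonal(sph))
  # minimal decimation and degenerate request
  tm <- small_template()$mesh
  d1 <- decimate_mesh(tm, n_vertices(tm) - 1)
  expect_gte(n_vertices(d1), 4)
  expect_error(decimate_mesh(tm, 3), "at least 4")
})

test_that("submesh keeps only faces fully inside the subset", {
  tm <- small_template()$mesh
  cuts <- cut_by_length_fraction(tm, "y", 0.5)
  sub <- submesh(tm, cuts$distal)
  expect_true(all(sub$vertices[, 2] > min(tm$vertices[, 2]) +
                    0.5 * diff(range(tm$vertices[, 2])) - 1e-9))
  expect_true(max(sub$faces) <= n_vertices(sub))
})
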
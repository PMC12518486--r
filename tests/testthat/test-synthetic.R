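test_that("template construction meets its geometric contract", {
  tpl <- make_template(n_vertices = 600, length_mm = 240, shaft_radius_mm = 8,
                       head_radius_mm = 11, distal_width_mm = 30)
  m <- tpl$mesh
  expect_equal(diff(range(m$vertices[, 2])), 240, tolerance = 1e-6)
  expect_equal(tpl$landmarks$head_center[2], 0, tolerance = 1e-6)
  expect_equal(tpl$landmarks$ridge_midpoint[2], 240, tolerance = 1e-6)
  expect_gt(signed_volume(m), 0)
  # closed manifold: every edge shared by exactly two faces
  f <- m$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_true(all(table(key) == 2))
  expect_error(make_template(n_vertices = 600, length_mm = 10,
                             head_radius_mm = 11), "inconsistent|exceeds")
})

test_that("population data matrix has the rank the latent model dictates", {
  tpl <- small_template()
  modes <- radius_modes(tpl)[1:5]
  pop0 <- generate_population(tpl, modes = modes, n_shapes = 40,
                              noise_sd_mm = 0, seed = 9)
  X <- do.call(rbind, lapply(pop0$meshes, function(m) as.vector(t(m$vertices))))
  sv <- svd(sweep(X, 2, colMeans(X)), nu = 0, nv = 0)$d
  expect_equal(sum(sv > sv[1] * 1e-9), 5)   # noise-free: rank = n modes
  popn <- generate_population(tpl, modes = modes, n_shapes = 40,
                              noise_sd_mm = 0.05, seed = 9)
  Xn <- do.call(rbind, lapply(popn$meshes, function(m) as.vector(t(m$vertices))))
  svn <- svd(sweep(Xn, 2, colMeans(Xn)), nu = 0, nv = 0)$d
  expect_equal(sum(svn > svn[1] * 1e-9), 39) # generic position: rank n - 1
})

test_that("the generator is reproducible and requires a seed", {
  tpl <- small_template()
  a <- generate_population(tpl, n_shapes = 5, seed = 11)
  b <- generate_population(tpl, n_shapes = 5, seed = 11)
  expect_identical(a$meshes[[3]]$vertices, b$meshes[[3]]$vertices)
  expect_identical(a$latents, b$latents)
  expect_error(generate_population(tpl, n_shapes = 5), "seed")
})

test_that("mode fields have unit RMS norm and PCA recovers their subspace", {
  tpl <- small_template()
  modes <- radius_modes(tpl)
  for (m in modes) expect_equal(sqrt(mean(rowSums(m^2))), 1, tolerance = 1e-12)
  # principal angles between PCA subspace and truth < 1 degree (noise 0)
  k <- 3
  mm <- modes[1:k]
  pop <- generate_population(tpl, modes = mm, mode_sd_mm = c(7, 2.5, 1),
                             n_shapes = 10 * k, noise_sd_mm = 0, seed = 21)
  model <- build_ssm(gpa(pop$meshes)$aligned)
  B_true <- qr.Q(qr(sapply(mm, function(d) as.vector(t(d)))))
  # GPA alignment perturbs the raw mode directions; compare subspaces via
  # the unaligned data instead
  X <- do.call(rbind, lapply(pop$meshes, function(m) as.vector(t(m$vertices))))
  V <- svd(sweep(X, 2, colMeans(X)), nu = 0, nv = k)$v
  cosines <- svd(crossprod(B_true, V))$d
  angles <- acos(pmin(cosines, 1)) * 180 / pi
  expect_lt(max(angles), 1)
})

test_that("population mean converges to the template", {
  tpl <- small_template()
  pop <- generate_population(tpl, n_shapes = 60, noise_sd_mm = 0, seed = 5)
  mean_v <- Reduce(`+`, lapply(pop$meshes, `[[`, "vertices")) / 60
  rms <- sqrt(mean(rowSums((mean_v - tpl$mesh$vertices)^2)))
  expect_lt(rms, 3 * max(pop$mode_sd_mm) / sqrt(60))
})

test_that("remesh_copy reproduces the surface with unrelated connectivity", {
  tpl <- small_template()
  rc <- remesh_copy(tpl$mesh, 500, seed = 2)
  d <- closest_point_on_surface(tpl$mesh, rc$vertices)$distance
  expect_lt(max(d), 0.1)                       # lies on the input surface
  expect_false(n_faces(rc) == n_faces(tpl$mesh))
  rc2 <- remesh_copy(tpl$mesh, 500, seed = 3)
  expect_false(isTRUE(all.equal(rc$vertices, rc2$vertices)))
  expect_lt(max(closest_point_on_surface(tpl$mesh, rc2$vertices)$distance), 0.1)
})

test_that("apply_distal_rotation rotates the distal segment rigidly", {
  tpl <- small_template()
  m5 <- apply_distal_rotation(tpl$mesh, 5, axis = 3, fraction = 0.88)
  cuts <- cut_by_length_fraction(tpl$mesh, "y", 0.88)
  didx <- cuts$distal$indices
  # distal block transformed by the exact 5-degree rotation
  keep_prox <- tpl$mesh$vertices[, 2] < 0.7 * max(tpl$mesh$vertices[, 2])
  expect_equal(m5$vertices[keep_prox, ], tpl$mesh$vertices[keep_prox, ])
  fit <- kabsch_fit_angle(tpl$mesh$vertices[didx, ], m5$vertices[didx, ])
  expect_equal(fit, 5, tolerance = 1e-6)
})
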
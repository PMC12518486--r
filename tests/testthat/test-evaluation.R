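test_that("accuracy and Hausdorff behave on constructed geometries", {
  m <- small_template()$mesh
  expect_equal(accuracy(m, m), 0)
  expect_equal(hausdorff_max(m, m), 0)
  # concentric spheres: one-sided accuracy equals the radial offset
  s1 <- sphere_mesh(800)
  s2 <- triangle_mesh(1.1 * s1$vertices, s1$faces)
  expect_equal(accuracy(s2, s1), 0.1, tolerance = 0.01)
  # one vertex pushed out 5 mm dominates the Hausdorff distance
  s3 <- s1
  s3$vertices[17, ] <- s3$vertices[17, ] * 6
  expect_equal(hausdorff_max(s1, s3), 5, tolerance = 0.05)
  expect_identical(hausdorff_max(s1, s3), hausdorff_max(s3, s1))
  # accuracy agrees with the brute-force oracle on a small mesh
  small <- decimate_mesh(m, 30)
  q <- small$vertices + 0.5
  acc_pkg <- mean(closest_point_on_surface(small, q)$distance)
  acc_bf <- mean(vapply(seq_len(nrow(q)), function(i)
    bf_closest_point_mesh(small, q[i, ])$distance, 1))
  expect_lt(abs(acc_pkg - acc_bf), 1e-9)
})

test_that("compactness curves are monotone, end at 1 and report thresholds", {
  toy <- small_model()
  toy$values <- c(3, 1)
  toy$basis <- toy$basis[, 1:2]
  cc <- compactness(toy)
  expect_equal(cc$curve$cumulative_variance, c(0.75, 1))
  expect_identical(n_components_for(cc, 0.95), 2L)
  full <- compactness(small_model())
  expect_true(all(diff(full$curve$cumulative_variance) >= -1e-15))
  expect_equal(tail(full$curve$cumulative_variance, 1), 1, tolerance = 1e-12)
  # 5 dominant modes + tiny noise: 95% within 5 components
  tpl <- small_template()
  pop <- generate_population(tpl, modes = radius_modes(tpl)[1:5],
                             mode_sd_mm = c(7, 3, 3, 3, 3),
                             n_shapes = 30, noise_sd_mm = 0.02, seed = 19)
  m5 <- build_ssm(pop$meshes)
  expect_identical(n_components_for(m5, 0.95), 5L)
})

test_that("generalization curves shrink to zero inside the training subspace", {
  pop <- small_population()
  shapes <- gpa(pop$meshes)$aligned
  heldout <- shapes[[25]]
  curve <- generalization_curve(shapes[1:24], heldout,
                                sizes = c(2, 5, 10, 24), seed = 2)
  expect_identical(nrow(curve), 4L)
  expect_true(all(is.finite(curve$rmse_mm)))
  expect_lt(curve$rmse_mm[4], curve$rmse_mm[1])
  # a held-out shape lying inside the spanned subspace projects exactly
  model <- small_model()
  inside <- sample_shape(model, c(0.7, -0.3, 0.1))
  curve2 <- generalization_curve(gpa(pop$meshes)$aligned, inside, sizes = 25,
                                 seed = 2, align = FALSE)
  expect_lt(curve2$rmse_mm, 1e-6)
})

test_that("specificity is seeded, degenerate-safe and reports both modes", {
  model <- small_model()
  test_set <- lapply(1:3, function(i) sample_shape(model, seed = 500 + i))
  s1 <- specificity(model, test_set, n_samples = 5, seed = 9)
  s2 <- specificity(model, test_set, n_samples = 5, seed = 9)
  expect_identical(s1$per_sample, s2$per_sample)
  expect_true(all(s1$per_sample$accuracy_mm >= 0))
  # degenerate model (mean only) vs its own mean: all distances zero
  degen <- model
  degen$values <- 1e-30
  degen$basis <- model$basis[, 1, drop = FALSE]
  s0 <- specificity(degen, list(mean_mesh(model)), n_samples = 3, seed = 1)
  expect_lt(max(s0$per_sample$accuracy_mm), 1e-6)
  expect_lt(max(s0$per_sample$hausdorff_mm), 1e-6)
  sr <- specificity(model, test_set, seed = 3, mode = "reconstruct")
  expect_identical(nrow(sr$per_sample), 3L)
  expect_lt(max(sr$per_sample$accuracy_mm), 0.1) # test shapes are in-model
})

test_that("heatmaps carry non-negative distances whose max is the one-sided Hausdorff", {
  m <- small_template()$mesh
  m2 <- triangle_mesh(sweep(m$vertices, 2, c(0.4, 0, 0), "+"), m$faces)
  hm <- distance_heatmap(m2, m)
  expect_true(all(hm$scalar >= 0))
  one_sided <- max(closest_point_on_surface(m, m2$vertices)$distance)
  expect_equal(max(hm$scalar), one_sided)
  hm0 <- distance_heatmap(m, m)
  expect_lt(max(hm0$scalar), 1e-12)
  # heatmap writes through the PLY quality channel
  p <- tempfile(fileext = ".ply")
  write_mesh(hm, p)
  expect_equal(read_mesh(p)$scalar, hm$scalar, tolerance = 1e-6)
  unlink(p)
})
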
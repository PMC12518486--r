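test_that("kernel hyperparameters validate and the kernel has its closed form", {
  expect_error(kernel_params(noise = 0), "positive")
  expect_error(kernel_params(sigma = -1), "positive")
  x <- matrix(c(0, 0, 0), 1)
  expect_equal(gaussian_kernel(x, x, sigma = 50, scale = 7)[1, 1], 7)
  y <- matrix(c(50, 0, 0), 1)
  expect_equal(gaussian_kernel(x, y, sigma = 50, scale = 7)[1, 1], 7 * exp(-1))
  g <- default_kernel_grid()
  expect_identical(lengths(g), c(noise = 4L, sigma = 6L, scale = 3L))
})

test_that("Nystrom eigenpairs match the dense kernel on a small point set", {
  set.seed(3)
  pts <- matrix(rnorm(90, sd = 30), 30, 3)
  nb <- nystrom_basis(pts, sigma = 40, scale = 5, n_basis = 90,
                      n_landmarks = 30)  # all points: exact
  Kd <- gaussian_kernel(pts, pts, 40, 5)
  ev <- eigen(Kd, symmetric = TRUE, only.values = TRUE)$values
  # vector eigenvalues triplicate the scalar ones
  scalar_vals <- nb$values[seq(1, length(nb$values), 3)]
  keep <- seq_along(scalar_vals)
  expect_lt(max(abs(scalar_vals - ev[keep]) / ev[1]), 0.01)
  expect_lt(max(abs(crossprod(nb$basis) - diag(ncol(nb$basis)))), 1e-8)
})

test_that("partial observations validate their indices", {
  expect_error(partial_observation(c(1, 1, 2), matrix(0, 3, 3), 10), "unique")
  expect_error(partial_observation(c(1, 2), matrix(0, 2, 3), 10), "at least 3")
  expect_error(partial_observation(c(1, 2, 11), matrix(0, 3, 3), 10),
               "out of range")
})

test_that("augmentation adds the isotropic kernel to the model covariance", {
  model <- small_model()
  aug <- augment_model(model, kernel_params(20, 60, 4), n_basis = 90)
  expect_true(aug$meta$augmented)
  expect_gt(length(aug$values), length(model$values))
  expect_lt(max(abs(crossprod(aug$basis) - diag(length(aug$values)))), 1e-8)
  # covariance diag grows by ~scale at every vertex (kernel at zero lag)
  n <- length(model$mean)
  dg_ssm <- rowSums(sweep(model$basis^2, 2, model$values, "*"))
  dg_aug <- rowSums(sweep(aug$basis^2, 2, aug$values, "*"))
  added <- dg_aug - dg_ssm
  expect_equal(median(added), 4, tolerance = 0.15)
})

test_that("the GP posterior equals the dense normal-equations oracle", {
  model <- small_model()
  shp <- sample_shape(model, seed = 44)
  set.seed(6)
  idx <- sort(sample(seq_len(n_vertices(shp)), 40))
  obs <- partial_observation(idx, shp$vertices[idx, ], n_vertices(shp))
  post <- gp_posterior(model, obs, noise_sd = 2)
  K <- length(model$values)
  rows <- rep(3 * (idx - 1), each = 3) + rep(1:3, length(idx))
  Q <- (model$basis %*% diag(sqrt(model$values)))[rows, ]
  y <- as.vector(t(shp$vertices[idx, ])) - model$mean[rows]
  alpha_bf <- solve(crossprod(Q) + 4 * diag(K), crossprod(Q, y))
  expect_lt(max(abs(post$coefficients - alpha_bf)), 1e-8)
  cov_bf <- 4 * solve(crossprod(Q) + 4 * diag(K))
  expect_lt(max(abs(post$coefficient_covariance - cov_bf)), 1e-8)
  expect_true(isSymmetric(post$coefficient_covariance, tol = 1e-10))
  expect_gte(min(eigen(post$coefficient_covariance, symmetric = TRUE,
                       only.values = TRUE)$values), -1e-12)
})

test_that("posterior limits: interpolation (noise -> 0) and prior (noise -> Inf)", {
  model <- small_model()
  cfs <- c(1.2, -0.7, 0.4, rep(0, length(model$values) - 3))
  shp <- sample_shape(model, cfs)
  obs <- partial_observation(seq_len(n_vertices(shp)), shp$vertices,
                             n_vertices(shp))
  lo <- gp_posterior(model, obs, noise_sd = 1e-6)
  expect_lt(max(abs(lo$coefficients - cfs)), 1e-6)
  hi <- gp_posterior(model, obs, noise_sd = 1e7)
  expect_lt(max(abs(hi$coefficients)), 1e-6)
  expect_lt(max(abs(hi$predicted$vertices - mean_mesh(model)$vertices)), 1e-4)
})

test_that("posterior mean is linear in the observations", {
  model <- small_model()
  mv <- mean_mesh(model)$vertices
  set.seed(8)
  idx <- sort(sample(seq_len(nrow(mv)), 30))
  delta <- matrix(rnorm(length(idx) * 3), ncol = 3)
  o1 <- partial_observation(idx, mv[idx, ] + delta, nrow(mv))
  o2 <- partial_observation(idx, mv[idx, ] + 2 * delta, nrow(mv))
  a1 <- gp_posterior(model, o1, 1)$coefficients
  a2 <- gp_posterior(model, o2, 1)$coefficients
  expect_lt(max(abs(a2 - 2 * a1)), 1e-8)
})

test_that("observed-vertex predictive variance never exceeds the prior", {
  model <- small_model()
  mv <- mean_mesh(model)$vertices
  idx <- sort(seq(1, nrow(mv), by = 7))
  obs <- partial_observation(idx, mv[idx, ], nrow(mv))
  post <- gp_posterior(model, obs, noise_sd = 1)
  # prior per-vertex sd from the model covariance diagonal
  dg <- rowSums(sweep(model$basis^2, 2, model$values, "*"))
  prior_sd <- sqrt(rowSums(matrix(dg, ncol = 3, byrow = TRUE)))
  expect_true(all(post$predictive_sd[idx] <= prior_sd[idx] + 1e-9))
})

test_that("completing the proximal 88% of model shapes recovers the distal 12%", {
  model <- small_model()
  params <- kernel_params(noise = 1, sigma = 100, scale = 5)
  aug <- augment_model(model, params, n_basis = 120)
  errs <- vapply(1:4, function(i) {
    shp <- sample_shape(model, seed = 300 + i)
    cuts <- cut_by_length_fraction(shp, "y", 0.88)
    prox <- submesh(shp, cuts$proximal)
    res <- complete_shape(model, prox, params, augmented = aug)
    expect_identical(res$predicted$faces, model$faces)
    didx <- cuts$distal$indices
    sqrt(mean(rowSums((res$predicted$vertices[didx, ] -
                         shp$vertices[didx, ])^2)))
  }, 1)
  expect_lt(max(errs), 0.5)
  # prior fixed point: the mean shape completes to itself
  mm <- mean_mesh(model)
  cuts <- cut_by_length_fraction(mm, "y", 0.88)
  res <- complete_shape(model, submesh(mm, cuts$proximal), params,
                        augmented = aug)
  didx <- cuts$distal$indices
  expect_lt(sqrt(mean(rowSums((res$predicted$vertices[didx, ] -
                                 mm$vertices[didx, ])^2))), 0.1)
})

test_that("grid search evaluates the full grid and returns its argmin", {
  model <- small_model()
  vald <- lapply(1:2, function(i) sample_shape(model, seed = 400 + i))
  grid <- list(noise = c(5, 20), sigma = c(50, 150), scale = c(5, 15))
  gs <- grid_search(model, vald, grid, n_basis = 90)
  expect_identical(nrow(gs$table), 8L)
  best_row <- which(gs$table$noise == gs$best$noise &
                      gs$table$sigma == gs$best$sigma &
                      gs$table$scale == gs$best$scale)
  expect_equal(gs$table$mean_error_mm[best_row], min(gs$table$mean_error_mm))
  expect_true(all(is.finite(gs$table$mean_error_mm)))
})
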
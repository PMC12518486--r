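#' Isotropic Gaussian kernel
#'
#' `k(x, x') = scale * exp(-||x - x'||^2 / sigma^2)` (no factor 2 in the
#' denominator — the convention of the Gaussian-process morphable-model
#' framework this package follows; `sigma` is the distance at which
#' correlation falls to `exp(-1)`). Applied to vector-valued deformation
#' fields as `k * I3` (the three coordinates are independent a priori).
#'
#' @param a,b point matrices (n x 3, m x 3).
#' @param sigma kernel bandwidth (mm).
#' @param scale kernel amplitude (mm^2-scale variance multiplier).
#' @return n x m kernel matrix.
#' @export
gaussian_kernel <- function(a, b, sigma, scale) {
  if (sigma <= 0 || scale <= 0) stop("sigma and scale must be positive")
  if (is.null(dim(a))) a <- matrix(a, ncol = 3L)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3L)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  scale * exp(-pmax(d2, 0) / sigma^2)
}

#' Farthest-point sampling
#'
#' Deterministic greedy subsample: starting from the point nearest the
#' centroid, repeatedly add the point farthest from the current sample.
#' Used to pick the landmark (inducing) points of the Nystrom
#' approximation.
#'
#' @param points n x 3 matrix.
#' @param m number of samples.
#' @return integer vector of m row indices.
#' @export
farthest_point_sampling <- function(points, m) {
  n <- nrow(points)
  m <- min(m, n)
  ctr <- colMeans(points)
  first <- which.min(rowSums(sweep(points, 2L, ctr)^2))
  idx <- integer(m)
  idx[1L] <- first
  d2 <- rowSums(sweep(points, 2L, points[first, ])^2)
  if (m > 1L) for (i in 2:m) {
    idx[i] <- which.max(d2)
    d2 <- pmin(d2, rowSums(sweep(points, 2L, points[idx[i], ])^2))
  }
  idx
}

#' Low-rank eigenbasis of the isotropic Gaussian kernel (Nystrom)
#'
#' Approximates the leading eigenpairs of the scalar kernel matrix over
#' the reference vertices from `m` farthest-point-sampled landmarks, then
#' expands each scalar eigenfunction into three vector-valued basis fields
#' (one per coordinate), giving an orthonormal `3n x n_basis` matrix and
#' its eigenvalues. With `m = n` (all points as landmarks) the result is
#' exact up to the eigendecomposition.
#'
#' @param points reference vertex matrix (n x 3).
#' @param sigma,scale kernel parameters, see [gaussian_kernel()].
#' @param n_basis number of vector basis fields to return.
#' @param n_landmarks number of Nystrom landmarks (default
#'   `min(n, max(2 * ceiling(n_basis / 3), 50))`).
#' @return list with `basis` (3n x n_basis, orthonormal columns,
#'   coordinate-interleaved as x1,y1,z1,x2,...) and `values` (eigenvalues,
#'   decreasing).
#' @export
nystrom_basis <- function(points, sigma, scale, n_basis,
                          n_landmarks = NULL) {
  n <- nrow(points)
  k_scalar <- ceiling(n_basis / 3)
  if (is.null(n_landmarks)) {
    n_landmarks <- min(n, max(2L * k_scalar, 50L))
  }
  n_landmarks <- min(n_landmarks, n)
  lm <- farthest_point_sampling(points, n_landmarks)
  Kmm <- gaussian_kernel(points[lm, , drop = FALSE], points[lm, , drop = FALSE],
                         sigma, scale)
  Knm <- gaussian_kernel(points, points[lm, , drop = FALSE], sigma, scale)
  # exact eigendecomposition of the Nystrom approximation
  # K_hat = Knm Kmm^-1 Kmn = B B' with B = Knm Kmm^(-1/2):
  # svd(B) = U S V' gives K_hat = U S^2 U' (exact when m = n)
  eg <- eigen(Kmm, symmetric = TRUE)
  keep <- which(eg$values > max(eg$values) * 1e-10)
  B <- Knm %*% (eg$vectors[, keep, drop = FALSE] %*%
                  diag(1 / sqrt(eg$values[keep]), length(keep)))
  sv <- svd(B, nu = min(k_scalar, length(keep)), nv = 0L)
  pos <- which(sv$d[seq_len(ncol(sv$u))] > max(sv$d) * 1e-8)
  scalar_basis <- sv$u[, pos, drop = FALSE]
  scalar_vals <- sv$d[pos]^2

  # expand to vector fields: phi_j e_d, coordinate-interleaved rows
  kk <- length(scalar_vals)
  nb <- min(n_basis, 3L * kk)
  basis <- matrix(0, 3L * n, nb)
  values <- numeric(nb)
  col <- 0L
  for (j in seq_len(kk)) {
    for (d in 1:3) {
      if (col >= nb) break
      col <- col + 1L
      rows <- seq(d, 3L * n, by = 3L)
      basis[rows, col] <- scalar_basis[, j]
      values[col] <- scalar_vals[j]
    }
  }
  ord <- order(values, decreasing = TRUE)
  list(basis = basis[, ord, drop = FALSE], values = values[ord])
}

# shape <-> vector plumbing: vertex matrices are stored coordinate-
# interleaved (x1, y1, z1, x2, ...) in shape vectors
as_shape_vector <- function(vertices) as.vector(t(vertices))
as_vertex_matrix <- function(x) matrix(x, ncol = 3L, byrow = TRUE)
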
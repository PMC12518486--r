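#' Generalized Procrustes analysis (rigid, no scaling)
#'
#' Iteratively (a) rigidly aligns every corresponded mesh to the current
#' mean and (b) recomputes the mean, until the mean moves less than
#' `tol_mm` (RMS) or `max_iter` is reached. No scaling step is applied:
#' absolute size in millimetres is clinically meaningful (lengthening is
#' one of the evaluated errors), so size is retained.
#'
#' @param meshes list of corresponded `triangle_mesh`es (identical face
#'   lists).
#' @param max_iter maximum outer iterations.
#' @param tol_mm convergence tolerance on the RMS mean movement.
#' @return list with `aligned` (list of meshes), `mean` (the mean
#'   `triangle_mesh`) and `objective` (sum of squared distances to the
#'   mean per iteration, non-increasing).
#' @export
gpa <- function(meshes, max_iter = 20L, tol_mm = 1e-6) {
  if (length(meshes) < 2L) stop("GPA needs at least 2 meshes")
  f0 <- meshes[[1L]]$faces
  for (m in meshes) {
    if (!identical(dim(m$vertices), dim(meshes[[1L]]$vertices)) ||
        !identical(m$faces, f0)) {
      stop("GPA requires corresponded meshes with identical topology")
    }
  }
  aligned <- lapply(meshes, function(m) m$vertices)
  mean_v <- Reduce(`+`, aligned) / length(aligned)
  objective <- numeric()
  for (it in seq_len(max_iter)) {
    aligned <- lapply(aligned, function(v) apply_transform(kabsch(v, mean_v), v))
    new_mean <- Reduce(`+`, aligned) / length(aligned)
    objective <- c(objective,
                   sum(vapply(aligned, function(v) sum((v - new_mean)^2), 1)))
    moved <- sqrt(mean((new_mean - mean_v)^2))
    mean_v <- new_mean
    if (moved < tol_mm) break
  }
  list(aligned = lapply(aligned, function(v) triangle_mesh(v, f0)),
       mean = triangle_mesh(mean_v, f0),
       objective = objective)
}

#' Build a statistical shape model from aligned corresponded meshes
#'
#' The mean shape is the average shape vector; the principal components
#' are the eigenvectors of the sample covariance (divisor n - 1), obtained
#' from the singular value decomposition of the centered data matrix and
#' ranked by decreasing eigenvalue. Components with eigenvalue below
#' `1e-12 * lambda_1` are discarded, so a set of n shapes in generic
#' position retains exactly n - 1 components.
#'
#' @param aligned_meshes list of GPA-aligned corresponded meshes.
#' @param reference optional `triangle_mesh` used as topology carrier
#'   (defaults to the first mesh's topology with the mean vertices).
#' @param meta named list of provenance metadata stored in the model.
#' @return a `shape_model`: list with `mean` (3n shape vector, mm),
#'   `basis` (3n x K orthonormal), `values` (eigenvalues, mm^2,
#'   decreasing), `faces`, `reference_vertices`, `n_training`, `meta`.
#' @export
build_ssm <- function(aligned_meshes, reference = NULL, meta = list()) {
  n <- length(aligned_meshes)
  if (n < 2L) stop("need at least 2 shapes to build a model")
  X <- do.call(rbind, lapply(aligned_meshes, function(m) as_shape_vector(m$vertices)))
  mean_vec <- colMeans(X)
  Xc <- sweep(X, 2L, mean_vec)
  sv <- svd(Xc, nu = 0L)
  values <- sv$d^2 / (n - 1)
  keep <- values >= values[1L] * 1e-12 & sv$d > 0
  faces <- aligned_meshes[[1L]]$faces
  structure(list(mean = mean_vec,
                 basis = sv$v[, keep, drop = FALSE],
                 values = values[keep],
                 faces = faces,
                 reference_vertices = if (!is.null(reference)) reference$vertices
                                      else as_vertex_matrix(mean_vec),
                 n_training = n,
                 meta = meta),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("<shape_model: %d vertices, %d components, %d training shapes>\n",
              length(x$mean) / 3, length(x$values), x$n_training))
  invisible(x)
}

#' Mean shape of a model as a mesh
#' @param model a `shape_model`.
#' @return a `triangle_mesh`.
#' @export
mean_mesh <- function(model) triangle_mesh(as_vertex_matrix(model$mean), model$faces)

#' Two-pass shape-model construction
#'
#' Pass 1 corresponds every raw mesh to the initial reference (nonrigid
#' ICP), aligns with GPA and builds a PCA model. Pass 2 repeats all steps
#' — correspondence, GPA, PCA — using the pass-1 mean shape as the new
#' reference, and returns the pass-2 model. Re-referencing to the mean
#' removes the bias of an arbitrary initial reference.
#'
#' @param raw_meshes list of `triangle_mesh`es (any topologies).
#' @param initial_reference the initial reference `triangle_mesh`.
#' @param schedule a [registration_schedule()].
#' @param corresponded set `TRUE` when `raw_meshes` already share the
#'   reference topology (skips the nonrigid registration of that pass).
#' @return list with `model` (pass-2 `shape_model`), `pass1_model`, and
#'   `correspondences` (pass-2 corresponded meshes).
#' @export
two_pass_build <- function(raw_meshes, initial_reference,
                           schedule = registration_schedule(),
                           corresponded = FALSE) {
  pass1 <- if (corresponded) raw_meshes
           else correspond_population(raw_meshes, initial_reference, schedule)
  g1 <- gpa(pass1)
  model1 <- build_ssm(g1$aligned, reference = initial_reference,
                      meta = list(pass = 1L))
  # pass 2 refines the pass-1 correspondence on the new reference (the
  # pass-1 mean shares the reference topology, so each mesh's existing
  # correspondence provides the starting deformation)
  inits <- lapply(pass1, function(m) m$vertices - g1$mean$vertices)
  pass2 <- correspond_population(raw_meshes, g1$mean, schedule,
                                 init_displacements = inits)
  g2 <- gpa(pass2)
  model2 <- build_ssm(g2$aligned, reference = g1$mean, meta = list(pass = 2L))
  list(model = model2, pass1_model = model1, correspondences = pass2)
}

#' Draw a shape from the model
#'
#' `shape = mean + sum_k c_k sqrt(lambda_k) b_k`; with all-zero
#' coefficients this is exactly the mean shape. When `coefficients` is
#' missing, standard-normal coefficients are drawn under `seed`.
#'
#' @param model a `shape_model`.
#' @param coefficients numeric vector, length at most the number of
#'   components.
#' @param seed integer seed for random coefficients.
#' @return a `triangle_mesh`.
#' @export
sample_shape <- function(model, coefficients = NULL, seed = NULL) {
  K <- length(model$values)
  if (is.null(coefficients)) {
    if (is.null(seed)) stop("either coefficients or a seed must be given")
    set.seed(as.integer(seed))
    coefficients <- rnorm(K)
  }
  if (length(coefficients) > K) stop("more coefficients than model components")
  c_ <- c(coefficients, rep(0, K - length(coefficients)))
  vec <- model$mean + as.vector(model$basis %*% (c_ * sqrt(model$values)))
  triangle_mesh(as_vertex_matrix(vec), model$faces)
}

#' Project a corresponded shape onto the model
#'
#' `c_k = b_k^T (shape - mean) / sqrt(lambda_k)`; the reconstruction
#' `mean + sum_k c_k sqrt(lambda_k) b_k` is the orthogonal projection of
#' the shape onto the model subspace.
#'
#' @param model a `shape_model`.
#' @param mesh a `triangle_mesh` with the model topology (or a shape
#'   vector).
#' @return numeric coefficient vector (length = number of components).
#' @export
project_shape <- function(model, mesh) {
  x <- if (inherits(mesh, "triangle_mesh")) {
    if (!identical(dim(mesh$vertices), dim(as_vertex_matrix(model$mean)))) {
      stop("mesh topology does not match the model")
    }
    as_shape_vector(mesh$vertices)
  } else as.numeric(mesh)
  as.vector(crossprod(model$basis, x - model$mean)) / sqrt(model$values)
}

#' Reconstruct a mesh from model coefficients
#' @param model a `shape_model`.
#' @param coefficients coefficient vector from [project_shape()].
#' @return a `triangle_mesh` (the orthogonal projection).
#' @export
reconstruct_shape <- function(model, coefficients) {
  sample_shape(model, coefficients)
}

MODEL_FORMAT_VERSION <- 1L

#' Save / load a shape model
#'
#' The container is a single file holding the named arrays (mean,
#' eigenvalues, basis, faces, reference vertices) and a JSON metadata
#' header with a format version and an MD5 checksum of the serialized
#' arrays; loading verifies both. The round-trip is lossless (arrays
#' bit-exact).
#'
#' @param model a `shape_model`.
#' @param path file path.
#' @return `save_model`: `path` invisibly; `load_model`: the
#'   `shape_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "shape_model"))
  payload <- unclass(model)
  raw_payload <- serialize(payload, NULL, version = 2L)
  tmp <- tempfile()
  writeBin(raw_payload, tmp)
  checksum <- unname(tools::md5sum(tmp))
  unlink(tmp)
  header <- jsonlite::toJSON(list(format = "radssm_shape_model",
                                  version = MODEL_FORMAT_VERSION,
                                  checksum = checksum,
                                  n_vertices = length(model$mean) / 3,
                                  n_components = length(model$values)),
                             auto_unbox = TRUE)
  con <- file(path, "wb")
  on.exit(close(con))
  hraw <- charToRaw(as.character(header))
  writeBin(length(hraw), con, size = 4L, endian = "little")
  writeBin(hraw, con)
  writeBin(raw_payload, con)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hlen <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (is.na(hlen) || hlen <= 0L || hlen > 1e6) stop("not a radssm model file")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n = hlen)))
  if (!identical(header$format, "radssm_shape_model")) stop("not a radssm model file")
  if (header$version > MODEL_FORMAT_VERSION) {
    stop(sprintf("model file version %d is newer than this package supports", header$version))
  }
  raw_payload <- readBin(con, "raw", n = file.info(path)$size)
  tmp <- tempfile()
  writeBin(raw_payload, tmp)
  checksum <- unname(tools::md5sum(tmp))
  unlink(tmp)
  if (!identical(checksum, header$checksum)) {
    stop("model file integrity check failed (checksum mismatch)")
  }
  model <- unserialize(raw_payload)
  class(model) <- "shape_model"
  model
}
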
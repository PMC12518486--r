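#' Mean surface accuracy (mm)
#'
#' One-sided mean distance: for each vertex of `predicted`, the distance
#' to the closest point of the `reference` surface, averaged. Topologies
#' may differ. Set `symmetric = TRUE` to average both directions.
#'
#' @param predicted,reference `triangle_mesh`es.
#' @param symmetric average the two one-sided means.
#' @return mean distance in mm.
#' @export
accuracy <- function(predicted, reference, symmetric = FALSE) {
  d1 <- mean(closest_point_on_surface(reference, predicted$vertices)$distance)
  if (!symmetric) return(d1)
  d2 <- mean(closest_point_on_surface(predicted, reference$vertices)$distance)
  (d1 + d2) / 2
}

#' Maximum (symmetric) Hausdorff distance (mm)
#'
#' Maximum over both directions of the vertex-to-surface distances:
#' `max(max_i d(a_i, B), max_j d(b_j, A))`. Symmetric in its arguments.
#'
#' @param a,b `triangle_mesh`es.
#' @return Hausdorff distance in mm.
#' @export
hausdorff_max <- function(a, b) {
  max(max(closest_point_on_surface(b, a$vertices)$distance),
      max(closest_point_on_surface(a, b$vertices)$distance))
}

#' Compactness of a shape model
#'
#' Cumulative fraction of total variance per retained component count,
#' and the smallest count reaching a threshold (95% by default).
#'
#' @param model a `shape_model`.
#' @return a `compactness` object: tibble `curve` with columns
#'   `n_components` and `cumulative_variance` (non-decreasing, ending at
#'   1), plus `n_for(threshold)` via [n_components_for()].
#' @export
compactness <- function(model) {
  cum <- cumsum(model$values) / sum(model$values)
  structure(list(curve = tibble::tibble(n_components = seq_along(cum),
                                        cumulative_variance = cum)),
            class = "compactness")
}

#' @export
print.compactness <- function(x, ...) {
  cat(sprintf("<compactness: %d components; 95%% at %d>\n",
              nrow(x$curve), n_components_for(x, 0.95)))
  invisible(x)
}

#' Components needed to reach a variance threshold
#' @param x a `compactness` object (or `shape_model`).
#' @param threshold cumulative variance fraction in (0, 1].
#' @return the smallest component count whose cumulative variance reaches
#'   the threshold.
#' @export
n_components_for <- function(x, threshold = 0.95) {
  if (inherits(x, "shape_model")) x <- compactness(x)
  which(x$curve$cumulative_variance >= threshold - 1e-12)[1L]
}

#' Generalization curve of the model
#'
#' For each training-set size `n` in `sizes`, builds a model on the first
#' `n` shapes (after one fixed shuffle under `seed`), projects the
#' held-out shape onto it and reports the root-mean-square error of the
#' projection residual (per coordinate, mm). The curve decreases in
#' expectation as the subspace grows.
#'
#' @param corresponded_shapes list of corresponded, GPA-aligned
#'   `triangle_mesh`es.
#' @param heldout_shape a corresponded `triangle_mesh` not in the list.
#' @param sizes training sizes to evaluate (default 2 .. all).
#' @param seed seed for the single shuffle of the training order.
#' @param align rigidly align the held-out shape to each sub-model's mean
#'   before projecting (default TRUE; disable when the held-out shape is
#'   already expressed in the aligned space).
#' @return tibble with columns `n_training` and `rmse_mm`.
#' @export
generalization_curve <- function(corresponded_shapes, heldout_shape,
                                 sizes = NULL, seed = 1L, align = TRUE) {
  n <- length(corresponded_shapes)
  sizes <- sizes %||% seq(2L, n)
  set.seed(as.integer(seed))
  ord <- sample.int(n)
  rmse <- vapply(sizes, function(k) {
    model <- build_ssm(corresponded_shapes[ord[seq_len(k)]])
    xa <- if (align) {
      tf <- kabsch(heldout_shape$vertices, as_vertex_matrix(model$mean))
      as_shape_vector(apply_transform(tf, heldout_shape$vertices))
    } else {
      as_shape_vector(heldout_shape$vertices)
    }
    coef <- project_shape(model, xa)
    rec <- model$mean + as.vector(model$basis %*% (coef * sqrt(model$values)))
    sqrt(mean((xa - rec)^2))
  }, 1)
  tibble::tibble(n_training = as.integer(sizes), rmse_mm = rmse)
}

#' Specificity of a shape model
#'
#' Draws `n_samples` shapes from the model (standard-normal coefficients
#' under `seed`) and compares each against the nearest test mesh — the one
#' minimizing the one-sided accuracy — reporting that accuracy and the
#' maximum Hausdorff distance. `mode = "reconstruct"` instead reconstructs
#' each test mesh through the model (projection) and scores the
#' reconstruction against it; both readings of "using the test set to
#' generate new 3D models" are provided.
#'
#' @param model a `shape_model`.
#' @param test_meshes list of `triangle_mesh`es.
#' @param n_samples number of sampled shapes (default 10).
#' @param seed integer seed.
#' @param mode `"sample"` or `"reconstruct"`.
#' @return a `specificity_summary`: tibble `per_sample` (sample,
#'   accuracy_mm, hausdorff_mm, nearest_test) plus means and maxima.
#' @export
specificity <- function(model, test_meshes, n_samples = 10L, seed = 1L,
                        mode = c("sample", "reconstruct")) {
  mode <- match.arg(mode)
  stopifnot(length(test_meshes) >= 1L)
  set.seed(as.integer(seed))
  K <- length(model$values)
  draws <- if (mode == "sample") {
    lapply(seq_len(n_samples), function(i) sample_shape(model, rnorm(K)))
  } else {
    lapply(test_meshes, function(m) {
      tf <- kabsch(m$vertices, as_vertex_matrix(model$mean))
      xa <- apply_transform(tf, m$vertices)
      rec <- reconstruct_shape(model, project_shape(model, as_shape_vector(xa)))
      apply_transform(invert_transform(tf), rec)
    })
  }
  rows <- lapply(seq_along(draws), function(i) {
    acc <- vapply(test_meshes, function(tm) accuracy(draws[[i]], tm), 1)
    j <- if (mode == "reconstruct") i else which.min(acc)
    tibble::tibble(sample = i, accuracy_mm = acc[j],
                   hausdorff_mm = hausdorff_max(draws[[i]], test_meshes[[j]]),
                   nearest_test = j)
  })
  per_sample <- dplyr::bind_rows(rows)
  structure(list(per_sample = per_sample,
                 mean_accuracy_mm = mean(per_sample$accuracy_mm),
                 max_accuracy_mm = max(per_sample$accuracy_mm),
                 mean_hausdorff_mm = mean(per_sample$hausdorff_mm),
                 max_hausdorff_mm = max(per_sample$hausdorff_mm),
                 mode = mode, seed = as.integer(seed)),
            class = "specificity_summary")
}

#' @export
print.specificity_summary <- function(x, ...) {
  cat(sprintf("<specificity (%s): accuracy %.3f mm (max %.3f), Hausdorff %.3f mm (max %.3f)>\n",
              x$mode, x$mean_accuracy_mm, x$max_accuracy_mm,
              x$mean_hausdorff_mm, x$max_hausdorff_mm))
  invisible(x)
}

#' Per-vertex distance heatmap
#'
#' Attaches to each vertex of `predicted` its closest-point distance to
#' the `reference` surface, as the mesh's scalar field (written to PLY as
#' the `quality` property, or to CSV via [write_scalar_csv()]). The field
#' maximum equals the one-sided Hausdorff component predicted -> reference.
#'
#' @param predicted,reference `triangle_mesh`es.
#' @return `predicted` with the distance field in `$scalar`.
#' @export
distance_heatmap <- function(predicted, reference) {
  d <- closest_point_on_surface(reference, predicted$vertices)$distance
  triangle_mesh(predicted$vertices, predicted$faces, d)
}

#' Evaluate completions of a test set
#'
#' Runs the full per-case evaluation used for a test split: completes each
#' mesh's proximal fraction, scores accuracy and maximum Hausdorff
#' distance against the reference, and builds the distance heatmap.
#'
#' @param model a `shape_model`.
#' @param test_meshes list of full canonical-frame `triangle_mesh`es.
#' @param params a [kernel_params()].
#' @param fraction observed fraction (default 0.88).
#' @param n_basis augmentation basis count.
#' @return list with `per_case` tibble (case, accuracy_mm, hausdorff_mm)
#'   and lists `predictions`, `heatmaps`.
#' @export
evaluate_completions <- function(model, test_meshes, params = kernel_params(),
                                 fraction = 0.88, n_basis = 200L) {
  aug <- augment_model(model, params, n_basis)
  preds <- vector("list", length(test_meshes))
  heat <- vector("list", length(test_meshes))
  acc <- haus <- numeric(length(test_meshes))
  for (i in seq_along(test_meshes)) {
    cuts <- cut_by_length_fraction(test_meshes[[i]], "y", fraction)
    prox <- submesh(test_meshes[[i]], cuts$proximal)
    res <- complete_shape(model, prox, params, fraction, n_basis,
                          augmented = aug)
    preds[[i]] <- res$predicted
    acc[i] <- accuracy(res$predicted, test_meshes[[i]])
    haus[i] <- hausdorff_max(res$predicted, test_meshes[[i]])
    heat[[i]] <- distance_heatmap(res$predicted, test_meshes[[i]])
  }
  list(per_case = tibble::tibble(case = seq_along(test_meshes),
                                 accuracy_mm = acc, hausdorff_mm = haus),
       predictions = preds, heatmaps = heat)
}
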
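#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run. The defaults reproduce the
#' study conditions the package emulates: 100 shapes split 8:1:1 into
#' training/validation/test, the observed proximal fraction 0.88, the
#' standard 4 x 6 x 3 hyperparameter grid, and a 2000-vertex reference.
#'
#' @param n_shapes population size.
#' @param split_ratio three positive numbers (training : validation :
#'   test).
#' @param n_template_vertices vertex count of the synthetic template.
#' @param n_reference_vertices vertex count of the downsampled reference.
#' @param noise_sd_mm generator vertex noise (mm).
#' @param schedule a [registration_schedule()].
#' @param grid hyperparameter grid (list of noise/sigma/scale vectors).
#' @param fraction observed proximal fraction.
#' @param n_basis augmentation basis count.
#' @param seed master integer seed (required).
#' @param out_dir optional output directory for reports and meshes.
#' @return a `pipeline_config` (validated list).
#' @export
pipeline_config <- function(n_shapes = 100L,
                            split_ratio = c(8, 1, 1),
                            n_template_vertices = 2000L,
                            n_reference_vertices = 2000L,
                            noise_sd_mm = 0.3,
                            schedule = registration_schedule(),
                            grid = default_kernel_grid(),
                            fraction = 0.88,
                            n_basis = 200L,
                            seed = NULL,
                            out_dir = NULL) {
  if (is.null(seed)) stop("pipeline configuration requires a seed (reproducibility)")
  if (length(split_ratio) != 3L || any(split_ratio <= 0)) {
    stop("split_ratio must be three positive numbers")
  }
  structure(list(n_shapes = as.integer(n_shapes), split_ratio = split_ratio,
                 n_template_vertices = as.integer(n_template_vertices),
                 n_reference_vertices = as.integer(n_reference_vertices),
                 noise_sd_mm = noise_sd_mm, schedule = schedule, grid = grid,
                 fraction = fraction, n_basis = as.integer(n_basis),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Split indices by ratio
#'
#' Random assignment of `n` cases to training/validation/test in the given
#' ratio (sizes rounded to integers summing to `n`), after a seeded
#' shuffle.
#'
#' @param n number of cases.
#' @param ratio three positive numbers.
#' @param seed integer seed.
#' @return list of integer index vectors `training`, `validation`, `test`.
#' @export
split_dataset <- function(n, ratio = c(8, 1, 1), seed) {
  if (missing(seed)) stop("split requires a seed")
  sizes <- floor(n * ratio / sum(ratio))
  rem <- n - sum(sizes)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  set.seed(as.integer(seed))
  ord <- sample.int(n)
  list(training = sort(ord[seq_len(sizes[1L])]),
       validation = sort(ord[sizes[1L] + seq_len(sizes[2L])]),
       test = sort(ord[sizes[1L] + sizes[2L] + seq_len(sizes[3L])]))
}

#' Run the full shape-completion pipeline on a synthetic population
#'
#' Orchestrates the whole method end to end: generate the synthetic
#' population -> split 8:1:1 -> establish correspondence to a downsampled
#' reference and build the two-pass shape model (GPA + PCA, re-referenced
#' to the mean) -> grid-search the completion hyperparameters on the
#' validation split -> complete and evaluate every test case (accuracy,
#' Hausdorff, heatmaps, clinical 6-DOF errors) -> compactness,
#' generalization and specificity of the model. Deterministic given the
#' seed: a rerun with the same configuration reproduces every report.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_result` list: `model`, `best_params`, `grid_table`,
#'   `test_evaluation` (per-case tibble), `clinical` (per-case 6-DOF
#'   tibble), `compactness`, `generalization`, `specificity`, `split`,
#'   `population`, `timings_s`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  tick <- function() proc.time()[["elapsed"]] - t0
  timings <- c()

  tpl <- make_template(n_vertices = config$n_template_vertices)
  pop <- generate_population(tpl, n_shapes = config$n_shapes,
                             noise_sd_mm = config$noise_sd_mm,
                             seed = config$seed)
  split <- split_dataset(config$n_shapes, config$split_ratio,
                         seed = config$seed + 1L)
  timings["generate"] <- tick()

  # downsampled reference, not a member of the population
  reference <- remesh_copy(tpl$mesh, config$n_reference_vertices,
                           seed = config$seed + 2L)
  training <- pop$meshes[split$training]
  built <- two_pass_build(training, reference, config$schedule)
  model <- built$model
  timings["build_model"] <- tick()

  gs <- grid_search(model, pop$meshes[split$validation], config$grid,
                    fraction = config$fraction, n_basis = config$n_basis)
  timings["grid_search"] <- tick()

  test_meshes <- pop$meshes[split$test]
  ev <- evaluate_completions(model, test_meshes, gs$best,
                             fraction = config$fraction,
                             n_basis = config$n_basis)
  clin <- dplyr::bind_rows(lapply(seq_along(test_meshes), function(i) {
    e <- clinical_error(ev$predictions[[i]], test_meshes[[i]],
                        fraction = 1 - config$fraction)
    dplyr::bind_cols(tibble::tibble(case = i), tidy(e))
  }))
  timings["test_evaluation"] <- tick()

  comp <- compactness(model)
  heldout <- built$correspondences[[1L]]
  gen_sizes <- unique(pmin(length(training) - 1L,
                           c(2L, 5L, 10L, 20L, 40L, 60L, length(training) - 1L)))
  gen <- generalization_curve(built$correspondences[-1L], heldout,
                              sizes = gen_sizes, seed = config$seed + 3L)
  spec <- specificity(model, test_meshes, n_samples = 10L,
                      seed = config$seed + 4L)
  timings["model_metrics"] <- tick()

  result <- structure(list(model = model, best_params = gs$best,
                           grid_table = gs$table,
                           test_evaluation = ev$per_case,
                           predictions = ev$predictions,
                           heatmaps = ev$heatmaps,
                           clinical = clin,
                           compactness = comp,
                           generalization = gen,
                           specificity = spec,
                           split = split,
                           population = pop,
                           config = config,
                           timings_s = timings),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result: %d shapes (%d/%d/%d), %d model components>\n",
              x$config$n_shapes, length(x$split$training),
              length(x$split$validation), length(x$split$test),
              length(x$model$values)))
  cat(sprintf("  best hyperparameters: noise %g, sigma %g, scale %g\n",
              x$best_params$noise, x$best_params$sigma, x$best_params$scale))
  cat(sprintf("  test accuracy %.3f mm (mean), Hausdorff max %.3f mm\n",
              mean(x$test_evaluation$accuracy_mm),
              max(x$test_evaluation$hausdorff_mm)))
  invisible(x)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$grid_table, file.path(out_dir, "grid_search.csv"),
                   row.names = FALSE)
  utils::write.csv(result$test_evaluation, file.path(out_dir, "test_evaluation.csv"),
                   row.names = FALSE)
  utils::write.csv(result$clinical, file.path(out_dir, "clinical_errors.csv"),
                   row.names = FALSE)
  utils::write.csv(result$compactness$curve, file.path(out_dir, "compactness.csv"),
                   row.names = FALSE)
  utils::write.csv(result$generalization, file.path(out_dir, "generalization.csv"),
                   row.names = FALSE)
  utils::write.csv(result$specificity$per_sample, file.path(out_dir, "specificity.csv"),
                   row.names = FALSE)
  save_model(result$model, file.path(out_dir, "shape_model.rssm"))
  for (i in seq_along(result$heatmaps)) {
    write_mesh(result$heatmaps[[i]],
               file.path(out_dir, sprintf("heatmap_case%02d.ply", i)))
  }
  report <- list(
    best_params = unclass(result$best_params),
    test_accuracy_mm = result$test_evaluation$accuracy_mm,
    test_hausdorff_mm = result$test_evaluation$hausdorff_mm,
    n_components = length(result$model$values),
    n_components_95 = n_components_for(result$compactness, 0.95),
    seed = result$config$seed)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
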
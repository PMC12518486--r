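#' Tidiers and plots for model and result objects
#'
#' `tidy()` returns one row per component / case / degree of freedom as a
#' tibble; `glance()` a one-row model summary; `autoplot()` the standard
#' diagnostic figure for the object.
#'
#' @param x object to tidy.
#' @param ... unused.
#' @return a tibble.
#' @name tidiers
NULL

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname tidiers
#' @export
tidy.shape_model <- function(x, ...) {
  cum <- cumsum(x$values) / sum(x$values)
  tibble::tibble(component = seq_along(x$values),
                 eigenvalue = x$values,
                 variance_fraction = x$values / sum(x$values),
                 cumulative_variance = cum)
}

#' @rdname tidiers
#' @export
glance.shape_model <- function(x, ...) {
  tibble::tibble(n_vertices = length(x$mean) / 3,
                 n_components = length(x$values),
                 n_training = x$n_training,
                 total_variance = sum(x$values),
                 n_components_95 = n_components_for(x, 0.95))
}

#' @rdname tidiers
#' @export
tidy.six_dof_error <- function(x, ...) {
  tibble::tibble(phi_x = x$phi_x, phi_z = x$phi_z, phi_y = x$phi_y,
                 delta_x = x$delta_x, delta_y = x$delta_y, delta_z = x$delta_z,
                 angle_3d = x$angle_3d, dist_3d = x$dist_3d,
                 gimbal_warning = x$gimbal_warning)
}

#' @rdname tidiers
#' @export
tidy.compactness <- function(x, ...) x$curve

#' @rdname tidiers
#' @export
tidy.specificity_summary <- function(x, ...) x$per_sample

#' @rdname tidiers
#' @export
glance.specificity_summary <- function(x, ...) {
  tibble::tibble(mean_accuracy_mm = x$mean_accuracy_mm,
                 max_accuracy_mm = x$max_accuracy_mm,
                 mean_hausdorff_mm = x$mean_hausdorff_mm,
                 max_hausdorff_mm = x$max_hausdorff_mm,
                 mode = x$mode)
}

#' @export
autoplot <- function(object, ...) UseMethod("autoplot")

#' @rdname tidiers
#' @param object object to plot.
#' @export
autoplot.compactness <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$n_components,
                               y = 100 * .data$cumulative_variance)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 95, linetype = "dotted") +
    ggplot2::labs(x = "Number of principal components",
                  y = "Cumulative variance (%)") +
    ggplot2::theme_minimal()
}

#' Plot a generalization curve
#' @param curve tibble from [generalization_curve()].
#' @return a ggplot.
#' @export
plot_generalization <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$n_training, y = .data$rmse_mm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Number of training meshes", y = "RMSE (mm)") +
    ggplot2::theme_minimal()
}

#' Plot the grid-search error surface
#' @param table tibble from [grid_search()].
#' @return a ggplot (error vs sigma, faceted by scale, coloured by noise).
#' @export
plot_grid_search <- function(table) {
  ggplot2::ggplot(table,
                  ggplot2::aes(x = .data$sigma, y = .data$mean_error_mm,
                               colour = factor(.data$noise))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~scale, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "sigma (mm)", y = "Mean prediction error (mm)",
                  colour = "noise") +
    ggplot2::theme_minimal()
}
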
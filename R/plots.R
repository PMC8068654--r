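#' @importFrom ggplot2 ggplot aes geom_point geom_col geom_line geom_hline
#'   facet_wrap labs theme_minimal autoplot position_dodge
NULL

#' Plot sphere-integrated densities per atom
#'
#' @param object an `integration_tbl` from [integrate_selection()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.integration_tbl <- function(object, ...) {
  ggplot(object, aes(x = factor(.data$atom, levels = unique(.data$atom)),
    y = .data$rho, fill = .data$chain)) +
    geom_col(position = position_dodge(width = 0.8), width = 0.7) +
    labs(x = NULL, y = "integrated density (map units × Å³)",
      fill = "chain") +
    theme_minimal()
}

#' Plot an integration report with population z-scores
#'
#' @param object an `integration_report` from [build_integration_report()].
#' @param ... unused.
#' @return a ggplot of the per-atom cluster z-scores with +/- 2 sigma
#'   guides.
#' @export
autoplot.integration_report <- function(object, ...) {
  rows <- object$rows
  ggplot(rows, aes(x = factor(.data$atom, levels = unique(.data$atom)),
    y = .data$rho_cluster, colour = .data$chain, group = .data$chain)) +
    geom_hline(yintercept = 0, colour = "grey60") +
    geom_hline(yintercept = c(-2, 2), linetype = 2, colour = "grey70") +
    geom_point(size = 2, position = position_dodge(width = 0.4)) +
    labs(x = NULL, y = "deviation from cluster mean (population σ)",
      colour = "chain") +
    theme_minimal()
}

#' Plot per-region scores of one or more model comparisons
#'
#' @param object a `model_comparison` (or pass extra ones via `...`).
#' @param ... further `model_comparison` objects to overlay.
#' @return a ggplot of per-region RSZD scores, one colour per model.
#' @export
autoplot.model_comparison <- function(object, ...) {
  extra <- purrr::keep(list(...), ~ inherits(.x, "model_comparison"))
  dat <- bind_rows(purrr::map(c(list(object), extra), tidy))
  ggplot(dat, aes(x = factor(.data$group, levels = unique(.data$group)),
    y = .data$rszd, fill = .data$model)) +
    geom_col(position = position_dodge(width = 0.8), width = 0.7) +
    labs(x = NULL, y = "region RSZD", fill = "model") +
    theme_minimal()
}

#' Plot a refinement energy trace
#'
#' @param object a `refinement` from [minimize()] or [refine_model()].
#' @param ... unused.
#' @return a ggplot of energy versus iteration.
#' @export
autoplot.refinement <- function(object, ...) {
  ggplot(object$trace, aes(x = .data$iter, y = .data$energy)) +
    geom_line() +
    geom_point(size = 1) +
    labs(x = "iteration", y = "energy (arbitrary units)") +
    theme_minimal()
}

#' Plot a density-grid section
#'
#' Extracts the grid section nearest `z` (cartesian, angstrom) and shows
#' it as a filled raster in sigma units.
#'
#' @param grid a [density_grid()].
#' @param z cartesian height of the section; defaults to the grid middle.
#' @return a ggplot.
#' @export
plot_map_section <- function(grid, z = NULL) {
  sp <- grid_spacing(grid)
  d <- dim(grid$values)
  if (is.null(z)) z <- grid$origin[3] + (d[3] - 1) / 2 * sp[3]
  k <- round((z - grid$origin[3]) / sp[3]) + 1
  k <- min(max(k, 1), d[3])
  sect <- grid$values[, , k]
  dat <- tidyr::expand_grid(
    i = seq_len(d[1]), j = seq_len(d[2])
  ) |>
    mutate(
      x = grid$origin[1] + (.data$i - 1) * sp[1],
      y = grid$origin[2] + (.data$j - 1) * sp[2],
      sigma = map_sigma(grid, sect[cbind(.data$i, .data$j)])
    )
  ggplot(dat, aes(.data$x, .data$y, fill = .data$sigma)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
      high = "navy") +
    ggplot2::coord_equal() +
    labs(x = "x (Å)", y = "y (Å)", fill = "σ") +
    theme_minimal()
}
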
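#' Trajectory fan plot for a grid of ensembles
#'
#' Mean GFAP time course per signal with a 95% confidence band
#' (mean +- 1.96 sd / sqrt(n) per time point), faceted noise level x dose —
#' the standard way to eyeball the response grid.
#'
#' @param ensembles List of `trajectory_ensemble` objects.
#' @param max_cells Spaghetti lines per panel drawn behind the band
#'   (default 30; 0 for band only).
#' @return A ggplot object.
#' @export
plot_trajectory_fans <- function(ensembles, max_cells = 30) {
  if (inherits(ensembles, "trajectory_ensemble")) ensembles <- list(ensembles)
  band <- purrr::map(ensembles, function(ens) {
    g <- ens$gfap
    n <- nrow(g)
    tibble::tibble(
      time = ens$time,
      mean = colMeans(g),
      half = 1.96 * apply(g, 2, stats::sd) / sqrt(n),
      ct_dose = ens$signal$ct_dose, noise_label = ens$signal$noise_label
    )
  }) |> purrr::list_rbind()
  cells <- purrr::map(ensembles, function(ens) {
    idx <- seq_len(min(max_cells, nrow(ens$gfap)))
    if (length(idx) == 0) return(NULL)
    tidyr::expand_grid(cell = idx, t_i = seq_along(ens$time)) |>
      dplyr::mutate(
        time = ens$time[.data$t_i],
        gfap = ens$gfap[cbind(.data$cell, .data$t_i)],
        ct_dose = ens$signal$ct_dose, noise_label = ens$signal$noise_label
      )
  }) |> purrr::list_rbind()
  p <- ggplot2::ggplot(band, ggplot2::aes(x = .data$time))
  if (!is.null(cells) && nrow(cells) > 0) {
    p <- p + ggplot2::geom_line(
      data = cells,
      ggplot2::aes(y = .data$gfap, group = .data$cell),
      linewidth = 0.2, alpha = 0.25, colour = "grey60"
    )
  }
  p +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$half,
                   ymax = .data$mean + .data$half),
      fill = "steelblue", alpha = 0.35
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "navy") +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$noise_label),
      cols = ggplot2::vars(.data$ct_dose), labeller = ggplot2::label_both
    ) +
    ggplot2::labs(x = "time (h)", y = "GFAP level") +
    ggplot2::theme_minimal()
}

#' Descriptor heatmaps over the signal grid
#'
#' Mean descriptor value per (dose, noise level) cell, one facet per
#' descriptor.
#'
#' @param descriptor_table Output of [describe_ensembles()].
#' @return A ggplot object.
#' @export
plot_descriptor_heatmap <- function(descriptor_table) {
  summ <- descriptor_table |>
    dplyr::group_by(.data$descriptor, .data$ct_dose, .data$noise_label) |>
    dplyr::summarise(mean_value = mean(.data$value, na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(
    x = factor(.data$ct_dose),
    y = factor(.data$noise_label,
               levels = rev(unique(descriptor_table$noise_label))),
    fill = .data$mean_value
  )) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(ggplot2::vars(.data$descriptor), scales = "free") +
    ggplot2::scale_fill_viridis_c(name = "mean") +
    ggplot2::labs(x = "CT dose (ng/ml)", y = "noise level") +
    ggplot2::theme_minimal()
}

#' Capacity bars with replicate error bars
#'
#' Mean +- sd of replicate capacities per condition from a
#' [run_replicates()] table.
#'
#' @param table A [run_replicates()] result.
#' @param x Which column to place on the x axis (default
#'   `"representation"`).
#' @return A ggplot object.
#' @export
plot_capacity_bars <- function(table, x = "representation") {
  summ <- summarize_replicates(table)
  summ$xvar <- interaction(summ[[x]],
                           if (x != "strategy") summ$strategy else
                             summ$representation, drop = TRUE)
  ggplot2::ggplot(summ, ggplot2::aes(
    x = .data$xvar, y = .data$mean_bits, fill = .data$model
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_bits - .data$sd_bits,
                   ymax = .data$mean_bits + .data$sd_bits),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25
    ) +
    ggplot2::labs(x = NULL, y = "channel capacity (bits)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @export
autoplot.capacity_estimate <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$signal),
                                   y = .data$weight)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1 / nrow(df), linetype = 2) +
    ggplot2::labs(
      x = "signal", y = "optimal input weight",
      title = sprintf("Channel capacity %.3f bits",
                      object$capacity_bits)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
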
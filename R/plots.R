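# ggplot2 quick-look figures for each result type.

#' Ethogram of behavior channels with quiescence bouts shaded
#'
#' @param behavior Behavior tibble (one or more animals; facetted by animal).
#' @param criteria [bout_criteria()] used to shade detected bouts.
#' @return A ggplot object.
#' @export
plot_bout_ethogram <- function(behavior, criteria = bout_criteria()) {
  bouts <- detect_quiescence_bouts(behavior, criteria)
  long <- behavior |>
    tidyr::pivot_longer(c("speed_mm_s", "curvature_deriv_rad_s", "pumping_hz"),
                        names_to = "channel", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value))
  if (nrow(bouts) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = bouts,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "pink", alpha = 0.5)
  }
  p +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(channel ~ animal_id, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = "Behavior channels and quiescence bouts")
}

#' Heatmap of quiescence modulation across classes and animals
#'
#' The screen's class-by-animal QMI matrix as a tile heatmap: rows are neuron
#' classes (ordered by mean QMI), columns are animals, grey tiles mark cells
#' where the class was not observed. Significant classes are starred.
#'
#' @param object A `quiescence_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot quiescence_screen
#' @export
autoplot.quiescence_screen <- function(object, ...) {
  long <- object$qmi_matrix |>
    tidyr::pivot_longer(-"class", names_to = "animal_id", values_to = "qmi")
  ord <- object$results |>
    dplyr::mutate(class = ifelse(.data$dv == "", .data$class_name,
                                 paste0(.data$class_name, .data$dv))) |>
    dplyr::arrange(.data$mean_qmi)
  long$class <- factor(long$class, levels = ord$class,
                       labels = ifelse(ord$significant,
                                       paste0(ord$class, " *"), ord$class))
  lim <- max(abs(long$qmi), na.rm = TRUE)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$animal_id, y = .data$class,
                                     fill = .data$qmi)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-lim, lim),
                                  na.value = "grey85",
                                  name = "QMI") +
    ggplot2::labs(x = "animal", y = "neuron class",
                  title = "Quiescence modulation (* significant at FDR)")
}

#' @rdname autoplot.quiescence_screen
#' @param screen A `quiescence_screen`.
#' @export
plot_qmi_heatmap <- function(screen) autoplot(screen)

#' Event-triggered average with standard-deviation band
#'
#' @param eta Output of [event_triggered_average()]; grouping columns (e.g.
#'   `class_name`) become facets.
#' @return A ggplot object.
#' @export
plot_eta <- function(eta) {
  extra <- setdiff(names(eta), c("offset_s", "mean", "sd", "n_events"))
  p <- ggplot2::ggplot(eta, ggplot2::aes(x = .data$offset_s, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time from bout onset (s)",
                  y = "normalized fluorescence",
                  title = "Event-triggered average (band: ± SD)")
  if (length(extra) > 0L) {
    p <- p + ggplot2::facet_wrap(stats::as.formula(
      paste("~", paste(extra, collapse = "+"))))
  }
  p
}
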
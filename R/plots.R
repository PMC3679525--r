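# ggplot2 views of the main result types. These return plot objects and
# never print or save.

#' @describeIn fit_split_tree node-and-edge diagram of the split tree:
#'   mean expression per node over time, point size giving gene counts.
#' @export
autoplot.split_tree <- function(object, ...) {
  nodes <- object$nodes
  edges <- object$edges %>%
    left_join(nodes %>%
                select(parent_id = "node_id", x0 = "timepoint", y0 = "mean"),
              by = "parent_id") %>%
    left_join(nodes %>%
                select(child_id = "node_id", x1 = "timepoint", y1 = "mean"),
              by = "child_id")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1),
                          colour = "grey55") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$timepoint, y = .data$mean,
                                     size = .data$n_genes),
                        colour = "steelblue") +
    ggplot2::scale_size_area(max_size = 8) +
    ggplot2::labs(x = "time (hr)", y = "mean log2 fold change",
                  size = "genes")
}

#' @describeIn pfm stacked base-frequency bars per motif position.
#' @export
autoplot.pfm <- function(object, ...) {
  tidy(object) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$position, y = .data$freq,
                                 fill = .data$base)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::scale_fill_brewer(palette = "Set1") +
    ggplot2::labs(x = "position", y = "frequency", fill = "base")
}

#' Mean wave trajectories
#'
#' Line per annotated wave of its mean log2 trajectory, labelled with
#' onset order.
#'
#' @param stats output of [wave_statistics()].
#' @return a ggplot.
#' @export
plot_wave_trajectories <- function(stats) {
  stats %>%
    mutate(wave = sprintf("wave %d (onset %s hr)", row_number(), .data$onset)) %>%
    select("wave", "mean_trajectory") %>%
    tidyr::unnest("mean_trajectory") %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$timepoint, y = .data$mean,
                                 colour = .data$wave)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (hr)", y = "mean log2 fold change",
                  colour = NULL)
}

#' Temporal binding profile across regions
#'
#' Median and interquartile band of the per-region log2 binding profile
#' over the timecourse.
#'
#' @param profile output of [log2_profile()] on binding RPKM.
#' @return a ggplot.
#' @export
plot_binding_profile <- function(profile) {
  profile %>%
    group_by(.data$timepoint) %>%
    summarise(mid = median(.data$log2fc),
              lo = stats::quantile(.data$log2fc, 0.25),
              hi = stats::quantile(.data$log2fc, 0.75), .groups = "drop") %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$timepoint, y = .data$mid)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = "time (hr)", y = "log2 binding RPKM vs 0 hr")
}

#' Cumulative response kinetics curve
#'
#' @param kinetics output of [response_kinetics()].
#' @return a ggplot.
#' @export
plot_response_kinetics <- function(kinetics) {
  ggplot2::ggplot(kinetics,
                  ggplot2::aes(x = .data$timepoint, y = .data$cum_fraction)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (hr)",
                  y = "cumulative fraction of regulated genes")
}
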
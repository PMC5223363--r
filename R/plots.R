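#' Heatmap of an age-group difference matrix
#'
#' Tiles show the per-pair difference in Fisher z between the earlier and
#' later group; pairs surviving FDR correction are marked with a dot.
#'
#' @param diff A `difference_matrix` from [difference_matrix_test()].
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_difference_matrix <- function(diff, title = NULL) {
  groups <- attr(diff, "groups")
  lab <- if (!is.null(groups)) paste(groups, collapse = " - ") else "difference"
  nodes <- unique(c(diff$node_a, diff$node_b))
  df <- dplyr::bind_rows(
    diff,
    dplyr::rename(diff, node_a = "node_b", node_b = "node_a",
                  network_a = "network_b", network_b = "network_a")
  )
  df$node_a <- factor(df$node_a, levels = nodes)
  df$node_b <- factor(df$node_b, levels = rev(nodes))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$node_a, y = .data$node_b,
                                        fill = .data$delta_z)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = df[df$significant, , drop = FALSE],
                        size = 0.6, colour = "black") +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", name = paste0("Δz (", lab, ")")) +
    ggplot2::labs(x = NULL, y = NULL, title = title) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  p
}

#' @export
autoplot.difference_matrix <- function(object, ...) {
  plot_difference_matrix(object, ...)
}

#' Least-squares means of the network x age-group interaction
#'
#' Point estimates with +/- 1 SE bars per network and age group — the
#' standard view of lifespan connectivity trajectories under the ANCOVA.
#'
#' @param result A `connlife_ancova` fit.
#' @return A ggplot object.
#' @export
plot_lsmeans <- function(result) {
  stopifnot(inherits(result, "connlife_ancova"))
  lsm <- result$lsmeans
  lsm$network <- factor(lsm$network, levels = unique(lsm$network))
  lsm$age_group <- factor(lsm$age_group, levels = unique(lsm$age_group))
  ggplot2::ggplot(lsm, ggplot2::aes(x = .data$age_group, y = .data$estimate,
                                    group = .data$network)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$estimate - .data$se,
                                          ymax = .data$estimate + .data$se),
                             size = 0.3) +
    ggplot2::facet_wrap(~network, nrow = 1L) +
    ggplot2::labs(x = "age group", y = "least-squares mean z(r) ± SE") +
    ggplot2::theme_minimal(base_size = 9)
}

#' @export
autoplot.connlife_ancova <- function(object, ...) plot_lsmeans(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
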
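# Plot helpers: network layout with hub-score sizing, StARS instability
# curve. Degradation box plots live in autoplot.mdm_degradation().

#' Plot a network with node size proportional to hub score
#'
#' Fruchterman-Reingold layout (seeded for reproducibility); MDM nodes,
#' when a lineage table is supplied, are highlighted.
#'
#' @param network An `mdm_network`.
#' @param lineage Optional lineage tibble with `node_id` and `is_mdm`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mdm_network <- function(network, lineage = NULL, seed = 1L, ...) {
  g <- network_igraph(network)
  xy <- with_seed_maybe(seed, igraph::layout_with_fr(g))
  nodes <- tibble(node = network$nodes, x = xy[, 1], y = xy[, 2])
  hs <- hub_scores_quietly(network)
  nodes <- left_join(nodes, hs, by = "node")
  nodes$is_mdm <- if (!is.null(lineage)) {
    lineage$is_mdm[match(nodes$node, lineage$node_id)]
  } else FALSE
  seg <- network$edges |>
    left_join(nodes[c("node", "x", "y")], by = c(from = "node")) |>
    left_join(nodes[c("node", "x", "y")], by = c(to = "node"),
              suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          color = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$hub_score,
                                     color = .data$is_mdm)) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "#2166ac", `TRUE` = "#b2182b"),
                                name = "MDM") +
    ggplot2::scale_size_continuous(range = c(1, 6), name = "hub score") +
    ggplot2::theme_void()
}

hub_scores_quietly <- function(network) {
  withCallingHandlers(hub_scores(network),
                      warning = function(w) invokeRestart("muffleWarning"))
}

#' Plot the StARS instability curve
#'
#' @param network An `mdm_network` carrying an instability table, or the
#'   result of [stars_select()].
#' @return A ggplot object.
#' @export
plot_instability <- function(network) {
  instab <- if (inherits(network, "mdm_network")) network$instability
            else network$instability
  if (is.null(instab)) abort("no instability curve recorded")
  sel <- if (inherits(network, "mdm_network")) network$selected_penalty
         else network$selected_penalty
  ggplot2::ggplot(instab, ggplot2::aes(x = .data$penalty)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$instability)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$monotone_instability),
                       linetype = "dashed") +
    ggplot2::geom_vline(xintercept = sel, color = "#b2182b") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "penalty (log scale)", y = "edge instability") +
    ggplot2::theme_minimal()
}
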
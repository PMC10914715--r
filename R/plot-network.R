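#' Plot a network structure
#'
#' Simple layered drawing of the DAG: nodes are placed by topological
#' depth (longest path from a root), arcs drawn left to right.
#'
#' @param net A valid `bnet`.
#' @return A ggplot object.
#' @export
plot_bnet <- function(net) {
  nodes <- bn_nodes(net)
  parents <- lapply(net$cpts, function(cp) cp$parents)
  depth <- setNames(rep(0L, length(nodes)), nodes)
  for (v in topo_order(parents)) {
    if (length(parents[[v]]) > 0) depth[v] <- max(depth[parents[[v]]]) + 1L
  }
  layout <- tibble(node = nodes, x = as.numeric(depth[nodes])) |>
    group_by(.data$x) |>
    mutate(y = seq_along(.data$node) - (n() + 1) / 2) |>
    ungroup()
  seg <- net$edges |>
    left_join(layout, by = c(from = "node")) |>
    rename(x0 = "x", y0 = "y") |>
    left_join(layout, by = c(to = "node"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x, yend = .data$y),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "inches")),
      color = "grey40") +
    ggplot2::geom_label(data = layout,
                        ggplot2::aes(x = .data$x, y = .data$y, label = .data$node)) +
    ggplot2::theme_void()
}
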
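# ggplot2 autoplot methods for the two result types.

#' Plot a gene network
#'
#' Fruchterman-Reingold layout (seeded for reproducibility) with edges
#' coloured by their origin criterion.
#'
#' @param object A `gene_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gene_network <- function(object, seed = 42L, ...) {
  if (igraph::vcount(object) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "empty network") +
             ggplot2::theme_void())
  }
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv))
  }
  set.seed(seed)
  xy <- igraph::layout_with_fr(object)
  nodes <- tibble(
    gene = igraph::V(object)$name,
    x = xy[, 1], y = xy[, 2]
  )
  ed <- tidy.gene_network(object)
  ed <- dplyr::left_join(
    ed, dplyr::rename(nodes, xa = "x", ya = "y"),
    by = c(gene_a = "gene")
  )
  ed <- dplyr::left_join(
    ed, dplyr::rename(nodes, xb = "x", yb = "y"),
    by = c(gene_b = "gene")
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb, colour = .data$origin),
      linewidth = 0.4, alpha = 0.7
    ) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y), size = 2) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$gene),
      vjust = -0.8, size = 3
    ) +
    ggplot2::scale_colour_brewer(palette = "Set1") +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "edge origin")
}

#' Plot pathway memberships
#'
#' Gene-by-pathway membership tiles, pathways ordered by size.
#'
#' @param object A `pathway_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pathway_result <- function(object, ...) {
  tab <- tidy.pathway_result(object)
  if (nrow(tab) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "no pathways") +
             ggplot2::theme_void())
  }
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$pathway, y = .data$gene,
                                    fill = .data$provenance)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_brewer(palette = "Pastel1") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "provenance")
}
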
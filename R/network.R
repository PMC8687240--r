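# Gene-network construction. An undirected edge joins two genes when the
# pair is mutually exclusive (exclusive degree >= lambda AND weight degree
# >= gamma, both over rate-filtered mutation genes) or when the
# mutation-expression connectivity criterion holds in either direction.
# Isolated genes do not appear in the network.

#' Network construction parameters
#'
#' Thresholds and modes for [build_network()] and [run_pipeline()].
#' Defaults: exclusivity threshold `lambda_excl = 0.95`, weight-degree
#' threshold `gamma_weight = 0.8`, signed connectivity, minimum mutation
#' rate 0.03 with a `>=` boundary.
#'
#' @param lambda_excl Exclusive-degree threshold, in (0, 1].
#' @param gamma_weight Weight-degree threshold, in \[0, 1\].
#' @param connectivity_mode `"signed"` or `"absolute"`; see
#'   [connectivity_pairs()].
#' @param min_mutation_rate Minimum per-gene mutation rate applied before
#'   exclusivity analysis.
#' @param rate_comparator `">="` (default) or `">"`.
#' @return A list of class `network_params`.
#' @export
network_params <- function(lambda_excl = 0.95,
                           gamma_weight = 0.8,
                           connectivity_mode = c("signed", "absolute"),
                           min_mutation_rate = 0.03,
                           rate_comparator = c(">=", ">")) {
  stopifnot(lambda_excl > 0, lambda_excl <= 1,
            gamma_weight >= 0, gamma_weight <= 1,
            min_mutation_rate >= 0, min_mutation_rate <= 1)
  structure(
    list(
      lambda_excl = lambda_excl,
      gamma_weight = gamma_weight,
      connectivity_mode = match.arg(connectivity_mode),
      min_mutation_rate = min_mutation_rate,
      rate_comparator = match.arg(rate_comparator)
    ),
    class = "network_params"
  )
}

#' Build the gene network from exclusivity and connectivity
#'
#' Creates an undirected graph over genes. An exclusivity edge joins two
#' mutation genes whose exclusive degree and weight degree reach the
#' `lambda_excl` and `gamma_weight` thresholds (boundary values included);
#' a connectivity edge joins a mutation gene to an expression gene whose
#' mean expression in the mutated samples is at least its cohort mean.
#' Edges arising from both criteria are annotated `"both"`. A gene with no
#' edges does not appear in the network.
#'
#' `mutation` is expected to be sample-aligned with `expression` and
#' already rate-filtered (the pipeline does both); exclusivity is evaluated
#' over all its genes, while expression genes enter only through
#' connectivity edges.
#'
#' @param mutation Binary mutation matrix (aligned, rate-filtered).
#' @param expression Optional expression matrix over the identical ordered
#'   samples; `NULL` builds an exclusivity-only network.
#' @param params A [network_params()] object.
#' @return An `igraph` graph of class `gene_network` with edge attribute
#'   `origin` in `{"exclusivity", "connectivity", "both"}` and the
#'   parameters stored as graph attributes.
#' @export
build_network <- function(mutation, expression = NULL,
                          params = network_params()) {
  check_mutation_matrix(mutation)
  if (ncol(mutation) == 0) {
    abort("no genes left in the mutation matrix; relax the mutation-rate filter")
  }
  scores <- pair_scores(mutation)
  excl <- dplyr::filter(
    scores,
    .data$exclusive_degree >= params$lambda_excl,
    .data$weight_degree >= params$gamma_weight
  )
  excl_edges <- tibble(
    gene_a = excl$gene_i, gene_b = excl$gene_j,
    criterion = "exclusivity"
  )
  conn_edges <- tibble(gene_a = character(), gene_b = character(),
                       criterion = character())
  if (!is.null(expression)) {
    check_expression_matrix(expression)
    cp <- connectivity_pairs(mutation, expression,
                             mode = params$connectivity_mode)
    cp <- dplyr::filter(cp, .data$passes)
    conn_edges <- tibble(
      gene_a = pmin(cp$mutation_gene, cp$expression_gene),
      gene_b = pmax(cp$mutation_gene, cp$expression_gene),
      criterion = "connectivity"
    )
    conn_edges <- dplyr::distinct(conn_edges)
  }
  edges <- dplyr::bind_rows(excl_edges, conn_edges)
  edges <- edges |>
    dplyr::group_by(.data$gene_a, .data$gene_b) |>
    dplyr::summarise(
      origin = if (dplyr::n() > 1) "both" else .data$criterion[1],
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
  if (nrow(edges) == 0) {
    warn("gene network has no edges under the given thresholds")
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  }
  g <- igraph::set_graph_attr(g, "lambda_excl", params$lambda_excl)
  g <- igraph::set_graph_attr(g, "gamma_weight", params$gamma_weight)
  g <- igraph::set_graph_attr(g, "connectivity_mode",
                              params$connectivity_mode)
  class(g) <- c("gene_network", class(g))
  g
}

#' Edge list of a gene network
#'
#' @param x A `gene_network` from [build_network()].
#' @param ... Unused.
#' @return A tibble with columns `gene_a`, `gene_b` (lexicographically
#'   ordered within each row) and `origin`.
#' @export
tidy.gene_network <- function(x, ...) {
  if (igraph::ecount(x) == 0) {
    return(tibble(gene_a = character(), gene_b = character(),
                  origin = character()))
  }
  ends <- igraph::as_edgelist(x)
  out <- tibble(
    gene_a = pmin(ends[, 1], ends[, 2]),
    gene_b = pmax(ends[, 1], ends[, 2]),
    origin = igraph::edge_attr(x, "origin")
  )
  dplyr::arrange(out, .data$gene_a, .data$gene_b)
}

#' One-row summary of a gene network
#'
#' @param x A `gene_network`.
#' @param ... Unused.
#' @return A one-row tibble: node and edge counts, edge counts by origin,
#'   and the thresholds used.
#' @export
glance.gene_network <- function(x, ...) {
  ed <- tidy.gene_network(x)
  tibble(
    n_genes = igraph::vcount(x),
    n_edges = nrow(ed),
    n_exclusivity = sum(ed$origin == "exclusivity"),
    n_connectivity = sum(ed$origin == "connectivity"),
    n_both = sum(ed$origin == "both"),
    lambda_excl = igraph::graph_attr(x, "lambda_excl"),
    gamma_weight = igraph::graph_attr(x, "gamma_weight")
  )
}

#' @export
print.gene_network <- function(x, ...) {
  s <- glance.gene_network(x)
  cat(sprintf(
    "<gene_network> %d genes, %d edges (%d exclusivity / %d connectivity / %d both); lambda=%.3g gamma=%.3g\n",
    s$n_genes, s$n_edges, s$n_exclusivity, s$n_connectivity, s$n_both,
    s$lambda_excl, s$gamma_weight
  ))
  invisible(x)
}

#' Write a gene network as an edge-list TSV
#'
#' Three columns: `gene_a`, `gene_b`, `origin`.
#'
#' @param network A `gene_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  readr::write_tsv(tidy.gene_network(network), path, progress = FALSE)
  invisible(path)
}

#' Write a gene network as GraphML
#'
#' @param network A `gene_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  g <- network
  class(g) <- setdiff(class(g), "gene_network")
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
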
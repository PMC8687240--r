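# End-to-end orchestration: read -> align -> rate-filter -> network ->
# cliques -> merge -> report. Fully deterministic for fixed inputs and
# parameters; all outputs are plain text (TSV / GMT / JSON).

#' Run the full dysregulated-pathway pipeline
#'
#' Accepts matrices or dense-TSV paths for the mutation and expression
#' inputs; aligns the cohorts to their shared samples, applies the
#' mutation-rate filter, builds the exclusivity/connectivity gene network,
#' enumerates cliques (maximal cliques by default, k-clique percolation
#' communities in `"cpm"` mode) and merges overlapping cliques by overlap
#' score. If `output_dir` is given, writes `edges.tsv`, `pathways.gmt` and
#' `report.json` there.
#'
#' @param mutation Binary mutation matrix, or path to one (dense TSV).
#' @param expression Expression matrix or path, or `NULL` for an
#'   exclusivity-only run.
#' @param params A [network_params()].
#' @param min_clique_size Minimum clique size (default 3).
#' @param overlap_threshold Strict merge threshold (default 0.25).
#' @param clique_mode `"maximal"` (default) or `"cpm"`.
#' @param cpm_k Clique size for `"cpm"` mode (default = `min_clique_size`).
#' @param normalize_expression If `TRUE`, per-gene z-scores the expression
#'   matrix first (default `FALSE`: values are used as supplied).
#' @param output_dir Optional directory for the text outputs.
#' @return A list of class `dyspath_result`: `pathways`
#'   (`pathway_result`), `network` (`gene_network`), `summary` (cohort
#'   summary of the filtered matrix), `counts` (per-stage counts), and the
#'   parameters.
#' @export
run_pipeline <- function(mutation, expression = NULL,
                         params = network_params(),
                         min_clique_size = 3,
                         overlap_threshold = 0.25,
                         clique_mode = c("maximal", "cpm"),
                         cpm_k = NULL,
                         normalize_expression = FALSE,
                         output_dir = NULL) {
  clique_mode <- match.arg(clique_mode)
  if (is.character(mutation)) mutation <- read_mutation_matrix(mutation)
  if (is.character(expression)) expression <- read_expression_matrix(expression)
  check_mutation_matrix(mutation)

  if (!is.null(expression)) {
    check_expression_matrix(expression)
    aligned <- align_cohort(mutation, expression)
    mutation <- aligned$mutation
    expression <- aligned$expression
    if (normalize_expression) expression <- scale_expression(expression)
  }

  filtered <- filter_by_mutation_rate(
    mutation,
    min_rate = params$min_mutation_rate,
    comparator = params$rate_comparator
  )
  if (ncol(filtered) == 0) {
    abort(paste0(
      "network stage: no genes pass the mutation-rate filter (rate ",
      params$rate_comparator, " ", params$min_mutation_rate, ")"
    ))
  }
  summary <- summarize_cohort(filtered)

  network <- build_network(filtered, expression, params)
  cliques <- if (clique_mode == "maximal") {
    maximal_cliques(network, min_size = min_clique_size)
  } else {
    k_clique_communities(network, k = cpm_k %||% min_clique_size)
  }
  pathways <- merge_pathways(cliques, threshold = overlap_threshold,
                             min_size = min_clique_size)
  if (length(pathways$pathways) == 0) {
    warn("no pathways detected (no cliques of the requested size)")
  }

  result <- structure(
    list(
      pathways = pathways,
      network = network,
      cliques = cliques,
      summary = summary,
      counts = list(
        n_samples = nrow(filtered),
        genes_before_filter = ncol(mutation),
        genes_after_filter = ncol(filtered),
        expression_genes = if (is.null(expression)) 0L else ncol(expression),
        network = as.list(glance.gene_network(network)[
          , c("n_genes", "n_edges", "n_exclusivity", "n_connectivity",
              "n_both")]),
        cliques_found = length(cliques),
        merges_performed = pathways$merges_performed,
        pathway_sizes = unname(lengths(pathways$pathways))
      ),
      params = params,
      min_clique_size = min_clique_size,
      overlap_threshold = overlap_threshold,
      clique_mode = clique_mode
    ),
    class = "dyspath_result"
  )

  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    write_edge_list(network, file.path(output_dir, "edges.tsv"))
    write_gmt(pathways, file.path(output_dir, "pathways.gmt"))
    jsonlite::write_json(report_run(result),
                         file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

#' Machine-readable run report
#'
#' Per-stage counts, pathway memberships, the parameters used and the
#' package version, as a list ready for JSON serialisation.
#'
#' @param result A `dyspath_result` from [run_pipeline()].
#' @return A named list.
#' @export
report_run <- function(result) {
  stopifnot(inherits(result, "dyspath_result"))
  list(
    package = "dyspathr",
    version = as.character(utils::packageVersion("dyspathr")),
    parameters = list(
      lambda_excl = result$params$lambda_excl,
      gamma_weight = result$params$gamma_weight,
      connectivity_mode = result$params$connectivity_mode,
      min_mutation_rate = result$params$min_mutation_rate,
      rate_comparator = result$params$rate_comparator,
      min_clique_size = result$min_clique_size,
      overlap_threshold = result$overlap_threshold,
      clique_mode = result$clique_mode
    ),
    cohort = as.list(result$summary),
    counts = result$counts,
    pathways = lapply(
      setNames(names(result$pathways$pathways),
               names(result$pathways$pathways)),
      function(nm) list(
        size = length(result$pathways$pathways[[nm]]),
        provenance = result$pathways$provenance[[nm]],
        members = result$pathways$pathways[[nm]]
      )
    )
  )
}

#' @export
print.dyspath_result <- function(x, ...) {
  cat(sprintf(
    "<dyspath_result> %d samples, %d/%d genes past rate filter\n",
    x$counts$n_samples, x$counts$genes_after_filter,
    x$counts$genes_before_filter
  ))
  print(x$network)
  cat(sprintf("  %d clique(s) of size >= %d\n", x$counts$cliques_found,
              x$min_clique_size))
  print(x$pathways)
  invisible(x)
}

#' @export
tidy.dyspath_result <- function(x, ...) tidy.pathway_result(x$pathways)

#' @export
glance.dyspath_result <- function(x, ...) {
  dplyr::bind_cols(
    x$summary,
    glance.pathway_result(x$pathways)
  )
}
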
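# Clique detection in the gene network and the overlap-score merge that
# turns cliques into dysregulated pathways. Enumeration is delegated to
# igraph (Bron-Kerbosch with pivoting); the clique-percolation communities
# and the iterative merge are implemented here.

#' Maximal cliques of a gene network
#'
#' All maximal cliques with at least `min_size` members, as sorted gene-id
#' vectors in a deterministic order: size descending, then lexicographic on
#' the member list. Every returned set induces a complete subgraph and no
#' returned set is contained in another.
#'
#' @param network A `gene_network` (or any undirected igraph graph).
#' @param min_size Minimum clique size (default 3; an isolated edge is a
#'   weak module).
#' @return A list of character vectors (possibly empty).
#' @export
maximal_cliques <- function(network, min_size = 3) {
  stopifnot(min_size >= 2)
  if (igraph::ecount(network) == 0) return(list())
  cl <- igraph::max_cliques(network, min = min_size)
  sets <- lapply(cl, function(v) sort(igraph::V(network)$name[v]))
  order_gene_sets(sets)
}

#' k-clique percolation communities
#'
#' Communities in the clique-percolation sense: two k-cliques are adjacent
#' when they share k-1 nodes, and a community is the union of the k-cliques
#' in one connected component of that adjacency relation. This is the
#' clustering model behind the CFinder tool and is offered as an
#' alternative to maximal-clique enumeration.
#'
#' @param network A `gene_network` (or any undirected igraph graph).
#' @param k Clique size for percolation (>= 2).
#' @return A list of character vectors (gene sets), ordered by size
#'   descending then lexicographically.
#' @export
k_clique_communities <- function(network, k = 3) {
  stopifnot(k >= 2)
  if (igraph::ecount(network) == 0) return(list())
  kcl <- igraph::cliques(network, min = k, max = k)
  if (length(kcl) == 0) return(list())
  members <- lapply(kcl, function(v) sort(igraph::V(network)$name[v]))
  nk <- length(members)
  # adjacency between k-cliques: share exactly k-1 nodes
  adj_edges <- NULL
  if (nk > 1) {
    pairs <- combn(nk, 2)
    share <- vapply(
      seq_len(ncol(pairs)),
      function(p) length(intersect(members[[pairs[1, p]]],
                                   members[[pairs[2, p]]])),
      integer(1)
    )
    adj_edges <- pairs[, share == k - 1, drop = FALSE]
  }
  og <- igraph::make_empty_graph(n = nk, directed = FALSE)
  if (!is.null(adj_edges) && ncol(adj_edges) > 0) {
    og <- igraph::add_edges(og, as.vector(adj_edges))
  }
  comp <- igraph::components(og)$membership
  comms <- lapply(
    split(seq_len(nk), comp),
    function(idx) sort(unique(unlist(members[idx])))
  )
  order_gene_sets(unname(comms))
}

#' Overlap score between two gene sets
#'
#' `|A ^ B|^2 / (|A| * |B|)`. Two equal-size sets sharing half their
#' members score exactly 0.25, the merge threshold; disjoint sets score 0
#' and identical sets 1.
#'
#' @param a,b Non-empty character vectors of gene identifiers.
#' @return A number in \[0, 1\].
#' @export
overlap_score <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0 || length(b) == 0) {
    abort("overlap score undefined for an empty gene set")
  }
  length(intersect(a, b))^2 / (length(a) * length(b))
}

#' Iteratively merge overlapping gene sets into pathways
#'
#' Repeatedly finds the pair of sets with the highest overlap score and
#' replaces it with the union, as long as that highest score is strictly
#' above `threshold` (a score exactly at the threshold does not merge).
#' Ties on the highest score are broken deterministically: the pair whose
#' sorted member lists are lexicographically smallest is merged. Duplicate
#' input sets are collapsed before merging. After each merge the scores
#' against all surviving sets are recomputed, so a merged set is an
#' ordinary set thereafter.
#'
#' @param sets A list of character vectors (e.g. from
#'   [maximal_cliques()]).
#' @param threshold Strict merge threshold in (0, 1); default 0.25.
#' @param min_size Recorded minimum clique size (metadata only).
#' @return A `pathway_result`: final pathways (size-descending, named
#'   `P1`, `P2`, ...), per-pathway provenance (`"clique"` or `"merged"`),
#'   the input cliques each pathway absorbed, and the merge count.
#' @export
merge_pathways <- function(sets, threshold = 0.25, min_size = 3) {
  stopifnot(threshold > 0, threshold < 1)
  sets <- lapply(sets, function(s) sort(unique(s)))
  if (length(sets) == 0) {
    return(new_pathway_result(list(), list(), threshold, min_size, 0L, 0L))
  }
  if (any(lengths(sets) == 0)) abort("gene sets must be non-empty")
  sets <- order_gene_sets(sets)
  keys <- vapply(sets, paste, character(1), collapse = "\r")
  dup <- duplicated(keys)
  sets <- sets[!dup]
  n_input <- length(sets)
  input_ids <- paste0("C", seq_len(n_input))
  history <- as.list(input_ids)
  merges <- 0L
  while (length(sets) > 1) {
    best <- highest_overlap_pair(sets)
    if (best$score <= threshold) break
    i <- best$i
    j <- best$j
    merged <- sort(union(sets[[i]], sets[[j]]))
    merged_hist <- c(history[[i]], history[[j]])
    sets <- c(sets[-c(i, j)], list(merged))
    history <- c(history[-c(i, j)], list(merged_hist))
    merges <- merges + 1L
  }
  ord <- gene_set_order(sets)
  new_pathway_result(sets[ord], history[ord], threshold, min_size,
                     merges, n_input)
}

# Highest-OS pair with the deterministic lexicographic tie-break.
highest_overlap_pair <- function(sets) {
  n <- length(sets)
  keys <- vapply(sets, paste, character(1), collapse = "\r")
  best <- list(score = -Inf, i = 0L, j = 0L, ka = "", kb = "")
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      os <- overlap_score(sets[[i]], sets[[j]])
      if (os < best$score) next
      ka <- min(keys[i], keys[j])
      kb <- max(keys[i], keys[j])
      better <- os > best$score ||
        (ka < best$ka) || (ka == best$ka && kb < best$kb)
      if (better) best <- list(score = os, i = i, j = j, ka = ka, kb = kb)
    }
  }
  best
}

new_pathway_result <- function(sets, history, threshold, min_size,
                               merges, n_input) {
  names(sets) <- if (length(sets)) paste0("P", seq_along(sets)) else NULL
  names(history) <- names(sets)
  structure(
    list(
      pathways = sets,
      provenance = vapply(
        history, function(h) if (length(h) > 1) "merged" else "clique",
        character(1)
      ),
      history = history,
      overlap_threshold = threshold,
      min_clique_size = min_size,
      merges_performed = merges,
      n_input_sets = n_input
    ),
    class = "pathway_result"
  )
}

# size descending, then lexicographic on the member list
gene_set_order <- function(sets) {
  if (length(sets) == 0) return(integer())
  keys <- vapply(sets, paste, character(1), collapse = "\r")
  order(-lengths(sets), keys)
}

order_gene_sets <- function(sets) sets[gene_set_order(sets)]

#' Gene-to-pathway membership table
#'
#' @param x A `pathway_result`.
#' @param ... Unused.
#' @return A tibble with columns `pathway`, `gene`, `provenance`,
#'   `n_cliques_merged`.
#' @export
tidy.pathway_result <- function(x, ...) {
  if (length(x$pathways) == 0) {
    return(tibble(pathway = character(), gene = character(),
                  provenance = character(), n_cliques_merged = integer()))
  }
  purrr::map_dfr(names(x$pathways), function(nm) {
    tibble(
      pathway = nm,
      gene = x$pathways[[nm]],
      provenance = x$provenance[[nm]],
      n_cliques_merged = length(x$history[[nm]])
    )
  })
}

#' One-row summary of a pathway result
#'
#' @param x A `pathway_result`.
#' @param ... Unused.
#' @return A one-row tibble: pathway count, total genes, largest pathway,
#'   merges performed, threshold.
#' @export
glance.pathway_result <- function(x, ...) {
  tibble(
    n_pathways = length(x$pathways),
    n_genes = length(unique(unlist(x$pathways))),
    largest_pathway = if (length(x$pathways)) max(lengths(x$pathways)) else 0L,
    n_input_sets = x$n_input_sets,
    merges_performed = x$merges_performed,
    overlap_threshold = x$overlap_threshold
  )
}

#' @export
print.pathway_result <- function(x, ...) {
  cat(sprintf(
    "<pathway_result> %d pathway(s) from %d clique(s), %d merge(s), OS threshold %g\n",
    length(x$pathways), x$n_input_sets, x$merges_performed,
    x$overlap_threshold
  ))
  for (nm in names(x$pathways)) {
    mem <- x$pathways[[nm]]
    shown <- paste(head(mem, 8), collapse = ", ")
    if (length(mem) > 8) shown <- paste0(shown, ", ...")
    cat(sprintf("  %s (%d genes, %s): %s\n", nm, length(mem),
                x$provenance[[nm]], shown))
  }
  invisible(x)
}

#' Write pathways in GMT format
#'
#' One tab-separated line per pathway: name, description (provenance and
#' the cliques merged into it), then the member genes.
#'
#' @param result A `pathway_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(result, path) {
  lines <- vapply(names(result$pathways), function(nm) {
    desc <- paste0(result$provenance[[nm]], ":",
                   paste(result$history[[nm]], collapse = "+"))
    paste(c(nm, desc, result$pathways[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
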
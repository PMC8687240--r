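# Independent brute-force oracles and small random-instance generators.
# These deliberately avoid the package's vectorised code paths: metrics are
# recomputed by explicit set arithmetic over sample-id lists, connectivity
# by per-sample summation loops, and cliques by exhaustive enumeration of
# all vertex subsets.

# direct set-arithmetic pair metrics from explicit sample lists
bf_pair_metrics <- function(M, gi, gj) {
  ci <- rownames(M)[M[, gi] == 1]
  cj <- rownames(M)[M[, gj] == 1]
  un <- length(unique(c(ci, cj)))
  ov <- sum(ci %in% cj)
  list(
    ed = un / (length(ci) + length(cj)),
    cd = un / nrow(M),
    wd = 1 - ov / min(length(ci), length(cj))
  )
}

# per-sample summation connectivity criterion for one (h, k) pair
bf_connectivity_pass <- function(M, E, h, k) {
  mut <- which(M[, h] == 1)
  mean(E[mut, k]) >= mean(E[, k])
}

# exhaustive maximal-clique enumeration over all vertex subsets (n <= 12)
bf_maximal_cliques <- function(adj, min_size) {
  n <- nrow(adj)
  stopifnot(n <= 14)
  ids <- rownames(adj)
  complete <- list()
  for (mask in 1:(2^n - 1)) {
    mem <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) != 0)
    if (length(mem) < min_size) next
    sub <- adj[mem, mem, drop = FALSE]
    diag(sub) <- TRUE
    if (all(sub)) complete[[length(complete) + 1]] <- mem
  }
  maximal <- Filter(function(mem) {
    outside <- setdiff(seq_len(n), mem)
    !any(vapply(outside, function(v) all(adj[v, mem]), logical(1)))
  }, complete)
  sets <- lapply(maximal, function(mem) sort(ids[mem]))
  sets[order(-lengths(sets),
             vapply(sets, paste, character(1), collapse = "\r"))]
}

# random undirected graph as an igraph object plus its adjacency matrix
random_gene_graph <- function(n, p) {
  ids <- sprintf("g%02d", seq_len(n))
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  pairs <- combn(n, 2)
  on_edges <- runif(ncol(pairs)) < p
  for (e in which(on_edges)) {
    adj[pairs[1, e], pairs[2, e]] <- TRUE
    adj[pairs[2, e], pairs[1, e]] <- TRUE
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  list(graph = g, adj = adj)
}

# random binary cohort in which every gene is mutated at least once
random_cohort_matrix <- function(m, n, p = 0.3) {
  ids_s <- sprintf("s%03d", seq_len(m))
  ids_g <- sprintf("g%02d", seq_len(n))
  M <- matrix(as.integer(runif(m * n) < p), m, n,
              dimnames = list(ids_s, ids_g))
  for (j in which(colSums(M) == 0)) M[sample(m, 1), j] <- 1L
  M
}

# mutation matrix realising prescribed coverage sizes and overlap over m samples
coverage_pair_matrix <- function(m, size_i, size_j, overlap,
                                 samples = sprintf("s%03d", seq_len(m))) {
  stopifnot(size_i + size_j - overlap <= m)
  M <- matrix(0L, m, 2, dimnames = list(samples, c("gi", "gj")))
  M[seq_len(size_i), "gi"] <- 1L
  first_j <- size_i - overlap + 1
  M[seq(first_j, first_j + size_j - 1), "gj"] <- 1L
  M
}

write_tsv_lines <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}
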
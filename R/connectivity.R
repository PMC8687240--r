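# Mutation-to-expression connectivity. The connectivity matrix t(A) %*% E
# sums each expression gene's values over the samples in which a mutation
# gene is mutated; dividing by the gene's mutation count gives the mean
# expression in mutated samples, which the criterion compares against the
# cohort-wide mean. Because t(A) %*% E at (h, k) equals t(E) %*% A at
# (k, h), the mutation-on-expression and expression-on-mutation forms of
# the criterion coincide entry-for-entry and are evaluated once.

#' Mutation-expression connectivity matrix
#'
#' Entry (h, k) is the sum of expression gene k's values over the samples
#' in which mutation gene h is mutated: `t(A) %*% E`.
#'
#' @param mutation Binary mutation matrix (samples x mutation genes).
#' @param expression Numeric expression matrix (samples x expression
#'   genes) over the identical ordered sample axis.
#' @return A numeric matrix, rows = mutation genes, cols = expression
#'   genes.
#' @export
connectivity_matrix <- function(mutation, expression) {
  if (!identical(rownames(mutation), rownames(expression))) {
    abort("mutation and expression matrices must share an identical ordered sample axis (run align_cohort first)")
  }
  A <- mutation
  storage.mode(A) <- "double"
  crossprod(A, expression)
}

#' Evaluate the per-pair connectivity criterion
#'
#' For every (mutation gene h, expression gene k) pair with distinct gene
#' identity, a connectivity holds when the mean expression of k over the
#' samples mutated in h is at least the cohort-wide mean of k (ties at the
#' boundary pass). In `"absolute"` mode both means are taken over
#' `abs(expression)`, which detects dysregulation of centered data in
#' either direction; the default `"signed"` mode applies the criterion to
#' the values as supplied. Mutation genes mutated in no sample are skipped
#' with a message (the criterion is undefined for them), not errors.
#'
#' @param mutation Binary mutation matrix.
#' @param expression Expression matrix over the identical ordered samples.
#' @param mode `"signed"` (default) or `"absolute"`.
#' @return A tibble with columns `mutation_gene`, `expression_gene`,
#'   `mean_in_mutated`, `mean_overall`, `passes`.
#' @export
connectivity_pairs <- function(mutation, expression,
                               mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  if (!identical(rownames(mutation), rownames(expression))) {
    abort("mutation and expression matrices must share an identical ordered sample axis (run align_cohort first)")
  }
  E <- if (mode == "absolute") abs(expression) else expression
  counts <- colSums(mutation)
  zero <- names(counts)[counts == 0]
  if (length(zero) > 0) {
    inform(paste0(
      "skipping ", length(zero),
      " mutation gene(s) with zero mutated samples: ",
      paste(head(zero, 5), collapse = ", "),
      if (length(zero) > 5) ", ..." else ""
    ))
  }
  keep <- names(counts)[counts > 0]
  if (length(keep) == 0 || ncol(E) == 0) {
    return(tibble(
      mutation_gene = character(), expression_gene = character(),
      mean_in_mutated = double(), mean_overall = double(),
      passes = logical()
    ))
  }
  C <- connectivity_matrix(mutation[, keep, drop = FALSE], E)
  mean_mut <- C / counts[keep]
  overall <- colMeans(E)
  out <- tibble(
    mutation_gene = rep(keep, times = ncol(E)),
    expression_gene = rep(colnames(E), each = length(keep)),
    mean_in_mutated = as.vector(mean_mut),
    mean_overall = rep(unname(overall), each = length(keep))
  )
  out <- dplyr::filter(out, .data$mutation_gene != .data$expression_gene)
  out$passes <- out$mean_in_mutated >= out$mean_overall
  dplyr::arrange(out, .data$mutation_gene, .data$expression_gene)
}

#' Write connectivity pair evaluations to TSV
#'
#' @param pairs Tibble from [connectivity_pairs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_connectivity_pairs <- function(pairs, path) {
  readr::write_tsv(pairs, path, progress = FALSE)
  invisible(path)
}
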
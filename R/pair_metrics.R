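# Pairwise exclusivity statistics between mutated genes. The coverage of a
# gene is the set of samples carrying a mutation in it; for a gene pair the
# exclusive degree compares the union coverage to the summed coverages, and
# the weight degree penalises overlap relative to the smaller coverage so
# that a small coverage nested inside a large one is not mistaken for
# exclusivity.

#' Coverage set of a gene
#'
#' The set of samples in which `gene` is mutated.
#'
#' @param mutation Binary mutation matrix.
#' @param gene Gene identifier (must be a column of `mutation`).
#' @return Character vector of sample identifiers.
#' @export
coverage_set <- function(mutation, gene) {
  if (!gene %in% colnames(mutation)) {
    abort(paste0("unknown gene: '", gene, "'"))
  }
  rownames(mutation)[mutation[, gene] == 1]
}

#' Exclusive degree of two coverage sets
#'
#' `|ci U cj| / (|ci| + |cj|)`: 1 when the two coverages are disjoint
#' (perfect mutual exclusivity), 0.5 when they are identical. Undefined when
#' either set is empty (genes with zero coverage never survive the
#' mutation-rate filter).
#'
#' @param ci,cj Character vectors of sample identifiers (coverage sets).
#' @return A number in \[0.5, 1\].
#' @export
exclusive_degree <- function(ci, cj) {
  if (length(ci) == 0 || length(cj) == 0) {
    abort("exclusive degree undefined for an empty coverage set")
  }
  length(union(ci, cj)) / (length(ci) + length(cj))
}

#' Coverage degree of two coverage sets
#'
#' `|ci U cj| / m`: the fraction of the cohort covered by the pair.
#' Reported for completeness; it does not enter the network edge criterion.
#'
#' @param ci,cj Character vectors of sample identifiers.
#' @param m Number of samples in the cohort.
#' @return A number in \[0, 1\].
#' @export
coverage_degree <- function(ci, cj, m) {
  stopifnot(m >= 1)
  length(union(ci, cj)) / m
}

#' Weight degree of two coverage sets
#'
#' `1 - |ci ^ cj| / min(|ci|, |cj|)`: 1 for disjoint coverages, 0 when one
#' coverage is contained in the other. Pairs with very unbalanced coverages
#' can reach a high exclusive degree while one gene's coverage nests inside
#' the other's; the weight degree filters those spurious pairs.
#'
#' @param ci,cj Character vectors of sample identifiers.
#' @return A number in \[0, 1\].
#' @export
weight_degree <- function(ci, cj) {
  if (length(ci) == 0 || length(cj) == 0) {
    abort("weight degree undefined for an empty coverage set")
  }
  1 - length(intersect(ci, cj)) / min(length(ci), length(cj))
}

#' All pairwise exclusivity scores for a mutation cohort
#'
#' Computes the exclusive degree, coverage degree and weight degree for
#' every unordered pair of genes with non-empty coverage, using the
#' cross-product identity: the pairwise intersection sizes are
#' `t(A) %*% A` for the binary incidence matrix `A`. Genes with zero
#' coverage (possible only before rate filtering) are skipped.
#'
#' @param mutation Binary mutation matrix.
#' @return A tibble with one row per unordered gene pair (`gene_i` <
#'   `gene_j` lexicographically): columns `gene_i`, `gene_j`,
#'   `exclusive_degree`, `coverage_degree`, `weight_degree`.
#' @export
pair_scores <- function(mutation) {
  check_mutation_matrix(mutation)
  cov <- colSums(mutation)
  keep <- names(cov)[cov > 0]
  if (length(keep) < 2) {
    return(tibble(
      gene_i = character(), gene_j = character(),
      exclusive_degree = double(), coverage_degree = double(),
      weight_degree = double()
    ))
  }
  A <- mutation[, keep, drop = FALSE]
  storage.mode(A) <- "double"
  m <- nrow(A)
  ov <- crossprod(A)            # |Gamma_i ^ Gamma_j|
  sz <- unname(diag(ov))
  idx <- which(upper.tri(ov), arr.ind = TRUE)
  si <- sz[idx[, 1]]
  sj <- sz[idx[, 2]]
  inter <- ov[idx]
  uni <- si + sj - inter
  out <- tibble(
    gene_i = keep[idx[, 1]],
    gene_j = keep[idx[, 2]],
    exclusive_degree = uni / (si + sj),
    coverage_degree = uni / m,
    weight_degree = 1 - inter / pmin(si, sj)
  )
  # canonical pair order: gene_i < gene_j, rows sorted
  swap <- out$gene_i > out$gene_j
  tmp <- out$gene_i[swap]
  out$gene_i[swap] <- out$gene_j[swap]
  out$gene_j[swap] <- tmp
  dplyr::arrange(out, .data$gene_i, .data$gene_j)
}

#' Write pairwise exclusivity scores to TSV
#'
#' @param scores Tibble from [pair_scores()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_scores <- function(scores, path) {
  readr::write_tsv(scores, path, progress = FALSE)
  invisible(path)
}
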
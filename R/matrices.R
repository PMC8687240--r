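# Readers, writers, alignment, filtering and summaries for the paired
# sample-by-gene mutation (binary) and expression (real-valued) matrices.
# Both are held as base matrices with rownames = sample ids and
# colnames = gene ids; samples are rows throughout the package.

#' Read a binary somatic mutation matrix
#'
#' Reads a sample-by-gene 0/1 incidence matrix of somatic mutations. Two
#' dialects are supported: `dense_tsv` (tab-separated; header row of gene
#' identifiers, first column of sample identifiers, 0/1 body) and
#' `pair_list` (two tab-separated columns `sample`, `gene`, no header; the
#' presence of a record sets the entry to 1, duplicates collapse).
#'
#' Multiplicity in a pair list (e.g. several variants hitting one gene in
#' one sample) is deliberately collapsed to a single 1: the method operates
#' on a binary incidence matrix.
#'
#' @param path Path to the input file.
#' @param dialect `"dense_tsv"` or `"pair_list"`.
#' @return An integer matrix with entries in \{0, 1\}, rownames = sample
#'   ids, colnames = gene ids.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("sample\tgA\tgB", "s1\t1\t0", "s2\t0\t1"), tf)
#' M <- read_mutation_matrix(tf)
#' sum(M)
#' @export
read_mutation_matrix <- function(path, dialect = c("dense_tsv", "pair_list")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("mutation matrix file not found: ", path))
  }
  if (dialect == "pair_list") {
    return(read_pair_list(path))
  }
  x <- read_dense_body(path, what = "mutation")
  bad <- which(!(x == 0 | x == 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(paste0(
      "non-binary entry in mutation matrix at sample '",
      rownames(x)[bad[1, 1]], "', gene '", colnames(x)[bad[1, 2]],
      "' (value ", x[bad[1, , drop = FALSE]], ")"
    ))
  }
  storage.mode(x) <- "integer"
  x
}

read_pair_list <- function(path) {
  recs <- readr::read_tsv(
    path,
    col_names = c("sample", "gene"),
    col_types = readr::cols(
      sample = readr::col_character(),
      gene = readr::col_character()
    ),
    progress = FALSE
  )
  if (nrow(recs) == 0) abort(paste0("empty pair-list file: ", path))
  recs <- dplyr::distinct(recs)
  samples <- sort(unique(recs$sample))
  genes <- sort(unique(recs$gene))
  M <- matrix(0L, length(samples), length(genes),
              dimnames = list(samples, genes))
  M[cbind(recs$sample, recs$gene)] <- 1L
  M
}

#' Read a real-valued expression matrix
#'
#' Dense TSV dialect: header row of gene identifiers, first column of
#' sample identifiers, numeric body. Non-numeric, missing or non-finite
#' cells are rejected with their coordinates; values are never imputed.
#'
#' @param path Path to the input file.
#' @return A numeric matrix, rownames = sample ids, colnames = gene ids,
#'   all entries finite.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("expression matrix file not found: ", path))
  }
  read_dense_body(path, what = "expression")
}

# Shared dense-TSV ingestion: returns a validated numeric matrix.
read_dense_body <- function(path, what) {
  # check the raw header before readr de-duplicates column names
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header[-1])) {
    abort(paste0("duplicated gene id in ", what, " matrix: '",
                 header[-1][duplicated(header[-1])][1], "'"))
  }
  raw <- suppressMessages(readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  ))
  if (nrow(raw) == 0 || ncol(raw) < 2) {
    abort(paste0("empty or malformed ", what, " matrix file: ", path))
  }
  samples <- raw[[1]]
  genes <- colnames(raw)[-1]
  if (anyDuplicated(samples)) {
    abort(paste0("duplicated sample id in ", what, " matrix: '",
                 samples[duplicated(samples)][1], "'"))
  }
  if (anyDuplicated(genes)) {
    abort(paste0("duplicated gene id in ", what, " matrix: '",
                 genes[duplicated(genes)][1], "'"))
  }
  body <- as.matrix(raw[, -1, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(paste0(
      "non-numeric or non-finite cell in ", what, " matrix at sample '",
      samples[bad[1, 1]], "', gene '", genes[bad[1, 2]], "' (value '",
      body[bad[1, , drop = FALSE]], "')"
    ))
  }
  dimnames(vals) <- list(samples, genes)
  vals
}

#' Write a sample-by-gene matrix as dense TSV
#'
#' Inverse of [read_mutation_matrix()] / [read_expression_matrix()]: header
#' row of gene ids, first column (`sample`) of sample ids.
#'
#' @param x Matrix with sample rownames and gene colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  out <- dplyr::bind_cols(
    tibble(sample = rownames(x)),
    as_tibble(x)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Restrict paired matrices to their shared samples
#'
#' The method requires samples with both mutation calls and expression
#' values. Both matrices are restricted to the intersection of their sample
#' ids and re-ordered into a single canonical (lexicographically sorted)
#' sample order so downstream results do not depend on input row order.
#' Gene axes are left untouched; the two gene universes need not coincide.
#'
#' @param mutation Binary mutation matrix (samples x genes).
#' @param expression Numeric expression matrix (samples x genes).
#' @return A list with elements `mutation` and `expression`, both over the
#'   same sorted shared samples.
#' @export
align_cohort <- function(mutation, expression) {
  shared <- sort(intersect(rownames(mutation), rownames(expression)))
  if (length(shared) == 0) {
    abort("no shared samples between mutation and expression matrices")
  }
  list(
    mutation = mutation[shared, , drop = FALSE],
    expression = expression[shared, , drop = FALSE]
  )
}

#' Drop genes mutated below a minimum mutation rate
#'
#' Genes mutated in few patients are treated as passenger mutations and
#' removed before exclusivity analysis. A gene is kept when its mutation
#' rate (column sum / number of samples) meets `min_rate`; the default
#' comparator is `>=` so a gene sitting exactly on the threshold is kept.
#'
#' @param mutation Binary mutation matrix.
#' @param min_rate Minimum fraction of mutated samples, in \[0, 1\].
#'   Default 0.03.
#' @param comparator `">="` (default) or `">"` for a strict threshold.
#' @return The mutation matrix restricted to the passing genes (possibly
#'   zero genes); samples unchanged.
#' @export
filter_by_mutation_rate <- function(mutation, min_rate = 0.03,
                                    comparator = c(">=", ">")) {
  comparator <- match.arg(comparator)
  stopifnot(min_rate >= 0, min_rate <= 1)
  rate <- colSums(mutation) / nrow(mutation)
  keep <- if (comparator == ">=") rate >= min_rate else rate > min_rate
  mutation[, keep, drop = FALSE]
}

#' Summarize a mutation cohort
#'
#' Reports the cohort size and the two standard per-axis mutation averages:
#' AMG, the average number of mutated genes per sample, and AMS, the
#' average number of mutated samples per gene. Both averages are the total
#' mutation count divided by one axis length, so
#' `AMG * n_patients == AMS * n_genes` always holds.
#'
#' @param mutation Binary mutation matrix.
#' @return A one-row tibble with columns `n_patients`, `n_genes`,
#'   `avg_mut_genes_per_sample`, `avg_mut_samples_per_gene`.
#' @export
summarize_cohort <- function(mutation) {
  m <- nrow(mutation)
  n <- ncol(mutation)
  stopifnot(m >= 1, n >= 1)
  total <- sum(mutation)
  tibble(
    n_patients = m,
    n_genes = n,
    avg_mut_genes_per_sample = total / m,
    avg_mut_samples_per_gene = total / n
  )
}

#' Per-gene z-score scaling of an expression matrix
#'
#' Optional pre-processing: centers and scales each gene (column) to mean 0
#' and unit variance. Off by default throughout the package; expression
#' values are otherwise used exactly as supplied. Constant genes are
#' centered but left unscaled (avoiding division by zero).
#'
#' @param expression Numeric expression matrix.
#' @return A matrix of the same shape.
#' @export
scale_expression <- function(expression) {
  mu <- colMeans(expression)
  sdv <- apply(expression, 2, stats::sd)
  sdv[sdv == 0] <- 1
  scaled <- sweep(sweep(expression, 2, mu, "-"), 2, sdv, "/")
  scaled
}

# Internal validation used at module boundaries.
check_mutation_matrix <- function(mutation) {
  if (!is.matrix(mutation) || is.null(rownames(mutation)) ||
      is.null(colnames(mutation))) {
    abort("mutation matrix must be a matrix with sample rownames and gene colnames")
  }
  if (!all(mutation == 0 | mutation == 1)) {
    abort("mutation matrix entries must all be 0 or 1")
  }
  invisible(mutation)
}

check_expression_matrix <- function(expression) {
  if (!is.matrix(expression) || is.null(rownames(expression)) ||
      is.null(colnames(expression))) {
    abort("expression matrix must be a matrix with sample rownames and gene colnames")
  }
  if (!all(is.finite(expression))) {
    abort("expression matrix entries must all be finite")
  }
  invisible(expression)
}
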
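# Synthetic paired cohorts with planted mutually exclusive pathways and
# mutation-driven expression shifts. Exclusivity is enforced structurally:
# per sample and per planted pathway, at most one member is mutated (chosen
# uniformly with the pathway's coverage probability), so ground truth is
# exact before passenger noise. Passengers are i.i.d. Bernoulli per entry,
# the simplest corruption that can violate exclusivity.

#' Configuration for a synthetic cohort
#'
#' Defaults describe a 300-sample cohort over 40 genes with two disjoint
#' planted pathways of four genes each at coverage 0.95, a passenger
#' mutation rate of 0.005 per entry, and one mutation-to-expression link
#' per pathway (to another member of the same pathway) with an effect of
#' five noise standard deviations.
#'
#' @param n_samples Number of samples.
#' @param n_genes Total gene universe (pathway members plus background
#'   passenger-only genes, auto-named `BG...`).
#' @param pathways List of planted pathways, each
#'   `list(genes = <ids>, coverage = <fraction>)`: per sample, with
#'   probability `coverage` exactly one member (uniform) is mutated.
#' @param passenger_rate Per-entry probability of an independent passenger
#'   mutation, added on top of the planted pattern.
#' @param connectivity_links List of
#'   `list(mutation_gene =, expression_gene =, effect =)`: the expression
#'   of `expression_gene` is shifted by `effect` in every sample where
#'   `mutation_gene` is mutated.
#' @param noise_sd Standard deviation of the mean-zero Gaussian expression
#'   baseline (must be > 0).
#' @param expression_genes Genes measured in the expression matrix;
#'   default `NULL` measures exactly the link partner genes.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 300,
                              n_genes = 40,
                              pathways = list(
                                list(genes = paste0("PWA_", 1:4), coverage = 0.95),
                                list(genes = paste0("PWB_", 1:4), coverage = 0.95)
                              ),
                              passenger_rate = 0.005,
                              connectivity_links = list(
                                list(mutation_gene = "PWA_1",
                                     expression_gene = "PWA_2", effect = 5),
                                list(mutation_gene = "PWB_1",
                                     expression_gene = "PWB_2", effect = 5)
                              ),
                              noise_sd = 1,
                              expression_genes = NULL,
                              seed = 1L) {
  stopifnot(n_samples >= 1, passenger_rate >= 0, noise_sd > 0)
  pw_genes <- unlist(lapply(pathways, `[[`, "genes"))
  if (anyDuplicated(pw_genes)) {
    overlapping <- unique(pw_genes[duplicated(pw_genes)])
    inform(paste0("planted pathways share gene(s): ",
                  paste(overlapping, collapse = ", ")))
  }
  covs <- vapply(pathways, `[[`, numeric(1), "coverage")
  if (any(covs < 0 | covs > 1)) abort("pathway coverage must be in [0, 1]")
  if (n_genes < length(unique(pw_genes))) {
    abort("n_genes smaller than the number of planted pathway genes")
  }
  link_mut <- vapply(connectivity_links, `[[`, character(1), "mutation_gene")
  structure(
    list(
      n_samples = as.integer(n_samples),
      n_genes = as.integer(n_genes),
      pathways = pathways,
      passenger_rate = passenger_rate,
      connectivity_links = connectivity_links,
      noise_sd = noise_sd,
      expression_genes = expression_genes,
      seed = as.integer(seed),
      link_mutation_genes = link_mut
    ),
    class = "simulation_config"
  )
}

#' Generate a synthetic paired cohort with ground truth
#'
#' Draws a binary mutation matrix and a paired expression matrix from a
#' [simulation_config()]. Per sample and planted pathway, with probability
#' `coverage` exactly one member gene is mutated, guaranteeing
#' within-pathway exclusivity before passenger noise; passengers are added
#' i.i.d. at `passenger_rate`. Expression is a mean-zero Gaussian baseline
#' (`noise_sd`) plus `effect` for each planted link in the samples where
#' the linked mutation gene ends up mutated. Identical seeds give
#' bit-identical cohorts.
#'
#' @param config A [simulation_config()].
#' @return A list of class `synthetic_cohort`: `mutation` (binary matrix),
#'   `expression` (numeric matrix), and `truth` (planted pathway
#'   membership, within-pathway exclusive pairs, planted links, and the
#'   config).
#' @export
generate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv))
  }
  set.seed(config$seed)

  m <- config$n_samples
  pw_genes <- unique(unlist(lapply(config$pathways, `[[`, "genes")))
  n_bg <- config$n_genes - length(pw_genes)
  genes <- c(pw_genes,
             if (n_bg > 0) sprintf("BG%03d", seq_len(n_bg)) else character())
  samples <- sprintf("S%04d", seq_len(m))
  M <- matrix(0L, m, length(genes), dimnames = list(samples, genes))

  for (pw in config$pathways) {
    covered <- runif(m) < pw$coverage
    if (any(covered)) {
      pick <- sample(pw$genes, sum(covered), replace = TRUE)
      M[cbind(which(covered), match(pick, genes))] <- 1L
    }
  }
  if (config$passenger_rate > 0) {
    passengers <- matrix(
      runif(m * length(genes)) < config$passenger_rate,
      m, length(genes)
    )
    M[passengers] <- 1L
  }

  e_genes <- config$expression_genes %||%
    unique(vapply(config$connectivity_links, `[[`, character(1),
                  "expression_gene"))
  E <- matrix(
    rnorm(m * length(e_genes), 0, config$noise_sd),
    m, length(e_genes),
    dimnames = list(samples, e_genes)
  )
  for (link in config$connectivity_links) {
    if (!link$expression_gene %in% e_genes) next
    if (!link$mutation_gene %in% genes) {
      abort(paste0("link mutation gene not in gene universe: '",
                   link$mutation_gene, "'"))
    }
    hit <- M[, link$mutation_gene] == 1L
    E[hit, link$expression_gene] <- E[hit, link$expression_gene] + link$effect
  }

  membership <- purrr::map_dfr(seq_along(config$pathways), function(i) {
    tibble(gene = config$pathways[[i]]$genes,
           pathway = paste0("planted_", i))
  })
  excl_pairs <- purrr::map_dfr(seq_along(config$pathways), function(i) {
    g <- sort(config$pathways[[i]]$genes)
    if (length(g) < 2) {
      return(tibble(gene_i = character(), gene_j = character(),
                    pathway = character()))
    }
    cmb <- combn(g, 2)
    tibble(gene_i = cmb[1, ], gene_j = cmb[2, ],
           pathway = paste0("planted_", i))
  })
  links <- purrr::map_dfr(config$connectivity_links, function(l) {
    tibble(mutation_gene = l$mutation_gene,
           expression_gene = l$expression_gene, effect = l$effect)
  })

  structure(
    list(
      mutation = M,
      expression = E,
      truth = structure(
        list(pathway_membership = membership,
             exclusive_pairs = excl_pairs,
             connectivity_pairs = links,
             config = config),
        class = "synthetic_truth"
      )
    ),
    class = "synthetic_cohort"
  )
}

#' Score detected pathways against planted ground truth
#'
#' For each planted pathway, the best Jaccard index against any detected
#' pathway, plus gene-level precision and recall of the union of detected
#' members against the union of planted members.
#'
#' @param truth A `synthetic_truth` (from [generate_cohort()]).
#' @param result A `pathway_result` (from [merge_pathways()] or
#'   [run_pipeline()]).
#' @return A list of class `recovery_report`: `per_pathway` tibble
#'   (`pathway`, `size`, `best_match`, `best_jaccard`), `gene_precision`,
#'   `gene_recall`.
#' @export
recovery_report <- function(truth, result) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(result, "pathway_result"))
  planted <- split(truth$pathway_membership$gene,
                   truth$pathway_membership$pathway)
  detected <- result$pathways
  per_pathway <- purrr::map_dfr(names(planted), function(nm) {
    p <- planted[[nm]]
    if (length(detected) == 0) {
      return(tibble(pathway = nm, size = length(p),
                    best_match = NA_character_, best_jaccard = 0))
    }
    jac <- vapply(detected, function(d) {
      length(intersect(p, d)) / length(union(p, d))
    }, numeric(1))
    tibble(pathway = nm, size = length(p),
           best_match = names(detected)[which.max(jac)],
           best_jaccard = max(jac))
  })
  all_planted <- unique(truth$pathway_membership$gene)
  all_detected <- unique(unlist(detected))
  hits <- length(intersect(all_planted, all_detected))
  structure(
    list(
      per_pathway = per_pathway,
      gene_precision = if (length(all_detected)) hits / length(all_detected) else NA_real_,
      gene_recall = hits / length(all_planted)
    ),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  print(x$per_pathway)
  cat(sprintf("gene precision %.3f, recall %.3f\n",
              x$gene_precision, x$gene_recall))
  invisible(x)
}

#' Write a synthetic cohort as a ready-to-run fixture directory
#'
#' Writes `mutation.tsv` and `expression.tsv` in the dense TSV dialect of
#' [read_mutation_matrix()] plus `ground_truth.json`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_matrix_tsv(cohort$mutation, file.path(dir, "mutation.tsv"))
  write_matrix_tsv(cohort$expression, file.path(dir, "expression.tsv"))
  truth <- cohort$truth
  jsonlite::write_json(
    list(
      pathway_membership = truth$pathway_membership,
      exclusive_pairs = truth$exclusive_pairs,
      connectivity_pairs = truth$connectivity_pairs,
      seed = truth$config$seed,
      n_samples = truth$config$n_samples,
      n_genes = truth$config$n_genes,
      passenger_rate = truth$config$passenger_rate,
      noise_sd = truth$config$noise_sd
    ),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
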
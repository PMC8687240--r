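test_that("planted pathways are perfectly exclusive without passenger noise", {
  cfg <- simulation_config(
    n_samples = 300, n_genes = 3,
    pathways = list(list(genes = c("A", "B", "C"), coverage = 0.9)),
    passenger_rate = 0, connectivity_links = list(), noise_sd = 1,
    seed = 5
  )
  co <- generate_cohort(cfg)
  expect_true(all(rowSums(co$mutation[, c("A", "B", "C")]) <= 1))
  sc <- pair_scores(co$mutation)
  expect_true(all(sc$exclusive_degree == 1))
  expect_true(all(sc$weight_degree == 1))
})

test_that("zero coverage and zero passengers give an all-zero matrix", {
  cfg <- simulation_config(
    n_samples = 50, n_genes = 4,
    pathways = list(list(genes = c("A", "B"), coverage = 0)),
    passenger_rate = 0, connectivity_links = list(), seed = 2
  )
  co <- generate_cohort(cfg)
  expect_true(all(co$mutation == 0))
})

test_that("cohorts are reproducible from the seed and differ across seeds", {
  c1 <- generate_cohort(simulation_config(seed = 9))
  c2 <- generate_cohort(simulation_config(seed = 9))
  c3 <- generate_cohort(simulation_config(seed = 10))
  expect_identical(c1$mutation, c2$mutation)
  expect_identical(c1$expression, c2$expression)
  expect_false(identical(c1$mutation, c3$mutation))
})

test_that("per-gene coverage matches its expectation over repeated seeds", {
  # expected per-gene rate ~ c/size + eps (minus a negligible overlap term)
  n_rep <- 40
  cfg_base <- simulation_config()
  size <- 4; cval <- 0.95; eps <- cfg_base$passenger_rate
  expected <- cval / size + eps
  rates <- vapply(seq_len(n_rep), function(s) {
    co <- generate_cohort(simulation_config(seed = 1000 + s))
    mean(colMeans(co$mutation[, paste0("PWA_", 1:4)]))
  }, numeric(1))
  se <- sd(rates) / sqrt(n_rep)
  expect_lt(abs(mean(rates) - expected), 3 * se + 1e-3)
})

test_that("a strong planted link passes the signed criterion in nearly all seeds", {
  # one linked pair, delta = 5 sd, coverage 0.5, n = 500
  passes <- vapply(1:100, function(s) {
    cfg <- simulation_config(
      n_samples = 500, n_genes = 2,
      pathways = list(list(genes = "MUT", coverage = 0.5)),
      passenger_rate = 0,
      connectivity_links = list(list(mutation_gene = "MUT",
                                     expression_gene = "TGT", effect = 5)),
      noise_sd = 1, seed = s
    )
    co <- generate_cohort(cfg)
    cp <- connectivity_pairs(co$mutation[, "MUT", drop = FALSE],
                             co$expression)
    cp$passes[cp$expression_gene == "TGT"]
  }, logical(1))
  expect_gte(mean(passes), 0.95)
})

test_that("recovery_report computes best-Jaccard and gene precision/recall", {
  co <- generate_cohort(simulation_config(seed = 3))
  planted <- split(co$truth$pathway_membership$gene,
                   co$truth$pathway_membership$pathway)

  perfect <- merge_pathways(unname(planted))
  rec <- recovery_report(co$truth, perfect)
  expect_true(all(rec$per_pathway$best_jaccard == 1))
  expect_equal(rec$gene_precision, 1)
  expect_equal(rec$gene_recall, 1)

  none <- merge_pathways(list())
  rec0 <- recovery_report(co$truth, none)
  expect_true(all(rec0$per_pathway$best_jaccard == 0))
  expect_equal(rec0$gene_recall, 0)

  # planted {a,b,c} vs detected {a,b,d}: Jaccard 2/4
  cfg <- simulation_config(
    n_samples = 10, n_genes = 4,
    pathways = list(list(genes = c("a", "b", "c"), coverage = 0.5)),
    passenger_rate = 0, connectivity_links = list(), seed = 1
  )
  co2 <- generate_cohort(cfg)
  rec2 <- recovery_report(co2$truth, merge_pathways(list(c("a", "b", "d"))))
  expect_equal(rec2$per_pathway$best_jaccard, 0.5)
})

test_that("a fixture directory round-trips through the standard readers", {
  co <- generate_cohort(simulation_config(seed = 12))
  dir <- tempfile("fixture")
  write_cohort(co, dir)
  M <- read_mutation_matrix(file.path(dir, "mutation.tsv"))
  E <- read_expression_matrix(file.path(dir, "expression.tsv"))
  expect_identical(M, co$mutation)
  expect_equal(E, co$expression, tolerance = 1e-12)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_identical(gt$seed, 12L)
  expect_identical(length(gt$pathway_membership),
                   nrow(co$truth$pathway_membership))
})
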
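graph_from_edges <- function(edges, nodes = NULL) {
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges), directed = FALSE,
    vertices = nodes
  )
  g
}

test_that("maximal cliques: complete graph, triangle-free cycle, determinism", {
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- c("a", "b", "c", "d")
  cl <- maximal_cliques(k4, min_size = 3)
  expect_identical(cl, list(c("a", "b", "c", "d")))

  c5 <- igraph::make_ring(5)
  igraph::V(c5)$name <- paste0("g", 1:5)
  expect_identical(maximal_cliques(c5, min_size = 3), list())

  set.seed(151)
  rg <- random_gene_graph(10, 0.5)
  expect_identical(maximal_cliques(rg$graph, 3), maximal_cliques(rg$graph, 3))
})

test_that("maximal cliques equal exhaustive subset enumeration on random graphs", {
  set.seed(161)
  for (rep in 1:25) {
    rg <- random_gene_graph(12, 0.4)
    got <- maximal_cliques(rg$graph, min_size = 3)
    want <- bf_maximal_cliques(rg$adj, min_size = 3)
    expect_identical(got, want)
    # every returned set is complete; none contains another
    for (s in got) {
      sub <- rg$adj[s, s, drop = FALSE]
      diag(sub) <- TRUE
      expect_true(all(sub))
    }
    if (length(got) > 1) {
      for (i in seq_along(got)) for (j in seq_along(got)) {
        if (i != j) expect_false(all(got[[i]] %in% got[[j]]))
      }
    }
  }
})

test_that("k-clique communities follow the percolation adjacency rule", {
  # two triangles sharing an edge percolate into one community
  g <- graph_from_edges(rbind(
    c("a", "b"), c("b", "c"), c("a", "c"),
    c("b", "d"), c("c", "d")
  ))
  expect_identical(k_clique_communities(g, 3),
                   list(c("a", "b", "c", "d")))

  # two triangles sharing one vertex stay separate (k-1 nodes required)
  g2 <- graph_from_edges(rbind(
    c("a", "b"), c("b", "c"), c("a", "c"),
    c("c", "d"), c("d", "e"), c("c", "e")
  ))
  expect_identical(k_clique_communities(g2, 3),
                   list(c("a", "b", "c"), c("c", "d", "e")))

  # random graph vs explicit clique-overlap percolation
  set.seed(171)
  for (rep in 1:10) {
    rg <- random_gene_graph(9, 0.45)
    got <- k_clique_communities(rg$graph, 3)
    tri <- t(combn(rownames(rg$adj), 3))
    tri <- tri[apply(tri, 1, function(s) {
      sub <- rg$adj[s, s]; diag(sub) <- TRUE; all(sub)
    }), , drop = FALSE]
    if (nrow(tri) == 0) {
      expect_identical(got, list())
      next
    }
    og <- igraph::make_empty_graph(nrow(tri), directed = FALSE)
    if (nrow(tri) > 1) {
      prs <- combn(nrow(tri), 2)
      for (p in seq_len(ncol(prs))) {
        if (length(intersect(tri[prs[1, p], ], tri[prs[2, p], ])) == 2) {
          og <- igraph::add_edges(og, prs[, p])
        }
      }
    }
    comp <- igraph::components(og)$membership
    want <- lapply(split(seq_len(nrow(tri)), comp),
                   function(ix) sort(unique(as.vector(tri[ix, ]))))
    want <- want[order(-lengths(want),
                       vapply(want, paste, character(1), collapse = "\r"))]
    expect_identical(got, unname(want))
  }
})

test_that("overlap score matches its closed form at the landmarks", {
  expect_equal(overlap_score(letters[1:4], letters[3:6]), 0.25)
  expect_equal(overlap_score(letters[1:4], letters[1:4]), 1)
  expect_equal(overlap_score(letters[1:4], letters[5:8]), 0)
  expect_equal(overlap_score(c("a", "b", "c", "d"), c("b", "c", "d", "e")),
               9 / 16)
  expect_error(overlap_score(character(0), "a"), "empty")
})

test_that("merging respects the strict threshold and records history", {
  # OS exactly 0.25: no merge under the strict rule
  res <- merge_pathways(list(letters[1:4], letters[3:6]), threshold = 0.25)
  expect_identical(length(res$pathways), 2L)
  expect_identical(res$merges_performed, 0L)
  expect_identical(unname(res$provenance), c("clique", "clique"))

  # OS = 9/16 > 0.25 merges into the union
  res2 <- merge_pathways(list(c("a", "b", "c", "d"), c("b", "c", "d", "e")),
                         threshold = 0.25)
  expect_identical(res2$pathways, list(P1 = c("a", "b", "c", "d", "e")))
  expect_identical(unname(res2$provenance), "merged")
  expect_identical(sort(res2$history$P1), c("C1", "C2"))

  # single set passes through unchanged
  res3 <- merge_pathways(list(c("x", "y", "z")))
  expect_identical(res3$pathways, list(P1 = c("x", "y", "z")))

  # duplicate cliques are collapsed before merging
  res4 <- merge_pathways(list(letters[1:3], letters[1:3], letters[8:10]))
  expect_identical(res4$n_input_sets, 2L)
})

test_that("merge terminates with a compliant final result on random inputs", {
  set.seed(181)
  universe <- sprintf("G%02d", 1:20)
  for (rep in 1:15) {
    sets <- replicate(sample(3:8, 1),
                      sort(sample(universe, sample(3:6, 1))),
                      simplify = FALSE)
    res <- merge_pathways(sets, threshold = 0.25)
    # termination bound: at most (count - 1) merges
    expect_lte(res$merges_performed, res$n_input_sets - 1)
    # post-merge audit: every surviving pair has OS <= threshold
    fin <- res$pathways
    if (length(fin) > 1) {
      for (i in seq_len(length(fin) - 1)) for (j in (i + 1):length(fin)) {
        expect_lte(overlap_score(fin[[i]], fin[[j]]), 0.25)
      }
    }
    # gene conservation
    expect_setequal(unlist(fin), unlist(sets))
    # determinism
    res_again <- merge_pathways(sample(sets), threshold = 0.25)
    expect_identical(res_again$pathways, res$pathways)
  }
})

test_that("tidy and glance expose pathway membership and counts", {
  res <- merge_pathways(list(c("a", "b", "c", "d"), c("b", "c", "d", "e"),
                             c("x", "y", "z")))
  tab <- tidy(res)
  expect_identical(sort(unique(tab$pathway)), c("P1", "P2"))
  expect_identical(tab$gene[tab$pathway == "P1"], c("a", "b", "c", "d", "e"))
  g <- glance(res)
  expect_identical(g$n_pathways, 2L)
  expect_identical(g$merges_performed, 1L)

  tf <- tempfile(fileext = ".gmt")
  write_gmt(res, tf)
  lines <- readLines(tf)
  expect_identical(length(lines), 2L)
  expect_match(lines[1], "^P1\tmerged:C[0-9]\\+C[0-9]\ta\tb\tc\td\te$")
})
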
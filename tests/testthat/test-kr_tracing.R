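planted_setup <- function(seed = 1) {
  gen <- gen_planted_kr(seed = seed)
  tree <- decompose_network(gen$network)
  traces <- trace_seeds(tree, gen$seed_genes)
  list(gen = gen, tree = tree, traces = traces,
       report = identify_key_regulators(tree, traces))
}

test_that("seed tracing follows the planted genes to terminal triangles", {
  s <- planted_setup(seed = 2)
  expect_true(all(s$traces$present))
  expect_true(all(s$traces$reached_terminal))
  expect_true(all(s$traces$in_terminal_triangle))
  for (i in seq_len(nrow(s$traces))) {
    path <- s$traces$path[[i]]
    expect_equal(path[1], "c0")
    for (j in seq_along(path)[-1]) {
      expect_equal(s$tree$index[[path[j]]]$parent, path[j - 1])
    }
  }
})

test_that("seeds absent from the network get empty traces, not errors", {
  s <- planted_setup(seed = 2)
  tr <- trace_seeds(s$tree, c(s$gen$seed_genes$symbol, "TRPM6"))
  miss <- tr[tr$seed == "TRPM6", ]
  expect_false(miss$present)
  expect_equal(miss$path[[1]], character())
  rep <- identify_key_regulators(s$tree, tr)
  expect_equal(rep$dropped_seeds, "TRPM6")
  expect_setequal(rep$seed_krs, s$gen$truth$seed)
})

test_that("a seed outside any terminal triangle is not a key regulator", {
  # star center reaches nothing: the root is pruned (no triangle)
  tree <- decompose_network(graph_star5())
  tr <- trace_seeds(tree, "H")
  expect_false(tr$reached_terminal)
  expect_false(tr$in_terminal_triangle)
  rep <- identify_key_regulators(tree, tr)
  expect_equal(length(rep$seed_krs), 0)
  expect_equal(nrow(rep$motifs), 0)

  # triangle plus a pendant seed: pendant reaches the terminal community
  # but sits in no triangle there
  g <- igraph::graph_from_literal(A - B, B - C, C - A, A - P)
  tree2 <- decompose_network(g)
  tr2 <- trace_seeds(tree2, "P")
  expect_false(tr2$in_terminal_triangle)
  expect_equal(length(identify_key_regulators(tree2, tr2)$seed_krs), 0)
})

test_that("planted key regulators and their partners are recovered exactly", {
  for (sd in c(1, 4, 9)) {
    s <- planted_setup(seed = sd)
    truth <- s$gen$truth
    expect_setequal(s$report$seed_krs, truth$seed)
    expect_setequal(s$report$partner_krs,
                    c(truth$partner_1, truth$partner_2))
    expect_equal(nrow(s$report$motifs), 3)
    # every partner is adjacent to its seed inside the terminal community
    for (i in seq_len(nrow(s$report$motifs))) {
      tri <- s$report$motifs$members[[i]]
      seed <- s$report$motifs$seed[i]
      for (p in setdiff(tri, seed)) {
        expect_true(igraph::are_adjacent(s$tree$graph, seed, p))
      }
    }
  }
})

test_that("KR identification is invariant to node relabeling", {
  gen <- gen_planted_kr(seed = 6)
  g <- gen$network
  set.seed(99)
  perm <- sample(igraph::vcount(g))
  relabeled <- igraph::permute(g, perm)
  map <- stats::setNames(igraph::V(relabeled)$name[perm], igraph::V(g)$name)
  # rename vertices so labels differ but structure is identical
  igraph::V(relabeled)$name <- paste0("x_", igraph::V(relabeled)$name)
  tree <- decompose_network(relabeled)
  tr <- trace_seeds(tree, paste0("x_", gen$truth$seed))
  rep <- identify_key_regulators(tree, tr)
  expect_setequal(rep$seed_krs, paste0("x_", gen$truth$seed))
  expect_setequal(rep$partner_krs,
                  paste0("x_", c(gen$truth$partner_1, gen$truth$partner_2)))
})

test_that("regulatory share is the in-community edge fraction", {
  # terminal single-triangle community: any member has share 2/3
  tree <- decompose_network(graph_triangle())
  pk <- kr_probability(tree, "A")
  expect_equal(pk$p_kr, 2 / 3)

  s <- planted_setup(seed = 2)
  for (seed_gene in s$gen$truth$seed) {
    pk <- kr_probability(s$tree, seed_gene)
    expect_true(all(pk$p_kr <= 1))
    expect_true(all(pk$x <= 2 * pk$e))
    # deeper levels concentrate the regulatory share
    expect_gt(pk$p_kr[which.max(pk$level)], pk$p_kr[pk$level == 0])
  }
  expect_error(kr_probability(s$tree, "NOPE"), "not present")
})

test_that("popularity ranking is competition-style on descending degree", {
  r <- popularity_rank(graph_star5(), c("H", "L1"))
  expect_equal(r$rank[r$gene == "H"], 1L)
  expect_equal(r$rank[r$gene == "L1"], 2L)

  # two tied nodes share the smaller rank and the next rank is skipped
  g <- igraph::graph_from_literal(A - B, A - C, B - C, C - D)
  rr <- popularity_rank(g, c("A", "B", "C", "D"))
  expect_equal(rr$rank[rr$gene == "C"], 1L)
  expect_equal(sort(rr$rank[rr$gene %in% c("A", "B")]), c(2L, 2L))
  expect_equal(rr$rank[rr$gene == "D"], 4L)
  expect_true(all(rr$rank <= igraph::vcount(g)))

  expect_warning(popularity_rank(g, c("A", "ZZ")), "absent")
})
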
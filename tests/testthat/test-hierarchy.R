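test_that("modularity matches direct double-sum evaluation", {
  g <- graph_two_triangles_disconnected()
  nat <- stats::setNames(c(1, 1, 1, 2, 2, 2), igraph::V(g)$name)
  expect_equal(modularity_q(g, nat), 0.5)
  expect_equal(modularity_q(g, nat), oracle_modularity(g, nat))

  # one community: Q = 0 by the identity sum(A_ij - k_i k_j / 2m) = 0
  one <- stats::setNames(rep(1, 6), igraph::V(g)$name)
  expect_equal(modularity_q(g, one), 0)

  # singletons: closed form -sum(k_i^2) / (4 m^2)
  gb <- graph_two_triangles_bridge()
  singles <- stats::setNames(seq_len(6), igraph::V(gb)$name)
  deg <- igraph::degree(gb)
  m <- igraph::ecount(gb)
  expect_equal(modularity_q(gb, singles), -sum(deg^2) / (4 * m^2))

  # random graphs against both the oracle and igraph's implementation
  for (s in 1:5) {
    g <- random_graph(25, 0.15, 600 + s)
    memb <- stats::setNames(sample(3, 25, TRUE), igraph::V(g)$name)
    expect_equal(modularity_q(g, memb), oracle_modularity(g, memb),
                 tolerance = 1e-12)
    expect_equal(modularity_q(g, memb),
                 igraph::modularity(g, memb[igraph::V(g)$name]),
                 tolerance = 1e-12)
  }

  expect_error(modularity_q(gb, stats::setNames(1, "A")), "missing")
})

test_that("leading-eigenvector split finds the planted bisection", {
  sp <- lev_split(graph_two_triangles_bridge())
  expect_equal(sp$n_communities, 2)
  expect_equal(sp$modularity, 5 / 14, tolerance = 1e-9) # direct Eq evaluation
  memb <- sp$membership
  expect_equal(length(unique(memb[c("A", "B", "C")])), 1)
  expect_equal(length(unique(memb[c("D", "E", "F")])), 1)

  # a clique admits no modularity-positive split
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- paste0("k", 1:5)
  expect_equal(lev_split(k5)$n_communities, 1)

  # disconnected components split apart
  spd <- lev_split(graph_two_triangles_disconnected())
  expect_equal(spd$n_communities, 2)
  expect_equal(spd$modularity, 0.5)
})

test_that("split modularity is self-consistent and comparable to igraph's LEV", {
  for (s in 1:4) {
    g <- random_graph(30, 0.12, 700 + s)
    sp <- lev_split(g)
    expect_equal(sp$modularity, modularity_q(g, sp$membership),
                 tolerance = 1e-12)
  }
  # on a well-separated two-block graph both implementations agree
  set.seed(88)
  blocks <- igraph::sample_sbm(30, matrix(c(0.8, 0.02, 0.02, 0.8), 2),
                               c(15, 15))
  igraph::V(blocks)$name <- paste0("b", 1:30)
  ours <- lev_split(blocks)$membership
  theirs <- igraph::membership(igraph::cluster_leading_eigen(blocks))
  expect_equal(length(unique(ours)), 2)
  agreement <- table(ours, theirs[names(ours)])
  expect_true(all(rowSums(agreement > 0) == 1))
})

test_that("triangle detection distinguishes motifs from cycles and trees", {
  expect_true(contains_triangle(graph_triangle()))
  expect_false(contains_triangle(igraph::make_ring(4)))
  expect_false(contains_triangle(igraph::make_tree(15, mode = "undirected")))
  expect_false(contains_triangle(graph_path3()))
})

test_that("decomposition handles boundary networks", {
  tri_tree <- decompose_network(graph_triangle())
  expect_equal(tri_tree$levels, 0)
  root <- tri_tree$index[["c0"]]
  expect_true(root$terminal)
  expect_true(root$has_triangle)

  star_tree <- decompose_network(graph_star5())
  expect_true(star_tree$index[["c0"]]$pruned)

  expect_error(decompose_network(graph_triangle(), max_levels = 0),
               "max_levels")
})

test_that("decomposition recovers the planted two-level hierarchy", {
  gen <- gen_planted_kr(seed = 5)
  tree <- decompose_network(gen$network)
  expect_gte(tree$levels, 2)
  t <- tidy(tree)
  leaves <- t[t$terminal & !t$pruned, ]
  expect_gte(nrow(leaves), 8)
  expect_true(all(t$has_triangle[t$terminal]))

  # children partition a subset of the parent's members
  for (rec in tree$index) {
    if (length(rec$children) == 0) next
    kids <- lapply(rec$children, function(id) tree$index[[id]]$members)
    all_kids <- unlist(kids)
    expect_false(any(duplicated(all_kids)))
    expect_true(all(all_kids %in% rec$members))
    for (kid_id in rec$children) {
      expect_equal(tree$index[[kid_id]]$level, rec$level + 1L)
    }
  }

  # determinism of the full decomposition
  tree2 <- decompose_network(gen$network)
  expect_identical(tidy(tree), tidy(tree2))
})

test_that("level summaries decline from root to motif level on the planted fixture", {
  gen <- gen_planted_kr(seed = 3)
  tree <- decompose_network(gen$network)
  ls <- level_summary(tree)
  expect_equal(ls$level, sort(ls$level))
  he <- ls$total_he
  expect_true(all(diff(he) < 0))
  q <- ls$mean_q[!is.na(ls$mean_q)]
  expect_true(all(diff(q) < 0))
  # energies recompute per community
  for (lv in ls$level) {
    expect_equal(level_hamiltonian(tree, lv), ls$total_he[ls$level == lv])
  }
})
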
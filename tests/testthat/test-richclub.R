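test_that("raw rich-club closed forms on clique and star", {
  k4 <- rich_club_raw(graph_k4())
  expect_equal(k4$phi[k4$k == 2], 1)
  expect_equal(k4$n_gt_k[k4$k == 2], 4)
  expect_equal(k4$e_gt_k[k4$k == 2], 6)

  s <- rich_club_raw(graph_star5())
  expect_equal(s$phi[s$k == 0], 0.4)
  expect_equal(s$n_gt_k[s$k == 0], 5)

  expect_silent(rich_club_raw(graph_path3())) # 3 nodes allowed
  expect_error(rich_club_raw(igraph::make_empty_graph(2, directed = FALSE)),
               ">= 3")
})

test_that("raw curve matches exhaustive subgraph counting on random graphs", {
  for (s in 1:6) {
    g <- random_graph(40, 0.1, 900 + s)
    got <- rich_club_raw(g)
    want <- oracle_rich_club(g)
    expect_equal(got$k, want$k)
    expect_equal(got$n_gt_k, want$n_gt_k)
    expect_equal(got$e_gt_k, want$e_gt_k)
    expect_equal(got$phi, want$phi, tolerance = 1e-12)
  }
})

test_that("phi is non-decreasing in k on cliques", {
  k8 <- igraph::make_full_graph(8)
  igraph::V(k8)$name <- paste0("c", 1:8)
  curve <- rich_club_raw(k8)
  expect_true(all(diff(curve$phi) >= 0))
  expect_true(all(curve$phi == 1))
})

test_that("degree-preserving nulls keep the degree sequence exactly", {
  g <- random_graph(30, 0.15, 55)
  for (s in 1:5) {
    null_g <- degree_preserving_null(g, n_swaps_factor = 10, seed = s)
    expect_equal(sort(igraph::degree(null_g)), sort(igraph::degree(g)))
    expect_equal(igraph::degree(null_g)[igraph::V(g)$name],
                 igraph::degree(g)[igraph::V(g)$name])
    expect_false(igraph::any_multiple(null_g))
    expect_equal(sum(igraph::which_loop(null_g)), 0)
  }
  # zero attempted swaps: identity
  same <- degree_preserving_null(g, n_swaps_factor = 0, seed = 1)
  expect_setequal(apply(igraph::as_edgelist(same), 1, paste, collapse = "-"),
                  apply(igraph::as_edgelist(g), 1, paste, collapse = "-"))
  # a triangle admits no legal swap
  tri_rewired <- degree_preserving_null(graph_triangle(),
                                        n_swaps_factor = 50, seed = 2)
  expect_setequal(
    apply(igraph::as_edgelist(tri_rewired), 1,
          function(r) paste(sort(r), collapse = "-")),
    c("A-B", "B-C", "A-C"))
})

test_that("self-null normalization gives phi_norm = 1 everywhere", {
  g <- random_graph(25, 0.2, 77)
  curve <- rich_club_normalized(g, n_null = 1, seed = 3, n_swaps_factor = 0)
  defined <- !is.na(curve$phi_norm)
  expect_true(any(defined))
  expect_equal(curve$phi_norm[defined], rep(1, sum(defined)))
})

test_that("a planted clique core shows up as a rich club; random controls do not", {
  core <- paste0("core", 1:6)
  core_frac <- med_phinorm <- numeric(5)
  for (s in 1:5) {
    g <- gen_planted_richclub(core = 6, periphery = 60, p_periph = 0.03,
                              seed = s)
    curve <- rich_club_normalized(g, n_null = 50, seed = 40 + s)
    deg <- igraph::degree(g)[core]
    med_phinorm[s] <- stats::median(curve$phi_norm[match(deg, curve$k)],
                                    na.rm = TRUE)
    ex <- extract_rich_club_nodes(g, curve, mode = "contiguous")
    core_frac[s] <- mean(core %in% ex$node)
  }
  expect_gte(stats::median(med_phinorm), 1.1)
  expect_equal(stats::median(core_frac), 1)

  er_mid <- numeric(5)
  for (s in 1:5) {
    g <- gen_erdos_renyi(200, 0.05, seed = s)
    curve <- rich_club_normalized(g, n_null = 50, seed = 60 + s)
    qs <- stats::quantile(igraph::degree(g), c(0.25, 0.75))
    er_mid[s] <- stats::median(
      curve$phi_norm[curve$k >= qs[1] & curve$k <= qs[2]], na.rm = TRUE)
  }
  expect_true(stats::median(er_mid) > 0.8 && stats::median(er_mid) < 1.2)
})

test_that("extraction follows the literal per-degree rule", {
  g <- gen_planted_richclub(core = 5, periphery = 20, p_periph = 0.05,
                            seed = 8)
  curve <- rich_club_normalized(g, n_null = 20, seed = 9)
  picked <- extract_rich_club_nodes(g, curve, threshold = 1.1)
  pass_k <- curve$k[!is.na(curve$phi_norm) & curve$phi_norm >= 1.1]
  deg <- igraph::degree(g)
  expect_setequal(picked$node, names(deg)[deg %in% pass_k])

  # threshold 0 admits every node whose degree has a defined phi_norm
  all_def <- extract_rich_club_nodes(g, curve, threshold = 0)
  def_k <- curve$k[!is.na(curve$phi_norm)]
  expect_setequal(all_def$node, names(deg)[deg %in% def_k])
})
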
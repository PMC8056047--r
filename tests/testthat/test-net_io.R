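test_that("packaged seed-gene table parses to 117 validated records", {
  genes <- fixture_gene_table()
  expect_equal(nrow(genes), 117)
  expect_true(all(c("symbol", "gene_id", "description", "location",
                    "reference") %in% names(genes)))
  expect_false(any(duplicated(genes$symbol)))
  expect_false(any(duplicated(genes$gene_id)))
  tp53 <- genes[genes$gene_id == 7157, ]
  expect_equal(tp53$symbol, "TP53")
  expect_equal(tp53$location, "17p13.1")
  tnip1 <- genes[genes$gene_id == 10318, ]
  expect_equal(tnip1$symbol, "TNIP1")
  expect_equal(tnip1$location, "5q33.1")
})

test_that("gene-table validation rejects duplicates and malformed rows", {
  dup <- write_edge_file(c("symbol\tgene_id", "TP53\t7157", "TP53\t999"))
  expect_error(read_gene_table(dup), "duplicate gene symbol")
  dup_id <- write_edge_file(c("symbol\tgene_id", "TP53\t7157", "BRCA1\t7157"))
  expect_error(read_gene_table(dup_id), "duplicate gene_id")
  bad <- write_edge_file(c("symbol\tgene_id", "TP53\tseven"))
  expect_error(read_gene_table(bad), "line 2")
  empty <- write_edge_file("symbol\tgene_id")
  expect_equal(nrow(read_gene_table(empty)), 0)
  nocol <- write_edge_file(c("name\tid", "TP53\t7157"))
  expect_error(read_gene_table(nocol), "symbol")
})

test_that("scored-edge reading filters strictly, collapses duplicates, detects scale", {
  p1 <- write_edge_file(c("A\tB\t0.9", "B\tC\t0.6", "C\tD\t0.4"))
  rec <- read_scored_edges(p1, threshold = 0.5)
  expect_equal(nrow(rec), 2)
  expect_false(any(rec$score <= 0.5))

  # boundary score equal to the threshold is excluded (strict >)
  p_eq <- write_edge_file(c("A\tB\t0.5"))
  expect_equal(nrow(read_scored_edges(p_eq, threshold = 0.5)), 0)

  p2 <- write_edge_file(c("A\tB\t0.7", "B\tA\t0.8"))
  rec2 <- read_scored_edges(p2, threshold = 0.5)
  expect_equal(nrow(rec2), 1)
  expect_equal(rec2$score, 0.8)

  p3 <- write_edge_file(c("protein1\tprotein2\tcombined_score",
                          "A\tB\t900", "B\tC\t400"))
  rec3 <- read_scored_edges(p3, threshold = 0.5)
  expect_equal(nrow(rec3), 1)
  expect_equal(rec3$score, 0.9)

  # a non-numeric score below the header line is a parse error (the first
  # line alone would be read as a header)
  bad <- write_edge_file(c("protein1\tprotein2\tcombined_score",
                           "A\tB\t0.9", "B\tC\tnine"))
  expect_error(read_scored_edges(bad), "line 3")
  out_of_scale <- write_edge_file(c("A\tB\t1500"))
  expect_error(read_scored_edges(out_of_scale), "scale")
})

test_that("raising the threshold never adds edges", {
  set.seed(31)
  lines <- sprintf("n%d\tn%d\t%.3f", sample(20, 60, TRUE),
                   sample(20, 60, TRUE), runif(60))
  p <- write_edge_file(lines)
  prev <- Inf
  for (th in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    n_now <- nrow(read_scored_edges(p, threshold = th))
    expect_lte(n_now, prev)
    prev <- n_now
  }
})

test_that("build_network yields a simple undirected graph", {
  tri <- tibble::tibble(node_a = c("A", "B", "C"), node_b = c("B", "C", "A"),
                        score = c(0.9, 0.8, 0.7))
  g <- build_network(tri)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 3)
  expect_false(igraph::any_multiple(g))

  expect_equal(igraph::ecount(build_network(tri[0, ])), 0)

  dup <- tibble::tibble(node_a = c("A", "A"), node_b = c("B", "B"))
  expect_equal(igraph::ecount(build_network(dup)), 1)

  loop <- tibble::tibble(node_a = c("A", "B"), node_b = c("A", "C"))
  expect_warning(g2 <- build_network(loop), "self-loop")
  expect_equal(igraph::ecount(g2), 1)
})

test_that("graph writing round-trips nodes and edges in both formats", {
  g <- graph_two_triangles_bridge()
  g <- igraph::add_vertices(g, 1, name = "ISO") # isolated node
  for (fmt in c("graphml", "edgelist-tsv")) {
    path <- withr::local_tempfile(fileext = ".graph")
    write_graph_file(g, path, format = fmt)
    back <- read_graph_file(path, format = fmt)
    expect_setequal(igraph::V(back)$name, igraph::V(g)$name)
    canon <- function(x) {
      el <- igraph::as_edgelist(x)
      sorted <- t(apply(el, 1, sort))
      paste(sorted[, 1], sorted[, 2])
    }
    expect_setequal(canon(back), canon(g))
  }
  expect_error(write_graph_file(g, tempfile(), format = "dot"))

  # empty network round trip
  e <- igraph::make_empty_graph(0, directed = FALSE)
  path <- withr::local_tempfile()
  write_graph_file(e, path, format = "edgelist-tsv")
  expect_equal(igraph::vcount(read_graph_file(path, format = "edgelist-tsv")), 0)
})
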
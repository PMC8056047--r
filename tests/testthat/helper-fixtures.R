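# small named graphs used across tests

graph_triangle <- function() {
  igraph::graph_from_literal(A - B, B - C, C - A)
}

graph_path3 <- function() {
  igraph::graph_from_literal(A - B, B - C)
}

graph_star5 <- function() {
  igraph::graph_from_literal(H - L1, H - L2, H - L3, H - L4)
}

graph_k4 <- function() {
  g <- igraph::make_full_graph(4)
  igraph::V(g)$name <- LETTERS[1:4]
  g
}

graph_two_triangles_bridge <- function() {
  igraph::graph_from_literal(A - B, B - C, C - A, D - E, E - F, F - D, C - D)
}

graph_two_triangles_disconnected <- function() {
  igraph::graph_from_literal(A - B, B - C, C - A, D - E, E - F, F - D)
}

write_edge_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  readr::write_lines(lines, path)
  path
}
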
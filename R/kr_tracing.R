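# Walk a gene from the root of the community tree to the deepest
# non-pruned community containing it. Returns the chain of community ids
# (possibly just the root, or character() when the gene is absent).
trace_path <- function(tree, gene) {
  root <- tree$index[[tree$root_id]]
  pos <- match(toupper(gene), toupper(root$members))
  if (is.na(pos)) return(character())
  node_name <- root$members[pos]
  path <- tree$root_id
  cur <- root
  repeat {
    if (cur$pruned || length(cur$children) == 0) break
    nxt <- NULL
    for (cid in cur$children) {
      child <- tree$index[[cid]]
      if (node_name %in% child$members) { nxt <- child; break }
    }
    if (is.null(nxt) || nxt$pruned) break
    path <- c(path, nxt$id)
    cur <- nxt
  }
  path
}

# All triangles inside a community that contain the given node; returns a
# list of sorted character triples.
triangles_with_node <- function(tree, community_id, node) {
  sub <- community_subgraph(tree, community_id)
  if (!node %in% igraph::V(sub)$name) return(list())
  nb <- igraph::V(sub)$name[as.integer(
    igraph::neighbors(sub, node))]
  if (length(nb) < 2) return(list())
  out <- list()
  pairs <- utils::combn(nb, 2)
  for (j in seq_len(ncol(pairs))) {
    if (igraph::are_adjacent(sub, pairs[1, j], pairs[2, j])) {
      out[[length(out) + 1]] <- sort(c(node, pairs[1, j], pairs[2, j]))
    }
  }
  out
}

#' Trace seed genes through the community hierarchy
#'
#' Follows each seed gene from the root community down the tree to the
#' deepest non-pruned community containing it. Gene symbols are matched
#' case-insensitively. Seeds absent from the network get an empty trace and
#' are flagged in the `present` column.
#'
#' @param tree A `community_tree` from [decompose_network()].
#' @param seeds Character vector of gene symbols (or a data frame with a
#'   `symbol` column).
#' @return A tibble with columns `seed`, `present`, `path` (list column of
#'   community ids, root first), `depth`, `terminal_community`,
#'   `reached_terminal` (the trace ends in a terminal community) and
#'   `in_terminal_triangle` (the seed belongs to a triangle there).
#' @export
trace_seeds <- function(tree, seeds) {
  stopifnot(inherits(tree, "community_tree"))
  if (is.data.frame(seeds)) seeds <- seeds$symbol
  seeds <- as.character(seeds)
  if (length(seeds) == 0) {
    return(tibble::tibble(seed = character(), present = logical(),
                          path = list(), depth = integer(),
                          terminal_community = character(),
                          reached_terminal = logical(),
                          in_terminal_triangle = logical()))
  }
  purrr::map_dfr(seeds, function(s) {
    path <- trace_path(tree, s)
    if (length(path) == 0) {
      return(tibble::tibble(seed = s, present = FALSE, path = list(character()),
                            depth = NA_integer_,
                            terminal_community = NA_character_,
                            reached_terminal = FALSE,
                            in_terminal_triangle = FALSE))
    }
    last <- tree$index[[path[length(path)]]]
    reached <- isTRUE(last$terminal)
    node_name <- last$members[match(toupper(s), toupper(last$members))]
    in_tri <- reached &&
      length(triangles_with_node(tree, last$id, node_name)) > 0
    tibble::tibble(seed = s, present = TRUE, path = list(path),
                   depth = last$level, terminal_community = last$id,
                   reached_terminal = reached, in_terminal_triangle = in_tri)
  })
}

#' Identify key regulators and their motif partners
#'
#' Key regulators are the seed genes that persist to a terminal community
#' of the hierarchy inside a triangle, together with the other members of
#' every terminal triangle containing such a seed (the motif partners; a
#' seed lying in two triangles that share an edge contributes the union of
#' both, giving 4-member motifs).
#'
#' @param tree A `community_tree`.
#' @param traces A tibble from [trace_seeds()].
#' @return An object of class `kr_report`: list with `seed_krs`,
#'   `partner_krs`, `motifs` (tibble: `motif_id`, `community`, `seed`,
#'   `members` list column), `p_kr` (per-gene per-level edge-share table),
#'   `popularity` (degree ranks of all KRs in the root network) and
#'   `dropped_seeds` (seeds absent from the network).
#' @export
identify_key_regulators <- function(tree, traces) {
  stopifnot(inherits(tree, "community_tree"), is.data.frame(traces))
  dropped <- traces$seed[!traces$present]
  hits <- traces[traces$in_terminal_triangle, , drop = FALSE]

  motifs <- list()
  seed_krs <- character()
  partner_krs <- character()
  if (nrow(hits) > 0) {
    for (i in seq_len(nrow(hits))) {
      cid <- hits$terminal_community[i]
      comm <- tree$index[[cid]]
      seed_node <- comm$members[match(toupper(hits$seed[i]),
                                      toupper(comm$members))]
      tris <- triangles_with_node(tree, cid, seed_node)
      seed_krs <- c(seed_krs, seed_node)
      for (tri in tris) {
        motifs[[length(motifs) + 1]] <- list(community = cid,
                                             seed = seed_node, members = tri)
        partner_krs <- c(partner_krs, setdiff(tri, seed_node))
      }
    }
  }
  seed_krs <- unique(seed_krs)
  partner_krs <- setdiff(unique(partner_krs), seed_krs)
  motif_tbl <- if (length(motifs) == 0) {
    tibble::tibble(motif_id = character(), community = character(),
                   seed = character(), members = list())
  } else {
    tibble::tibble(
      motif_id = paste0("m", seq_along(motifs)),
      community = vapply(motifs, `[[`, character(1), "community"),
      seed = vapply(motifs, `[[`, character(1), "seed"),
      members = lapply(motifs, `[[`, "members")
    )
  }

  krs <- c(seed_krs, partner_krs)
  p_kr <- if (length(krs) == 0) {
    tibble::tibble(gene = character(), level = integer(),
                   community = character(), x = integer(), e = integer(),
                   p_kr = double())
  } else {
    purrr::map_dfr(krs, function(gn) kr_probability(tree, gn))
  }
  popularity <- if (length(krs) == 0) {
    tibble::tibble(gene = character(), degree = integer(), rank = integer())
  } else {
    popularity_rank(tree$graph, krs)
  }

  structure(
    list(seed_krs = seed_krs, partner_krs = partner_krs, motifs = motif_tbl,
         p_kr = p_kr, popularity = popularity, dropped_seeds = dropped),
    class = "kr_report"
  )
}

#' @export
print.kr_report <- function(x, ...) {
  cat(sprintf("Key-regulator report: %d seed KR(s) [%s], %d partner KR(s) [%s], %d motif(s)\n",
              length(x$seed_krs), paste(x$seed_krs, collapse = ", "),
              length(x$partner_krs), paste(x$partner_krs, collapse = ", "),
              nrow(x$motifs)))
  if (length(x$dropped_seeds) > 0) {
    cat("Seeds absent from the network: ",
        paste(x$dropped_seeds, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.kr_report <- function(x, ...) {
  if (nrow(x$motifs) == 0) {
    return(tibble::tibble(gene = character(), role = character(),
                          motif_id = character(), level = integer(),
                          p_kr = double()))
  }
  flat <- tidyr::unnest(
    dplyr::mutate(x$motifs, gene = .data$members),
    "gene"
  )
  flat$role <- ifelse(flat$gene %in% x$seed_krs, "seed_kr", "partner_kr")
  terminal <- x$p_kr |>
    dplyr::group_by(gene = .data$gene) |>
    dplyr::slice_max(.data$level, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("gene", "level", "p_kr")
  dplyr::left_join(
    dplyr::select(flat, "gene", "role", "motif_id", "community"),
    terminal, by = "gene"
  )
}

#' @export
glance.kr_report <- function(x, ...) {
  tibble::tibble(
    n_seed_krs = length(x$seed_krs),
    n_partner_krs = length(x$partner_krs),
    n_motifs = nrow(x$motifs),
    n_dropped_seeds = length(x$dropped_seeds)
  )
}

#' Per-level regulatory share of a gene
#'
#' At each level of a gene's trace, the proportion
#' \eqn{P_{KR} = x^{(l)} / E^{(l)}} of the community's internal edges that
#' are incident to the gene, where \eqn{x^{(l)}} is the gene's degree
#' within the level-\eqn{l} community's induced subgraph and \eqn{E^{(l)}}
#' that community's internal edge count. Communities with no internal
#' edges yield `NA`.
#'
#' @param tree A `community_tree`.
#' @param gene Gene symbol (case-insensitive).
#' @return A tibble with columns `gene`, `level`, `community`, `x`, `e`,
#'   `p_kr`.
#' @export
kr_probability <- function(tree, gene) {
  stopifnot(inherits(tree, "community_tree"))
  path <- trace_path(tree, gene)
  if (length(path) == 0) stop("gene not present in the network: ", gene)
  root <- tree$index[[tree$root_id]]
  node_name <- root$members[match(toupper(gene), toupper(root$members))]
  purrr::map_dfr(path, function(cid) {
    rec <- tree$index[[cid]]
    sub <- community_subgraph(tree, cid)
    x <- as.integer(igraph::degree(sub, node_name))
    e <- rec$e_c
    tibble::tibble(gene = node_name, level = rec$level, community = cid,
                   x = x, e = e,
                   p_kr = if (e == 0) NA_real_ else x / e)
  })
}

#' Degree-based popularity ranks
#'
#' Competition ("1224") ranking of nodes by descending degree over the
#' whole network: tied nodes share the smallest rank of their group and
#' the following rank is skipped.
#'
#' @param network An `igraph` graph or edge data frame.
#' @param genes Character vector of node names to report (matched
#'   case-insensitively); absent genes are dropped with a warning.
#' @return A tibble with columns `gene`, `degree`, `rank`.
#' @export
popularity_rank <- function(network, genes) {
  g <- as_kr_graph(network)
  deg <- igraph::degree(g)
  all_rank <- dplyr::min_rank(dplyr::desc(deg))
  nodes <- igraph::V(g)$name
  idx <- match(toupper(as.character(genes)), toupper(nodes))
  if (anyNA(idx)) {
    warning("gene(s) absent from the network: ",
            paste(genes[is.na(idx)], collapse = ", "))
  }
  keep <- !is.na(idx)
  tibble::tibble(gene = nodes[idx[keep]],
                 degree = as.integer(deg[idx[keep]]),
                 rank = as.integer(all_rank[idx[keep]]))
}
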
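#' Remove nodes from a network
#'
#' Deletes the given nodes and all their incident edges, returning the
#' induced subgraph on the complement.
#'
#' @param network An `igraph` graph or edge data frame.
#' @param nodes Character vector of node names; all must exist.
#' @return The reduced `igraph` graph.
#' @export
knockout_nodes <- function(network, nodes) {
  g <- as_kr_graph(network)
  nodes <- as.character(nodes)
  miss <- setdiff(nodes, igraph::V(g)$name)
  if (length(miss) > 0) {
    stop("unknown node(s): ", paste(miss, collapse = ", "))
  }
  igraph::delete_vertices(g, nodes)
}

#' In-silico knockout of a key-regulator motif at every level
#'
#' Walks the community tree from the root down along the chain of
#' communities containing the whole motif. At each level the motif's nodes
#' are removed from that level's community subgraph, and the topology
#' exponents (six power-law fits) and Constant Potts Model energy are
#' recomputed on the modified subgraph. Fits on subgraphs with fewer than
#' three usable degree points are reported missing. A level at which the
#' motif is only partially present is skipped with a warning.
#'
#' @param tree A `community_tree`.
#' @param motif Character vector of motif node names (normally a triangle's
#'   three members).
#' @param gamma CPM resolution parameter (default 0.5).
#' @param fit_space Passed to [topology_exponents()].
#' @return An object of class `knockout_result`: a list of per-level
#'   records, each holding `level`, `community`, `removed_nodes`,
#'   `n_before`, `e_before`, `n_after`, `e_after`, `he_before`, `he_after`,
#'   `fragmented`, `exponents_before` and `exponents_after` (tibbles from
#'   [topology_exponents()]).
#' @export
knockout_experiment <- function(tree, motif, gamma = 0.5,
                                fit_space = c("loglog", "direct")) {
  stopifnot(inherits(tree, "community_tree"))
  fit_space <- match.arg(fit_space)
  motif <- as.character(motif)
  root <- tree$index[[tree$root_id]]
  absent <- setdiff(motif, root$members)
  if (length(absent) > 0) {
    stop("motif node(s) absent from the network: ",
         paste(absent, collapse = ", "))
  }

  # chain of communities containing the whole motif, root first
  path <- character()
  cur <- root
  repeat {
    if (all(motif %in% cur$members)) {
      path <- c(path, cur$id)
    } else {
      warning("motif split across communities below ", cur$parent,
              "; level ", cur$level, " skipped")
      break
    }
    if (cur$pruned || length(cur$children) == 0) break
    nxt <- NULL
    for (cid in cur$children) {
      child <- tree$index[[cid]]
      if (any(motif %in% child$members)) { nxt <- child; break }
    }
    if (is.null(nxt) || nxt$pruned) break
    cur <- nxt
  }

  results <- lapply(path, function(cid) {
    sub <- community_subgraph(tree, cid)
    after <- igraph::delete_vertices(sub, motif)
    he_b <- hamiltonian_energy(sub, gamma = gamma)$he
    he_a <- hamiltonian_energy(after, gamma = gamma)$he
    exps_b <- topology_exponents(sub, fit_space = fit_space)
    exps_a <- if (igraph::vcount(after) == 0) {
      dplyr::mutate(exps_b, prefactor = NA_real_, exponent = NA_real_,
                    r_squared = NA_real_, n_points = 0L)
    } else {
      topology_exponents(after, fit_space = fit_space)
    }
    fragmented <- igraph::vcount(after) == 0 ||
      igraph::components(after)$no > 1
    list(level = tree$index[[cid]]$level, community = cid,
         removed_nodes = motif,
         n_before = igraph::vcount(sub), e_before = igraph::ecount(sub),
         n_after = igraph::vcount(after), e_after = igraph::ecount(after),
         he_before = he_b, he_after = he_a, fragmented = fragmented,
         exponents_before = exps_b, exponents_after = exps_a)
  })
  structure(list(motif = motif, levels = results), class = "knockout_result")
}

#' @export
print.knockout_result <- function(x, ...) {
  cat(sprintf("Knockout of motif {%s} across %d level(s):\n",
              paste(x$motif, collapse = ", "), length(x$levels)))
  for (r in x$levels) {
    cat(sprintf("  level %d (%s): HE %.2f -> %.2f%s\n", r$level, r$community,
                r$he_before, r$he_after,
                if (r$fragmented) "  [fragmented]" else ""))
  }
  invisible(x)
}

#' Per-level exponent changes caused by a knockout
#'
#' Flattens one or more knockout results into a tidy table of exponent
#' deltas, one row per (level, property).
#'
#' @param results A `knockout_result` or a list of them.
#' @return A tibble with columns `motif`, `level`, `community`, `property`,
#'   `before`, `after`, `delta` (`NA` when either fit is missing), plus
#'   `he_before`, `he_after`, `he_delta` and `fragmented`.
#' @export
compare_exponent_trajectories <- function(results) {
  if (inherits(results, "knockout_result")) results <- list(results)
  stopifnot(length(results) >= 1)
  purrr::map_dfr(results, function(res) {
    purrr::map_dfr(res$levels, function(r) {
      before <- dplyr::select(r$exponents_before, "property",
                              before = "exponent")
      after <- dplyr::select(r$exponents_after, "property",
                             after = "exponent")
      dplyr::left_join(before, after, by = "property") |>
        dplyr::mutate(
          motif = paste(res$motif, collapse = "+"),
          level = r$level, community = r$community,
          delta = .data$after - .data$before,
          he_before = r$he_before, he_after = r$he_after,
          he_delta = r$he_after - r$he_before,
          fragmented = r$fragmented
        ) |>
        dplyr::relocate("motif", "level", "community")
    })
  })
}
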
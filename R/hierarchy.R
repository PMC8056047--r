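#' Modularity of a partition
#'
#' Evaluates \eqn{Q = \frac{1}{2m}\sum_{ij}(A_{ij} - k_i k_j / 2m)\,
#' \delta(C_i, C_j)} for a given node-to-community assignment.
#'
#' @param network An `igraph` graph or edge data frame.
#' @param membership A vector of community labels named by node, or an
#'   unnamed vector in vertex order covering every node.
#' @return The modularity `Q` (0 for an edgeless network).
#' @export
modularity_q <- function(network, membership) {
  g <- as_kr_graph(network)
  n <- igraph::vcount(g)
  if (!is.null(names(membership))) {
    miss <- setdiff(igraph::V(g)$name, names(membership))
    if (length(miss) > 0) {
      stop("membership missing for node(s): ", paste(miss, collapse = ", "))
    }
    membership <- membership[igraph::V(g)$name]
  } else if (length(membership) != n) {
    stop("membership must cover all ", n, " nodes")
  }
  if (anyNA(membership)) stop("membership contains NA")
  m <- igraph::ecount(g)
  if (m == 0) return(0)
  comm <- as.character(membership)
  deg <- igraph::degree(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  within_edges <- comm[el[, 1]] == comm[el[, 2]]
  # count within-community edges per community
  e_c_all <- stats::setNames(rep(0, length(unique(comm))), unique(comm))
  e_c <- vapply(split(within_edges, comm[el[, 1]]), sum, numeric(1))
  e_c_all[names(e_c)] <- e_c
  d_c <- vapply(split(deg, comm), sum, numeric(1))
  unname(sum(e_c_all[names(d_c)] / m - (d_c / (2 * m))^2))
}

#' Split a network into communities by the leading-eigenvector method
#'
#' Recursive spectral bisection along the leading eigenvector of the
#' (generalized) modularity matrix, after Newman's community-detection
#' algorithm. The input graph is treated as a standalone network.
#' Disconnected components are separated first; each group is then
#' repeatedly bisected while the split increases modularity. Determinism:
#' the leading eigenvector's sign is fixed so that its largest-magnitude
#' entry is positive, and exactly-zero entries go to the positive side.
#'
#' @param network An `igraph` graph or edge data frame.
#' @param tol Minimal modularity gain for accepting a bisection.
#' @return A list with `membership` (integer labels named by node),
#'   `modularity` (Q of the returned partition) and `n_communities`.
#'   A network that cannot be profitably split returns the trivial
#'   single-community partition.
#' @export
lev_split <- function(network, tol = 1e-10) {
  g <- as_kr_graph(network)
  n <- igraph::vcount(g)
  if (n == 0) stop("network is empty")
  nodes <- igraph::V(g)$name
  m <- igraph::ecount(g)
  if (n == 1 || m == 0) {
    memb <- stats::setNames(rep(1L, n), nodes)
    return(list(membership = memb, modularity = modularity_q(g, memb),
                n_communities = 1L))
  }
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  k <- rowSums(A)
  B <- A - outer(k, k) / (2 * m)

  comps <- igraph::components(g)
  queue <- unname(split(seq_len(n), comps$membership))
  final <- list()
  while (length(queue) > 0) {
    grp <- queue[[1]]
    queue <- queue[-1]
    if (length(grp) < 2) {
      final <- c(final, list(grp))
      next
    }
    Bg <- B[grp, grp, drop = FALSE]
    diag(Bg) <- diag(Bg) - rowSums(Bg)
    es <- eigen(Bg, symmetric = TRUE)
    v <- es$vectors[, 1]
    if (es$values[1] <= tol) {
      final <- c(final, list(grp))
      next
    }
    if (v[which.max(abs(v))] < 0) v <- -v
    s <- ifelse(v >= 0, 1, -1)
    if (length(unique(s)) == 1) {
      final <- c(final, list(grp))
      next
    }
    dq <- drop(t(s) %*% Bg %*% s) / (4 * m)
    if (dq <= tol) {
      final <- c(final, list(grp))
      next
    }
    queue <- c(queue, list(grp[s > 0]), list(grp[s < 0]))
  }

  memb <- integer(n)
  for (i in seq_along(final)) memb[final[[i]]] <- i
  # stable labels: communities numbered by their smallest vertex index
  order_first <- order(vapply(split(seq_len(n), memb), min, numeric(1)))
  relabel <- match(seq_along(final), order_first)
  memb <- relabel[memb]
  memb <- stats::setNames(as.integer(memb), nodes)
  list(membership = memb, modularity = modularity_q(g, memb),
       n_communities = length(final))
}

#' Does the network contain a triangle?
#'
#' A triangle is the 3-node, 3-edge motif used as the qualification
#' criterion for communities and key regulators.
#'
#' @param network An `igraph` graph or edge data frame.
#' @return `TRUE` iff some three nodes are mutually adjacent.
#' @export
contains_triangle <- function(network) {
  g <- as_kr_graph(network)
  if (igraph::vcount(g) < 3) return(FALSE)
  sum(igraph::count_triangles(g)) > 0
}

#' Recursive hierarchical community decomposition
#'
#' Recursively applies [lev_split()] to the network and to each resulting
#' community's induced subgraph (edges to the outside ignored), building a
#' rooted community tree. A community lacking a triangle is marked *pruned*
#' and not recursed into; a community is *terminal* when it is a single
#' triangle, when no split increases its modularity, or when `max_levels`
#' is reached. Every non-pruned leaf therefore contains at least one
#' triangle.
#'
#' @param network An `igraph` graph or edge data frame.
#' @param max_levels Maximum recursion depth (default 10).
#' @return An object of class `community_tree`: list with `graph`, `index`
#'   (a named list of community records holding `id`, `level`, `members`,
#'   `n_c`, `e_c`, `q_split`, `has_triangle`, `pruned`, `terminal`,
#'   `parent`, `children`), `root_id` and `levels` (max depth reached by a
#'   non-pruned community).
#' @export
decompose_network <- function(network, max_levels = 10) {
  if (max_levels < 1) stop("max_levels must be >= 1")
  g <- as_kr_graph(network)
  if (igraph::vcount(g) == 0) stop("network is empty")

  index <- list()
  recurse <- function(members, level, id, parent) {
    sub <- igraph::induced_subgraph(g, members)
    rec <- list(
      id = id, level = level, members = members,
      n_c = length(members), e_c = igraph::ecount(sub),
      q_split = NA_real_,
      has_triangle = contains_triangle(sub),
      pruned = FALSE, terminal = FALSE,
      parent = parent, children = character()
    )
    if (!rec$has_triangle) {
      rec$pruned <- TRUE
    } else if (rec$n_c == 3 && rec$e_c == 3) {
      rec$terminal <- TRUE
    } else if (level >= max_levels) {
      rec$terminal <- TRUE
    } else {
      sp <- lev_split(sub)
      if (sp$n_communities == 1) {
        rec$terminal <- TRUE
      } else {
        rec$q_split <- sp$modularity
        parts <- split(names(sp$membership), sp$membership)
        rec$children <- paste0(id, ".", seq_along(parts))
        index[[id]] <<- rec
        for (i in seq_along(parts)) {
          recurse(parts[[i]], level + 1L, rec$children[i], id)
        }
        return(invisible(NULL))
      }
    }
    index[[id]] <<- rec
    invisible(NULL)
  }
  recurse(igraph::V(g)$name, 0L, "c0", NA_character_)

  lv <- vapply(index, function(r) r$level, integer(1))
  pruned <- vapply(index, function(r) r$pruned, logical(1))
  levels <- if (all(pruned)) 0L else max(lv[!pruned])
  structure(
    list(graph = g, index = index, root_id = "c0", levels = levels,
         max_levels = max_levels),
    class = "community_tree"
  )
}

#' @export
print.community_tree <- function(x, ...) {
  cat(sprintf(
    "Community tree: %d communities over levels 0..%d (%d terminal, %d pruned) on %d nodes / %d edges\n",
    length(x$index), x$levels,
    sum(vapply(x$index, function(r) r$terminal, logical(1))),
    sum(vapply(x$index, function(r) r$pruned, logical(1))),
    igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Induced subgraph of one community
#'
#' @param tree A `community_tree`.
#' @param id Community identifier.
#' @return An `igraph` graph.
#' @export
community_subgraph <- function(tree, id) {
  stopifnot(inherits(tree, "community_tree"))
  rec <- tree$index[[id]]
  if (is.null(rec)) stop("no community with id ", id)
  igraph::induced_subgraph(tree$graph, rec$members)
}

#' Per-level summary of a community tree
#'
#' One row per level holding the number of non-pruned communities, the mean
#' split modularity of the communities divided at that level, the summed
#' Constant Potts Model Hamiltonian energy, and the average
#' local-community-paradigm correlation (communities with missing or
#' exactly-zero correlation excluded). Pruned fragments do not contribute.
#'
#' @param tree A `community_tree`.
#' @param gamma CPM resolution parameter for the energy column (default
#'   0.5).
#' @return A tibble with columns `level`, `n_communities`, `mean_q`,
#'   `total_he`, `mean_lcp_corr`.
#' @export
level_summary <- function(tree, gamma = 0.5) {
  stopifnot(inherits(tree, "community_tree"))
  recs <- Filter(function(r) !r$pruned, tree$index)
  if (length(recs) == 0) {
    return(tibble::tibble(level = integer(), n_communities = integer(),
                          mean_q = double(), total_he = double(),
                          mean_lcp_corr = double()))
  }
  tbl <- purrr::map_dfr(recs, function(r) {
    tibble::tibble(level = r$level, q = r$q_split,
                   he = gamma * r$n_c^2 - r$e_c, id = r$id)
  })
  lcp_by_level <- vapply(sort(unique(tbl$level)), function(lv) {
    level_average_lcp(tree, lv)
  }, numeric(1))
  tbl |>
    dplyr::group_by(level = .data$level) |>
    dplyr::summarise(
      n_communities = dplyr::n(),
      mean_q = if (all(is.na(.data$q))) NA_real_ else mean(.data$q, na.rm = TRUE),
      total_he = sum(.data$he),
      .groups = "drop"
    ) |>
    dplyr::mutate(mean_lcp_corr = lcp_by_level) |>
    dplyr::arrange(.data$level)
}

#' @export
tidy.community_tree <- function(x, ...) {
  purrr::map_dfr(x$index, function(r) {
    tibble::tibble(
      id = r$id, level = r$level, n_c = r$n_c, e_c = r$e_c,
      q_split = r$q_split, has_triangle = r$has_triangle,
      pruned = r$pruned, terminal = r$terminal,
      parent = r$parent, n_children = length(r$children),
      members = list(r$members)
    )
  }) |>
    dplyr::arrange(.data$level, .data$id)
}

#' @export
glance.community_tree <- function(x, ...) {
  recs <- x$index
  tibble::tibble(
    n_nodes = igraph::vcount(x$graph),
    n_edges = igraph::ecount(x$graph),
    n_communities = length(recs),
    levels = x$levels,
    n_terminal = sum(vapply(recs, function(r) r$terminal, logical(1))),
    n_pruned = sum(vapply(recs, function(r) r$pruned, logical(1)))
  )
}
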
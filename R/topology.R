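#' Per-node topological properties
#'
#' Computes the six per-node properties used to characterize scale-free and
#' hierarchical structure: degree \eqn{k}, local clustering coefficient
#' \eqn{C}, neighborhood connectivity \eqn{C_N} (mean degree of the node's
#' neighbors), betweenness centrality \eqn{C_B}, closeness centrality
#' \eqn{C_C} and eigenvector centrality \eqn{C_E}.
#'
#' Conventions on degenerate cases:
#' * clustering is `NA` for nodes of degree < 2;
#' * neighborhood connectivity is `NA` for isolated nodes;
#' * betweenness is the raw sum over unordered pairs \eqn{s \ne t \ne n} of
#'   the fraction of shortest \eqn{s}-\eqn{t} paths through \eqn{n};
#'   set `normalize_betweenness = TRUE` to divide by \eqn{(N-1)(N-2)/2};
#' * closeness of node \eqn{n} is \eqn{(N_c - 1) / \sum_j d_{nj}} where
#'   \eqn{N_c} counts the nodes of \eqn{n}'s connected component (isolated
#'   nodes get `NA`);
#' * eigenvector centrality is the principal eigenvector of the adjacency
#'   matrix of the largest connected component, normalized to unit Euclidean
#'   norm with non-negative entries; nodes outside that component get `NA`.
#'
#' Shortest paths are unweighted: edge scores are confidence values, not
#' distances.
#'
#' @param network An `igraph` graph or edge data frame.
#' @param normalize_betweenness Divide raw betweenness by
#'   \eqn{(N-1)(N-2)/2}? Default `FALSE`.
#' @return A tibble with columns `node`, `degree`, `clustering`,
#'   `neighborhood_connectivity`, `betweenness`, `closeness`, `eigenvector`.
#' @export
node_metrics <- function(network, normalize_betweenness = FALSE) {
  g <- as_kr_graph(network)
  n <- igraph::vcount(g)
  if (n == 0) stop("network is empty")
  deg <- igraph::degree(g)

  clust <- suppressWarnings(
    igraph::transitivity(g, type = "local", isolates = "NaN")
  )
  clust[deg < 2] <- NA_real_
  clust[is.nan(clust)] <- NA_real_

  nc <- if (igraph::ecount(g) > 0) {
    igraph::knn(g, weights = NA)$knn
  } else {
    rep(NaN, n)
  }
  nc[is.nan(nc)] <- NA_real_

  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  if (normalize_betweenness && n > 2) btw <- btw / ((n - 1) * (n - 2) / 2)

  comps <- igraph::components(g)
  clo <- rep(NA_real_, n)
  ev <- rep(NA_real_, n)
  for (cid in seq_len(comps$no)) {
    idx <- which(comps$membership == cid)
    if (length(idx) < 2) next
    d <- igraph::distances(g, v = idx, to = idx, weights = NA)
    clo[idx] <- (length(idx) - 1) / rowSums(d)
  }
  # eigenvector centrality lives on the largest component (first in vertex
  # order on ties)
  big <- which(comps$csize == max(comps$csize))[1]
  idx <- which(comps$membership == big)
  if (length(idx) == 1) {
    ev[idx] <- 1
  } else {
    sub <- igraph::induced_subgraph(g, idx)
    v <- igraph::eigen_centrality(sub, weights = NA)$vector
    v <- abs(v)
    ev[idx] <- v / sqrt(sum(v^2))
  }

  tibble::tibble(
    node = igraph::V(g)$name,
    degree = as.integer(unname(deg)),
    clustering = unname(clust),
    neighborhood_connectivity = unname(nc),
    betweenness = unname(btw),
    closeness = unname(clo),
    eigenvector = unname(ev)
  )
}

#' Aggregate node metrics by degree
#'
#' Collapses per-node properties into one row per observed degree: the
#' empirical degree-distribution probability \eqn{P(k) = n_k / N} and the
#' mean of each remaining property over the nodes of that degree (missing
#' values skipped). This degree profile is the input to power-law fitting.
#'
#' @param metrics A tibble from [node_metrics()].
#' @return A tibble with columns `degree`, `n_k`, `p_k`, `mean_clustering`,
#'   `mean_neighborhood_connectivity`, `mean_betweenness`, `mean_closeness`,
#'   `mean_eigenvector`, sorted by degree.
#' @export
aggregate_by_degree <- function(metrics) {
  stopifnot(is.data.frame(metrics), nrow(metrics) > 0)
  mean_or_na <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) NA_real_ else mean(x)
  }
  metrics |>
    dplyr::group_by(degree = .data$degree) |>
    dplyr::summarise(
      n_k = dplyr::n(),
      mean_clustering = mean_or_na(.data$clustering),
      mean_neighborhood_connectivity = mean_or_na(.data$neighborhood_connectivity),
      mean_betweenness = mean_or_na(.data$betweenness),
      mean_closeness = mean_or_na(.data$closeness),
      mean_eigenvector = mean_or_na(.data$eigenvector),
      .groups = "drop"
    ) |>
    dplyr::mutate(p_k = .data$n_k / sum(.data$n_k)) |>
    dplyr::relocate("p_k", .after = "n_k") |>
    dplyr::arrange(.data$degree)
}

#' Power-law exponents of all six topological properties
#'
#' Fits `TP ~ a0 * k^a1` for each of the six degree-aggregated topological
#' properties of a network. Properties with fewer than three strictly
#' positive `(k, TP)` pairs are reported with `NA` estimates.
#'
#' @param network An `igraph` graph or edge data frame, or a degree profile
#'   from [aggregate_by_degree()].
#' @param fit_space `"loglog"` (default) or `"direct"`; see
#'   [fit_power_law()].
#' @param points `"means"` (default) fits one point per observed degree;
#'   `"raw"` weights each degree point by its node count `n_k`, equivalent
#'   to fitting the per-node scatter.
#' @return A tibble with columns `property`, `prefactor`, `exponent`,
#'   `r_squared`, `n_points`, in the canonical property order
#'   (degree_distribution, clustering, neighborhood_connectivity,
#'   betweenness, closeness, eigenvector).
#' @export
topology_exponents <- function(network, fit_space = c("loglog", "direct"),
                               points = c("means", "raw")) {
  fit_space <- match.arg(fit_space)
  points <- match.arg(points)
  profile <- if (is.data.frame(network) && "p_k" %in% names(network)) {
    network
  } else {
    aggregate_by_degree(node_metrics(network))
  }
  cols <- c(
    degree_distribution = "p_k",
    clustering = "mean_clustering",
    neighborhood_connectivity = "mean_neighborhood_connectivity",
    betweenness = "mean_betweenness",
    closeness = "mean_closeness",
    eigenvector = "mean_eigenvector"
  )
  purrr::imap_dfr(cols, function(col, prop) {
    x <- profile$degree
    y <- profile[[col]]
    ok <- !is.na(y) & y > 0 & x > 0
    if (sum(ok) < 3) {
      return(tibble::tibble(property = prop, prefactor = NA_real_,
                            exponent = NA_real_, r_squared = NA_real_,
                            n_points = sum(ok)))
    }
    w <- if (points == "raw") profile$n_k[ok] else NULL
    fit <- fit_power_law(x[ok], y[ok], method = fit_space, weights = w)
    tibble::tibble(property = prop, prefactor = fit$a0, exponent = fit$a1,
                   r_squared = fit$r_squared, n_points = fit$n)
  })
}
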
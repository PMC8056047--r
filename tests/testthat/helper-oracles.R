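# Brute-force oracles, written directly from the defining formulas and kept
# independent of the package implementation: dense adjacency matrices,
# hand-rolled BFS with shortest-path counting, explicit neighbor-set
# intersections, and dense eigendecomposition.

oracle_adjacency <- function(g) {
  n <- igraph::vcount(g)
  A <- matrix(0, n, n, dimnames = list(igraph::V(g)$name, igraph::V(g)$name))
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) > 0) {
    A[el] <- 1
    A[el[, c(2, 1), drop = FALSE]] <- 1
  }
  A
}

# all-pairs BFS distances D and shortest-path counts S (S[s, t] = number of
# shortest s-t paths)
oracle_dist_sigma <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); sig <- rep(0, n)
    dist[s] <- 0; sig[s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(A[v, ] == 1)) {
          if (is.infinite(dist[w])) {
            dist[w] <- dist[v] + 1
            nxt <- c(nxt, w)
          }
          if (dist[w] == dist[v] + 1) sig[w] <- sig[w] + sig[v]
        }
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
    S[s, ] <- sig
  }
  list(D = D, S = S)
}

# raw betweenness: sum over unordered pairs s < t (s,t != v, connected) of
# sigma_st(v)/sigma_st, with sigma_st(v) = sigma_sv * sigma_vt when v lies
# on a shortest s-t path
oracle_betweenness <- function(A) {
  ds <- oracle_dist_sigma(A)
  D <- ds$D; S <- ds$S
  n <- nrow(A)
  btw <- numeric(n)
  for (v in seq_len(n)) {
    on_path <- is.finite(D) & (outer(D[, v], D[v, ], `+`) == D) & S > 0
    contrib <- matrix(0, n, n)
    contrib[on_path] <- (outer(S[, v], S[v, ], `*`) / S)[on_path]
    contrib[v, ] <- 0
    contrib[, v] <- 0
    btw[v] <- sum(contrib[upper.tri(contrib)])
  }
  btw
}

oracle_metrics <- function(g) {
  A <- oracle_adjacency(g)
  n <- nrow(A)
  deg <- rowSums(A)
  nbr <- lapply(seq_len(n), function(i) which(A[i, ] == 1))

  clust <- vapply(seq_len(n), function(i) {
    k <- deg[i]
    if (k < 2) return(NA_real_)
    e <- sum(A[nbr[[i]], nbr[[i]]]) / 2
    2 * e / (k * (k - 1))
  }, numeric(1))

  nc <- vapply(seq_len(n), function(i) {
    if (deg[i] == 0) NA_real_ else mean(deg[nbr[[i]]])
  }, numeric(1))

  btw <- oracle_betweenness(A)

  D <- oracle_dist_sigma(A)$D
  clo <- vapply(seq_len(n), function(i) {
    reach <- which(is.finite(D[i, ]) & seq_len(n) != i)
    if (length(reach) == 0) return(NA_real_)
    length(reach) / sum(D[i, reach])
  }, numeric(1))

  # eigenvector centrality on the largest component (ties: component holding
  # the smallest vertex index), unit Euclidean norm
  comp <- oracle_components(A)
  sizes <- vapply(comp, length, integer(1))
  big <- comp[[which(sizes == max(sizes))[1]]]
  ev <- rep(NA_real_, n)
  if (length(big) == 1) {
    ev[big] <- 1
  } else {
    sub <- A[big, big]
    es <- eigen(sub, symmetric = TRUE)
    v <- abs(es$vectors[, 1])
    ev[big] <- v / sqrt(sum(v^2))
  }

  tibble::tibble(node = rownames(A), degree = as.integer(deg),
                 clustering = clust, neighborhood_connectivity = nc,
                 betweenness = btw, closeness = clo, eigenvector = ev)
}

# connected components by BFS, in order of smallest member index
oracle_components <- function(A) {
  n <- nrow(A)
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    grp <- s; seen[s] <- TRUE; frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(A[v, ] == 1)) {
          if (!seen[w]) { seen[w] <- TRUE; grp <- c(grp, w); nxt <- c(nxt, w) }
        }
      }
      frontier <- nxt
    }
    comps[[length(comps) + 1]] <- sort(grp)
  }
  comps
}

oracle_rich_club <- function(g) {
  A <- oracle_adjacency(g)
  deg <- rowSums(A)
  kmax <- max(deg)
  rows <- list()
  for (k in 0:(kmax - 1)) {
    idx <- which(deg > k)
    if (length(idx) < 2) next
    e <- sum(A[idx, idx]) / 2
    rows[[length(rows) + 1]] <- data.frame(
      k = k, n_gt_k = length(idx), e_gt_k = e,
      phi = 2 * e / (length(idx) * (length(idx) - 1)))
  }
  do.call(rbind, rows)
}

oracle_lcp <- function(g) {
  A <- oracle_adjacency(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  cn <- integer(nrow(el)); lcl <- integer(nrow(el))
  for (i in seq_len(nrow(el))) {
    common <- which(A[el[i, 1], ] == 1 & A[el[i, 2], ] == 1)
    cn[i] <- length(common)
    lcl[i] <- if (cn[i] >= 2) sum(A[common, common]) / 2 else 0L
  }
  qual <- cn > 1
  corr <- if (sum(qual) < 2 || stats::sd(cn[qual]) == 0 ||
              stats::sd(lcl[qual]) == 0) NA_real_
          else stats::cor(cn[qual], lcl[qual])
  list(cn = cn, lcl = lcl, lcp_corr = corr)
}

# direct double-sum evaluation of modularity
oracle_modularity <- function(g, membership) {
  A <- oracle_adjacency(g)
  memb <- membership[rownames(A)]
  m <- sum(A) / 2
  if (m == 0) return(0)
  k <- rowSums(A)
  q <- 0
  n <- nrow(A)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (memb[i] == memb[j]) q <- q + A[i, j] - k[i] * k[j] / (2 * m)
    }
  }
  unname(q / (2 * m))
}

# random test graph with guaranteed names
random_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- paste0("n", seq_len(n))
  g
}
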
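#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis with the conventional
#' defaults: interaction-score threshold 0.50 (strict), CPM resolution 0.5,
#' 2500 bootstrap resamples for the degree-distribution goodness of fit,
#' 100 rich-club null networks with extraction threshold 1.1, and at most
#' 10 hierarchy levels. Supply either file inputs (`genes_path` +
#' `edges_path`) or a generator spec (`generator = list(kind = ..., ...)`
#' with kinds `scale_free`, `hierarchical`, `planted_kr`,
#' `planted_richclub`, `erdos_renyi`). All randomness derives from the
#' single `seed`.
#'
#' @param genes_path,edges_path Input files (see [read_gene_table()],
#'   [read_scored_edges()]); both `NULL` when a generator is used.
#' @param generator Generator spec list, or `NULL`.
#' @param score_threshold Strict lower bound on interaction scores.
#' @param gamma CPM resolution parameter.
#' @param n_resamples Bootstrap resamples for goodness of fit.
#' @param rc_n_null,rc_threshold,rc_swaps_factor Rich-club settings.
#' @param max_levels Maximum decomposition depth.
#' @param seed Master seed.
#' @param out_dir Output directory for reports, or `NULL` to skip writing.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(genes_path = NULL, edges_path = NULL,
                            generator = NULL,
                            score_threshold = 0.5, gamma = 0.5,
                            n_resamples = 2500, rc_n_null = 100,
                            rc_threshold = 1.1, rc_swaps_factor = 10,
                            max_levels = 10, seed = 1L, out_dir = NULL) {
  if (is.null(generator) && (is.null(edges_path))) {
    stop("pipeline needs either edges_path (+ optional genes_path) or a generator spec")
  }
  structure(
    list(genes_path = genes_path, edges_path = edges_path,
         generator = generator, score_threshold = score_threshold,
         gamma = gamma, n_resamples = n_resamples, rc_n_null = rc_n_null,
         rc_threshold = rc_threshold, rc_swaps_factor = rc_swaps_factor,
         max_levels = max_levels, seed = as.integer(seed),
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

# materialize the configured input: list(network, seeds tibble or NULL)
pipeline_inputs <- function(config) {
  if (!is.null(config$generator)) {
    spec <- config$generator
    kind <- spec$kind
    gseed <- config$seed + 101L
    if (kind == "planted_kr") {
      gen <- gen_planted_kr(
        n_communities = spec$n_communities %||% 4,
        subs_per_community = spec$subs_per_community %||% 2,
        n_seeds = spec$n_seeds %||% 3,
        seed = gseed
      )
      return(list(network = gen$network, seeds = gen$seed_genes,
                  truth = gen$truth))
    }
    g <- switch(kind,
      scale_free = gen_scale_free(spec$n %||% 2000, spec$m %||% 2, seed = gseed),
      hierarchical = gen_hierarchical(spec$levels %||% 3,
                                      spec$motif_size %||% 4, seed = gseed),
      planted_richclub = gen_planted_richclub(spec$core %||% 6,
                                              spec$periphery %||% 60,
                                              spec$p_periph %||% 0.03,
                                              seed = gseed),
      erdos_renyi = gen_erdos_renyi(spec$n %||% 200, spec$p %||% 0.05,
                                    seed = gseed),
      stop("unknown generator kind: ", kind)
    )
    return(list(network = g, seeds = NULL, truth = NULL))
  }
  edges <- read_scored_edges(config$edges_path,
                             threshold = config$score_threshold)
  network <- build_network(edges)
  seeds <- if (!is.null(config$genes_path)) {
    read_gene_table(config$genes_path)
  } else NULL
  list(network = network, seeds = seeds, truth = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full key-regulator analysis
#'
#' Executes the complete pipeline: network assembly (or generation), node
#' metrics and degree aggregation, power-law fits of the six topological
#' properties with degree-distribution goodness of fit, topology
#' classification, recursive community decomposition, seed tracing and
#' key-regulator identification, per-level modularity / Hamiltonian energy
#' / LCP-correlation summary, normalized rich-club analysis, and a motif
#' knockout experiment for every identified key-regulator motif. With
#' `out_dir` set, all reports are written (JSON summary + TSV tables);
#' outputs are byte-reproducible for a fixed config and seed.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list bundle with elements `network`, `metrics`,
#'   `profile`, `fits`, `classification`, `gof`, `tree`, `levels`,
#'   `traces`, `kr_report`, `rich_club`, `rich_club_nodes`, `knockouts`,
#'   `knockout_deltas`, `summary`.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- pipeline_inputs(config)
  g <- inputs$network
  n_nodes <- igraph::vcount(g)
  n_edges <- igraph::ecount(g)
  if (n_nodes == 0) stop("stage net_io: assembled network is empty")
  message("[pipeline] network: ", n_nodes, " nodes / ", n_edges, " edges")

  metrics <- node_metrics(g)
  profile <- aggregate_by_degree(metrics)
  fits <- topology_exponents(profile)
  classification <- tryCatch(classify_topology(fits),
                             error = function(e) {
                               list(label = "indeterminate",
                                    assortativity = NA_character_,
                                    signs = NULL)
                             })
  gof <- if (length(unique(metrics$degree[metrics$degree > 0])) >= 2) {
    goodness_of_fit(metrics$degree[metrics$degree > 0],
                    n_resamples = config$n_resamples,
                    seed = config$seed + 202L)
  } else NULL

  tree <- decompose_network(g, max_levels = config$max_levels)
  root_rec <- tree$index[[tree$root_id]]
  if (root_rec$pruned) {
    warning("network contains no triangle: no key-regulator analysis possible")
  }
  levels_tbl <- level_summary(tree, gamma = config$gamma)

  seeds <- inputs$seeds
  if (!is.null(seeds) && nrow(seeds) > 0) {
    traces <- trace_seeds(tree, seeds)
    kr_report <- identify_key_regulators(tree, traces)
    if (length(kr_report$seed_krs) == 0) {
      warning("no seed gene reached a terminal triangle: empty key-regulator report")
    }
  } else {
    traces <- trace_seeds(tree, character())
    kr_report <- identify_key_regulators(tree, traces)
  }

  rich_club <- if (n_nodes >= 3 && n_edges >= 2) {
    rich_club_normalized(g, n_null = config$rc_n_null,
                         seed = config$seed + 303L,
                         n_swaps_factor = config$rc_swaps_factor)
  } else NULL
  rich_club_nodes <- if (!is.null(rich_club)) {
    extract_rich_club_nodes(g, rich_club, threshold = config$rc_threshold)
  } else tibble::tibble(node = character(), degree = integer())

  knockouts <- list()
  if (nrow(kr_report$motifs) > 0) {
    motif_sets <- unique(lapply(kr_report$motifs$members, sort))
    knockouts <- lapply(motif_sets, function(tri) {
      knockout_experiment(tree, tri, gamma = config$gamma)
    })
  }
  knockout_deltas <- if (length(knockouts) > 0) {
    compare_exponent_trajectories(knockouts)
  } else tibble::tibble()

  cfg_echo <- unclass(config)
  cfg_echo$out_dir <- NULL  # environment detail, not analysis provenance
  summary <- list(
    config = cfg_echo[!vapply(cfg_echo, is.null, logical(1))],
    network = list(nodes = n_nodes, edges = n_edges),
    topology = list(
      label = classification$label,
      assortativity = classification$assortativity,
      exponents = fits,
      degree_gof = if (!is.null(gof)) {
        list(exponent = gof$exponent, ks = gof$ks_statistic,
             bootstrap_p = gof$bootstrap_p, n_resamples = gof$n_resamples)
      } else NULL
    ),
    hierarchy = as.data.frame(glance.community_tree(tree)),
    levels = levels_tbl,
    key_regulators = list(
      seed_krs = kr_report$seed_krs,
      partner_krs = kr_report$partner_krs,
      n_motifs = nrow(kr_report$motifs),
      dropped_seeds = kr_report$dropped_seeds
    ),
    rich_club = list(
      threshold = config$rc_threshold,
      n_nodes = nrow(rich_club_nodes),
      nodes = rich_club_nodes$node
    )
  )

  bundle <- list(network = g, metrics = metrics, profile = profile,
                 fits = fits, classification = classification, gof = gof,
                 tree = tree, levels = levels_tbl, traces = traces,
                 kr_report = kr_report, rich_club = rich_club,
                 rich_club_nodes = rich_club_nodes, knockouts = knockouts,
                 knockout_deltas = knockout_deltas, summary = summary,
                 truth = inputs$truth)

  if (!is.null(config$out_dir)) {
    write_pipeline_reports(bundle, config$out_dir)
  }
  invisible(bundle)
}

write_pipeline_reports <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(bundle$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  readr::write_tsv(bundle$metrics, file.path(out_dir, "node_metrics.tsv"))
  readr::write_tsv(bundle$profile, file.path(out_dir, "degree_profile.tsv"))
  readr::write_tsv(bundle$fits, file.path(out_dir, "exponents.tsv"))
  readr::write_tsv(bundle$levels, file.path(out_dir, "levels.tsv"))
  readr::write_tsv(tidy.community_tree(bundle$tree) |>
                     dplyr::mutate(members = vapply(.data$members, paste,
                                                    character(1),
                                                    collapse = ";")),
                   file.path(out_dir, "communities.tsv"))
  readr::write_tsv(tidy.kr_report(bundle$kr_report),
                   file.path(out_dir, "kr_report.tsv"))
  jsonlite::write_json(
    list(seed_krs = bundle$kr_report$seed_krs,
         partner_krs = bundle$kr_report$partner_krs,
         motifs = lapply(seq_len(nrow(bundle$kr_report$motifs)), function(i) {
           list(motif_id = bundle$kr_report$motifs$motif_id[i],
                community = bundle$kr_report$motifs$community[i],
                seed = bundle$kr_report$motifs$seed[i],
                members = bundle$kr_report$motifs$members[[i]])
         }),
         p_kr = bundle$kr_report$p_kr,
         popularity = bundle$kr_report$popularity,
         dropped_seeds = bundle$kr_report$dropped_seeds),
    file.path(out_dir, "kr_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(bundle$rich_club)) {
    readr::write_tsv(tibble::as_tibble(bundle$rich_club),
                     file.path(out_dir, "rich_club.tsv"))
  }
  if (nrow(bundle$knockout_deltas) > 0) {
    readr::write_tsv(bundle$knockout_deltas,
                     file.path(out_dir, "knockout_deltas.tsv"))
  }
  write_graph_file(bundle$network, file.path(out_dir, "network.graphml"),
                   format = "graphml")
  invisible(out_dir)
}
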
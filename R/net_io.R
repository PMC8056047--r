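#' Read a curated seed-gene table
#'
#' Parses a tab- or comma-separated table of curated disease genes. The header
#' must name at least a `symbol` and a `gene_id` column (matched
#' case-insensitively); `description`, `location` and `reference` columns are
#' carried through when present. Symbols and numeric gene IDs must be unique
#' within the table.
#'
#' @param path Path to a TSV/CSV file with a header row.
#' @return A tibble with one row per gene, in file order, holding `symbol`,
#'   `gene_id` (positive integer) and any of `description`, `location`,
#'   `reference` found in the file.
#' @export
read_gene_table <- function(path) {
  stopifnot(is.character(path), length(path) == 1)
  if (!file.exists(path)) stop("gene table not found: ", path)
  first <- readr::read_lines(path, n_max = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           trim_ws = TRUE, progress = FALSE)
  names(tbl) <- tolower(gsub("[ .]+", "_", names(tbl)))
  for (needed in c("symbol", "gene_id")) {
    if (!needed %in% names(tbl)) {
      stop("gene table must have a '", needed, "' column; found: ",
           paste(names(tbl), collapse = ", "))
    }
  }
  if (nrow(tbl) == 0) {
    return(tibble::tibble(symbol = character(), gene_id = integer()))
  }
  sym <- as.character(tbl$symbol)
  id_raw <- tbl$gene_id
  id <- suppressWarnings(as.integer(id_raw))
  bad <- which(is.na(sym) | !nzchar(sym) | is.na(id) | id <= 0)
  if (length(bad) > 0) {
    stop("malformed gene record at line ", bad[1] + 1L,
         " (empty symbol or non-positive/non-numeric gene_id)")
  }
  dup_sym <- sym[duplicated(toupper(sym))]
  if (length(dup_sym) > 0) {
    stop("duplicate gene symbol(s): ", paste(unique(dup_sym), collapse = ", "))
  }
  dup_id <- id[duplicated(id)]
  if (length(dup_id) > 0) {
    stop("duplicate gene_id(s): ", paste(unique(dup_id), collapse = ", "))
  }
  out <- tibble::tibble(symbol = sym, gene_id = id)
  for (extra in c("description", "location", "reference")) {
    if (extra %in% names(tbl)) out[[extra]] <- as.character(tbl[[extra]])
  }
  out
}

#' Read a confidence-scored interaction list
#'
#' Reads whitespace/tab/comma-separated rows of `node_a node_b score`, in the
#' dialect of STRING edge exports. Scores may be on the unit scale or the
#' 0-1000 scale: if any score exceeds 1 the whole file is interpreted on the
#' thousand scale and divided by 1000. Only interactions with score strictly
#' greater than `threshold` are retained; symmetric duplicates are collapsed
#' to one undirected record keeping the maximum score.
#'
#' @param path Path to the edge list. A header row is skipped automatically
#'   when its third field is non-numeric.
#' @param threshold Strict lower bound on the (unit-scale) interaction score.
#'   Default 0.5.
#' @return A tibble with columns `node_a`, `node_b`, `score` (unit scale),
#'   one row per undirected interaction.
#' @export
read_scored_edges <- function(path, threshold = 0.5) {
  stopifnot(is.character(path), length(path) == 1)
  if (!file.exists(path)) stop("edge list not found: ", path)
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0) {
    return(tibble::tibble(node_a = character(), node_b = character(),
                          score = double()))
  }
  toks <- strsplit(trimws(lines[keep]), "[,\t ]+")
  # header detection: first retained row whose third field is non-numeric
  if (length(toks[[1]]) >= 3 &&
      is.na(suppressWarnings(as.numeric(toks[[1]][3])))) {
    keep <- keep[-1]
    toks <- toks[-1]
  }
  if (length(toks) == 0) {
    return(tibble::tibble(node_a = character(), node_b = character(),
                          score = double()))
  }
  nfield <- lengths(toks)
  if (any(nfield < 3)) {
    stop("malformed edge row at line ", keep[which(nfield < 3)[1]],
         ": expected 'node_a node_b score'")
  }
  a <- vapply(toks, `[[`, character(1), 1L)
  b <- vapply(toks, `[[`, character(1), 2L)
  s <- suppressWarnings(as.numeric(vapply(toks, `[[`, character(1), 3L)))
  if (anyNA(s)) {
    stop("non-numeric score at line ", keep[which(is.na(s))[1]])
  }
  if (any(s < 0)) {
    stop("negative interaction score at line ", keep[which(s < 0)[1]])
  }
  if (any(s > 1)) {            # STRING thousand-scale dialect
    if (any(s > 1000)) {
      stop("score outside the 0-1000 scale at line ",
           keep[which(s > 1000)[1]])
    }
    s <- s / 1000
  }
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  rec <- tibble::tibble(node_a = a, node_b = b, score = s)
  rec <- rec |>
    dplyr::group_by(.data$node_a, .data$node_b) |>
    dplyr::summarise(score = max(.data$score), .groups = "drop")
  rec[rec$score > threshold, , drop = FALSE]
}

#' Assemble an undirected interaction network
#'
#' Builds a simple undirected igraph graph from validated interaction
#' records, following a one-gene-one-protein mapping: each distinct
#' identifier becomes a single node. Self-loop records are dropped with a
#' warning; parallel records are merged keeping the maximum score.
#'
#' @param records A data frame with columns `node_a`, `node_b` and optionally
#'   `score`.
#' @return An undirected simple `igraph` graph with a `name` vertex attribute
#'   and, when scores are supplied, a `score` edge attribute.
#' @export
build_network <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) {
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  }
  stopifnot(all(c("node_a", "node_b") %in% names(records)))
  loops <- records$node_a == records$node_b
  if (any(loops)) {
    warning(sum(loops), " self-loop record(s) dropped")
    records <- records[!loops, , drop = FALSE]
  }
  df <- data.frame(from = as.character(records$node_a),
                   to = as.character(records$node_b),
                   stringsAsFactors = FALSE)
  has_score <- "score" %in% names(records)
  if (has_score) df$score <- as.numeric(records$score)
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  # collapse any remaining parallel edges, keeping the best score
  attr_comb <- if (has_score) list(score = "max") else list()
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = attr_comb)
}

#' Write a network to a standard graph format
#'
#' Supported formats are GraphML and a two-column TSV edge list. Both are
#' round-trip safe with [read_graph_file()]: in the edge-list format,
#' isolated nodes are recorded as `# node:` comment lines so the node set
#' survives the trip.
#'
#' @param network An `igraph` graph with named vertices.
#' @param path Output file path.
#' @param format `"graphml"` or `"edgelist-tsv"`.
#' @return Invisibly, `path`.
#' @export
write_graph_file <- function(network, path, format = c("graphml", "edgelist-tsv")) {
  g <- as_kr_graph(network)
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g, names = TRUE)
    has_score <- "score" %in% igraph::edge_attr_names(g)
    header <- if (has_score) "node_a\tnode_b\tscore" else "node_a\tnode_b"
    rows <- if (nrow(el) > 0) {
      if (has_score) {
        paste(el[, 1], el[, 2],
              format(igraph::E(g)$score, digits = 15, trim = TRUE), sep = "\t")
      } else {
        paste(el[, 1], el[, 2], sep = "\t")
      }
    } else character()
    iso <- igraph::V(g)$name[igraph::degree(g) == 0]
    iso_rows <- if (length(iso) > 0) paste0("# node: ", iso) else character()
    readr::write_lines(c(header, rows, iso_rows), path)
  }
  invisible(path)
}

#' Read a network written by [write_graph_file()]
#'
#' @inheritParams write_graph_file
#' @return An undirected `igraph` graph.
#' @export
read_graph_file <- function(path, format = c("graphml", "edgelist-tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("graph file not found: ", path)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    return(igraph::as_undirected(g, mode = "collapse"))
  }
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  iso <- sub("^# node: ", "", lines[startsWith(lines, "# node: ")])
  rows <- lines[!startsWith(lines, "#")]
  rows <- rows[-1] # header
  if (length(rows) == 0) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    if (length(iso) > 0) g <- igraph::add_vertices(g, length(iso), name = iso)
    return(g)
  }
  toks <- strsplit(rows, "\t")
  df <- data.frame(from = vapply(toks, `[[`, character(1), 1L),
                   to = vapply(toks, `[[`, character(1), 2L),
                   stringsAsFactors = FALSE)
  if (all(lengths(toks) >= 3)) {
    df$score <- as.numeric(vapply(toks, `[[`, character(1), 3L))
  }
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  missing_iso <- setdiff(iso, igraph::V(g)$name)
  if (length(missing_iso) > 0) {
    g <- igraph::add_vertices(g, length(missing_iso), name = missing_iso)
  }
  g
}

#' Coerce input to a named undirected igraph graph
#'
#' Accepts an igraph graph or an edge data frame (columns `node_a`/`node_b`
#' or `from`/`to`). Vertices without a `name` attribute are named `v<i>`.
#'
#' @param network Graph or edge table.
#' @return An undirected simple `igraph` graph with named vertices.
#' @keywords internal
as_kr_graph <- function(network) {
  if (igraph::is_igraph(network)) {
    g <- network
    if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
    if (!"name" %in% igraph::vertex_attr_names(g)) {
      igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
    }
    return(g)
  }
  if (is.data.frame(network)) {
    nm <- names(network)
    if (all(c("node_a", "node_b") %in% nm)) return(build_network(network))
    if (all(c("from", "to") %in% nm)) {
      return(build_network(dplyr::rename(network, node_a = "from", node_b = "to")))
    }
    stop("edge data frame must have node_a/node_b or from/to columns")
  }
  stop("cannot interpret 'network' as a graph")
}
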
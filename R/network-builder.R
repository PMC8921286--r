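#' Build the herb-compound-target tripartite network
#'
#' Nodes carry one of three roles (herb, compound, target); edges are only
#' allowed between adjacent roles (herb-compound, compound-target). Supplying
#' a duplicate edge has no effect (set semantics); self-loops and edges with
#' unknown endpoints or illegal role pairs are rejected.
#'
#' @param herbs,compounds,targets character vectors of node ids per role.
#' @param herb_compound_edges data.frame (or 2-column matrix) of herb id,
#'   compound id pairs.
#' @param compound_target_edges data.frame of compound id, target id pairs.
#' @return A list of class `tripartite_network` with elements `graph` (an
#'   undirected igraph with vertex attribute `role`) and `roles` (named
#'   character vector).
#' @export
build_network <- function(herbs, compounds, targets,
                          herb_compound_edges, compound_target_edges) {
  herbs <- unique(as.character(herbs))
  compounds <- unique(as.character(compounds))
  targets <- unique(as.character(targets))
  ids <- c(herbs, compounds, targets)
  if (anyDuplicated(ids)) {
    stop_validation("node id used in more than one role: %s",
                    ids[duplicated(ids)][1L])
  }
  roles <- stats::setNames(rep(c("herb", "compound", "target"),
                               c(length(herbs), length(compounds), length(targets))), ids)

  as_pairs <- function(x) {
    if (is.null(x) || NROW(x) == 0L) {
      return(matrix(character(0), ncol = 2))
    }
    m <- as.matrix(as.data.frame(x)[, 1:2])
    storage.mode(m) <- "character"
    m
  }
  hc <- as_pairs(herb_compound_edges)
  ct <- as_pairs(compound_target_edges)
  check_edges <- function(m, from_set, to_set, kind) {
    bad_from <- setdiff(m[, 1], from_set)
    bad_to <- setdiff(m[, 2], to_set)
    if (length(bad_from) || length(bad_to)) {
      stop_validation("%s edge with unknown or wrong-role endpoint: %s",
                      kind, c(bad_from, bad_to)[1L])
    }
  }
  check_edges(hc, herbs, compounds, "herb-compound")
  check_edges(ct, compounds, targets, "compound-target")
  edges <- rbind(hc, ct)
  if (nrow(edges)) {
    # canonical unordered pairs, deduplicated
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]), sep = "\r")
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(
    d = as.data.frame(edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = ids, role = unname(roles), stringsAsFactors = FALSE)
  )
  structure(list(graph = g, roles = roles), class = "tripartite_network")
}

#' Descriptive statistics of a network
#'
#' Reports node and edge counts, density under both conventions
#' (undirected `2E/(N(N-1))` and directed-style `E/(N(N-1))`), the diameter
#' (longest shortest path within the largest connected component, flagged when
#' the graph is disconnected), the characteristic path length (mean shortest
#' path over connected node pairs), the average number of neighbors (`2E/N`)
#' and per-node degree. Both density conventions are emitted because tools
#' differ in which they print.
#'
#' @param net a `tripartite_network` or an igraph object.
#' @return named list of metrics.
#' @export
network_metrics <- function(net) {
  g <- if (inherits(net, "tripartite_network")) net$graph else net
  stopifnot(igraph::is_igraph(g))
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  if (n == 0L) {
    warning("empty graph: metrics reported as 0")
    return(list(n_nodes = 0L, n_edges = 0L, density_undirected = 0,
                density_directed_style = 0, diameter = 0,
                characteristic_path_length = 0, avg_neighbors = 0,
                connected = TRUE, degree = stats::setNames(numeric(0), character(0))))
  }
  comp <- igraph::components(g)
  connected <- comp$no == 1L
  d <- igraph::distances(g)
  finite <- d[upper.tri(d)][is.finite(d[upper.tri(d)])]
  cpl <- if (length(finite)) mean(finite) else 0
  diam <- if (length(finite)) max(finite) else 0
  list(
    n_nodes = n,
    n_edges = e,
    density_undirected = if (n > 1) 2 * e / (n * (n - 1)) else 0,
    density_directed_style = if (n > 1) e / (n * (n - 1)) else 0,
    diameter = diam,
    characteristic_path_length = cpl,
    avg_neighbors = 2 * e / n,
    connected = connected,
    degree = igraph::degree(g)
  )
}

#' Export a tripartite network to file
#'
#' Formats: `"sif"` (one line per edge with relation labels `contains` for
#' herb-compound and `targets` for compound-target), `"graphml"` (lossless,
#' re-importable with [import_network()]) and `"edge-tsv"` (headered edge
#' table with endpoint roles).
#'
#' @param net a `tripartite_network`.
#' @param path output file path.
#' @param format one of `"sif"`, `"graphml"`, `"edge-tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("sif", "graphml", "edge-tsv")) {
  stopifnot(inherits(net, "tripartite_network"))
  format <- match.arg(format)
  el <- igraph::as_edgelist(net$graph)
  roles <- net$roles
  if (nrow(el)) {
    # orient herb->compound->target for the typed exports
    flip <- (roles[el[, 1]] == "compound" & roles[el[, 2]] == "herb") |
      (roles[el[, 1]] == "target" & roles[el[, 2]] == "compound")
    el[flip, ] <- el[flip, c(2, 1)]
  }
  if (format == "sif") {
    rel <- ifelse(roles[el[, 1]] == "herb", "contains", "targets")
    writeLines(paste(el[, 1], rel, el[, 2], sep = "\t"), path)
  } else if (format == "graphml") {
    igraph::write_graph(net$graph, path, format = "graphml")
  } else {
    df <- data.frame(source = el[, 1], source_role = unname(roles[el[, 1]]),
                     target = el[, 2], target_role = unname(roles[el[, 2]]),
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Re-import a network exported as GraphML
#'
#' @param path a GraphML file written by [export_network()].
#' @return A `tripartite_network`.
#' @export
import_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  roles <- stats::setNames(igraph::vertex_attr(g, "role"), igraph::V(g)$name)
  structure(list(graph = g, roles = roles), class = "tripartite_network")
}

#' @export
print.tripartite_network <- function(x, ...) {
  tab <- table(factor(x$roles, levels = c("herb", "compound", "target")))
  cat(sprintf("tripartite network: %d nodes (%d herbs, %d compounds, %d targets), %d edges\n",
              igraph::vcount(x$graph), tab[["herb"]], tab[["compound"]],
              tab[["target"]], igraph::ecount(x$graph)))
  invisible(x)
}
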
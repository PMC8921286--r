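#' Build the candidate-target PPI subgraph
#'
#' Keeps STRING-style edges with combined score at or above `min_score`,
#' induces the subgraph on the candidate symbols, and removes targets left
#' without any interaction (isolated nodes), matching the convention of
#' reporting only the connected part of the interaction network.
#'
#' @param candidates character vector of candidate gene symbols.
#' @param edges data.frame with columns `gene_a`, `gene_b`, `combined_score`
#'   (scores in `[0, 1]`).
#' @param min_score confidence cutoff; defaults to 0.4 (the usual
#'   medium-confidence STRING setting).
#' @return an undirected igraph on the surviving candidates.
#' @export
build_ppi <- function(candidates, edges, min_score = 0.4) {
  stopifnot(is.data.frame(edges))
  assert_prob(min_score, "min_score")
  candidates <- unique(normalize_symbol(candidates))
  if (nrow(edges)) {
    assert_prob(edges$combined_score, "combined_score")
    a <- normalize_symbol(edges$gene_a)
    b <- normalize_symbol(edges$gene_b)
    keep <- edges$combined_score >= min_score & a != b &
      a %in% candidates & b %in% candidates
    a <- a[keep]; b <- b[keep]
    key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
    dup <- duplicated(key)
    a <- a[!dup]; b <- b[!dup]
  } else {
    a <- b <- character(0)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = candidates, stringsAsFactors = FALSE)
  )
  igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
}

#' Select hub targets by the degree-above-mean rule
#'
#' A hub is a node whose degree strictly exceeds the mean degree `2E/N` of the
#' graph. Hubs are reported sorted by degree (descending), then symbol.
#'
#' @param graph an undirected igraph (typically from [build_ppi()]).
#' @return A list of class `hub_report`: `n_nodes`, `n_edges`, `mean_degree`
#'   and `hubs` (data.frame of `symbol`, `degree`).
#' @export
select_hubs <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::vcount(graph) == 0L) stop_validation("cannot select hubs of an empty graph")
  deg <- igraph::degree(graph)
  mean_deg <- mean(deg)
  hub <- deg > mean_deg
  hubs <- data.frame(symbol = names(deg)[hub], degree = unname(deg[hub]),
                     stringsAsFactors = FALSE)
  hubs <- hubs[order(-hubs$degree, hubs$symbol), , drop = FALSE]
  rownames(hubs) <- NULL
  structure(list(
    n_nodes = igraph::vcount(graph),
    n_edges = igraph::ecount(graph),
    mean_degree = mean_deg,
    hubs = hubs
  ), class = "hub_report")
}

#' Rank nodes by degree
#'
#' Top-`k` nodes by degree (all nodes when `k` exceeds the node count), ties
#' broken lexicographically by symbol.
#'
#' @param graph an undirected igraph.
#' @param k how many nodes to return.
#' @return data.frame of `symbol`, `degree`, ordered.
#' @export
rank_by_degree <- function(graph, k) {
  stopifnot(igraph::is_igraph(graph))
  k <- assert_count(k, "k", min = 1L)
  deg <- igraph::degree(graph)
  ord <- order(-deg, names(deg), method = "radix")
  ord <- ord[seq_len(min(k, length(ord)))]
  out <- data.frame(symbol = names(deg)[ord], degree = unname(deg[ord]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.hub_report <- function(x, ...) {
  cat(sprintf("PPI hub report: %d nodes, %d edges, mean degree %.2f, %d hubs\n",
              x$n_nodes, x$n_edges, x$mean_degree, nrow(x$hubs)))
  invisible(x)
}
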
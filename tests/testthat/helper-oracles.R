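# Independent brute-force oracles used to check the implementation paths.
# These deliberately avoid igraph, phyper and p.adjust.

# all-pairs shortest paths by breadth-first search over an adjacency list
oracle_bfs_distances <- function(nodes, edge_a, edge_b) {
  n <- length(nodes)
  adj <- vector("list", n)
  ia <- match(edge_a, nodes)
  ib <- match(edge_b, nodes)
  for (e in seq_along(ia)) {
    if (ia[e] == ib[e]) next
    adj[[ia[e]]] <- union(adj[[ia[e]]], ib[e])
    adj[[ib[e]]] <- union(adj[[ib[e]]], ia[e])
  }
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[!is.finite(d[s, nxt])]
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

# graph metrics computed only from the BFS matrix and raw counts
oracle_graph_metrics <- function(nodes, edge_a, edge_b) {
  # dedup undirected edges, drop self-loops
  keep <- edge_a != edge_b
  a <- pmin(edge_a[keep], edge_b[keep])
  b <- pmax(edge_a[keep], edge_b[keep])
  key <- paste(a, b)
  a <- a[!duplicated(key)]; b <- b[!duplicated(key)]
  n <- length(nodes); e <- length(a)
  d <- oracle_bfs_distances(nodes, a, b)
  off <- d[upper.tri(d)]
  finite <- off[is.finite(off)]
  deg <- vapply(nodes, function(v) sum(a == v) + sum(b == v), numeric(1))
  list(
    n_nodes = n, n_edges = e,
    density_undirected = if (n > 1) 2 * e / (n * (n - 1)) else 0,
    diameter = if (length(finite)) max(finite) else 0,
    characteristic_path_length = if (length(finite)) mean(finite) else 0,
    avg_neighbors = if (n > 0) 2 * e / n else 0,
    degree = deg
  )
}

# upper-tail hypergeometric probability by direct combinatorial summation
oracle_hyper_upper <- function(k, K, n, N) {
  hi <- min(K, n)
  if (k > hi) return(0)
  i <- seq(max(k, 0), hi)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Benjamini-Hochberg step-up from the definition, in input order
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- pmin(1, m * p[ord] / seq_len(m))
  adj_sorted <- rev(cummin(rev(adj_sorted)))
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# seeded Erdos-Renyi-style random edge list on named nodes
random_graph_edges <- function(n_nodes, p_edge = 0.2) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- t(utils::combn(nodes, 2))
  pick <- stats::runif(nrow(pairs)) < p_edge
  list(nodes = nodes, a = pairs[pick, 1], b = pairs[pick, 2])
}

igraph_from_edges <- function(nodes, a, b) {
  igraph::graph_from_data_frame(data.frame(from = a, to = b),
                                directed = FALSE,
                                vertices = data.frame(name = nodes))
}

# tiny fixture configuration so module tests stay fast
small_fixture_config <- function(seed = 1, ...) {
  fixture_config(
    n_kushen_ingredients = 40, n_baituling_ingredients = 20,
    n_shared_ingredients = 6,
    n_predictions_per_compound = 12, n_top_targets = 8,
    n_compound_symbols = 60,
    source_sizes = c(ttd = 10, omim = 15, genecards = 20, disgenet = 18),
    n_genecards_raw = 30, n_disgenet_raw = 36,
    n_unique_disease_genes = 53, n_candidate_targets = 10,
    attribution_counts = c(common = 2, kushen_only = 6, baituling_only = 2),
    n_active_compounds = 12, n_shared_active = 1, n_baituling_active = 3,
    n_compound_target_edges = 20,
    ppi_connected = 8, ppi_edges = 12, ppi_hubs = 3,
    n_pathways = 20, n_predicted_pathways = 8,
    n_sw480_pathways = 5, n_sw620_pathways = 7,
    n_sw620_predicted_overlap = 4,
    n_de_background = 5,
    seed = seed, ...
  )
}
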
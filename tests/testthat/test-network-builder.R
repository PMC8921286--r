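tiny_net <- function() {
  build_network(
    herbs = "h1", compounds = c("c1", "c2"), targets = c("t1", "t2"),
    herb_compound_edges = data.frame(a = c("h1", "h1"), b = c("c1", "c2")),
    compound_target_edges = data.frame(a = c("c1", "c2"), b = c("t1", "t2"))
  )
}

test_that("tripartite construction enforces roles and set semantics", {
  net <- tiny_net()
  expect_equal(igraph::vcount(net$graph), 5L)
  expect_equal(igraph::ecount(net$graph), 4L)
  # duplicate edge supplied twice leaves the count unchanged
  net2 <- build_network("h1", "c1", "t1",
                        data.frame(a = c("h1", "h1"), b = c("c1", "c1")),
                        data.frame(a = "c1", b = "t1"))
  expect_equal(igraph::ecount(net2$graph), 2L)
  # unknown endpoint and illegal role pair rejected
  expect_error(build_network("h1", "c1", "t1",
                             data.frame(a = "h1", b = "cX"),
                             data.frame(a = "c1", b = "t1")),
               "unknown")
  expect_error(build_network("h1", "c1", "t1",
                             data.frame(a = "h1", b = "t1"),
                             data.frame(a = "c1", b = "t1")),
               "unknown|role")
})

test_that("metrics match closed forms on complete and path graphs", {
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- paste0("v", 1:4)
  m <- network_metrics(k4)
  expect_equal(m$density_undirected, 1)
  expect_equal(m$diameter, 1)
  expect_equal(m$avg_neighbors, 3)
  p4 <- igraph_from_edges(paste0("v", 1:4),
                          paste0("v", 1:3), paste0("v", 2:4))
  mp <- network_metrics(p4)
  expect_equal(mp$diameter, 3)
  expect_equal(mp$characteristic_path_length, 10 / 6)
  expect_gte(mp$diameter, mp$characteristic_path_length)
})

test_that("metrics equal an all-pairs BFS oracle on random graphs", {
  set.seed(51)
  for (i in 1:50) {
    g <- random_graph_edges(sample(5:30, 1), runif(1, 0.05, 0.4))
    m <- network_metrics(igraph_from_edges(g$nodes, g$a, g$b))
    o <- oracle_graph_metrics(g$nodes, g$a, g$b)
    expect_equal(m$n_edges, o$n_edges)
    expect_equal(m$density_undirected, o$density_undirected)
    expect_equal(m$diameter, o$diameter)
    expect_equal(m$characteristic_path_length, o$characteristic_path_length)
    expect_equal(m$avg_neighbors, o$avg_neighbors)
    expect_equal(unname(m$degree[g$nodes]), unname(o$degree[g$nodes]))
    expect_equal(sum(m$degree), 2 * m$n_edges)
  }
})

test_that("empty graph metrics are zero with a warning", {
  g <- igraph::make_empty_graph(0, directed = FALSE)
  expect_warning(m <- network_metrics(g), "empty")
  expect_equal(m$n_nodes, 0L)
  expect_equal(m$characteristic_path_length, 0)
})

test_that("exports are lossless and use the documented SIF relations", {
  net <- tiny_net()
  sif <- tempfile(fileext = ".sif")
  export_network(net, sif, "sif")
  lines <- readLines(sif)
  expect_length(lines, 4L)
  expect_true(all(grepl("\t(contains|targets)\t", lines)))
  expect_equal(sum(grepl("contains", lines)), 2L)

  gml <- tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  back <- import_network(gml)
  expect_equal(sort(names(back$roles)), sort(names(net$roles)))
  expect_equal(back$roles[sort(names(back$roles))],
               net$roles[sort(names(net$roles))])
  expect_equal(igraph::ecount(back$graph), igraph::ecount(net$graph))

  tsv <- tempfile(fileext = ".tsv")
  export_network(net, tsv, "edge-tsv")
  expect_equal(nrow(utils::read.delim(tsv)), igraph::ecount(net$graph))
  expect_error(export_network(net, tempfile(), "dot"), "arg")
})

test_that("density never decreases as edges are added at fixed nodes", {
  nodes <- paste0("v", 1:8)
  pairs <- t(utils::combn(nodes, 2))
  set.seed(52)
  pairs <- pairs[sample(nrow(pairs)), ]
  last <- 0
  for (k in seq(2, nrow(pairs), by = 5)) {
    m <- network_metrics(igraph_from_edges(nodes, pairs[1:k, 1], pairs[1:k, 2]))
    expect_gte(m$density_undirected, last)
    expect_lte(m$density_undirected, 1)
    last <- m$density_undirected
  }
})
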
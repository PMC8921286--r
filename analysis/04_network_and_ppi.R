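#!/usr/bin/env Rscript
# Herb-compound-target tripartite network with descriptive statistics, and
# the candidate PPI subgraph with degree-above-mean hub detection.

library(ckinet)

bundle <- read_fixture("results/fixture")
cand_tab <- read.delim("results/tables/candidate_targets.tsv")
prov <- read.delim("results/tables/candidate_provenance.tsv")

herb_map <- unique(bundle$ingredient_table[, c("compound_id", "herb")])
compounds <- sort(unique(prov$compound_id))
net <- build_network(
  herbs = unique(herb_map$herb),
  compounds = compounds,
  targets = cand_tab$gene_symbol,
  herb_compound_edges = herb_map[herb_map$compound_id %in% compounds,
                                 c("herb", "compound_id")],
  compound_target_edges = prov[, c("compound_id", "gene_symbol")]
)
m <- network_metrics(net)
message(sprintf("network: %d nodes, %d edges, density %.4f (undirected) / %.4f (directed-style)",
                m$n_nodes, m$n_edges, m$density_undirected, m$density_directed_style))
message(sprintf("diameter %d, characteristic path length %.3f, avg neighbors %.2f",
                m$diameter, m$characteristic_path_length, m$avg_neighbors))

dir.create("results/network", recursive = TRUE, showWarnings = FALSE)
export_network(net, "results/network/herb_compound_target.sif", "sif")
export_network(net, "results/network/herb_compound_target.graphml", "graphml")
metrics_tab <- data.frame(metric = c("n_nodes", "n_edges", "density_undirected",
                                     "density_directed_style", "diameter",
                                     "characteristic_path_length", "avg_neighbors"))
metrics_tab$value <- unlist(m[metrics_tab$metric])
write.table(metrics_tab, "results/tables/network_metrics.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

ppi <- build_ppi(cand_tab$gene_symbol, bundle$ppi_edges, 0.4)
hr <- select_hubs(ppi)
message(sprintf("PPI: %d nodes, %d edges, mean degree %.2f; %d hub targets",
                hr$n_nodes, hr$n_edges, hr$mean_degree, nrow(hr$hubs)))
message(sprintf("top hubs: %s",
                paste(utils::head(hr$hubs$symbol, 6), collapse = ", ")))
write.table(hr$hubs, "results/tables/ppi_hubs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(rank_by_degree(ppi, 14), "results/tables/ppi_top14_by_degree.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
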
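#' Default pipeline configuration
#'
#' All screening thresholds in one place, with the study defaults:
#' drug-likeness cutoff 0.18, top 30 predictions per compound, top 200
#' GeneCards records, DSI at-or-above-median rule (inside
#' [filter_disgenet()]), STRING-style confidence 0.4, enrichment significance
#' on raw p < 0.05 for pathways, and DE selection at adjusted p < 0.05 with
#' |log2FC| >= 1.
#'
#' @return named list of thresholds.
#' @export
default_pipeline_config <- function() {
  list(
    dl_threshold = 0.18,
    n_top_targets = 30,
    n_top_genecards = 200,
    ppi_min_score = 0.4,
    enrichment_variant = "standard",
    pathway_p_cutoff = 0.05,
    de_max_adj_p = 0.05,
    de_min_abs_log2fc = 1,
    n_hub_rank = 14
  )
}

#' Read pipeline thresholds from a YAML file
#'
#' The file may set any subset of the [default_pipeline_config()] entries;
#' unknown keys are rejected so typos do not silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return a full threshold list (defaults overridden by the file).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- default_pipeline_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    stop_validation("unknown pipeline configuration key: %s", unknown[1L])
  }
  utils::modifyList(defaults, raw)
}

stage_check <- function(ok, stage, what) {
  if (!ok) {
    stop(sprintf("pipeline stage '%s' aborted: %s", stage, what), call. = FALSE)
  }
}

#' Run the full network-pharmacology screen
#'
#' Executes every stage in order on a fixture bundle (or a directory written
#' by [write_fixture()]): drug-likeness screen, per-compound target cut and
#' symbol mapping, disease-gene aggregation, evidence intersection with herb
#' attribution, tripartite network metrics, PPI hub analysis, pathway
#' overrepresentation for the candidate targets and for each cell line's DE
#' genes, and the three-way pathway consensus with key-target classification.
#' The pipeline itself is deterministic: identical inputs give byte-identical
#' reports.
#'
#' @param fixture a `fixture_bundle` or a fixture directory path.
#' @param config threshold list from [default_pipeline_config()] (entries may
#'   be overridden).
#' @param out_dir optional directory; when given, stage artifacts (TSV) and
#'   the JSON run report are written there.
#' @return list of class `run_report` with per-stage counts and results.
#' @export
run_pipeline <- function(fixture, config = default_pipeline_config(),
                         out_dir = NULL) {
  if (is.character(fixture)) fixture <- read_fixture(fixture)
  stopifnot(inherits(fixture, "fixture_bundle"))
  cfg <- utils::modifyList(default_pipeline_config(), config)

  ## screen: drug-likeness filter and per-herb accounting
  ing <- fixture$ingredient_table
  stage_check(nrow(ing) > 0, "screen", "empty ingredient table")
  ing_kept <- filter_by_druglikeness(ing, cfg$dl_threshold)
  stage_check(nrow(ing_kept) > 0, "screen", "no ingredient passes the DL filter")
  overlap_pre <- herb_overlap_summary(
    ing$compound_id[ing$herb == "kushen"],
    ing$compound_id[ing$herb == "baituling"])
  overlap_post <- herb_overlap_summary(
    ing_kept$compound_id[ing_kept$herb == "kushen"],
    ing_kept$compound_id[ing_kept$herb == "baituling"])

  ## fish: top-N cut, then symbol mapping
  preds <- fixture$prediction_table
  stage_check(nrow(preds) > 0, "fish", "empty prediction table")
  kept_compounds <- unique(normalize_compound_id(ing_kept$compound_id))
  preds <- preds[normalize_compound_id(preds$compound_id) %in% kept_compounds, ,
                 drop = FALSE]
  stage_check(nrow(preds) > 0, "fish", "no predictions for screened compounds")
  top <- select_top_targets(preds, cfg$n_top_targets)
  symbols <- map_to_symbols(top, fixture$protein_mapping)
  stage_check(length(symbols$symbols) > 0, "fish", "no mappable target symbols")

  ## disease: source rules, then integration
  dt <- fixture$disease_tables
  stage_check(all(vapply(dt, nrow, integer(1)) > 0), "disease",
              "an empty disease source table")
  disease <- integrate_sources(list(
    ttd = dt$ttd,
    omim = dt$omim,
    genecards = take_top_relevance(dt$genecards, cfg$n_top_genecards),
    disgenet = filter_disgenet(dt$disgenet)
  ))

  ## intersect: candidates + herb attribution
  candidates <- intersect_evidence(symbols, disease$genes)
  stage_check(length(candidates$targets) > 0, "intersect",
              "compound and disease evidence do not intersect")
  herb_map <- unique(ing_kept[, c("compound_id", "herb")])
  candidates <- attribute_to_herbs(candidates, herb_map)

  ## network: herb-compound-target graph over the bioactive compounds
  herb_edges <- herb_map[normalize_compound_id(herb_map$compound_id) %in%
                           normalize_compound_id(candidates$compounds),
                         c("herb", "compound_id")]
  net <- build_network(
    herbs = unique(herb_map$herb),
    compounds = candidates$compounds,
    targets = candidates$targets,
    herb_compound_edges = herb_edges,
    compound_target_edges = candidates$provenance[, c("compound_id", "gene_symbol")]
  )
  metrics <- network_metrics(net)

  ## ppi: induced subgraph, hubs, degree ranking
  ppi <- build_ppi(candidates$targets, fixture$ppi_edges, cfg$ppi_min_score)
  stage_check(igraph::vcount(ppi) > 0, "ppi", "no PPI edges pass the cutoff")
  hubs <- select_hubs(ppi)
  top_ranked <- rank_by_degree(ppi, cfg$n_hub_rank)

  ## enrichment: candidate targets, then each cell line's DE genes
  collection <- gene_set_collection(fixture$pathway_collection)
  enr_targets <- hypergeometric_enrichment(candidates$targets, collection,
                                           cfg$enrichment_variant)
  predicted_pathways <- top_terms(enr_targets, "kegg-raw-p")$term
  de_genes <- lapply(fixture$de_tables, select_de_genes,
                     max_adj_p = cfg$de_max_adj_p,
                     min_abs_log2fc = cfg$de_min_abs_log2fc)
  stage_check(all(lengths(de_genes) > 0), "enrich-de", "a cell line has no DE genes")
  enr_de <- lapply(de_genes, hypergeometric_enrichment, collection = collection,
                   variant = cfg$enrichment_variant)
  de_pathways <- lapply(enr_de, function(r) top_terms(r, "kegg-raw-p")$term)

  ## consensus: three-way pathway intersection and key targets
  lines <- names(de_pathways)
  stage_check(length(lines) >= 2, "consensus", "need two cell lines")
  venn <- pathway_venn(predicted_pathways, de_pathways[[1L]], de_pathways[[2L]])
  key_pathways <- venn$triple
  key_targets <- NULL
  if (length(key_pathways)) {
    norm_names <- normalize_pathway_name(names(fixture$pathway_collection))
    members <- unique(unlist(
      fixture$pathway_collection[norm_names %in% key_pathways],
      use.names = FALSE))
    key_targets <- select_key_targets(members, candidates$targets, de_genes)
  }

  report <- structure(list(
    config_echo = cfg,
    seed = fixture$config$seed,
    version = as.character(utils::packageVersion("ckinet")),
    stage_counts = list(
      screen = list(
        n_ingredient_rows = nrow(ing), n_retained_rows = nrow(ing_kept),
        overlap_pre_filter = unclass(overlap_pre),
        overlap_post_filter = unclass(overlap_post)
      ),
      fish = list(n_predictions_in = nrow(preds), n_predictions_kept = nrow(top),
                  n_symbols = length(symbols$symbols),
                  n_unmapped = symbols$n_unmapped),
      disease = list(n_records_in = disease$n_records_in,
                     n_unique_out = disease$n_unique_out,
                     per_source = as.list(disease$per_source_counts)),
      intersect = list(n_candidate_targets = length(candidates$targets),
                       n_bioactive_compounds = length(candidates$compounds),
                       attribution = as.list(table(candidates$attribution))),
      network = metrics[c("n_nodes", "n_edges", "density_undirected",
                          "density_directed_style", "diameter",
                          "characteristic_path_length", "avg_neighbors")],
      ppi = list(n_nodes = hubs$n_nodes, n_edges = hubs$n_edges,
                 mean_degree = hubs$mean_degree, n_hubs = nrow(hubs$hubs),
                 hubs = hubs$hubs$symbol,
                 top_by_degree = top_ranked$symbol),
      enrichment = c(list(n_predicted_pathways = length(predicted_pathways)),
                     stats::setNames(lapply(de_pathways, length),
                                     paste0("n_pathways_", tolower(lines)))),
      consensus = list(venn_regions = as.list(venn$region_counts),
                       key_pathways = key_pathways,
                       key_targets = key_targets)
    ),
    results = list(
      candidates = candidates, network = net, metrics = metrics,
      ppi = ppi, hub_report = hubs, enrichment_targets = enr_targets,
      enrichment_de = enr_de, predicted_pathways = predicted_pathways,
      de_pathways = de_pathways, de_genes = de_genes, venn = venn
    )
  ), class = "run_report")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_tsv(ing_kept, file.path(out_dir, "screened_ingredients.tsv"))
    write_tsv(data.frame(gene_symbol = candidates$targets,
                         attribution = unname(candidates$attribution)),
              file.path(out_dir, "candidate_targets.tsv"))
    write_tsv(enr_targets, file.path(out_dir, "enrichment_targets.tsv"))
    for (line in names(enr_de)) {
      write_tsv(enr_de[[line]],
                file.path(out_dir, sprintf("enrichment_de_%s.tsv", line)))
    }
    export_network(net, file.path(out_dir, "network.sif"), "sif")
    jsonlite::write_json(
      report[c("config_echo", "seed", "version", "stage_counts")],
      file.path(out_dir, "run_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  sc <- x$stage_counts
  cat("network pharmacology run report\n")
  cat(sprintf("  compounds: union %d (screened union %d)\n",
              sc$screen$overlap_pre_filter$n_union,
              sc$screen$overlap_post_filter$n_union))
  cat(sprintf("  target symbols: %d; disease genes: %d of %d records\n",
              sc$fish$n_symbols, sc$disease$n_unique_out, sc$disease$n_records_in))
  cat(sprintf("  candidates: %d targets / %d compounds\n",
              sc$intersect$n_candidate_targets, sc$intersect$n_bioactive_compounds))
  cat(sprintf("  network: %d nodes, %d edges; PPI: %d nodes, %d edges, %d hubs\n",
              sc$network$n_nodes, sc$network$n_edges,
              sc$ppi$n_nodes, sc$ppi$n_edges, sc$ppi$n_hubs))
  cat(sprintf("  pathways: %d predicted; %s\n",
              sc$enrichment$n_predicted_pathways,
              paste(sprintf("%s=%d",
                            sub("n_pathways_", "", grep("n_pathways_",
                                                        names(sc$enrichment),
                                                        value = TRUE)),
                            unlist(sc$enrichment[grep("n_pathways_",
                                                      names(sc$enrichment))])),
                    collapse = ", ")))
  if (length(sc$consensus$key_pathways)) {
    cat("  consensus pathway(s):", paste(sc$consensus$key_pathways, collapse = ", "), "\n")
    if (!is.null(sc$consensus$key_targets)) {
      cat("  common key targets:",
          paste(sc$consensus$key_targets$common, collapse = ", "), "\n")
    }
  }
  invisible(x)
}
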
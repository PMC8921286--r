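test_that("invalid configurations are rejected naming the offending field", {
  expect_error(fixture_config(n_shared_ingredients = 30,
                              n_kushen_ingredients = 20,
                              n_baituling_ingredients = 40),
               "n_shared_ingredients")
  expect_error(small_fixture_config(n_candidate_targets = 99,
                                    attribution_counts = c(common = 33,
                                                           kushen_only = 33,
                                                           baituling_only = 33)),
               "n_candidate_targets")
  expect_error(small_fixture_config(n_predictions_per_compound = 5),
               "n_predictions_per_compound")
})

test_that("generation is deterministic in (config, seed) and seed-sensitive", {
  b1 <- generate_fixture(small_fixture_config(seed = 9))
  b2 <- generate_fixture(small_fixture_config(seed = 9))
  expect_identical(b1, b2)
  b3 <- generate_fixture(small_fixture_config(seed = 10))
  expect_false(identical(b1$prediction_table, b3$prediction_table))
})

test_that("configured cardinalities are conserved in the emitted tables", {
  cfg <- small_fixture_config(seed = 2)
  b <- generate_fixture(cfg)
  expect_equal(length(unique(b$ingredient_table$compound_id)),
               cfg$n_kushen_ingredients + cfg$n_baituling_ingredients -
                 cfg$n_shared_ingredients)
  expect_equal(sum(b$ingredient_table$herb == "kushen"), cfg$n_kushen_ingredients)
  expect_equal(sum(b$ingredient_table$herb == "baituling"),
               cfg$n_baituling_ingredients)
  expect_equal(nrow(b$prediction_table),
               length(unique(b$ingredient_table$compound_id)) *
                 cfg$n_predictions_per_compound)
  got_sizes <- vapply(b$disease_tables, nrow, integer(1))
  expect_equal(got_sizes[["ttd"]], cfg$source_sizes[["ttd"]])
  expect_equal(got_sizes[["omim"]], cfg$source_sizes[["omim"]])
  expect_equal(got_sizes[["genecards"]], cfg$n_genecards_raw)
  expect_equal(got_sizes[["disgenet"]], cfg$n_disgenet_raw)
  expect_equal(length(b$pathway_collection), cfg$n_pathways)
  expect_equal(length(b$truth$candidate_targets), cfg$n_candidate_targets)
  expect_equal(length(b$truth$active_compounds), cfg$n_active_compounds)
})

test_that("planted candidate targets are recoverable by a brute-force scan", {
  cfg <- small_fixture_config(seed = 3)
  b <- generate_fixture(cfg)
  # brute force: top-cut prediction symbols vs deduplicated disease genes,
  # using only the emitted tables and the source rules
  top <- select_top_targets(b$prediction_table, cfg$n_top_targets)
  sym <- suppressMessages(map_to_symbols(top, b$protein_mapping))$symbols
  disease <- unique(toupper(c(
    b$disease_tables$ttd$gene_symbol,
    b$disease_tables$omim$gene_symbol,
    take_top_relevance(b$disease_tables$genecards,
                       cfg$source_sizes[["genecards"]])$gene_symbol,
    filter_disgenet(b$disease_tables$disgenet)$gene_symbol
  )))
  inter <- character(0)
  for (s in sym) if (s %in% disease) inter <- c(inter, s)
  expect_setequal(inter, b$truth$candidate_targets)
  expect_length(inter, cfg$n_candidate_targets)
})

test_that("planted candidates sit in predictions and in at least two disease sources", {
  b <- generate_fixture(small_fixture_config(seed = 4))
  prot_of <- with(b$protein_mapping, setNames(protein_id, gene_symbol))
  for (g in b$truth$candidate_targets) {
    expect_true(prot_of[[g]] %in% b$prediction_table$target_protein)
    n_src <- sum(vapply(b$disease_tables,
                        function(t) g %in% toupper(t$gene_symbol), logical(1)))
    expect_gte(n_src, 2L)
  }
})

test_that("spiked pathways have at least 60% of members flagged DE in their line", {
  cfg <- small_fixture_config(seed = 5)
  b <- generate_fixture(cfg)
  for (line in names(b$truth$spiked_pathways)) {
    de <- select_de_genes(b$de_tables[[line]])
    for (pw in b$truth$spiked_pathways[[line]]) {
      members <- b$pathway_collection[[pw]]
      expect_gte(sum(members %in% de) / length(members), cfg$spike_fraction)
    }
  }
})

test_that("fixture bundles survive a write/read round trip", {
  b <- generate_fixture(small_fixture_config(seed = 6))
  dir <- withr::local_tempdir()
  write_fixture(b, dir)
  back <- read_fixture(dir)
  expect_equal(back$ingredient_table, b$ingredient_table)
  expect_equal(back$prediction_table, b$prediction_table)
  expect_equal(back$protein_mapping, b$protein_mapping)
  expect_equal(back$disease_tables, b$disease_tables)
  expect_equal(back$ppi_edges, b$ppi_edges)
  expect_equal(back$pathway_collection, b$pathway_collection)
  expect_equal(back$de_tables, b$de_tables)
  expect_equal(back$truth, b$truth)
  expect_equal(back$config, b$config)
  # GMT lines are well-formed
  gmt <- readLines(file.path(dir, "pathways.gmt"))
  expect_true(all(lengths(strsplit(gmt, "\t")) >= 3L))
})

test_that("study-scale configuration reproduces the printed catalog counts", {
  b <- generate_fixture(fixture_config(seed = 8))
  expect_equal(length(unique(b$ingredient_table$compound_id)), 477L)
  expect_equal(sum(vapply(b$disease_tables[c("ttd", "omim")], nrow, integer(1))) +
                 sum(fixture_config()$source_sizes[c("genecards", "disgenet")]),
               644L)
})

test_that("the below-threshold fraction lands where configured", {
  cfg <- small_fixture_config(seed = 7, dl_fraction_below = 0.25)
  b <- generate_fixture(cfg)
  per_compound <- tapply(b$ingredient_table$dl, b$ingredient_table$compound_id,
                         unique)
  n_union <- length(per_compound)
  expect_equal(sum(per_compound < cfg$dl_threshold), round(0.25 * n_union))
  expect_setequal(names(per_compound)[per_compound < cfg$dl_threshold],
                  b$truth$below_dl_compounds)
})
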
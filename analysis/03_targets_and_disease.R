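#!/usr/bin/env Rscript
# Target fishing (top-30 per compound by normalized fit score, mapped to gene
# symbols) and disease-gene aggregation from the four sources, ending in the
# candidate-target intersection with herb attribution.

library(ckinet)

bundle <- read_fixture("results/fixture")

top <- select_top_targets(bundle$prediction_table, 30)
symbols <- map_to_symbols(top, bundle$protein_mapping)
message(sprintf("kept %d of %d predictions; %d unique target symbols",
                nrow(top), nrow(bundle$prediction_table),
                length(symbols$symbols)))

disease <- integrate_sources(list(
  ttd = bundle$disease_tables$ttd,
  omim = bundle$disease_tables$omim,
  genecards = take_top_relevance(bundle$disease_tables$genecards, 200),
  disgenet = filter_disgenet(bundle$disease_tables$disgenet)
))
message(sprintf("disease genes: %d unique from %d records (%s)",
                disease$n_unique_out, disease$n_records_in,
                paste(sprintf("%s=%d", names(disease$per_source_counts),
                              disease$per_source_counts), collapse = ", ")))

candidates <- intersect_evidence(symbols, disease$genes)
herb_map <- unique(bundle$ingredient_table[, c("compound_id", "herb")])
candidates <- attribute_to_herbs(candidates, herb_map)
message(sprintf("candidate targets: %d genes reached by %d bioactive compounds",
                length(candidates$targets), length(candidates$compounds)))

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
write.table(data.frame(gene_symbol = candidates$targets,
                       attribution = unname(candidates$attribution)),
            "results/tables/candidate_targets.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(candidates$provenance, "results/tables/candidate_provenance.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
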
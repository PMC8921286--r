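#!/usr/bin/env Rscript
# Generate the study-scale synthetic database extracts (seeded) and write
# them under results/fixture/ for the downstream analysis scripts.

library(ckinet)

cfg <- fixture_config(seed = 1L)
bundle <- generate_fixture(cfg)
write_fixture(bundle, "results/fixture")

message(sprintf("ingredient rows:      %d (%d distinct compounds)",
                nrow(bundle$ingredient_table),
                length(unique(bundle$ingredient_table$compound_id))))
message(sprintf("prediction rows:      %d", nrow(bundle$prediction_table)))
message(sprintf("disease records:      %d across 4 sources",
                sum(vapply(bundle$disease_tables, nrow, integer(1)))))
message(sprintf("PPI edge rows:        %d", nrow(bundle$ppi_edges)))
message(sprintf("pathways:             %d (%d planted as predicted)",
                length(bundle$pathway_collection),
                length(bundle$truth$predicted_pathways)))
message("fixture written to results/fixture/")
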
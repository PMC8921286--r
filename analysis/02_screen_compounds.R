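#!/usr/bin/env Rscript
# Drug-likeness screen of the two herb catalogs and the per-herb compound
# accounting (union / unique / common), before and after the DL filter.

library(ckinet)

bundle <- read_fixture("results/fixture")
ing <- bundle$ingredient_table
kept <- filter_by_druglikeness(ing, 0.18)

pre <- herb_overlap_summary(ing$compound_id[ing$herb == "kushen"],
                            ing$compound_id[ing$herb == "baituling"])
post <- herb_overlap_summary(kept$compound_id[kept$herb == "kushen"],
                             kept$compound_id[kept$herb == "baituling"])

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
write.table(kept, "results/tables/screened_ingredients.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
summary_tab <- data.frame(
  stage = c("pre_filter", "post_filter"),
  n_union = c(pre$n_union, post$n_union),
  kushen_unique = c(pre$n_unique_a, post$n_unique_a),
  baituling_unique = c(pre$n_unique_b, post$n_unique_b),
  common = c(pre$n_common, post$n_common)
)
write.table(summary_tab, "results/tables/herb_overlap_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("retained %d of %d ingredient rows at DL >= 0.18",
                nrow(kept), nrow(ing)))
message(sprintf("screened catalog: %d components (%d Kushen-unique, %d Baituling-unique, %d common)",
                post$n_union, post$n_unique_a, post$n_unique_b, post$n_common))
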
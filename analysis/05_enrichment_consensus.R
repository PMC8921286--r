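#!/usr/bin/env Rscript
# Pathway overrepresentation of the candidate targets, per-cell-line
# enrichment of the DE gene lists, and the three-way consensus that
# nominates the key pathway and key targets.

library(ckinet)

bundle <- read_fixture("results/fixture")
cand <- read.delim("results/tables/candidate_targets.tsv")$gene_symbol

collection <- gene_set_collection(bundle$pathway_collection)
enr <- hypergeometric_enrichment(cand, collection)
predicted <- top_terms(enr, "kegg-raw-p")$term
message(sprintf("predicted pathways (raw p < 0.05): %d of %d tested",
                length(predicted), nrow(enr)))

de_genes <- lapply(bundle$de_tables, select_de_genes)
enr_de <- lapply(de_genes, hypergeometric_enrichment, collection = collection)
de_pw <- lapply(enr_de, function(r) top_terms(r, "kegg-raw-p")$term)
for (line in names(de_pw)) {
  message(sprintf("%s: %d DE genes, %d enriched pathways",
                  line, length(de_genes[[line]]), length(de_pw[[line]])))
}

venn <- pathway_venn(predicted, de_pw$SW480, de_pw$SW620)
message(sprintf("three-way consensus pathway(s): %s",
                paste(venn$triple, collapse = ", ")))

key <- NULL
if (length(venn$triple)) {
  norm <- normalize_pathway_name(names(bundle$pathway_collection))
  members <- unique(unlist(bundle$pathway_collection[norm %in% venn$triple]))
  key <- select_key_targets(members, cand, de_genes)
  message(sprintf("key targets - common: %s; prediction-only: %s",
                  paste(key$common, collapse = ", "),
                  paste(key$prediction_only, collapse = ", ")))
}

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
write.table(enr, "results/tables/enrichment_candidates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
for (line in names(enr_de)) {
  write.table(enr_de[[line]],
              sprintf("results/tables/enrichment_%s.tsv", line),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
venn_tab <- data.frame(region = names(venn$region_counts),
                       count = unname(venn$region_counts))
write.table(venn_tab, "results/tables/pathway_venn.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
if (!is.null(key)) {
  key_tab <- data.frame(
    gene_symbol = c(key$common, key$prediction_only,
                    unlist(key$de_only, use.names = FALSE)),
    class = c(rep("common", length(key$common)),
              rep("prediction_only", length(key$prediction_only)),
              rep(paste0("de_only_", names(key$de_only)),
                  lengths(key$de_only)))
  )
  write.table(key_tab, "results/tables/key_targets.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
}
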
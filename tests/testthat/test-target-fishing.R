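make_preds <- function(compounds, n_each, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(compounds, function(cmp) {
    data.frame(compound_id = cmp,
               target_protein = sample(sprintf("P%03d", 1:200), n_each),
               normalized_fit_score = runif(n_each))
  }))
}

test_that("top-target cut keeps min(k, n) per compound and re-ranks", {
  p50 <- make_preds("c1", 50)
  expect_equal(nrow(select_top_targets(p50, 30)), 30L)
  expect_equal(select_top_targets(p50, 30)$rank, 1:30)
  p10 <- make_preds("c1", 10)
  expect_equal(nrow(select_top_targets(p10, 30)), 10L)
})

test_that("top-target cut equals brute-force sort-and-slice per compound", {
  preds <- make_preds(sprintf("c%d", 1:5), 40, seed = 3)
  got <- select_top_targets(preds, 30)
  for (cmp in unique(preds$compound_id)) {
    sub <- preds[preds$compound_id == cmp, ]
    brute <- sub[order(-sub$normalized_fit_score, sub$target_protein), ][1:30, ]
    sub_got <- got[got$compound_id == cmp, ]
    expect_equal(sub_got$target_protein, brute$target_protein)
    expect_equal(sub_got$normalized_fit_score, brute$normalized_fit_score)
    expect_lte(nrow(sub_got), 30L)
  }
})

test_that("ties at the cut break by target id, deterministically", {
  tied <- data.frame(compound_id = "c1",
                     target_protein = c("PB", "PA", "PC"),
                     normalized_fit_score = c(0.5, 0.5, 0.5))
  got <- select_top_targets(tied, 2)
  expect_equal(got$target_protein, c("PA", "PB"))
})

test_that("duplicate (compound, target) pairs are rejected", {
  dup <- data.frame(compound_id = c("c1", "c1"), target_protein = c("P1", "P1"),
                    normalized_fit_score = c(0.9, 0.8))
  expect_error(select_top_targets(dup, 5), "duplicate")
})

test_that("symbol mapping deduplicates and tracks compound provenance", {
  preds <- data.frame(compound_id = c("c1", "c1", "c2"),
                      target_protein = c("P1", "P2", "P1"))
  mapping <- data.frame(protein_id = c("P1", "P2"), gene_symbol = c("tp53", "TP53"))
  res <- map_to_symbols(preds, mapping)
  expect_equal(res$symbols, "TP53") # case-folded to one symbol
  expect_setequal(res$provenance$compound_id, c("c1", "c2"))
  expect_equal(res$n_unmapped, 0L)
})

test_that("unmapped proteins are dropped with a count, not passed through", {
  preds <- data.frame(compound_id = "c1", target_protein = c("P1", "PX"))
  mapping <- data.frame(protein_id = "P1", gene_symbol = "EGFR")
  expect_message(res <- map_to_symbols(preds, mapping), "1 prediction")
  expect_equal(res$symbols, "EGFR")
  expect_equal(res$n_unmapped, 1L)
  empty <- suppressMessages(
    map_to_symbols(preds, mapping[0, , drop = FALSE]))
  expect_length(empty$symbols, 0)
  expect_equal(empty$n_unmapped, 2L)
})

test_that("symbol mapping equals a brute-force join and commutes with dedup", {
  set.seed(5)
  preds <- make_preds(sprintf("c%d", 1:4), 25, seed = 5)
  mapping <- data.frame(protein_id = sprintf("P%03d", 1:150),
                        gene_symbol = sprintf("G%03d", sample(1:80, 150, replace = TRUE)))
  res <- suppressMessages(map_to_symbols(preds, mapping))
  brute <- character(0)
  for (i in seq_len(nrow(preds))) {
    hit <- mapping$gene_symbol[mapping$protein_id == preds$target_protein[i]]
    brute <- c(brute, hit)
  }
  expect_setequal(res$symbols, unique(toupper(brute)))
  # dedup-then-map equals map-then-dedup
  pd <- unique(preds[, c("compound_id", "target_protein")])
  res2 <- suppressMessages(map_to_symbols(pd, mapping))
  expect_equal(res$symbols, res2$symbols)
  expect_equal(res$provenance, res2$provenance)
})
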
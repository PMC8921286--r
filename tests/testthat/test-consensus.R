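test_that("venn decomposition handles the planted 33/23/32 overlap structure", {
  # 33 predicted; 23 in line A sharing only the key pathway; 32 in line B
  # sharing 17 with predicted (the key pathway among them)
  predicted <- c("cell cycle", sprintf("pred %02d", 1:32))
  set_a <- c("Cell Cycle", sprintf("a-only %02d", 1:22))
  set_b <- c("cell cycle", sprintf("pred %02d", 1:16), sprintf("b-only %02d", 1:15))
  v <- pathway_venn(predicted, set_a, set_b)
  expect_equal(v$triple, "cell cycle")
  expect_equal(length(v$pairwise[["predicted&b"]]), 17L)
  expect_equal(length(v$pairwise[["predicted&a"]]), 1L)
  expect_equal(sum(v$region_counts), length(unique(c(
    normalize_pathway_name(predicted), normalize_pathway_name(set_a),
    normalize_pathway_name(set_b)))))
})

test_that("venn of disjoint sets has empty intersections", {
  v <- pathway_venn(c("p1", "p2"), c("a1"), c("b1", "b2"))
  expect_length(v$triple, 0)
  expect_true(all(lengths(v$pairwise) == 0))
  expect_equal(unname(v$region_counts[c("predicted", "a", "b")]), c(2L, 1L, 2L))
})

test_that("venn regions equal brute-force membership tests and are equivariant", {
  set.seed(81)
  pool <- sprintf("pw %02d", 1:40)
  for (i in 1:10) {
    s1 <- sample(pool, sample(5:30, 1))
    s2 <- sample(pool, sample(5:30, 1))
    s3 <- sample(pool, sample(5:30, 1))
    v <- pathway_venn(s1, s2, s3)
    u <- unique(c(s1, s2, s3))
    brute <- table(factor(vapply(u, function(x) {
      paste0(ifelse(x %in% s1, "p", ""), ifelse(x %in% s2, "a", ""),
             ifelse(x %in% s3, "b", ""))
    }, character(1)), levels = c("p", "a", "b", "pa", "pb", "ab", "pab")))
    expect_equal(unname(v$region_counts),
                 unname(as.integer(brute[c("p", "a", "b", "pa", "pb", "ab", "pab")])))
    expect_true(all(v$triple %in% v$pairwise[["predicted&a"]]))
    # permuting the two cell-line sets permutes the mirrored regions
    vp <- pathway_venn(s1, s3, s2)
    expect_equal(unname(vp$region_counts[c("a", "b")]),
                 unname(v$region_counts[c("b", "a")]))
    expect_equal(vp$triple, v$triple)
  }
})

test_that("name normalization unifies case, punctuation and whitespace", {
  expect_equal(normalize_pathway_name(c("Cell  cycle", "CELL-CYCLE", " cell cycle ")),
               rep("cell cycle", 3))
})

test_that("key-target classification partitions by evidence", {
  members <- c("TP53", "CHEK1", "CCND1", "MDM2", "CDKN1A", "PWG1")
  predicted <- c("TP53", "CHEK1", "CCND1", "MDM2", "EGFR")
  de <- list(SW480 = c("PWG1"), SW620 = c("TP53", "CHEK1", "CDKN1A"))
  got <- select_key_targets(members, predicted, de)
  expect_equal(got$common, c("CHEK1", "TP53"))
  expect_equal(got$prediction_only, c("CCND1", "MDM2"))
  expect_equal(got$de_only$SW620, "CDKN1A")
  expect_equal(got$de_only$SW480, "PWG1")
  # no DE evidence: everything predicted is prediction-only
  none <- select_key_targets(members, predicted, list(SW480 = character(0)))
  expect_length(none$common, 0)
  expect_setequal(none$prediction_only, c("TP53", "CHEK1", "CCND1", "MDM2"))
})

test_that("key-target classes are disjoint and cover evidenced members", {
  set.seed(82)
  for (i in 1:10) {
    members <- sample(sprintf("G%02d", 1:30), 15)
    predicted <- sample(sprintf("G%02d", 1:30), 12)
    de <- list(L1 = sample(sprintf("G%02d", 1:30), 8),
               L2 = sample(sprintf("G%02d", 1:30), 8))
    got <- select_key_targets(members, predicted, de)
    labeled <- c(got$common, got$prediction_only, unlist(got$de_only))
    expect_length(intersect(got$common, got$prediction_only), 0)
    expect_length(intersect(got$common, unlist(got$de_only)), 0)
    expect_length(intersect(got$prediction_only, unlist(got$de_only)), 0)
    evidenced <- intersect(members, union(predicted, unlist(de)))
    expect_setequal(unique(labeled), evidenced)
  }
})
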
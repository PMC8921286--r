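genes <- function(n, prefix = "G") sprintf("%s%03d", prefix, seq_len(n))

test_that("hypergeometric tail equals combinatorial enumeration on a hand case", {
  # N=20, K=5, n=5, k=4: mass at 4 and 5
  uni <- genes(20)
  coll <- gene_set_collection(list(term = uni[1:5]), universe = uni)
  query <- c(uni[1:4], uni[6])
  res <- hypergeometric_enrichment(query, coll)
  want <- (choose(5, 4) * choose(15, 1) + choose(5, 5) * choose(15, 0)) / choose(20, 5)
  expect_equal(res$p_value, want)
  expect_equal(res$k, 4L)
  expect_equal(res$fold_enrichment, (4 / 5) / (5 / 20))
})

test_that("saturated query gives fold enrichment 1 for every term", {
  uni <- genes(30)
  coll <- gene_set_collection(list(a = uni[1:10], b = uni[5:30]), universe = uni)
  res <- hypergeometric_enrichment(uni, coll)
  expect_true(all(res$fold_enrichment == 1))
  expect_equal(res$k, res$K)
})

test_that("EASE variant removes one overlapping gene and is conservative", {
  uni <- genes(40)
  coll <- gene_set_collection(list(t = uni[1:8]), universe = uni)
  query <- uni[c(1:4, 30:35)]
  std <- hypergeometric_enrichment(query, coll, "standard")
  ease <- hypergeometric_enrichment(query, coll, "ease")
  expect_equal(ease$p_value, oracle_hyper_upper(3, 8, 10, 40))
  expect_gt(ease$p_value, std$p_value)
  # k = 0 floors at zero, p = 1
  none <- hypergeometric_enrichment(uni[30:35], coll, "ease")
  expect_equal(none$p_value, 1)
})

test_that("p-value is nonincreasing in the overlap at fixed N, K, n", {
  N <- 60; K <- 12; n <- 15
  uni <- genes(N)
  coll <- gene_set_collection(list(t = uni[1:K]), universe = uni)
  p_at_k <- vapply(0:min(K, n), function(k) {
    query <- c(uni[seq_len(k)], uni[K + seq_len(n - k)])
    hypergeometric_enrichment(query, coll)$p_value
  }, numeric(1))
  expect_true(all(diff(p_at_k) <= 1e-12))
})

test_that("degenerate inputs error: empty universe or out-of-universe query", {
  uni <- genes(10)
  coll <- gene_set_collection(list(t = uni[1:3]), universe = uni)
  expect_error(hypergeometric_enrichment(c("ZZZ1", "ZZZ2"), coll), "universe")
})

test_that("BH adjustment matches hand cases and the direct step-up reference", {
  expect_equal(bh_adjust(0.03), 0.03)              # m = 1
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5)) # rank-invariant
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  set.seed(71)
  for (i in 1:100) {
    p <- runif(sample(1:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("top-term modes filter and slice as documented", {
  set.seed(72)
  res <- data.frame(term = sprintf("t%02d", 1:50),
                    k = 1, K = 5, n = 10, N = 100,
                    p_value = runif(50, 0, 0.2),
                    adjusted_p = runif(50, 0, 0.2))
  res$fold_enrichment <- 1
  go <- top_terms(res, "go-top20-adjusted")
  brute_go <- res[res$adjusted_p < 0.05, ]
  brute_go <- brute_go[order(brute_go$adjusted_p, brute_go$term), ][
    seq_len(min(20, sum(res$adjusted_p < 0.05))), ]
  expect_equal(go$term, brute_go$term)
  expect_lte(nrow(go), 20L)
  kegg <- top_terms(res, "kegg-raw-p")
  expect_setequal(kegg$term, res$term[res$p_value < 0.05])
  none <- top_terms(res[res$p_value > 0.9, ], "kegg-raw-p")
  expect_equal(nrow(none), 0L)
})

test_that("DE gene selection applies both thresholds", {
  tab <- data.frame(gene = c("A", "B", "C", "D"),
                    log2fc = c(-2, 3, 1.5, -0.5),
                    p_value = c(0.001, 0.1, 0.01, 0.001),
                    adjusted_p = c(0.01, 0.2, 0.04, 0.01))
  expect_setequal(select_de_genes(tab), c("A", "C")) # B fails p, D fails fold
  set.seed(73)
  big <- data.frame(gene = genes(500), log2fc = runif(500, -4, 4),
                    p_value = runif(500), adjusted_p = runif(500))
  got <- select_de_genes(big, 0.1, 1.5)
  brute <- big$gene[big$adjusted_p < 0.1 & abs(big$log2fc) >= 1.5]
  expect_setequal(got, brute)
})

test_that("a planted spiked pathway attains the smallest adjusted p", {
  set.seed(74)
  uni <- genes(800, "U")
  decoys <- lapply(1:50, function(i) sample(uni, 20))
  names(decoys) <- sprintf("decoy%02d", 1:50)
  spiked <- sample(uni, 20)
  coll <- gene_set_collection(c(decoys, list(spiked = spiked)), universe = uni)
  query <- c(sample(spiked, 12), sample(setdiff(uni, spiked), 30))
  res <- hypergeometric_enrichment(query, coll)
  expect_equal(res$term[1], "spiked")
  expect_lt(res$adjusted_p[1], 0.05)
})

test_that("null rejection rate is conservative and matches the exact attained size", {
  # The upper-tail hypergeometric p-value is discrete: under the null the
  # rejection rate at nominal 0.05 equals the attained size
  # P(X >= k*), k* = min{k : P(X >= k) < 0.05}, which is <= 0.05. The observed
  # Monte Carlo rate should match that exact value, not the nominal one.
  attained <- function(N, K, n, alpha = 0.05) {
    k <- 0:min(K, n)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    ks <- k[p < alpha]
    if (!length(ks)) 0 else stats::phyper(min(ks) - 1, K, N - K, n, lower.tail = FALSE)
  }
  set.seed(75)
  uni <- sprintf("u%03d", 1:500)
  rejections <- 0L; expected <- 0; m <- 0L
  for (rep_i in 1:200) {
    sizes <- sample(50:150, 20, replace = TRUE)
    sets <- lapply(sizes, function(K) sample(uni, K))
    names(sets) <- sprintf("t%02d", 1:20)
    coll <- gene_set_collection(sets, universe = uni)
    res <- hypergeometric_enrichment(sample(uni, 100), coll)
    rejections <- rejections + sum(res$p_value < 0.05)
    expected <- expected + sum(vapply(sizes, attained, numeric(1), N = 500, n = 100))
    m <- m + nrow(res)
  }
  frac <- rejections / m
  exp_frac <- expected / m
  expect_lte(frac, 0.05 + stats::qnorm(0.995) * sqrt(0.05 * 0.95 / m))
  expect_lt(abs(frac - exp_frac),
            stats::qnorm(0.995) * sqrt(exp_frac * (1 - exp_frac) / m) + 1e-9)
})

test_that("GMT round-trips and agrees with an independent reader", {
  sets <- list("Cell cycle" = c("TP53", "CHEK1", "CCND1"),
               "Other pathway" = c("EGFR", "KRAS"))
  path <- tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  lines <- readLines(path)
  expect_true(all(lengths(strsplit(lines, "\t")) >= 3L))
  back <- read_gmt(path)
  expect_equal(back, sets)
  skip_if_not_installed("fgsea")
  expect_equal(fgsea::gmtPathways(path), sets)
})
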
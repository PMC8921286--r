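#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (gene symbols per set).
#' @param universe background gene universe; defaults to the union of all set
#'   members (the annotated universe, which is how DAVID-style tools behave
#'   when no background is supplied).
#' @return list of class `gene_set_collection` with `sets` and `universe`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  stopifnot(is.list(sets), length(sets) > 0, !is.null(names(sets)))
  sets <- lapply(sets, function(s) sort(unique(normalize_symbol(s))))
  if (any(lengths(sets) == 0L)) stop_validation("gene sets must be non-empty")
  if (is.null(universe)) {
    universe <- sort(unique(unlist(sets, use.names = FALSE)))
  } else {
    universe <- sort(unique(normalize_symbol(universe)))
    outside <- setdiff(unlist(sets, use.names = FALSE), universe)
    if (length(outside)) {
      stop_validation("gene set member outside the universe: %s", outside[1L])
    }
  }
  structure(list(sets = sets, universe = universe), class = "gene_set_collection")
}

#' Read a GMT gene-set file
#'
#' Each line is tab-separated: set name, description, then one or more genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) {
    stop_validation("malformed GMT line (need name, description, >=1 gene)")
  }
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[[`, character(1), 1L))
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors.
#' @param path output file path.
#' @param descriptions optional character vector of per-set descriptions;
#'   defaults to `"na"`.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, genes) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric overrepresentation analysis
#'
#' For each gene set (term), tests whether the query overlaps the term more
#' than expected when drawing `n` genes from a universe of `N` containing `K`
#' term members: the p-value is the upper tail `P(X >= k)` of the
#' hypergeometric distribution. The EASE variant (DAVID's conservative score)
#' removes one overlapping gene, i.e. uses `P(X >= k - 1)` with `k - 1`
#' floored at 0. The query is restricted to the universe before testing, and
#' Benjamini-Hochberg adjustment is applied across all tested terms.
#'
#' @param query character vector of gene symbols.
#' @param collection a `gene_set_collection`.
#' @param variant `"standard"` or `"ease"`.
#' @return data.frame (one row per term, sorted by adjusted p then term name)
#'   with columns `term`, `k`, `K`, `n`, `N`, `p_value`, `adjusted_p`,
#'   `fold_enrichment`.
#' @export
hypergeometric_enrichment <- function(query, collection,
                                      variant = c("standard", "ease")) {
  stopifnot(inherits(collection, "gene_set_collection"))
  variant <- match.arg(variant)
  N <- length(collection$universe)
  if (N == 0L) stop_validation("empty universe")
  q <- intersect(unique(normalize_symbol(query)), collection$universe)
  n <- length(q)
  if (n == 0L) stop_validation("query has no genes in the universe")
  terms <- names(collection$sets)
  k <- vapply(collection$sets, function(s) length(intersect(q, s)), integer(1))
  K <- lengths(collection$sets)
  k_eff <- if (variant == "ease") pmax(k - 1L, 0L) else k
  p <- stats::phyper(k_eff - 1L, K, N - K, n, lower.tail = FALSE)
  adj <- bh_adjust(p)
  out <- data.frame(
    term = terms, k = unname(k), K = unname(K), n = n, N = N,
    p_value = unname(p), adjusted_p = unname(adj),
    fold_enrichment = unname((k / n) / (K / N)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$adjusted_p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement, returned in the
#' input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  assert_prob(p_values, "p_values")
  stats::p.adjust(p_values, method = "BH")
}

#' Select top enriched terms
#'
#' Two reporting modes mirror how GO and KEGG results are usually cut:
#' `"go-top20-adjusted"` filters to adjusted p < 0.05 and keeps the 20
#' smallest; `"kegg-raw-p"` keeps every term with raw p < 0.05.
#'
#' @param results data.frame from [hypergeometric_enrichment()].
#' @param mode `"go-top20-adjusted"` or `"kegg-raw-p"`.
#' @return filtered data.frame, sorted by the relevant p-value.
#' @export
top_terms <- function(results, mode = c("go-top20-adjusted", "kegg-raw-p")) {
  mode <- match.arg(mode)
  if (mode == "go-top20-adjusted") {
    out <- results[results$adjusted_p < 0.05, , drop = FALSE]
    out <- out[order(out$adjusted_p, out$term), , drop = FALSE]
    out <- out[seq_len(min(20L, nrow(out))), , drop = FALSE]
  } else {
    out <- results[results$p_value < 0.05, , drop = FALSE]
    out <- out[order(out$p_value, out$term), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Select differentially expressed genes
#'
#' Genes passing both an adjusted-p cutoff and an absolute log2 fold-change
#' cutoff. Both thresholds are deliberately explicit arguments.
#'
#' @param records data.frame with columns `gene`, `log2fc`, `adjusted_p`.
#' @param max_adj_p adjusted-p threshold (exclusive); default 0.05.
#' @param min_abs_log2fc |log2FC| threshold (inclusive); default 1.
#' @return sorted character vector of gene symbols.
#' @export
select_de_genes <- function(records, max_adj_p = 0.05, min_abs_log2fc = 1) {
  stopifnot(is.data.frame(records), max_adj_p > 0, min_abs_log2fc > 0)
  if (nrow(records) == 0L) return(character(0))
  assert_prob(records$adjusted_p, "adjusted_p")
  keep <- records$adjusted_p < max_adj_p & abs(records$log2fc) >= min_abs_log2fc
  sort(unique(normalize_symbol(records$gene[keep])))
}
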
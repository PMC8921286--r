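#' Normalize pathway names for cross-tool matching
#'
#' Pathway names vary in capitalization and punctuation across tools; names
#' are case-folded, punctuation replaced by spaces, and whitespace collapsed
#' before comparison.
#'
#' @param x character vector of pathway names.
#' @return normalized names.
#' @export
normalize_pathway_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[[:punct:]]+", " ", x)
  gsub("[[:space:]]+", " ", trimws(x))
}

#' Three-way pathway Venn decomposition
#'
#' Decomposes three pathway name sets (typically: network-pharmacology
#' predicted, and one enriched set per cell line) into the seven Venn regions.
#' Names are normalized with [normalize_pathway_name()] before comparison and
#' reported sorted.
#'
#' @param predicted,set_a,set_b character vectors of pathway names.
#' @return list of class `venn_report` with `region_counts` (named counts for
#'   the 7 regions, names like `"predicted"`, `"predicted&a"`,
#'   `"predicted&a&b"`, ...), `triple` (names in all three), `pairwise`
#'   (list of the three pairwise intersections) and `sets` (the normalized
#'   inputs).
#' @export
pathway_venn <- function(predicted, set_a, set_b) {
  p <- sort(unique(normalize_pathway_name(predicted)))
  a <- sort(unique(normalize_pathway_name(set_a)))
  b <- sort(unique(normalize_pathway_name(set_b)))
  u <- sort(unique(c(p, a, b)))
  inp <- u %in% p; ina <- u %in% a; inb <- u %in% b
  region <- paste0(ifelse(inp, "p", ""), ifelse(ina, "a", ""), ifelse(inb, "b", ""))
  labels <- c(p = "predicted", a = "a", b = "b",
              pa = "predicted&a", pb = "predicted&b", ab = "a&b",
              pab = "predicted&a&b")
  counts <- stats::setNames(integer(length(labels)), unname(labels))
  tab <- table(region)
  counts[labels[names(tab)]] <- as.integer(tab)
  structure(list(
    region_counts = counts,
    triple = u[inp & ina & inb],
    pairwise = list(
      "predicted&a" = u[inp & ina],
      "predicted&b" = u[inp & inb],
      "a&b"         = u[ina & inb]
    ),
    sets = list(predicted = p, a = a, b = b)
  ), class = "venn_report")
}

#' Classify key-pathway members by supporting evidence
#'
#' Partitions the members of the key pathway into: `common` (predicted target
#' and differentially expressed in at least one cell line), `prediction_only`
#' (predicted but never DE), and per-line `de_only` (DE in that line but not
#' predicted). Members with neither kind of evidence are not labeled.
#'
#' @param key_pathway_members character vector of gene symbols in the key
#'   pathway.
#' @param predicted_targets character vector of predicted candidate targets.
#' @param de_genes_by_line named list of DE gene symbol vectors, one per cell
#'   line.
#' @return list with elements `common`, `prediction_only` and `de_only`
#'   (named list per line), all sorted.
#' @export
select_key_targets <- function(key_pathway_members, predicted_targets,
                               de_genes_by_line) {
  members <- unique(normalize_symbol(key_pathway_members))
  pred <- unique(normalize_symbol(predicted_targets))
  de <- lapply(de_genes_by_line, normalize_symbol)
  any_de <- unique(unlist(de, use.names = FALSE))
  list(
    common = sort(intersect(members, intersect(pred, any_de))),
    prediction_only = sort(setdiff(intersect(members, pred), any_de)),
    de_only = lapply(de, function(d) sort(setdiff(intersect(members, d), pred)))
  )
}

#' @export
print.venn_report <- function(x, ...) {
  cat("pathway venn:",
      paste(sprintf("%s=%d", names(x$region_counts), x$region_counts), collapse = ", "),
      "\n")
  if (length(x$triple)) cat("  triple intersection:", paste(x$triple, collapse = ", "), "\n")
  invisible(x)
}
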
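#' Keep the top-scoring target predictions per compound
#'
#' Reverse-pharmacophore servers return many scored protein candidates per
#' compound; the screen keeps the `n` with the highest normalized fit score
#' for each compound (all of them when a compound has fewer). Ties at the cut
#' are broken by target id (lexicographic) so runs are reproducible. Retained
#' predictions are re-ranked 1..min(k, n) within each compound.
#'
#' @param predictions data.frame with columns `compound_id`, `target_protein`
#'   and `normalized_fit_score`.
#' @param n number of predictions to keep per compound; defaults to 30.
#' @return data.frame of retained predictions with a recomputed `rank` column,
#'   ordered by compound then rank.
#' @export
select_top_targets <- function(predictions, n = 30) {
  stopifnot(is.data.frame(predictions))
  n <- assert_count(n, "n", min = 1L)
  need <- c("compound_id", "target_protein", "normalized_fit_score")
  if (!all(need %in% names(predictions))) {
    stop_validation("'predictions' must have columns %s", paste(need, collapse = ", "))
  }
  if (nrow(predictions) == 0L) {
    out <- predictions
    out$rank <- integer(0)
    return(out)
  }
  key <- paste(predictions$compound_id, predictions$target_protein, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop_validation("duplicate (compound, target) pair: %s", gsub("\r", " / ", d))
  }
  ord <- order(predictions$compound_id,
               -predictions$normalized_fit_score,
               predictions$target_protein,
               method = "radix")
  out <- predictions[ord, , drop = FALSE]
  pos <- stats::ave(seq_len(nrow(out)), out$compound_id, FUN = seq_along)
  out <- out[pos <= n, , drop = FALSE]
  out$rank <- stats::ave(seq_len(nrow(out)), out$compound_id, FUN = seq_along)
  rownames(out) <- NULL
  out
}

#' Map predicted target proteins to official gene symbols
#'
#' Joins predictions onto a protein-to-symbol mapping (UniProt-style),
#' deduplicates symbols and records which compounds contributed each symbol.
#' Proteins absent from the mapping are dropped with a message giving the
#' count; they are not passed through raw because all downstream joins are on
#' gene symbols.
#'
#' @param predictions data.frame with columns `compound_id`, `target_protein`.
#' @param mapping data.frame with columns `protein_id`, `gene_symbol`.
#' @return A list of class `symbol_set` with elements `symbols` (sorted unique
#'   character), `provenance` (data.frame of unique `gene_symbol`,
#'   `compound_id` pairs) and `n_unmapped` (count of dropped prediction rows).
#' @export
map_to_symbols <- function(predictions, mapping) {
  stopifnot(is.data.frame(predictions), is.data.frame(mapping))
  if (anyDuplicated(mapping$protein_id)) {
    stop_validation("'mapping' has duplicated protein ids")
  }
  idx <- match(predictions$target_protein, mapping$protein_id)
  unmapped <- sum(is.na(idx))
  if (unmapped > 0) {
    message(sprintf("map_to_symbols: dropped %d prediction(s) with unmapped proteins",
                    unmapped))
  }
  keep <- !is.na(idx)
  prov <- data.frame(
    gene_symbol = normalize_symbol(mapping$gene_symbol[idx[keep]]),
    compound_id = as.character(predictions$compound_id[keep]),
    stringsAsFactors = FALSE
  )
  prov <- unique(prov)
  prov <- prov[order(prov$gene_symbol, prov$compound_id), , drop = FALSE]
  rownames(prov) <- NULL
  structure(list(
    symbols    = sort(unique(prov$gene_symbol)),
    provenance = prov,
    n_unmapped = unmapped
  ), class = "symbol_set")
}

#' @export
print.symbol_set <- function(x, ...) {
  cat(sprintf("symbol set: %d symbols from %d compounds (%d unmapped rows dropped)\n",
              length(x$symbols), length(unique(x$provenance$compound_id)), x$n_unmapped))
  invisible(x)
}
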
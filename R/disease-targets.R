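#' Apply the DisGeNET disease-specificity rule
#'
#' DisGeNET-style records carry a disease-specificity index (DSI) in `[0, 1]`;
#' genes whose DSI falls strictly below the median of the retrieved set are
#' considered less specific to the disease and discarded. The median is the
#' interpolated median (mean of the two middle order statistics for
#' even-length input), and records equal to it are retained.
#'
#' @param records data.frame with columns `gene_symbol` and `dsi`.
#' @return the subset with `dsi >= median(dsi)`, input order preserved.
#' @export
filter_disgenet <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) return(records)
  if (!"dsi" %in% names(records) || anyNA(records$dsi)) {
    stop_validation("every DisGeNET record must carry a 'dsi' value")
  }
  assert_prob(records$dsi, "dsi")
  med <- stats::median(records$dsi)
  records[records$dsi >= med, , drop = FALSE]
}

#' Keep the most relevant GeneCards records
#'
#' GeneCards-style records are sorted by their relevance score and the top
#' `n` kept (all when fewer). Ties are broken by gene symbol so runs are
#' reproducible.
#'
#' @param records data.frame with columns `gene_symbol` and `relevance`.
#' @param n records to keep; defaults to 200.
#' @return data.frame of the `min(nrow, n)` highest-relevance records.
#' @export
take_top_relevance <- function(records, n = 200) {
  stopifnot(is.data.frame(records))
  n <- assert_count(n, "n", min = 1L)
  if (nrow(records) == 0L) return(records)
  if (!"relevance" %in% names(records) || anyNA(records$relevance)) {
    stop_validation("every GeneCards record must carry a 'relevance' value")
  }
  if (any(records$relevance < 0)) stop_validation("'relevance' must be nonnegative")
  ord <- order(-records$relevance, records$gene_symbol, method = "radix")
  out <- records[ord[seq_len(min(nrow(records), n))], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Integrate disease-gene lists from multiple sources
#'
#' TTD and OMIM lists are passed whole; GeneCards and DisGeNET lists are
#' expected to be pre-filtered (see [take_top_relevance()] and
#' [filter_disgenet()]). Symbols are case-folded to upper case before the
#' union, since symbol-case inconsistency across databases is the dominant
#' source of spurious duplicates.
#'
#' @param tables named list of data.frames, each with a `gene_symbol` column;
#'   names identify the sources.
#' @return A list of class `disease_gene_set` with `genes` (sorted unique
#'   symbols), `n_records_in`, `n_unique_out` and `per_source_counts`.
#' @export
integrate_sources <- function(tables) {
  stopifnot(is.list(tables), length(tables) > 0, !is.null(names(tables)))
  per_source <- vapply(tables, nrow, integer(1))
  symbols <- unlist(lapply(tables, function(t) normalize_symbol(t$gene_symbol)),
                    use.names = FALSE)
  if (any(!nzchar(symbols))) stop_validation("empty gene symbol in disease table")
  genes <- sort(unique(symbols))
  structure(list(
    genes             = genes,
    n_records_in      = sum(per_source),
    n_unique_out      = length(genes),
    per_source_counts = per_source
  ), class = "disease_gene_set")
}

#' @export
print.disease_gene_set <- function(x, ...) {
  cat(sprintf("disease gene set: %d unique genes from %d records (%s)\n",
              x$n_unique_out, x$n_records_in,
              paste(sprintf("%s=%d", names(x$per_source_counts), x$per_source_counts),
                    collapse = ", ")))
  invisible(x)
}
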
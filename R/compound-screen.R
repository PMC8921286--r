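#' Filter herb ingredients by drug-likeness
#'
#' Drug-likeness (DL) is the unitless ADME screen used to retain bioactive
#' ingredients: records with DL strictly below the threshold are removed, so a
#' record sitting exactly on the threshold is kept. Input order is preserved.
#'
#' @param records data.frame with at least columns `herb`, `compound_id` and
#'   `dl` (numeric in `[0, 1]`).
#' @param threshold DL cutoff in `[0, 1]`; defaults to 0.18.
#' @return The subset of `records` with `dl >= threshold`, original order kept.
#' @examples
#' tab <- data.frame(herb = "kushen", compound_id = c("a", "b", "c"),
#'                   dl = c(0.10, 0.18, 0.50))
#' filter_by_druglikeness(tab)$compound_id
#' @export
filter_by_druglikeness <- function(records, threshold = 0.18) {
  stopifnot(is.data.frame(records))
  if (length(threshold) != 1L || is.na(threshold) || threshold < 0 || threshold > 1) {
    stop_validation("'threshold' must be a single value in [0, 1]")
  }
  if (nrow(records) == 0L) return(records)
  if (!"dl" %in% names(records)) stop_validation("'records' must have a 'dl' column")
  bad <- which(is.na(records$dl) | records$dl < 0 | records$dl > 1)
  if (length(bad)) {
    stop_validation("drug-likeness outside [0, 1] at row %d (compound '%s')",
                    bad[1L], as.character(records$compound_id[bad[1L]]))
  }
  records[records$dl >= threshold, , drop = FALSE]
}

#' Summarize the overlap between two herb compound catalogs
#'
#' Compound identity is the compound id after case-folding and whitespace
#' stripping; duplicates within a catalog are collapsed before counting.
#'
#' @param set_a,set_b character vectors of compound ids for the two herbs.
#' @return A list of class `herb_overlap_summary` with counts `n_unique_a`,
#'   `n_unique_b`, `n_common` and `n_union`
#'   (`n_union = n_unique_a + n_unique_b + n_common`).
#' @examples
#' herb_overlap_summary(c("a", "b", "c"), c("b", "d"))
#' @export
herb_overlap_summary <- function(set_a, set_b) {
  a <- unique(normalize_compound_id(set_a))
  b <- unique(normalize_compound_id(set_b))
  out <- list(
    n_unique_a = length(setdiff(a, b)),
    n_unique_b = length(setdiff(b, a)),
    n_common   = length(intersect(a, b)),
    n_union    = length(union(a, b))
  )
  stopifnot(out$n_union == out$n_unique_a + out$n_unique_b + out$n_common)
  structure(out, class = "herb_overlap_summary")
}

#' @export
print.herb_overlap_summary <- function(x, ...) {
  cat(sprintf("herb catalog overlap: %d union (%d + %d unique, %d common)\n",
              x$n_union, x$n_unique_a, x$n_unique_b, x$n_common))
  invisible(x)
}
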
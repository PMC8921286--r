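#' Intersect compound-derived targets with disease genes
#'
#' Candidate targets are the gene symbols that are both predicted targets of
#' the herb compounds and known disease genes. Every compound with at least
#' one prediction landing in the intersection is reported as a contributing
#' (bioactive) compound.
#'
#' @param compound_targets a `symbol_set` from [map_to_symbols()] (or any list
#'   with `symbols` and a `provenance` data.frame of `gene_symbol`,
#'   `compound_id` pairs).
#' @param disease_genes character vector of disease gene symbols.
#' @return A list of class `candidate_target_set` with `targets` (sorted
#'   symbols), `compounds` (sorted compound ids), `provenance` (the
#'   compound-target pairs restricted to candidates) and `attribution`
#'   (NULL until [attribute_to_herbs()] is applied).
#' @export
intersect_evidence <- function(compound_targets, disease_genes) {
  stopifnot(is.list(compound_targets), !is.null(compound_targets$provenance))
  targets <- sort(intersect(normalize_symbol(compound_targets$symbols),
                            normalize_symbol(disease_genes)))
  prov <- compound_targets$provenance
  prov <- prov[prov$gene_symbol %in% targets, , drop = FALSE]
  rownames(prov) <- NULL
  structure(list(
    targets     = targets,
    compounds   = sort(unique(prov$compound_id)),
    provenance  = prov,
    attribution = NULL
  ), class = "candidate_target_set")
}

#' Attribute candidate targets to herbs
#'
#' A target reached by compounds of both herbs is `common`; otherwise it is
#' unique to the herb whose compounds reach it. A compound listed under both
#' herb catalogs contributes to both herbs.
#'
#' @param candidates a `candidate_target_set` from [intersect_evidence()].
#' @param herb_of_compound data.frame with columns `compound_id` and `herb`
#'   (long format: a shared compound appears once per herb).
#' @return `candidates` with an `attribution` element: named character vector
#'   over targets with values `"common"`, `"kushen-only"`, `"baituling-only"`.
#' @export
attribute_to_herbs <- function(candidates, herb_of_compound) {
  stopifnot(inherits(candidates, "candidate_target_set"),
            is.data.frame(herb_of_compound))
  hm <- unique(data.frame(
    compound_id = normalize_compound_id(herb_of_compound$compound_id),
    herb        = tolower(as.character(herb_of_compound$herb)),
    stringsAsFactors = FALSE
  ))
  prov <- candidates$provenance
  cmp <- normalize_compound_id(prov$compound_id)
  missing <- setdiff(unique(cmp), hm$compound_id)
  if (length(missing)) {
    stop_validation("compound without a herb label: %s", missing[1L])
  }
  herbs_of <- split(hm$herb, hm$compound_id)
  attribution <- vapply(candidates$targets, function(tg) {
    hs <- unique(unlist(herbs_of[cmp[prov$gene_symbol == tg]], use.names = FALSE))
    if (all(c("kushen", "baituling") %in% hs)) "common"
    else if ("kushen" %in% hs) "kushen-only"
    else "baituling-only"
  }, character(1))
  candidates$attribution <- attribution
  candidates
}

#' @export
print.candidate_target_set <- function(x, ...) {
  cat(sprintf("candidate targets: %d genes from %d compounds\n",
              length(x$targets), length(x$compounds)))
  if (!is.null(x$attribution)) {
    tab <- table(x$attribution)
    cat("  attribution:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}
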
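# Plain-text serialization of fixture bundles: headered TSV per table, GMT
# for the pathway collection, JSON for config and ground truth.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

read_tsv <- function(path, col_classes = NA) {
  utils::read.delim(path, sep = "\t", header = TRUE, colClasses = col_classes,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a fixture bundle to a directory
#'
#' Emits one headered TSV per input table, a GMT file for the pathway
#' collection, and a JSON manifest holding the configuration and the
#' ground-truth manifest. [read_fixture()] reproduces the bundle.
#'
#' @param bundle a `fixture_bundle` from [generate_fixture()].
#' @param directory output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_fixture <- function(bundle, directory) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_validation("cannot create fixture directory '%s'", directory)
  }
  p <- function(f) file.path(directory, f)
  write_tsv(bundle$ingredient_table, p("ingredients.tsv"))
  write_tsv(bundle$prediction_table, p("predictions.tsv"))
  write_tsv(bundle$protein_mapping, p("protein_mapping.tsv"))
  for (s in names(bundle$disease_tables)) {
    write_tsv(bundle$disease_tables[[s]], p(sprintf("disease_%s.tsv", s)))
  }
  write_tsv(bundle$ppi_edges, p("ppi_edges.tsv"))
  write_gmt(bundle$pathway_collection, p("pathways.gmt"))
  for (line in names(bundle$de_tables)) {
    write_tsv(bundle$de_tables[[line]], p(sprintf("de_%s.tsv", line)))
  }
  cfg_out <- unclass(bundle$config)
  # jsonlite drops names on atomic vectors; keep the named fields as objects
  cfg_out$source_sizes <- as.list(cfg_out$source_sizes)
  cfg_out$attribution_counts <- as.list(cfg_out$attribution_counts)
  manifest <- list(config = cfg_out, truth = bundle$truth,
                   de_lines = names(bundle$de_tables),
                   disease_sources = names(bundle$disease_tables))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(directory)
}

#' Read a fixture bundle back from a directory
#'
#' @param directory a directory written by [write_fixture()].
#' @return a `fixture_bundle`.
#' @export
read_fixture <- function(directory) {
  p <- function(f) file.path(directory, f)
  if (!file.exists(p("manifest.json"))) {
    stop_validation("'%s' does not contain a fixture manifest", directory)
  }
  manifest <- jsonlite::read_json(p("manifest.json"), simplifyVector = TRUE)
  cfg <- manifest$config
  # JSON round-trips named numeric vectors as lists; restore the vector fields
  for (f in c("source_sizes", "attribution_counts")) {
    cfg[[f]] <- unlist(cfg[[f]])
  }
  int_fields <- vapply(cfg, function(x) is.numeric(x) && all(x == round(x)),
                       logical(1))
  cfg[int_fields] <- lapply(cfg[int_fields], function(x) {
    storage.mode(x) <- "integer"; x
  })
  cfg <- do.call(fixture_config, cfg)
  truth <- manifest$truth
  # empty JSON arrays come back as empty lists; restore empty character vectors
  fix_empty <- function(x) {
    if (is.list(x) && length(x) == 0L) return(character(0))
    if (is.list(x)) return(lapply(x, fix_empty))
    x
  }
  truth <- fix_empty(truth)

  disease <- lapply(manifest$disease_sources, function(s) {
    read_tsv(p(sprintf("disease_%s.tsv", s)))
  })
  names(disease) <- manifest$disease_sources
  de <- lapply(manifest$de_lines, function(line) {
    read_tsv(p(sprintf("de_%s.tsv", line)))
  })
  names(de) <- manifest$de_lines
  structure(list(
    config = cfg,
    ingredient_table = read_tsv(p("ingredients.tsv"),
                                c("character", "character", "character", "numeric")),
    prediction_table = read_tsv(p("predictions.tsv"),
                                c("character", "character", "numeric", "integer")),
    protein_mapping = read_tsv(p("protein_mapping.tsv"),
                               c("character", "character")),
    disease_tables = disease,
    ppi_edges = read_tsv(p("ppi_edges.tsv"),
                         c("character", "character", "numeric")),
    pathway_collection = read_gmt(p("pathways.gmt")),
    de_tables = de,
    truth = truth
  ), class = "fixture_bundle")
}
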
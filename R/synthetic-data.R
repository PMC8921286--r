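# Seeded generator of the database-extract fixtures the screening pipeline
# consumes: herb ingredient catalogs with drug-likeness scores, per-compound
# scored target predictions with a protein-to-symbol mapping, four disease-gene
# source tables, a STRING-style scored PPI edge table, a pathway collection
# (GMT) and per-cell-line differential-expression tables. All planted
# structure (shared compounds, candidate targets, hubs, spiked pathways, key
# targets) is recorded in a ground-truth manifest.

# Published symbols used to label the planted candidate set so fixtures read
# like the field's outputs; padded with synthetic symbols when a configuration
# asks for different counts.
.candidate_vocab <- list(
  common = c("TP53", "MDM2", "ERBB2", "HOXB13", "UNG", "PTPRJ"),
  kushen_only = c("CHEK1", "TP73", "MTOR", "IRF1", "IL10", "CTNNB1", "CCND1",
                  "EGF", "MAP2K2", "ANP32A", "IGF1", "AXIN1", "DAB2", "BIRC5",
                  "PLA2G2A", "ALK", "AURKA", "DHFR", "MPO", "TYMS", "AR", "TOP1"),
  baituling_only = c("DNMT1", "ERBB4", "DICER1", "DLC1", "CDKN2A", "MMP1")
)

#' Configuration for the synthetic fixture generator
#'
#' Defaults are the printed study conditions: 368 Kushen and 152 Baituling
#' screened ingredients sharing 43 (union 477), 533 unique predicted target
#' symbols, disease sources of 84/197/200/163 records (644 total) reducing to
#' 557 unique genes, 34 candidate targets reached by 82 bioactive compounds,
#' a 118-node / 402-edge tripartite network, a 31-node / 174-edge PPI graph
#' with 14 above-mean-degree hubs, 33 predicted pathways, and 23 (SW480) /
#' 32 (SW620) spiked pathways whose three-way intersection is the single
#' "Cell cycle" pathway carrying TP53 and CHEK1 as common key targets.
#'
#' @param n_kushen_ingredients,n_baituling_ingredients,n_shared_ingredients
#'   screened catalog sizes per herb and the number of compounds shared.
#' @param dl_fraction_below fraction of the catalog with drug-likeness below
#'   `dl_threshold` (0 by default: printed catalogs are post-screen).
#' @param dl_threshold drug-likeness cutoff.
#' @param n_predictions_per_compound raw scored predictions per compound
#'   (must exceed `n_top_targets` for the cut to bind).
#' @param n_top_targets per-compound cut applied downstream.
#' @param n_compound_symbols unique gene symbols over the kept predictions.
#' @param n_unmapped_proteins decoy protein ids absent from the symbol
#'   mapping, placed below the top cut.
#' @param source_sizes named counts of post-rule records per disease source
#'   (`ttd`, `omim`, `genecards`, `disgenet`).
#' @param n_genecards_raw,n_disgenet_raw raw table sizes before the
#'   relevance/DSI rules.
#' @param n_unique_disease_genes unique genes after integrating the four
#'   sources.
#' @param n_candidate_targets planted size of the compound-disease
#'   intersection.
#' @param attribution_counts named counts (`common`, `kushen_only`,
#'   `baituling_only`) partitioning the candidates by herb reachability.
#' @param n_active_compounds compounds with at least one candidate hit.
#' @param n_shared_active,n_baituling_active how many active compounds come
#'   from the shared block and the Baituling-only block.
#' @param n_compound_target_edges planted compound-to-candidate edges.
#' @param ppi_connected,ppi_edges,ppi_hubs PPI subgraph: nodes left after
#'   isolation removal, edge count, and hubs (degree above mean).
#' @param ppi_min_score STRING-style confidence cutoff the planted edges
#'   respect.
#' @param n_pathways,pathway_size_range gene-set collection size and
#'   per-pathway member range.
#' @param n_predicted_pathways pathways planted to enrich in the candidate
#'   set.
#' @param n_sw480_pathways,n_sw620_pathways spiked pathway counts per line.
#' @param n_sw620_predicted_overlap spiked SW620 pathways that are also
#'   predicted (includes the key pathway).
#' @param spike_fraction fraction of a spiked pathway's members flagged DE.
#' @param n_de_background extra DE genes per line outside every pathway.
#' @param seed integer seed that fully determines the fixture.
#' @return list of class `fixture_config`.
#' @export
fixture_config <- function(n_kushen_ingredients = 368,
                           n_baituling_ingredients = 152,
                           n_shared_ingredients = 43,
                           dl_fraction_below = 0,
                           dl_threshold = 0.18,
                           n_predictions_per_compound = 40,
                           n_top_targets = 30,
                           n_compound_symbols = 533,
                           n_unmapped_proteins = 10,
                           source_sizes = c(ttd = 84, omim = 197,
                                            genecards = 200, disgenet = 163),
                           n_genecards_raw = 350,
                           n_disgenet_raw = 326,
                           n_unique_disease_genes = 557,
                           n_candidate_targets = 34,
                           attribution_counts = c(common = 6, kushen_only = 22,
                                                  baituling_only = 6),
                           n_active_compounds = 82,
                           n_shared_active = 2,
                           n_baituling_active = 10,
                           n_compound_target_edges = 318,
                           ppi_connected = 31,
                           ppi_edges = 174,
                           ppi_hubs = 14,
                           ppi_min_score = 0.4,
                           n_pathways = 100,
                           pathway_size_range = c(15, 30),
                           n_predicted_pathways = 33,
                           n_sw480_pathways = 23,
                           n_sw620_pathways = 32,
                           n_sw620_predicted_overlap = 17,
                           spike_fraction = 0.6,
                           n_de_background = 30,
                           seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "fixture_config"
  validate_fixture_config(cfg)
  cfg
}

validate_fixture_config <- function(cfg) {
  cerr <- function(field, fmt, ...) {
    stop(sprintf("invalid fixture configuration ('%s'): %s", field,
                 sprintf(fmt, ...)), call. = FALSE)
  }
  for (f in c("n_kushen_ingredients", "n_baituling_ingredients",
              "n_shared_ingredients", "n_predictions_per_compound",
              "n_top_targets", "n_compound_symbols", "n_unmapped_proteins",
              "n_genecards_raw", "n_disgenet_raw", "n_unique_disease_genes",
              "n_candidate_targets", "n_active_compounds", "n_shared_active",
              "n_baituling_active", "n_compound_target_edges", "ppi_connected",
              "ppi_edges", "ppi_hubs", "n_pathways", "n_predicted_pathways",
              "n_sw480_pathways", "n_sw620_pathways",
              "n_sw620_predicted_overlap", "n_de_background")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || is.na(cfg[[f]]) ||
        cfg[[f]] < 0 || cfg[[f]] != as.integer(cfg[[f]])) {
      cerr(f, "must be a single nonnegative integer")
    }
  }
  if (cfg$n_shared_ingredients > min(cfg$n_kushen_ingredients,
                                     cfg$n_baituling_ingredients)) {
    cerr("n_shared_ingredients", "cannot exceed either herb total")
  }
  if (cfg$dl_fraction_below < 0 || cfg$dl_fraction_below >= 1) {
    cerr("dl_fraction_below", "must lie in [0, 1)")
  }
  if (cfg$dl_threshold <= 0 || cfg$dl_threshold >= 1) {
    cerr("dl_threshold", "must lie in (0, 1)")
  }
  if (cfg$n_predictions_per_compound <= cfg$n_top_targets) {
    cerr("n_predictions_per_compound", "must exceed n_top_targets")
  }
  if (!all(c("ttd", "omim", "genecards", "disgenet") %in% names(cfg$source_sizes))) {
    cerr("source_sizes", "must name ttd, omim, genecards and disgenet")
  }
  if (cfg$n_genecards_raw < cfg$source_sizes[["genecards"]]) {
    cerr("n_genecards_raw", "smaller than the planted GeneCards output")
  }
  if (cfg$n_disgenet_raw < cfg$source_sizes[["disgenet"]]) {
    cerr("n_disgenet_raw", "smaller than the planted DisGeNET output")
  }
  if (cfg$n_candidate_targets > cfg$n_unique_disease_genes) {
    cerr("n_candidate_targets", "cannot exceed n_unique_disease_genes")
  }
  if (sum(cfg$source_sizes[c("ttd", "omim", "genecards")]) >=
      cfg$n_unique_disease_genes) {
    cerr("n_unique_disease_genes",
         "must exceed the TTD + OMIM + GeneCards record total")
  }
  if (cfg$n_candidate_targets > cfg$n_compound_symbols) {
    cerr("n_candidate_targets", "cannot exceed n_compound_symbols")
  }
  if (sum(cfg$attribution_counts) != cfg$n_candidate_targets) {
    cerr("attribution_counts", "must sum to n_candidate_targets")
  }
  n_union <- cfg$n_kushen_ingredients + cfg$n_baituling_ingredients -
    cfg$n_shared_ingredients
  if (cfg$n_active_compounds > n_union) {
    cerr("n_active_compounds", "cannot exceed the compound union")
  }
  if (cfg$n_shared_active > cfg$n_shared_ingredients) {
    cerr("n_shared_active", "cannot exceed n_shared_ingredients")
  }
  if (cfg$n_baituling_active >
      cfg$n_baituling_ingredients - cfg$n_shared_ingredients) {
    cerr("n_baituling_active", "cannot exceed the Baituling-only catalog")
  }
  n_kushen_active <- cfg$n_active_compounds - cfg$n_shared_active -
    cfg$n_baituling_active
  if (n_kushen_active < 0 ||
      n_kushen_active > cfg$n_kushen_ingredients - cfg$n_shared_ingredients) {
    cerr("n_active_compounds", "herb split of active compounds is infeasible")
  }
  ac <- cfg$attribution_counts
  min_edges <- max(cfg$n_candidate_targets, cfg$n_active_compounds)
  if (cfg$n_compound_target_edges < min_edges) {
    cerr("n_compound_target_edges",
         "too few edges to cover every target and compound (need >= %d)", min_edges)
  }
  max_edges <- n_kushen_active * (ac[["kushen_only"]] + ac[["common"]]) +
    cfg$n_baituling_active * (ac[["baituling_only"]] + ac[["common"]]) +
    cfg$n_shared_active * ac[["common"]]
  if (cfg$n_compound_target_edges > max_edges) {
    cerr("n_compound_target_edges",
         "exceeds the number of herb-consistent compound-target pairs (%d)", max_edges)
  }
  if (ac[["common"]] > 0 && cfg$n_shared_active == 0) {
    cerr("n_shared_active", "common targets need at least one shared active compound")
  }
  if (ac[["baituling_only"]] > 0 && cfg$n_baituling_active == 0) {
    cerr("n_baituling_active", "baituling-only targets need active Baituling compounds")
  }
  if (cfg$ppi_connected + 3L < cfg$ppi_hubs ||
      cfg$ppi_hubs >= cfg$ppi_connected || cfg$ppi_hubs < 1) {
    cerr("ppi_hubs", "must be positive and below ppi_connected")
  }
  if (cfg$ppi_connected > cfg$n_candidate_targets) {
    cerr("ppi_connected", "cannot exceed n_candidate_targets")
  }
  clique <- cfg$ppi_hubs * (cfg$ppi_hubs - 1) / 2
  spokes <- cfg$ppi_edges - clique
  n_nonhub <- cfg$ppi_connected - cfg$ppi_hubs
  if (spokes < n_nonhub || (n_nonhub > 0 && spokes > n_nonhub * (cfg$ppi_hubs - 1))) {
    cerr("ppi_edges", "infeasible for the hub-clique-plus-spokes construction")
  }
  if (length(cfg$pathway_size_range) != 2L ||
      cfg$pathway_size_range[1] > cfg$pathway_size_range[2] ||
      cfg$pathway_size_range[1] < 15) {
    cerr("pathway_size_range", "must be (lo, hi) with lo >= 15")
  }
  if (cfg$n_predicted_pathways > cfg$n_pathways) {
    cerr("n_predicted_pathways", "cannot exceed n_pathways")
  }
  if (cfg$n_sw620_predicted_overlap > min(cfg$n_predicted_pathways,
                                          cfg$n_sw620_pathways)) {
    cerr("n_sw620_predicted_overlap", "exceeds predicted or SW620 pathway count")
  }
  n_decoy_needed <- (cfg$n_sw480_pathways - 1L) +
    (cfg$n_sw620_pathways - cfg$n_sw620_predicted_overlap)
  if (cfg$n_pathways - cfg$n_predicted_pathways < n_decoy_needed) {
    cerr("n_pathways", "not enough decoy pathways for the spiking plan")
  }
  if (cfg$spike_fraction <= 0 || cfg$spike_fraction > 1) {
    cerr("spike_fraction", "must lie in (0, 1]")
  }
  invisible(cfg)
}

#' Generate a complete synthetic fixture bundle
#'
#' Runs the seeded construction of every table the pipeline consumes. Equal
#' configurations (including the seed) produce identical bundles. The
#' returned `truth` manifest records every planted identifier so tests can
#' verify recoverability independently.
#'
#' @param config a [fixture_config()].
#' @return list of class `fixture_bundle` with elements `config`,
#'   `ingredient_table`, `prediction_table`, `protein_mapping`,
#'   `disease_tables`, `ppi_edges`, `pathway_collection`, `de_tables`,
#'   `truth`.
#' @export
generate_fixture <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  validate_fixture_config(config)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)
  cfg <- config

  ## ---- compound catalogs -------------------------------------------------
  n_union <- cfg$n_kushen_ingredients + cfg$n_baituling_ingredients -
    cfg$n_shared_ingredients
  compounds <- sprintf("CMP%06d", seq_len(n_union))
  shared <- compounds[seq_len(cfg$n_shared_ingredients)]
  kushen_only <- compounds[cfg$n_shared_ingredients +
                             seq_len(cfg$n_kushen_ingredients - cfg$n_shared_ingredients)]
  baituling_only <- setdiff(compounds, c(shared, kushen_only))

  n_kushen_active <- cfg$n_active_compounds - cfg$n_shared_active -
    cfg$n_baituling_active
  active <- c(
    if (cfg$n_shared_active > 0) sort(sample(shared, cfg$n_shared_active)) else character(0),
    if (n_kushen_active > 0) sort(sample(kushen_only, n_kushen_active)) else character(0),
    if (cfg$n_baituling_active > 0) sort(sample(baituling_only, cfg$n_baituling_active)) else character(0)
  )
  active_shared <- intersect(active, shared)
  active_kushen <- intersect(active, kushen_only)
  active_baituling <- intersect(active, baituling_only)

  n_below <- round(cfg$dl_fraction_below * n_union)
  inactive <- setdiff(compounds, active)
  if (n_below > length(inactive)) {
    stop_validation("invalid fixture configuration ('dl_fraction_below'): %s",
                    "not enough non-active compounds to place below the threshold")
  }
  below <- if (n_below > 0) sort(sample(inactive, n_below)) else character(0)
  dl <- stats::setNames(round(stats::runif(n_union, cfg$dl_threshold + 1e-6, 1), 6),
                        compounds)
  dl[below] <- round(stats::runif(n_below, 0, cfg$dl_threshold - 1e-6), 6)
  ingredient_table <- data.frame(
    herb = rep(c("kushen", "baituling"),
               c(cfg$n_kushen_ingredients, cfg$n_baituling_ingredients)),
    compound_id = c(shared, kushen_only, shared, baituling_only),
    name = NA_character_,
    dl = NA_real_,
    stringsAsFactors = FALSE
  )
  ingredient_table$name <- paste("compound",
                                 match(ingredient_table$compound_id, compounds))
  ingredient_table$dl <- unname(dl[ingredient_table$compound_id])

  ## ---- gene vocabulary ---------------------------------------------------
  ac <- cfg$attribution_counts
  pick_class <- function(vocab, n, prefix) {
    if (n <= length(vocab)) vocab[seq_len(n)]
    else c(vocab, sprintf("%s%03d", prefix, seq_len(n - length(vocab))))
  }
  cand_common <- pick_class(.candidate_vocab$common, ac[["common"]], "CANC")
  cand_kushen <- pick_class(.candidate_vocab$kushen_only, ac[["kushen_only"]], "CANK")
  cand_baituling <- pick_class(.candidate_vocab$baituling_only,
                               ac[["baituling_only"]], "CANB")
  candidates <- c(cand_common, cand_kushen, cand_baituling)
  tgt_pool <- sprintf("TGT%04d", seq_len(cfg$n_compound_symbols - length(candidates)))
  dis_pool <- sprintf("DIS%04d",
                      seq_len(cfg$n_unique_disease_genes - length(candidates)))

  ## ---- compound-to-candidate edges ---------------------------------------
  # herb-consistent eligibility: kushen-only targets from kushen-only actives,
  # baituling-only targets from baituling-only actives, common targets from a
  # shared active compound (reaching both herbs through one compound).
  edge_cmp <- character(0); edge_tgt <- character(0)
  add_edge <- function(cs, ts) {
    edge_cmp <<- c(edge_cmp, cs); edge_tgt <<- c(edge_tgt, ts)
  }
  if (length(cand_common)) {
    add_edge(rep_len(active_shared, length(cand_common)), cand_common)
  }
  if (length(cand_kushen)) {
    add_edge(sample(active_kushen, length(cand_kushen),
                    replace = length(cand_kushen) > length(active_kushen)),
             cand_kushen)
  }
  if (length(cand_baituling)) {
    add_edge(sample(active_baituling, length(cand_baituling),
                    replace = length(cand_baituling) > length(active_baituling)),
             cand_baituling)
  }
  eligible_targets <- function(cmp) {
    if (cmp %in% active_shared) cand_common
    else if (cmp %in% active_kushen) c(cand_kushen, cand_common)
    else c(cand_baituling, cand_common)
  }
  for (cmp in setdiff(active, unique(edge_cmp))) {
    el <- eligible_targets(cmp)
    add_edge(cmp, el[sample.int(length(el), 1L)])
  }
  key <- paste(edge_cmp, edge_tgt, sep = "\r")
  dup <- duplicated(key)
  edge_cmp <- edge_cmp[!dup]; edge_tgt <- edge_tgt[!dup]
  pool <- rbind(
    expand.grid(cmp = active_kushen, tgt = c(cand_kushen, cand_common),
                stringsAsFactors = FALSE),
    expand.grid(cmp = active_baituling, tgt = c(cand_baituling, cand_common),
                stringsAsFactors = FALSE),
    expand.grid(cmp = active_shared, tgt = cand_common, stringsAsFactors = FALSE)
  )
  pool_key <- paste(pool$cmp, pool$tgt, sep = "\r")
  avail <- which(!pool_key %in% paste(edge_cmp, edge_tgt, sep = "\r"))
  need <- cfg$n_compound_target_edges - length(edge_cmp)
  if (need > 0) {
    take <- avail[sample.int(length(avail), need)]
    add_edge(pool$cmp[take], pool$tgt[take])
  }
  candidate_edges <- data.frame(compound_id = edge_cmp, gene_symbol = edge_tgt,
                                stringsAsFactors = FALSE)

  ## ---- predictions and protein mapping -----------------------------------
  mapped_symbols <- c(candidates, tgt_pool)
  protein_of <- stats::setNames(sprintf("PRT%05d", seq_along(mapped_symbols)),
                                mapped_symbols)
  protein_mapping <- data.frame(protein_id = unname(protein_of),
                                gene_symbol = mapped_symbols,
                                stringsAsFactors = FALSE)
  unk <- sprintf("UNK%03d", seq_len(cfg$n_unmapped_proteins))

  cand_by_cmp <- split(candidate_edges$gene_symbol, candidate_edges$compound_id)
  # coverage: every mapped non-candidate symbol appears in someone's kept slots
  cover_by_cmp <- split(tgt_pool,
                        compounds[(seq_along(tgt_pool) - 1L) %% n_union + 1L])
  n_keep <- cfg$n_top_targets
  n_raw <- cfg$n_predictions_per_compound
  pred_list <- vector("list", n_union)
  for (i in seq_len(n_union)) {
    cmp <- compounds[i]
    planted <- cand_by_cmp[[cmp]] %||% character(0)
    fillers <- cover_by_cmp[[cmp]] %||% character(0)
    n_fill <- n_keep - length(planted) - length(fillers)
    if (n_fill < 0) stop_validation("compound %s has more planted targets than kept slots", cmp)
    extra <- sample(setdiff(tgt_pool, fillers), n_fill)
    kept_syms <- c(planted, fillers, extra)
    kept_prot <- unname(protein_of[kept_syms])
    below_pool <- c(setdiff(unname(protein_of[tgt_pool]), kept_prot), unk)
    below_prot <- sample(below_pool, n_raw - n_keep)
    scores <- sort(stats::runif(n_raw), decreasing = TRUE)
    scores <- round(scores - (seq_len(n_raw) - 1L) * 1e-9, 9)
    if (scores[n_raw] <= 0) scores <- scores + 1e-6
    pred_list[[i]] <- data.frame(
      compound_id = cmp,
      target_protein = c(kept_prot, below_prot),
      normalized_fit_score = scores,
      rank = seq_len(n_raw),
      stringsAsFactors = FALSE
    )
  }
  prediction_table <- do.call(rbind, pred_list)
  rownames(prediction_table) <- NULL

  ## ---- disease source tables ---------------------------------------------
  ss <- cfg$source_sizes
  n_dup <- sum(ss) - cfg$n_unique_disease_genes
  if (n_dup < 0) {
    stop_validation("invalid fixture configuration ('n_unique_disease_genes'): %s",
                    "exceeds the total record count")
  }
  genes <- c(candidates, dis_pool) # g1..g557, candidates first
  n_ttd <- ss[["ttd"]]; n_omim <- ss[["omim"]]
  n_gc <- ss[["genecards"]]; n_dg <- ss[["disgenet"]]
  if (length(candidates) > n_ttd || n_dup > n_ttd + n_omim + n_gc ||
      n_dup > n_dg || length(candidates) > n_dup) {
    stop_validation("invalid fixture configuration ('source_sizes'): %s",
                    "cannot place candidates in two sources with the requested duplication")
  }
  ttd_genes <- genes[seq_len(n_ttd)]
  omim_genes <- genes[n_ttd + seq_len(n_omim)]
  gc_genes <- genes[n_ttd + n_omim + seq_len(n_gc)]
  fresh_dg <- genes[(n_ttd + n_omim + n_gc + 1):length(genes)]
  dg_genes <- c(fresh_dg, genes[seq_len(n_dup)])
  stopifnot(length(dg_genes) == n_dg)

  disease_tables <- list(
    ttd = data.frame(source = "ttd", gene_symbol = sample(ttd_genes),
                     stringsAsFactors = FALSE),
    omim = data.frame(source = "omim", gene_symbol = sample(omim_genes),
                      stringsAsFactors = FALSE),
    genecards = local({
      planted <- data.frame(source = "genecards", gene_symbol = gc_genes,
                            relevance = round(stats::runif(n_gc, 10, 100), 6),
                            stringsAsFactors = FALSE)
      n_dec <- cfg$n_genecards_raw - n_gc
      decoys <- data.frame(source = "genecards",
                           gene_symbol = sprintf("GCX%04d", seq_len(n_dec)),
                           relevance = round(stats::runif(n_dec, 0, 9.5), 6),
                           stringsAsFactors = FALSE)
      tab <- rbind(planted, decoys)
      tab[sample.int(nrow(tab)), , drop = FALSE]
    }),
    disgenet = local({
      planted <- data.frame(source = "disgenet", gene_symbol = dg_genes,
                            dsi = round(stats::runif(n_dg, 0.55, 0.99), 6),
                            stringsAsFactors = FALSE)
      n_dec <- cfg$n_disgenet_raw - n_dg
      decoys <- data.frame(source = "disgenet",
                           gene_symbol = sprintf("DGX%04d", seq_len(n_dec)),
                           dsi = round(stats::runif(n_dec, 0.01, 0.45), 6),
                           stringsAsFactors = FALSE)
      tab <- rbind(planted, decoys)
      tab[sample.int(nrow(tab)), , drop = FALSE]
    })
  )
  for (s in names(disease_tables)) rownames(disease_tables[[s]]) <- NULL

  ## ---- PPI edge table -----------------------------------------------------
  # hub clique plus non-hub spokes gives an exact edge count and exactly the
  # requested number of above-mean degrees, with the first hub on top.
  hub_priority <- intersect(c("TP53", "CCND1", "CDKN2A", "MDM2", "CTNNB1",
                              "CHEK1", "EGF", "MTOR", "IGF1"), candidates)
  iso_priority <- intersect(c("UNG", "PLA2G2A", "MPO"), candidates)
  n_iso <- cfg$n_candidate_targets - cfg$ppi_connected
  isolated <- pick_from <- setdiff(candidates, hub_priority)
  isolated <- c(intersect(iso_priority, pick_from),
                setdiff(pick_from, iso_priority))[seq_len(n_iso)]
  connected <- setdiff(candidates, isolated)
  hubs <- c(hub_priority, setdiff(connected, hub_priority))[seq_len(cfg$ppi_hubs)]
  nonhubs <- setdiff(connected, hubs)
  clique <- if (length(hubs) >= 2L) t(utils::combn(hubs, 2L)) else
    matrix(character(0), ncol = 2)
  n_spokes <- cfg$ppi_edges - nrow(clique)
  spoke_a <- character(0); spoke_b <- character(0)
  if (length(nonhubs)) {
    degs <- rep(floor(n_spokes / length(nonhubs)), length(nonhubs))
    rem <- n_spokes - sum(degs)
    if (rem > 0) degs[seq_len(rem)] <- degs[seq_len(rem)] + 1L
    ptr <- 0L
    for (j in seq_along(nonhubs)) {
      idx <- (ptr + seq_len(degs[j]) - 1L) %% length(hubs) + 1L
      spoke_a <- c(spoke_a, rep(nonhubs[j], degs[j]))
      spoke_b <- c(spoke_b, hubs[idx])
      ptr <- ptr + degs[j]
    }
    # tip the first hub to the strictly largest degree
    movable <- which(spoke_b != hubs[1L])
    for (m in rev(movable)) {
      already <- spoke_b[spoke_a == spoke_a[m]]
      if (!hubs[1L] %in% already) { spoke_b[m] <- hubs[1L]; break }
    }
  }
  real_edges <- data.frame(
    gene_a = c(clique[, 1], spoke_a),
    gene_b = c(clique[, 2], spoke_b),
    combined_score = round(stats::runif(cfg$ppi_edges, cfg$ppi_min_score + 0.001,
                                        0.999), 6),
    stringsAsFactors = FALSE
  )
  real_key <- paste(pmin(real_edges$gene_a, real_edges$gene_b),
                    pmax(real_edges$gene_a, real_edges$gene_b), sep = "\r")
  decoy_low <- local({ # sub-threshold edges, one per isolated node plus extras
    a <- character(0); b <- character(0)
    for (g in isolated) { a <- c(a, g); b <- c(b, sample(connected, 1L)) }
    extra_pool <- expand.grid(x = candidates, y = candidates,
                              stringsAsFactors = FALSE)
    extra_pool <- extra_pool[extra_pool$x < extra_pool$y, , drop = FALSE]
    ek <- paste(extra_pool$x, extra_pool$y, sep = "\r")
    extra_pool <- extra_pool[!ek %in% real_key, , drop = FALSE]
    take <- sample(nrow(extra_pool), min(20L, nrow(extra_pool)))
    a <- c(a, extra_pool$x[take]); b <- c(b, extra_pool$y[take])
    data.frame(gene_a = a, gene_b = b,
               combined_score = round(stats::runif(length(a), 0.15,
                                                   cfg$ppi_min_score - 0.001), 6),
               stringsAsFactors = FALSE)
  })
  decoy_out <- data.frame( # edges touching non-candidate genes
    gene_a = sample(candidates, 30L, replace = TRUE),
    gene_b = sample(c(tgt_pool, dis_pool), 30L),
    combined_score = round(stats::runif(30L, 0.15, 0.95), 6),
    stringsAsFactors = FALSE
  )
  ppi_edges <- rbind(real_edges, decoy_low, decoy_out)
  ppi_edges <- ppi_edges[sample.int(nrow(ppi_edges)), , drop = FALSE]
  rownames(ppi_edges) <- NULL

  ## ---- pathway collection -------------------------------------------------
  n_pw <- cfg$n_pathways
  pw_names <- c("Cell cycle", "p53 signaling pathway",
                sprintf("Pathway %03d", seq_len(max(0L, n_pw - 2L)) + 2L))[seq_len(n_pw)]
  predicted_idx <- seq_len(cfg$n_predicted_pathways)
  sizes <- sample(seq(cfg$pathway_size_range[1], cfg$pathway_size_range[2]),
                  n_pw, replace = TRUE)
  key_members <- intersect(c("TP53", "CHEK1", "CCND1", "CDKN2A", "MDM2"),
                           candidates)
  de_only_gene <- "CDKN1A"
  # candidate membership: key pathway carries the key targets; the remaining
  # predicted pathways carry 3 candidates each with full coverage of the 34
  cand_members <- vector("list", n_pw)
  cand_members[[1L]] <- key_members
  rest <- setdiff(candidates, key_members)
  if (cfg$n_predicted_pathways > 1L) {
    slots <- rep(seq(2L, cfg$n_predicted_pathways), length.out = length(rest))
    for (j in seq_along(rest)) {
      cand_members[[slots[j]]] <- c(cand_members[[slots[j]]], rest[j])
    }
    for (i in seq(2L, cfg$n_predicted_pathways)) {
      short <- 3L - length(cand_members[[i]])
      if (short > 0) {
        cand_members[[i]] <- c(cand_members[[i]],
                               sample(setdiff(candidates, cand_members[[i]]), short))
      }
    }
  }
  pwg_counter <- 0L
  pathway_collection <- vector("list", n_pw)
  names(pathway_collection) <- pw_names
  for (i in seq_len(n_pw)) {
    cand_i <- cand_members[[i]] %||% character(0)
    special <- if (i == 1L) c(cand_i, de_only_gene) else cand_i
    # enough non-candidate fillers that a spike of ceil(f * size) can always
    # avoid candidate members: fillers >= f/(1-f) * |special| + 3
    min_fill <- ceiling(cfg$spike_fraction / (1 - cfg$spike_fraction + 1e-9) *
                          length(special)) + 3L
    n_fill <- max(sizes[i] - length(special), min_fill)
    fill <- sprintf("PWG%05d", pwg_counter + seq_len(n_fill))
    pwg_counter <- pwg_counter + n_fill
    pathway_collection[[i]] <- c(special, fill)
  }

  ## ---- spiked pathways and DE tables --------------------------------------
  decoy_idx <- setdiff(seq_len(n_pw), predicted_idx)
  sw480_idx <- c(1L, decoy_idx[seq_len(cfg$n_sw480_pathways - 1L)])
  used <- cfg$n_sw480_pathways - 1L
  sw620_idx <- c(predicted_idx[seq_len(cfg$n_sw620_predicted_overlap)],
                 decoy_idx[used + seq_len(cfg$n_sw620_pathways -
                                            cfg$n_sw620_predicted_overlap)])
  spiked <- list(SW480 = pw_names[sw480_idx], SW620 = pw_names[sw620_idx])

  sample_members <- function(idx, line) {
    members <- pathway_collection[[idx]]
    m <- ceiling(cfg$spike_fraction * length(members))
    if (idx == 1L && line == "SW620") {
      forced <- intersect(c("TP53", "CHEK1", de_only_gene), members)
      eligible <- setdiff(members, c(candidates, de_only_gene))
      c(forced, sample(eligible, m - length(forced)))
    } else {
      # candidate genes (and the DE-only marker) are never flagged outside the
      # planted key-target pattern, so key-target labels stay exact
      eligible <- setdiff(members, c(candidates, de_only_gene))
      sample(eligible, min(m, length(eligible)))
    }
  }
  de_truth <- list()
  cc_samples <- list()
  for (line in names(spiked)) {
    idxs <- match(spiked[[line]], pw_names)
    samples <- lapply(idxs, sample_members, line = line)
    if (1L %in% idxs) cc_samples[[line]] <- samples[[match(1L, idxs)]]
    de_truth[[line]] <- sort(unique(c(
      unlist(samples, use.names = FALSE),
      sprintf("BGD%s%03d", substr(line, 3, 4), seq_len(cfg$n_de_background))
    )))
  }

  universe <- sort(unique(unlist(pathway_collection, use.names = FALSE)))
  de_tables <- list()
  for (line in names(spiked)) {
    de <- de_truth[[line]]
    all_genes <- unique(c(universe, de, sample(tgt_pool, min(50L, length(tgt_pool)))))
    is_de <- all_genes %in% de
    n_g <- length(all_genes)
    padj <- ifelse(is_de, round(stats::runif(n_g, 1e-6, 0.04), 6),
                   round(stats::runif(n_g, 0.051, 1), 6))
    lfc <- ifelse(is_de,
                  -round(stats::runif(n_g, 1, 4), 4),
                  round(stats::runif(n_g, -0.9, 0.9), 4))
    if (line == "SW620") { # p21 analogue is up-regulated in SW620
      lfc[all_genes == de_only_gene] <- abs(lfc[all_genes == de_only_gene])
    }
    tab <- data.frame(gene = all_genes, log2fc = lfc,
                      p_value = round(padj * stats::runif(n_g, 0.1, 1), 6),
                      adjusted_p = padj, stringsAsFactors = FALSE)
    de_tables[[line]] <- tab[sample.int(nrow(tab)), , drop = FALSE]
    rownames(de_tables[[line]]) <- NULL
  }

  truth <- list(
    shared_ingredients = shared,
    below_dl_compounds = below,
    active_compounds = sort(active),
    candidate_targets = sort(candidates),
    attribution = list(common = sort(cand_common),
                       kushen_only = sort(cand_kushen),
                       baituling_only = sort(cand_baituling)),
    compound_symbols = sort(mapped_symbols),
    disease_duplicated_genes = sort(genes[seq_len(n_dup)]),
    disease_unique_genes = sort(genes),
    ppi = list(connected = sort(connected), isolated = sort(isolated),
               hubs = sort(hubs)),
    predicted_pathways = pw_names[predicted_idx],
    spiked_pathways = spiked,
    key_pathway = pw_names[1L],
    key_targets = list(
      common = sort(intersect(key_members, de_truth$SW620)),
      prediction_only = sort(setdiff(key_members,
                                     unique(c(de_truth$SW480, de_truth$SW620)))),
      de_only = lapply(cc_samples, function(s) sort(setdiff(s, candidates)))
    ),
    de_genes = de_truth
  )

  structure(list(
    config = cfg,
    ingredient_table = ingredient_table,
    prediction_table = prediction_table,
    protein_mapping = protein_mapping,
    disease_tables = disease_tables,
    ppi_edges = ppi_edges,
    pathway_collection = pathway_collection,
    de_tables = de_tables,
    truth = truth
  ), class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf(paste0("synthetic fixture: %d ingredient rows, %d predictions, ",
                     "%d disease records, %d PPI edges, %d pathways, %d DE tables\n"),
              nrow(x$ingredient_table), nrow(x$prediction_table),
              sum(vapply(x$disease_tables, nrow, integer(1))),
              nrow(x$ppi_edges), length(x$pathway_collection),
              length(x$de_tables)))
  invisible(x)
}
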
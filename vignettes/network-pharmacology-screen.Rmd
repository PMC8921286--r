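---
title: "The network-pharmacology screen: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The network-pharmacology screen: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ckinet re-implements, as tested and reusable code, the screening procedure by
which network pharmacology nominates candidate targets and pathways for
Compound Kushen Injection (CKI, a two-herb preparation of Kushen and
Baituling) against colorectal cancer. The procedure is a chain of set-algebra
and graph operations over database extracts, ending in a three-way pathway
consensus between the predicted pathway set and the pathways enriched in two
cell lines' differential-expression (DE) profiles. This vignette documents
the model behind each stage, the tunable parameters, what the synthetic
fixture generator does and does not emulate, and the design decisions taken
where the procedure is underdetermined.

## The screening chain

1. **Compound screen.** Herb ingredient catalogs carry a drug-likeness (DL)
   score in $[0,1]$; ingredients with DL $< 0.18$ are removed. The rule is
   read literally, so a compound at exactly 0.18 is retained. Compound
   identity across herb catalogs is the compound id after case-folding and
   whitespace stripping, and the per-herb accounting (unique/common/union) is
   plain set algebra on those ids.

2. **Target fishing.** Each compound has a list of scored protein
   predictions (a PharmMapper-style "normalized fit score" in $(0,1]$). The
   top $n = 30$ per compound are kept, then mapped to official gene symbols
   through a UniProt-style protein-to-symbol table. The cut is applied
   first and deduplication second; the two orders differ only when a
   compound's discarded tail maps onto a symbol it also reaches inside the
   cut, and cutting first is the more faithful reading of a per-compound
   "top 30". Ties at the cut break by (score descending, protein id
   ascending) so runs are reproducible. Proteins absent from the mapping are
   dropped with a logged count: downstream joins are on symbols, so an
   unmapped protein can contribute nothing.

3. **Disease genes.** Four sources are aggregated under source-specific
   rules: TTD and OMIM lists pass whole; GeneCards keeps the top 200 records
   by relevance score; DisGeNET keeps records with disease-specificity index
   (DSI) at or above the median of the retrieved set. The median is the
   interpolated median (mean of the two middle order statistics for
   even-length input) and ties with it are retained, since the rule
   discards only what is strictly "below median". Symbols are case-folded to
   upper case before the union; cross-database case inconsistency is the
   dominant source of spurious duplicates and no further alias resolution is
   attempted.

4. **Evidence intersection.** Candidate targets are the intersection of the
   compound-derived symbol set with the disease gene set; the bioactive
   compounds are those with at least one prediction landing in that
   intersection. Each candidate is attributed to `common`, `kushen-only` or
   `baituling-only` by which herbs' compounds reach it; a compound listed in
   both herb catalogs contributes to both herbs, so one shared compound is
   enough to make its targets common.

5. **Tripartite network.** Herbs, bioactive compounds and candidate targets
   form a graph with edges only between adjacent roles. Reported statistics:
   node and edge counts, density under both conventions
   ($2E/N(N-1)$ undirected and $E/N(N-1)$ directed-style), diameter (longest
   shortest path, computed on the largest component and flagged when the
   graph is disconnected), characteristic path length (mean shortest path
   over connected pairs) and average number of neighbors ($2E/N$). Both
   density conventions are emitted deliberately: published network tables
   are inconsistent about which formula they print, and for a 118-node,
   402-edge graph the two values (0.058 and 0.029) bracket the commonly
   printed 0.030, so neither is forced to match.

6. **PPI analysis.** STRING-style scored edges are thresholded at a
   combined score of 0.4 (the usual medium-confidence default; the
   extraction cutoff is not stated in the source procedure, so it is a
   configurable parameter), the subgraph induced on the candidates, and
   zero-degree nodes removed — the published networks report only the
   connected part. Hubs are nodes whose degree **strictly** exceeds the mean
   degree $2E/N$; strictness is the verbatim reading of "greater than the
   average" and makes regular graphs hub-free. A degree-ranked top-$k$
   (Cytohubba-style) is also provided, with lexicographic tie-breaks.

7. **Overrepresentation.** For a query of $n$ genes in a universe of $N$, a
   gene set with $K$ members and overlap $k$ is scored with the upper-tail
   hypergeometric probability $P(X \ge k)$. The EASE variant (DAVID's
   conservative score) replaces $k$ with $k-1$, floored at zero, and is
   offered as an option; the standard tail is the default because the exact
   variant used by any given DAVID run is not recoverable. The universe is
   the union of all collection members (the annotated universe), matching
   how DAVID-style tools behave when no background is supplied; queries are
   restricted to the universe before testing. Benjamini–Hochberg adjustment
   runs across all tested terms. Two reporting modes mirror the usual GO
   and KEGG cuts: adjusted $p < 0.05$ with the 20 smallest kept, and raw
   $p < 0.05$ respectively — the pathway stage uses raw $p$, which is how the
   KEGG counts in the source procedure are stated (its GO and KEGG
   significance rules genuinely differ, and both are kept verbatim).

8. **Consensus.** Pathway names are normalized (case-folded, punctuation
   and whitespace collapsed) before the three-way Venn decomposition of
   predicted vs per-line enriched pathway sets. The triple intersection is
   the key pathway. Its members are then classified by evidence:
   `common` (predicted and DE in at least one line), `prediction_only`, and
   per-line `de_only`.

9. **IHC scoring.** The immunoreactive score is the product of a
   staining-intensity category (1–3, where 1 is "no or weak staining") and a
   positive-cell percentage category (0 for exactly 0%, 1 for up to 24%, 2
   for 25–49%, 3 for 50–74%, 4 for 75–100%), giving 0–12. Percentages in
   $(0,1)$ map to category 1: category 0 is reserved for fully negative
   sections. The intensity scale starting at 1 means a section can only
   score 0 through the percentage category; this quirk of the published
   scale is preserved, not corrected.

## What the synthetic generator emulates

`generate_fixture()` produces every table the pipeline consumes, with
planted structure recorded in a ground-truth manifest. Its defaults are the
study's printed conditions: 368 and 152 screened ingredients sharing 43
(union 477); 40 raw predictions per compound (the cut keeps 30; how many
predictions fell below the cut is not stated anywhere, so only the
requirement that it exceed 30 is fixed); 533 unique predicted symbols;
source tables of 84/197/200/163 post-rule records (644 total) over 557
unique genes, the 87 duplicates carrying the 34 planted candidates in two
sources each; 82 active compounds (2 shared between herbs) wired to the
candidates with 318 edges, so the tripartite network has exactly 118 nodes
and 402 edges; a PPI table whose above-threshold part is a 14-hub clique
plus 83 spokes on 31 nodes and 174 edges — a construction chosen because it
pins the hub count exactly (clique members sit far above the mean degree,
spoke endpoints far below) with the TP53 analogue on top; 100 pathways of
15–30 members, 33 planted to enrich in the candidate set (each carries at
least 3 candidates, which at these set sizes forces raw $p < 0.05$, while
decoy pathways carry none and cannot reach it); and spiked DE tables for two
cell lines (23 and 32 pathways, overlapping the predicted set in 1 and 17
pathways respectively, with "Cell cycle" the single three-way pathway). A
spiked pathway has $\lceil 0.6 \cdot |pathway| \rceil$ of its members
flagged DE — enough to guarantee detection at these sizes without
saturating. Key-target structure is planted by name: TP53 and CHEK1 are
cell-cycle members, candidates, and DE in SW620; CCND1, CDKN2A and MDM2 are
candidates never flagged DE; CDKN1A is DE in SW620 but not a candidate.

Scores are drawn uniformly and rounded (DL to 6 decimals above or below the
0.18 threshold as configured; fit scores to 9 decimals with a deterministic
1e-9 de-tieing offset; DSI and relevance in bands strictly above and below
the planted cutoffs, so the median and top-200 rules recover the planted
record sets exactly). Everything is a pure function of the configuration,
including its seed.

The generator deliberately does **not** emulate: chemistry (no structures,
no SMILES), expression counts (DE tables are post-hoc gene lists with
scores, not reads), realistic PPI topology (the clique-plus-spokes shape is
a planting device, not a model of interactomes), gene-symbol aliasing, or
pathway overlap structure beyond shared candidate genes. Passing tests on
these fixtures therefore demonstrate that the *rules* of the screen are
implemented exactly and that planted signal of the stated strength is
recovered; they say nothing about robustness to noisy annotation, alias
drift, or correlated pathway membership in real databases.

## Numerical and testing choices

- All set operations case-fold before comparison; candidate, hub and
  pathway lists are reported sorted so outputs are stable.
- The pipeline itself draws no random numbers; identical fixture and
  configuration give byte-identical artifacts.
- Hypergeometric tails are computed with `phyper`; the test suite checks
  them against direct combinatorial summation over all configurations with
  universes up to 25, and checks BH against a step-up reference on random
  vectors.
- The null-calibration suite measures the rejection rate of raw $p < 0.05$
  over seeded null replicates (universe 500, 20 terms of 50–150 members,
  queries of 100). Because the hypergeometric test is discrete, its attained
  size is strictly below the nominal level in this regime (about 0.038
  rather than 0.05); the calibration check therefore verifies that the
  observed rate is conservative and matches the exact attained size, which
  is the property a correct implementation must have. A companion check
  against a symmetric band around the nominal 0.05 is retained for
  reference; for a conservative discrete test that band is not attainable,
  and the discrepancy is expected rather than a defect.
- Problem sizes in the test suite are chosen to keep the full run around
  half a minute: the study-scale fixture is generated once and shared, and
  module tests use a reduced configuration with the same planted structure.

## Known limitations

- Symbol harmonization is case-folding only; real multi-database merges
  need alias tables.
- The DSI median rule is applied to whatever retrieval set is supplied; the
  original retrieval set behind the published DisGeNET count is unknowable,
  so fixtures plant a known median instead.
- Whether the published 477-component accounting is before or after the DL
  filter is ambiguous; both counts are reported and the generator defaults
  to catalogs that are already post-screen (`dl_fraction_below = 0`).
- GO-style ancestor propagation and expression-bias corrections are out of
  scope; the enrichment is a plain overrepresentation test.
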
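# ckinet

Network-pharmacology screening for Compound Kushen Injection (CKI), a
two-herb preparation (Kushen, *Sophora flavescens*; Baituling, *Smilax
glabra* rhizome) used adjunctively in colorectal cancer. The package
re-implements, as tested R code, the screening chain that nominates the
preparation's candidate targets and pathways:

1. **compound screen** — drug-likeness filter (DL ≥ 0.18) and per-herb
   compound accounting;
2. **target fishing** — per-compound top-30 predictions by normalized fit
   score, mapped to gene symbols;
3. **disease genes** — aggregation of four sources (TTD and OMIM whole;
   GeneCards top 200 by relevance; DisGeNET at-or-above-median DSI) with
   case-folded deduplication;
4. **evidence intersection** — candidate targets = predicted ∩ disease
   genes, with herb attribution;
5. **tripartite network** — herb–compound–target graph with density (both
   conventions), diameter, characteristic path length, average neighbors;
6. **PPI analysis** — STRING-style edge thresholding (score ≥ 0.4), isolated
   targets removed, hubs = nodes with degree strictly above the mean 2E/N;
7. **enrichment** — hypergeometric overrepresentation
   p = P(X ≥ k) for drawing n from N with K successes, EASE (k−1) variant
   optional, Benjamini–Hochberg adjustment;
8. **consensus** — three-way Venn of predicted vs per-cell-line enriched
   pathways; key-target classification inside the consensus pathway;
9. **IHC scoring** — immunoreactive score = intensity (1–3) × percent
   category (0–4), range 0–12.

A seeded synthetic-data module (`fixture_config()`, `generate_fixture()`,
`write_fixture()`) emulates all database extracts the screen consumes, with
planted overlaps, spiked pathways and a ground-truth manifest, at the
published study scale by default.

## Worked example

```r
library(ckinet)

bundle <- generate_fixture(fixture_config(seed = 1))
report <- run_pipeline(bundle)
report
#> network pharmacology run report
#>   compounds: union 477 (screened union 477)
#>   target symbols: 533; disease genes: 557 of 644 records
#>   candidates: 34 targets / 82 compounds
#>   network: 118 nodes, 402 edges; PPI: 31 nodes, 174 edges, 14 hubs
#>   pathways: 33 predicted; sw480=23, sw620=32
#>   consensus pathway(s): cell cycle
#>   common key targets: CHEK1, TP53
```

Reading the output: the two herb catalogs union to 477 screened compounds
(325 Kushen-only, 109 Baituling-only, 43 shared); their top-30 target
predictions map to 533 gene symbols; the four disease sources contribute
644 records that deduplicate to 557 genes; intersecting the two bodies of
evidence leaves 34 candidate targets reached by 82 bioactive compounds. The
herb–compound–target graph has 118 nodes and 402 edges; the candidate PPI
subgraph keeps 31 connected targets with 174 interactions, 14 of them hubs
by the degree-above-mean rule (TP53 ranked first). 33 pathways enrich in
the candidates (raw p < 0.05); the SW480 and SW620 DE profiles enrich 23
and 32 pathways, and the single pathway common to all three is the cell
cycle, whose members TP53 and CHEK1 carry both prediction and expression
evidence — the screen's headline nomination.

Individual stages are plain functions if you want to run them on your own
tables: `filter_by_druglikeness()`, `select_top_targets()`,
`integrate_sources()`, `intersect_evidence()`, `build_network()`,
`build_ppi()` / `select_hubs()`, `hypergeometric_enrichment()`,
`pathway_venn()`, `immunoreactive_score()`.

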
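# ppintegrate

Integration and quality assessment of protein–protein interaction (PPI)
evidence.

Public human PPI catalogues disagree: curated physical-interaction databases
are small and precise, prediction-heavy resources are huge and noisy.
`ppintegrate` is for systems biologists who need to merge such sources into
one scored interactome *and* audit the result. It implements:

* **Confidence scoring** — each evidence platform carries a reliability
  index `S_i ∈ [0,1]`; per interaction the platform scores combine by
  noisy-OR, `P_new = 1 − Π(1 − S_i)`, fuse with a previous release's score
  by `P = 1 − (1 − P_prev)(1 − P_new)`, and map onto five star tiers
  (1★ `P < 0.25` … 5★ `P ≥ 0.90`).
* **Integration accounting** — union merge with provenance, pairwise
  coverage-overlap ratios `r_ij = O_ij / N_i`, gold-standard q-score.
* **Quality evaluation** — repeated-sampling gold-standard enrichment (MPE)
  with normalized sample sizes, false-positive ratio `E = O/N` against a
  curated negative set, rank-based AUC, Lin/best-match-average GO semantic
  similarity per star tier with Welch tests against random pairs,
  hypergeometric + Benjamini–Hochberg term enrichment for the
  absent-protein / missing-overlap / hub bias sets.
* **Network statistics** — largest component, log–log degree fit, SNAP-style
  interpolated effective diameter, Spearman hub-rank correlation
  `ρ = 1 − 6Σd_i²/(n(n²−1))`.
* **Rediscovery benchmark** — hide half of a curated gene set, expand the
  rest one step through the network, score sensitivity `|H∩G|/|H|` and the
  density-normalized rediscovery factor `α = |H∩G|/|G| × f`.
* **Synthetic generators** — seeded scale-free truth networks, overlapping
  noisy sources, gold/negative sets, toy ontologies and gene sets, so the
  whole pipeline runs and is tested without downloads.

See `vignettes/interactome-integration.Rmd` for the model details, design
choices and limitations.

## Worked example

Score a synthetic five-source study system and audit it:

```r
library(ppintegrate)

cfg     <- synth_config(seed = 11)          # 500 proteins, 2000 truth edges
truth   <- synth_truth_network(cfg)
sources <- synth_sources(truth, cfg)        # 5 sources, curated -> text-mined
scored  <- score_database(sources)
scored
#> <scored_interactions> 3962 interactions; star tiers: 1*:1366 2*:784 3*:768 4*:455 5*:589
#>             key      a      b p_prev  p_new p_final star                            sources
#> 1 P00001|P00002 P00001 P00002      0 0.9916  0.9916    5 apms;coexpr;curated_a;textmine;y2h
#> 2 P00001|P00008 P00001 P00008      0 0.4400  0.4400    2                    coexpr;textmine
#> ...
```

A pair reported by all five platforms reaches `P = 0.9916` (5★); a pair seen
only by co-expression and text mining stays at `0.44` (2★). Now the audit:

```r
gold      <- synth_gold(truth, cfg)         # 400 embedded gold pairs
negatives <- synth_negatives(truth, cfg)    # 400 non-edges

score_auc(scored, gold, negatives)
#> [1] 0.8719512
false_positive_ratio(scored$key, negatives)
#> <false_positive_report> O = 8, N = 3962, E = 0.002019
mpe_distribution(scored$key, gold, sample_size = 500, n_samples = 500,
                 seed = 12)
#> <mpe_distribution> 500 samples of 500 pairs: mean overlap 46.65 (sd 6.02),
#>   hypergeometric expectation 46.57

ns <- network_summary(scored = scored, min_star = 3)
ns$effective_diameter
#> [1] 3.815765
ns$degree_fit
#> <degree_fit> slope -1.388, intercept 2.353, R^2 0.682
```

Reading the numbers: the scores separate embedded gold pairs from known
non-edges (AUC 0.87); only 8 of 3,962 integrated pairs hit the negative set
(E ≈ 0.002); the MPE sample mean (46.65) sits on its hypergeometric
expectation (46.57), i.e. the gold content of random slices behaves as the
embedded fraction predicts; and the medium-and-above subnetwork is compact
(90% of shortest paths ≤ 3.8 hops) with a heavy-tailed degree distribution
(log–log slope −1.4).

## Command line

A thin wrapper (`exec/ppint`) exposes the same pipeline:

```sh
ppint synth      --outdir fixtures --seed 1
ppint score      --sources fixtures/curated_a.tsv,fixtures/apms.tsv,fixtures/y2h.tsv \
                 --mapping fixtures/mapping.tsv --out scored.tsv
ppint eval       --mode mpe --db scored.tsv --gold fixtures/gold.tsv \
                 --mapping fixtures/mapping.tsv --seed 1 --out mpe.json
ppint netstats   --db scored.tsv --min-star 3 --out netstats.json
ppint rediscover --gene-sets fixtures/gene_sets.gmt --dbs truth=fixtures/truth.tsv \
                 --reference truth --mapping fixtures/mapping.tsv --out redisc.json
```

Every run writes a `.manifest.json` with parameters, seed, input digests and
package version.

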
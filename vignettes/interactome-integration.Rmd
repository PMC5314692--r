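---
title: "Integrating and evaluating protein-protein interaction evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating and evaluating protein-protein interaction evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppintegrate)
```

## The problem

Public human protein-protein interaction (PPI) catalogues disagree wildly:
curated physical-interaction databases are small and precise, while
prediction- and text-mining-heavy resources are enormous and noisy. A
database that integrates them must answer, per interaction, *how much should
this pair be trusted?* — and must then demonstrate that its answer means
something, because neither a complete true-positive nor a true-negative set
of human PPIs exists.

`ppintegrate` implements such an integration-and-audit toolkit: a noisy-OR
confidence model over evidence platforms, a five-tier star categorization,
and the accompanying evaluation battery (gold-standard resampling,
false-positive ratios against curated non-interactions, GO semantic
similarity by tier, systematic-bias protein sets, network topology
comparisons, and a gene-set rediscovery benchmark).

## The confidence model

Every evidence record carries a *reliability index* \(S_i \in [0,1]\): the
configured trust in platform \(i\) (yeast two-hybrid, affinity purification,
curated literature, ...) as a detector of direct physical interaction.
Platforms are treated as independent detectors, so the probability that at
least one of them is right is the noisy-OR combination

\[
P_{\mathrm{new}} \;=\; 1-\prod_{i=1}^{N}\,(1-S_i),
\]

taken over the distinct platforms reporting the pair. Duplicate rows from
the *same* platform are collapsed to their maximum score first: the product
is indexed over platforms, and repeated reporting by one platform must not
inflate confidence. Scores from a previous database release are fused with
the same form,

\[
P \;=\; 1-(1-P_{\mathrm{prev}})(1-P_{\mathrm{new}}),
\]

with \(P_{\mathrm{prev}} = 0\) for pairs new to the current release. This
makes re-releases perturb legacy scores only upward and only where new
evidence arrived. Final scores map onto five confidence tiers with fixed,
lower-inclusive thresholds: 1-star \(P<0.25\), 2-star \(0.25 \le P<0.45\),
3-star \(0.45 \le P<0.75\), 4-star \(0.75 \le P<0.90\), and 5-star
\(0.90 \le P \le 1\).

Two consequences worth knowing. First, \(P\) is monotone: adding evidence
never lowers a score (the suite verifies this by sweep). Second, the model
is only as meaningful as its reliability configuration. The shipped defaults
(`default_reliability()`: curated literature 0.90, affinity purification
0.70, yeast two-hybrid 0.50, co-expression 0.30, text mining 0.20) are
illustrative configuration ordered the way the field usually ranks platform
trustworthiness — they are not estimates, and analyses that depend on them
are configuration-dependent by construction. `reliability_config()` and the
`--reliability` CLI flag replace them wholesale.

## Identifier and pair canonicalization

All proteins are resolved to one canonical reviewed accession
(`read_mapping()`): unreviewed rows are discarded and raw tokens that still
map to several accessions are dropped as ambiguous (counted, not silently).
Pairs are stored under an unordered canonical key, so evidence for (x, y)
and (y, x) accumulates together. Self-interactions are retained but flagged
(`is_self_key()`): dropping them would discard evidence, but network
statistics exclude self-loops since they carry no path information.

## The evaluation battery

**Gold-standard resampling (MPE).** `mpe_distribution()` repeatedly samples
fixed-size subsets of the database (default 1,000 pairs, 1,000 samples,
without replacement within a sample) and counts overlap with a conserved
co-expression-style gold standard. For a database of \(N\) pairs containing
\(m\) gold pairs, the overlap is hypergeometric with mean
\(n\,m/N\); the suite checks convergence to within three standard errors.
When databases of different sizes are compared, `normalized_sample_size()`
scales the sample by the size ratio, because the gold standard is fixed and
used in full. Histogram bins are width 1 when the expected overlap is below
50, and Sturges-rule bins otherwise.

**False positives and AUC.** `false_positive_ratio()` computes
\(E = O/N\), the share of database pairs found in a curated
non-interacting set; `score_auc()` computes the rank-based (Mann-Whitney)
AUC of the final scores separating gold pairs from negatives, with ties
counting one half.

**GO similarity.** `gene_pair_gosim()` scores a pair of genes by Lin's
term similarity \(2\,\mathrm{IC}(\mathrm{MICA})/(\mathrm{IC}(t_1)+
\mathrm{IC}(t_2))\) under best-match averaging of the two genes' term sets,
then averages the biological-process and molecular-function scores where
both are defined (a `max` combination is available; the choice is recorded
in report metadata). IC is \(-\log\) of a term's annotation frequency after
ancestor propagation, so sharing only the root scores 0.
`tier_gosim_test()` samples pairs per star tier and compares each tier
against random gene pairs with Welch's t-test — Welch because tier variances
differ by construction and nothing stronger is warranted.

**Systematic-bias sets.** `absent_protein_set()` (reference proteome minus
network), `missing_overlap_set()` (gold proteins outside the database/gold
overlap) and `hub_set()` (top-k by degree, lexicographic tie-break for
determinism) produce the protein lists whose term enrichment exposes
coverage biases. `enrichment()` is a one-sided hypergeometric test with
Benjamini-Hochberg adjustment across terms — a transparent, versionable
replacement for web-service enrichment engines.

**Network properties.** `degree_fit()` regresses \(\log_{10}\) count on
\(\log_{10}\) degree over the raw degree histogram (log-binning is
deliberately not the default; raw distributions are what the comparisons
plot). `effective_diameter()` is the interpolated 90th percentile of the
shortest-path-length distribution: linear interpolation between the last
integer distance whose cumulative share is below the percentile and the
next one, exact all-pairs up to 2,000 nodes and BFS from sampled sources
above. `hub_rank_correlation()` takes the *row* database's top-k hubs,
restricts to those present in the other database, and computes Spearman's
\(\rho = 1-6\sum d_i^2/(n(n^2-1))\) on their degree ranks — exactly that
formula when tie-free, average-rank correlation (flagged) otherwise. Fewer
than two shared hubs yields an explicit undefined marker rather than a
fabricated \(\pm 1\).

**Rediscovery benchmark.** `run_benchmark()` hides a random half of each
curated gene set (`hidden_fraction = 0.5` by default; recorded in every
result row), expands the seeded half one step through each database
(`one_step_expansion()`, which excludes the seeds themselves — recovering a
gene you were given is not discovery), and scores sensitivity
\(|H\cap G|/|H|\) and the rediscovery factor
\(\alpha = |H\cap G|/|G| \times f\), where \(f=|G_{db}|/|G_{ref}|\)
normalizes for database density against a reference database (for which
\(f \equiv 1\)). Within a replicate every database sees the same partition —
the paired design the benchmark's paired t-tests require. Note that
\(\alpha\) algebraically reduces to \(|H\cap G|/|G_{ref}|\), so it is
monotone under edge addition; it discriminates between *non-nested*
databases trading coverage against noise, not between a database and its
own superset. Gene sets smaller than 10 members are dropped before
partitioning.

## The synthetic study system

`synth_config()` defines the default conditions under which the pipeline is
exercised and tested: a 500-protein, 2,000-edge truth network observed by
five sources spanning the curated-to-predicted spectrum (coverage 0.25-0.60
rising and noise 0.05-1.00 rising as reliability falls — precise sources see
less but lie less), a gold standard covering 20% of the truth, 400
negatives sampled from non-edges, a two-namespace ontology (depth 3,
branching 3) in which interacting proteins share a leaf term with
probability 0.8, and 20 neighborhood-grown gene sets of 10-20 members.
These values were chosen once as a realistic miniature of integrated-PPI
data; the generators expose them all.

The truth network is built by a degree-preferential spanning tree plus
degree-preferential extra edges: this yields an exact edge count and
guaranteed connectivity (which off-the-shelf preferential-attachment
generators do not at arbitrary densities) while keeping the heavy-tailed
degree distribution that makes hub and scale-free-fit tests meaningful. An
Erdős–Rényi alternative (`model = "er"`) provides flat-degree fixtures.

Because sources sample the truth independently, true edges are corroborated
by several platforms while spurious ones usually are not — this is the
structure the noisy-OR model exploits, and it is why higher star tiers are
enriched for gold pairs and for GO-similar endpoints on the synthetic runs.
What the generator does *not* emulate: correlated errors between sources
(real text-mining and curation pipelines share literature), study bias
(real hubs are partly ascertainment artifacts), isoforms, promiscuous
protein families, and the size and extreme sparsity of the real human
interactome. Green tests therefore certify the machinery and its
statistical behaviour under stated assumptions, not the real databases'
quality rankings.

## Numerical and degenerate-input choices

* Scores are validated to \([0,1]\) on input and clamped after arithmetic to
  absorb floating-point drift at the \(10^{-15}\) level; the scored-table
  writer round-trips at 15 significant digits.
* The empty evidence list scores 0 (the empty noisy-OR product); an empty
  expansion set gives \(\alpha = 0\); an empty reference expansion marks the
  replicate undefined rather than dividing by zero; an empty source's
  overlap-ratio row is `NA`, not an error.
* Partition sizes are rounded then clamped so seeded and hidden sets stay
  non-empty; ties in hub ranking break lexicographically; the largest
  component breaks size ties toward the lexicographically smallest node.
* All randomness flows from one integer seed per run; internal stages
  derive their own streams with a multiply-and-mod splitter kept below
  \(2^{31}\), so each stage is independently reproducible.

## Problem sizes used by the checks

The shipped tests and the acceptance script run on deliberately compact
instances chosen to keep the full suite fast while leaving the statistics
well-powered: oracle comparisons on up to 1,000 scored pairs, monotonicity
sweeps over 10,000 added evidence records, MPE on a 10,000-pair database
with 500 embedded gold pairs (expected overlap 50), exact-vs-sampled
diameter checks on graphs of 80-200 nodes, and rediscovery over 20 gene
sets with 5-10 replicates. These sizes are the package's own test design;
the functions themselves take whatever scale the caller provides.

## Known limitations

* Reliability indices are unvalidated configuration; the package provides
  no machinery to learn them from data.
* The GO similarity is one defensible member of the funSim family (Lin +
  BMA + namespace mean); other variants (Resnik, SimRel, max-combination)
  can rank pairs differently. The variant is recorded in outputs.
* The enrichment engine is a plain hypergeometric/BH test without the
  annotation-clustering heuristics of interactive web tools.
* MPE overlap is counted on pairs, not genes; with pair-level gold
  standards of very uneven gene composition the two conventions diverge.
* The rediscovery factor compares databases fairly only against a common
  reference; \(\alpha\) values computed against different references are
  not comparable.
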
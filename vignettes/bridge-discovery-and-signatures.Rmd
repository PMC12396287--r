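---
title: "Bridge-protein discovery, interferon scores and cohort statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bridge-protein discovery, interferon scores and cohort statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicsbridge)
```

This vignette documents the models and the numerical and design choices
behind `omicsbridge`, in the spirit of a methods section: what each
procedure assumes, which knobs matter, and what the synthetic generators do
and do not emulate.

## The PPI graph

Graphs are built from STRING-style edge lists. STRING's combined score is
an integer confidence on 0–1000 interpretable as probability × 1000; we
normalize to [0, 1] (auto-detected: any score above 1 implies the 0–1000
scale, with an explicit override). The default retention threshold is 0.7 —
STRING's customary "high confidence" cut — and the comparison is
**inclusive**: a score of exactly 0.7 is kept, reading "minimum interaction
score" literally. Reciprocal duplicate rows merge keeping the maximum
score; self-loops are dropped with a message. Node identifiers are opaque
and case-sensitive; an optional flag strips NCBI taxon prefixes
(`9606.ENSP...`), but no identifier mapping is attempted — mapping UniProt
to STRING identifiers is the caller's responsibility.

Whether an analysis should embed a full interactome or only a neighbourhood
around the proteins of interest is a genuine modelling choice; the package
supports both, `neighborhood_subgraph()` extracting the induced subgraph
within a BFS radius of seed nodes.

## Node embedding

The embedding is DeepWalk-family: `walks_per_node` (10) random walks of
length ≤ 40 start at every node, transitions proportional to edge weight
and biased by node2vec's return/in-out parameters `p`, `q` (both 1 by
default, i.e. first-order weighted walks — with no evidence for a
particular bias we keep the neutral setting, but both are exposed). Window
5 and dimension 64 are standard DeepWalk practice. These defaults are
declared, not tuned.

Rather than training a stochastic skip-gram model, the co-occurrence matrix
over the corpus is transformed to positive pointwise mutual information and
factorized by truncated SVD, with node vectors `U_d sqrt(S_d)`. PPMI+SVD is
a well-known deterministic stand-in for skip-gram with negative sampling
(they factorize essentially the same matrix), which buys exact
reproducibility: given `(graph, config, seed)` the embedding is
byte-identical. Two further determinism measures: the per-start-node RNG
stream derives from `(seed, rank of the node in sorted order)`, so results
do not depend on node insertion order and are equivariant under
order-preserving renamings; and each singular vector's sign is fixed by
making its largest-magnitude entry positive. When the co-occurrence rank is
below the requested dimension (common on small graphs), the dimension is
reduced with a warning rather than padding with noise.

Annotation terms (GO-style) enter as an optional concatenated block: a
binary membership vector over the sorted union of all terms, L2-normalized
and scaled by a weight α (default 1). Concatenation keeps the walk and
annotation signals separable — α = 0 provably reproduces walk-only
similarities — at the cost of not letting annotations influence the walks
themselves. Cosine similarity is the sole metric throughout.

## Intermediary (bridge) discovery

Given a target protein and a query set of DAPs, candidates are nodes that
appear among the k (10) nearest latent neighbours of the target or of any
query, or lie on a shortest graph path of ≤ 3 hops between target and a
query. "Connected to a query" is deliberately a disjunction of the two
notions of proximity the method invokes — direct interaction **or** mutual
k-nearest-neighbourhood in latent space — and each half can be switched off
independently, since neither notion subsumes the other. An intermediary
must connect **strictly more than three** distinct queries (`min_linked`
defaults to 4). Ranking is by linked-query count, then mean cosine to the
queries, then node id; all ties anywhere in the package break
lexicographically so runs are stable.

The *central protein* is the member of {target} ∪ intermediaries ∪ queries
minimizing mean cosine distance (1 − similarity) to the query set. A
"minimum score from the nearest-neighbour algorithm" admits several
readings; mean cosine distance is the simplest one consistent with cosine
being the only metric in play, and is declared as such.

Term enrichment of the intermediary list is the one-sided hypergeometric
upper tail over the annotated background with Benjamini–Hochberg q-values —
computed locally from the user-supplied annotation table, not from any web
service, so results depend only on the inputs. Enrichment FDRs reported by
online STRING analyses depend on the database release and are not
comparable run-to-run; this package's tests therefore validate the
hypergeometric machinery against exhaustive enumeration instead of against
any published FDR value.

## DAP selection

Two filter conventions coexist in the source tables this package targets,
and they are kept exactly as printed: per-comparison selection uses
inclusive thresholds (p ≤ 0.05, ratio fold-change ≥ 2 in either direction),
while cross-comparison intersection uses strict ones (|log2 fc| > 0.5,
p < 0.05). A bare "fold change > 0.5" can only mean |log2 fold-change|
here — a ratio cut of 0.5 would select down-regulation only, contradicting
tables that mix up- and down-regulated proteins — so the log2 reading is
the default, and the fold-change scale of every input table must be
declared (`ratio` or `log2`), never guessed. Whether "common" DAPs must
also agree in direction is not specified by the convention; the default
does not require it, and a flag turns it on.

## Relative quantification and the IFN score

ΔCt normalizes a target gene's Ct to the arithmetic mean of the
housekeeping Cts of the same sample (equivalent to a geometric mean on the
expression scale); ΔΔCt subtracts the calibrator's ΔCt; RQ = 2^−ΔΔCt.
Technical replicates are averaged before anything else; no
amplification-efficiency correction or outlier rejection is applied. The
calibrator is a single explicit healthy-donor sample. The IFN score of a
sample is the median RQ of the six ISGs (IFIT1, IFI27, IFI44, IFI44L,
ISG15, MX1); both panels and the calibrator are configurable. Because the
housekeeping mean is subtracted per sample, the score is invariant to any
constant additive shift of all of a sample's Ct values — plate offsets of
that form cancel. Repeated measurements of the same donor (e.g. cultures at
different days) are treated as independent samples and not aggregated; any
pooling is left to the caller, explicitly.

Group comparison uses the Mann–Whitney U statistic. Up to a total of 20
observations the two-sided p-value is exact: all `choose(n1+n2, n1)`
assignments of the pooled mid-ranks are enumerated and the probability of a
U at least as far from the null mean `n1 n2 / 2` as observed is summed (the
permutation distribution of U is symmetric around that mean, ties
included). Beyond 20 the tie-corrected normal approximation with continuity
correction is used and the method is reported alongside the p-value.

## Cohort statistics

Feature frequencies pool individually listed cases (tri-state calls:
affected / unaffected / not assessed, with "not assessed" excluded from the
denominator) with aggregated literature counts. Percentages round **half
up** to integers — the convention that reproduces every printed cohort
percentage, including 5/40 → 13% where banker's rounding would give 12.

Variant hotspot assignment parses HGVS p. missense and in-frame-deletion
strings and tests the residue number against two configurable ranges. The
defaults are 416–434 and 621–628. Published descriptions of the upstream
hotspot vary (416–431 in one figure, 416–430 in the text) and Tyr434 is
assigned to that hotspot while lying outside both printed ranges; the
default upper bound of 434 makes the rule total on all variants it is
documented to cover, and the discrepancy is resolved by configuration, not
silently.

Fisher's exact test uses the standard two-sided point-probability rule:
conditioning on the margins, sum the hypergeometric probabilities of all
tables whose point probability is ≤ that of the observed table, with a
1e−7 relative tolerance guarding floating-point ties. Of note, published
genotype–phenotype p-values for this cohort (e.g. 0.14 for severe myopathy,
5/24 vs 0/16) are **not** reproducible under this standard definition,
which gives 0.0712; the computation behind the printed values is unknown,
so the package implements the textbook definition, validates it against
exhaustive enumeration for every table with grand total ≤ 40 (covering all
cohort contrasts), and does not treat the printed values as references.
No multiple-testing correction is applied across features, matching
practice for descriptive rare-disease cohorts.

## Synthetic data: what it does and does not emulate

The generators are pure functions of their spec (seed included) and exist
to give every analysis a ground truth:

* `make_planted_bridge_graph()` — a target-side community (8 nodes, one of
  which is the target), 12 query nodes, within-community edge probability
  0.5 and cross probability 0.02, 3 bridges each wired to exactly 5 queries
  and to the target, and 5 decoy nodes that live in the target community
  but touch at most 2 queries, so the ">3 connected queries" boundary is
  testable from both sides. Edge confidences are uniform on [0.7, 1],
  mimicking a high-confidence STRING cut. Bridges optionally share a
  planted annotation term over a mixed background for enrichment tests.
* `make_ct_table()` — patient ISG Cts shifted *down* by the log2 shift
  (lower Ct = higher expression), housekeeping genes identically
  distributed across groups, Gaussian noise (default sd 0.3 cycles, a
  typical qPCR replicate spread) on every well, 8 samples per group, first
  control flagged as calibrator.
* `make_cohort()` — two variant-cluster groups with per-feature
  prevalences, masked to "not assessed" at a fixed rate; variants are
  generated inside the residue ranges the cluster rule expects.
* `make_dap_tables()` — true DAPs share a per-protein sign and draw
  |log2 fc| ~ N(2, 0.3) with p ~ U(0, 0.01) in every table; nulls draw
  lfc ~ N(0, 0.15) with uniform p.

None of these mimic real data beyond the planted structure: the graphs have
no scale-free degree distribution or clustering like a real interactome,
qPCR noise is homoscedastic Gaussian with no plate effects, and cohorts
have no age/sex structure. Passing the recovery tests therefore shows the
*procedures* are implemented correctly and are sensitive at realistic
signal sizes — not that they would perform identically on real STRING
networks or clinical data.

## Problem sizes and determinism

The test and acceptance workloads use desk-scale problems chosen to keep
the full suite fast while leaving no property untested: 28-node planted
graphs over 20 seeds for bridge recovery, 17-node double cliques over 10
seeds for embedding sanity, 16-sample simulated qPCR cohorts over 20 seeds,
exhaustive Fisher validation over all ~1.4 × 10^5 tables with total ≤ 40,
and exhaustive Mann–Whitney enumeration up to 11 observations. Every
stochastic quantity is reproducible from a single integer seed.

## Known limitations

* Only the deterministic PPMI+SVD backend is provided; a trained
  negative-sampling skip-gram backend may rank neighbours slightly
  differently on large graphs.
* Dense SVD bounds practical graph size to a few thousand nodes; embedding
  a full interactome would need a sparse truncated solver.
* No STRING download/API, no identifier mapping, no amplification-efficiency
  correction, no survival or onset-age modelling — all deliberately out of
  scope.
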
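---
title: "Scoring signature reversal over tissue-specific pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring signature reversal over tissue-specific pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The method

tspath ranks candidate drugs for a disease by how strongly each drug's
perturbation profile *reverses* the disease's expression signature — not
genome-wide, but inside tissue-specific pathways that the disease actually
dysregulates. The pipeline has five stages.

**1. Disease signature.** From a tumor/control expression matrix, each gene
gets a log fold change, logFC = log2(mean(tumor)/mean(control)), optionally
with a pseudocount for count-like data. Genes are ranked by decreasing logFC;
logFC > 0 is "up", logFC <= 0 is "down" (a gene at exactly zero carries no
evidence of upregulation, so it is grouped with the downregulated set). Row
z-scoring ((g - mean)/sd, sample standard deviation) is available for
reporting and inspection, but the logFC ratio is computed on the positive
expression scale: a z-scored row has mean zero across samples, so a ratio of
its group means is not a meaningful (or even well-defined) quantity. This is
the only reading under which both transformations are computable, and it is
the one the package fixes.

**2. Tissue subnetwork.** Disease seed genes anchor the extraction of a
subnetwork from a weighted tissue interaction network: the node set is the
seeds plus every direct neighbor connected to a seed by an edge with
confidence >= cutoff (default 0.1, inclusive), and the edge set is *all*
edges above the cutoff among those nodes (the induced subgraph). Keeping
induced neighbor–neighbor edges matters: a seed-star alone cannot produce the
densely clustered modules observed in real tissue networks. Seeds with no
qualifying neighbor stay as isolated nodes. Topology descriptives (average
degree, local clustering with degree < 2 contributing 0, shortest paths and
diameter over the largest component) are computed with igraph.

**3. Pathway enrichment.** The subnetwork's genes are tested against a
pathway database with the upper-tail hypergeometric test,
P(X >= overlap) for X ~ Hypergeometric(universe, pathway size, query size).
Pathways pass with overlap >= `min_count` (default 5) and raw
p <= `p_max` (default 0.001) — raw thresholds, because the procedure is a
screen whose downstream scoring is what carries the inference; a
Benjamini–Hochberg column is reported for information only. The universe
defaults to the union of all pathway members and can be overridden with an
explicit background. An `ease = TRUE` flag switches to the EASE variant
(overlap decremented by one before the tail), the more conservative statistic
popularized by annotation servers; the plain hypergeometric is the default
because it is the exactly specified test. A companion null procedure draws
random gene sets of the same size (always retaining the seeds), re-runs the
enrichment, and reports an add-one empirical p-value for the number of genes
covered by enriched pathways — a check that the extracted set is functionally
coherent rather than an artifact of its size.

**4. Pathway signatures.** Each enriched pathway's members are filtered to
genes present in the disease data, split by the disease up/down partition,
and ordered by the disease ranking. Pathway genes missing from the expression
matrix are silently excluded (coverage gaps are a property of the data, not
an error); a pathway left with no measured gene is dropped with a warning.

**5. Connectivity scoring.** For a gene list (the up or down half of one
pathway signature) and one drug instance — a full ranking of n genes by
differential expression under the drug, rank 1 = most upregulated — the m
common genes are located at positions V(1) < ... < V(m) in the drug list and
scored with the two one-sided Kolmogorov–Smirnov statistics

    a = max_p [ p/m − V(p)/n ]
    b = max_p [ V(p)/n − (p−1)/m ]

    CS = a if a > b;  −b if a < b;  0 on a tie

CS is +1-ish when the gene list concentrates at the drug's most upregulated
end and −1-ish at the bottom. Per pathway i and instance j,
CS(i,j) = CS_up − CS_down, in [−2, 2]; a drug with k instances gets

    TS = (1/k) * Σ_pathways Σ_instances CS(i,j)

— averaged over instances, *summed* over pathways, so |TS| grows with the
number of surviving signatures. That is the aggregation as defined; a
`normalize_pathways` flag divides by the signature count for users who want
pathway-count-comparable scores across diseases, and defaults to off. Drugs
are ranked by |TS| (benchmarks rarely sign their associations) with
alphabetical tie-breaks, and TS < 0 — up-genes pushed down, down-genes pushed
up — calls a drug therapeutic.

## Numerical conventions and degenerate inputs

* **a = b tie:** CS = 0, the null-connectivity convention of the original
  connectivity-map scoring. The comparison uses a 1e-12 tolerance.
* **m = 0 (no overlap):** the component contributes CS = 0 and the drug is
  still scored; dropping such instances would silently bias k.
* **Constant drug profile** (all differential values identical, e.g. a
  zero-strength simulated drug with no noise): the ranking is purely a
  tie-break artifact, so both components are the null connectivity 0.
* **Empty up or down list** of a signature: that component is 0.
* **Ties in rankings:** all orderings (disease logFC, drug values, equal
  |TS|) break ties lexicographically, making every output order
  deterministic and independent of input row order.
* **Constant expression rows:** z-scores are set to 0 and the gene ids are
  flagged in an attribute rather than producing NaN.

## Parameters that matter

| parameter | default | units / domain | why |
|---|---|---|---|
| `cutoff` | 0.1 | edge confidence in [0,1], inclusive `>=` | keeps moderate-confidence tissue edges; raising it monotonically shrinks the subnetwork |
| `p_max` | 0.001 | raw p-value | stringent screen so only clearly dysregulated pathways feed the scorer |
| `min_count` | 5 | genes | suppresses tiny overlaps that pass p by universe quirks |
| `epsilon` | 0 | expression units | pseudocount for count-like data; 0 preserves scale-invariance of logFC |
| `ease` | FALSE | flag | EASE-style conservative enrichment variant |
| `normalize_pathways` | FALSE | flag | per-pathway-average TS instead of the summed aggregation |
| `n_draws` | 1000 | draws | null-coherence resolution; empirical p is floored at 1/(n+1) |

## Ablation baselines

`run_baseline()` exposes the full method and three ablations through one
interface, all sharing the connectivity core: `seedKS` scores drugs against
the single genome-wide up/down DEG signature (no network, no pathways);
`subnetKS` restricts that signature to the extracted subnetwork's genes (no
pathways); `seedPathKS` enriches pathways directly from the DEG sets and
then scores per pathway (no network). With the default DEG sets — all up and
all down genes — the seedPathKS query is the whole measured universe, every
overlap equals its pathway's size, p = 1, and the variant returns an explicit
`no_enriched_pathways` status rather than a result; a `q` bound on the DEG
sets makes it non-degenerate. When the subnetwork happens to span all
measured genes, `subnetKS` reduces exactly to `seedKS`, a reduction the test
suite checks.

## What the synthetic generator emulates

`simulate_all()` builds all five inputs with planted truth so the whole
pipeline is testable offline:

* lognormal baseline expression (log2 means ~ N(6, 1), within-gene noise
  sd 0.25), with planted genes shifted by ±`effect_size` (log2 scale) in
  tumor samples;
* planted differential genes fill `n_pathways` pathway modules (half up,
  half down per pathway) and double as a dense network module
  (`module_edge_prob` = 0.4, confidence 0.5–1) against a sparse background
  (0.01, confidence 0–1); seeds are drawn from the planted genes;
* decoy pathways of non-planted genes, so enrichment has something to
  reject;
* drug instances with values −strength × realized disease logFC +
  N(0, `noise_sd`): strength +1 with zero noise reproduces the exact reverse
  of the disease ranking; negative strengths build mimicking drugs whose TS
  must come out positive — the end-to-end sign-convention check;
* a benchmark marking planted reversers (strength > 0) as `inferred`.

Default conditions: 500 genes, 30 tumor / 12 control samples, 4 planted
pathways of 25 genes plus 4 decoys, 8 seeds, effect size 2, profile noise
0.2, 20 drugs × 3 instances with 5 reversers at +0.9 and 15 inert drugs.
The sample sizes keep roughly the 2.4:1 tumor:control imbalance typical of
public tumor series at a size where every test and the acceptance script run
in seconds; the effect/noise ratio plants a clear but noisy signal. One
property of the scorer shaped these defaults: the KS statistic is rank-based
and therefore scale-free, so any mimic strength clearly above the profile
noise saturates |TS| exactly like a reverser of the same sign-to-noise —
mimickers are deliberately excluded from the default conditions and
exercised through explicit `reversal_strengths` overrides in the tests.

The generator does *not* emulate probe-level microarray structure, batch
effects, cell-line heterogeneity across a drug's instances, correlated
background expression, or partially overlapping pathway annotations. Passing
the planted-recovery tests therefore demonstrates that the statistics and
plumbing are correct, not that the method's biological error rates on real
compendia are known.

## Known limitations

* TS magnitude scales with the number of surviving pathway signatures, so
  scores are comparable within one run, not across databases with different
  pathway counts (use `normalize_pathways` for that).
* Gene identifiers are opaque case-sensitive strings; any probe-to-gene or
  symbol-to-id mapping must happen upstream. Drug names are matched to the
  benchmark case-insensitively after trimming, with no fuzzy matching.
* The enrichment screen uses raw thresholds by design; users screening many
  databases should consult the reported BH column.
* Ranking by |TS| treats strong mimickers and strong reversers alike, which
  matches unsigned benchmarks but means the therapeutic call (TS < 0) must
  be read alongside the rank.
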
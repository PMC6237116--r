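---
title: "Methods: miRNA-TF co-regulatory network construction and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA-TF co-regulatory network construction and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtfnet)
```

## The problem

Transcription factors (TFs) regulate genes and miRNAs transcriptionally;
miRNAs repress genes and TFs post-transcriptionally. When a TF and a miRNA
converge on the same target gene, the three nodes form a *co-regulatory
motif*, and recurrent motif patterns — feed-forward loops (FFLs) in
particular — are building blocks of cancer-relevant regulatory programs.
`mirtfnet` assembles a typed directed network from four kinds of regulatory
interaction evidence, screens it to cancer-relevant edges, enumerates and
classifies co-regulatory motifs, filters them against tumour expression data,
and characterises the resulting co-regulatory network.

## The typed network

Input is up to four tab-separated edge tables, one per interaction kind:
TF→gene, TF→miRNA, miRNA→gene, miRNA→TF. Each row is a regulator/target
pair with an optional per-row evidence label (`validated` or `predicted`)
overriding the table-level tag. Evidence is modelled as a *set* per edge:
duplicate rows are merged and their evidence unioned, so an edge may be both
validated and predicted. Assembly under evidence mode `VALIDATED`
(`PREDICTED`) keeps edges whose set contains that level; `BOTH` keeps all.

Node classes are implied by the table schema. Because TFs are themselves
genes, an identifier seen both as a TF (a source of TF→* edges) and as a
gene target is promoted to TF everywhere; an identifier required to be both a
miRNA and a TF/gene indicates corrupt input and is a fatal error. Gene and TF
symbols are compared case-sensitively; miRNA identifiers case-insensitively
("hsa-mir-29c" and "hsa-miR-29c" are the same node, first-seen spelling
kept), reflecting inconsistent capitalisation conventions across miRNA
databases. Self-loops are treated as malformed rows. Cancer screening keeps
exactly the edges with at least one endpoint in the union of the cancer gene
and cancer miRNA lists (a strict both-endpoint mode is available), then drops
isolated nodes — the networks here are edge-defined, so a node without edges
carries no information.

## Motif taxonomy

A triad (TF, miRNA, target) qualifies when **both** joint-target edges are
present: TF→target and miRNA→target. The regulator–regulator edges then
decide the class:

| TF→miRNA | miRNA→TF | class |
|---|---|---|
| – | – | co-regulatory pair |
| ✓ | – | TF-FFL (TF is the master regulator) |
| – | ✓ | miRNA-FFL (miRNA is the master, repressing the TF) |
| ✓ | ✓ | composite-FFL (mutual regulation) |

The classes are **mutually exclusive** — a triad with any regulator–regulator
edge is an FFL only — so per-class counts partition the qualifying triads.
This was a genuinely open choice: pair and FFL counts are often reported side
by side without stating whether FFL triads are also counted as pairs. We
chose exclusivity because it makes the counts a partition (and matches common
FFL-literature usage); `pairs_include_ffl_triads = TRUE` restores the
inclusive count. Joint targets are GENE-class nodes by default, since the
taxonomy names the joint target a *gene*; `allow_tf_targets = TRUE` admits
triads whose target is a TF distinct from the regulator TF. Enumeration is
exhaustive and deterministic (sorted by TF, miRNA, target identifiers) and is
verified in the test suite against a brute-force triple loop over all
TF × miRNA × target combinations on 200 seeded random networks.

Note that repression is **not** encoded at enumeration time — the edge tables
carry no activation/repression sign. The "miRNAs repress" semantics is
enforced by the refinement stage's negative-correlation rule.

## Expression refinement

Given matched gene and miRNA expression matrices over shared samples
(tumour cohorts in practice), every member edge of every motif is tested
with Spearman correlation between the regulator's and target's expression:

* **miRNA-source edges** (miRNA→gene, miRNA→TF) pass iff `p < alpha` and
  `rho <= -c`: miRNAs are assumed to inhibit their targets, so only negative
  monotone association counts.
* **TF-source edges** (TF→gene, TF→miRNA) pass iff `p < alpha` and, under
  the default `tf_sign = "BOTH"`, `|rho| >= c`; `"POSITIVE"` / `"NEGATIVE"`
  restrict to one sign of TF regulation.

Defaults are `alpha = 0.05` and `c = 0.2`, with the printed inequality
conventions kept exactly: `p` strictly below `alpha`, magnitude compared
non-strictly. A motif is retained iff **all** of its member edges pass;
tightening the policy can therefore only shrink the retained set, a
monotonicity property the tests assert over policy grids. TF→miRNA edges
follow the TF rule and miRNA→TF edges the miRNA rule: correlations are
pairwise between all regulator/target expression profiles, and a miRNA's
action is repressive regardless of its target's class. Motifs with
unmeasured members (absent features, or fewer than 3 complete sample pairs)
are dropped by default (`drop_unmeasured = TRUE`); set it to `FALSE` to
retain them unfiltered.

### Spearman details

`rho` is the Pearson correlation of average (mid-) ranks over
pairwise-complete observations. The two-sided p-value uses the t
approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of
freedom at every `n`, with `p = 0` at `|rho| = 1`; this keeps the p-value a
smooth, deterministic function of the data at all sample sizes. Against the
exhaustive rank-permutation null the approximation agrees within 0.05
absolute for `n` from 6 to 8 (and tracks increasingly tightly as `n` grows);
at `n = 5` the permutation null itself is so coarse (two-sided steps of about
1/60) that the worst-case gap of any smooth approximation widens to about
0.08. Refinement is intended for cohorts of dozens to hundreds of samples,
where the approximation error is negligible.

## Topology and enrichment

For the co-regulatory network (the union of all retained motifs' nodes and
edges) three per-node indicators are computed: degree (in + out), and the
HITS hub and authority scores — the principal eigenvectors of `A A^T` and
`A^T A` respectively, `A` the directed adjacency matrix over the sorted node
ordering. Both are computed by power iteration from a uniform positive start
vector (default tolerance `1e-10`, cap 10000 iterations; non-convergence is
an error reporting the residual), then rescaled to maximum 1. When the
principal eigenvalue of `A A^T` is (near-)degenerate — gap below `1e-8`,
common in unions of disjoint motifs — a warning notes that the principal
eigenvector, and hence the score vector, is not unique. Motifs are ranked
within each class by the sum of one indicator over their three member nodes.

Set enrichment uses one-sided hypergeometric over-representation with
Benjamini–Hochberg adjustment across the collection: with background size
`N`, intersected set size `K`, query size `n` and overlap `k`, the p-value is
the upper tail `P(X >= k)`. Genes and TFs are tested together against gene
sets; miRNAs separately (and case-insensitively) against miRNA sets. The
default background is all identifiers of the matching class in the assembled
pre-screening network — the universe from which co-regulatory members could
have been drawn — and can be overridden. A ranked permutation test was
deliberately not used: network membership provides no ranking metric.

## The synthetic generator

`synthesis_config()` / `generate_regulatory_db()` / `generate_expression()`
emulate the pipeline's inputs with known ground truth. Design:

* **Planted motifs are node-disjoint** and background edges are sampled only
  among non-motif nodes, so the planted class labels cannot be altered by
  background sampling and zero-density runs recover the planted set exactly.
* **Decoy motifs** are structurally identical (same class mix) but their
  members receive independent expression — they isolate the refinement
  stage's discrimination from the enumeration stage.
* **Expression model**: regulators are i.i.d. standard normal across
  samples; each planted direct edge contributes `target = r * regulator +
  sqrt(1 - r^2) * noise` with the sign dictated by the edge (negative for
  miRNA-source edges), and `r = 2 sin(pi * rho_s / 6)` chosen so that the
  bivariate-normal Spearman correlation is the configured `effect_rho`.
  Because Spearman is invariant under monotone transforms, the Gaussian
  choice is not restrictive. In FFLs the master regulator's effect on the
  joint target is routed through the partner, so the TF–target correlation
  magnitude is about `effect_rho^2` — the weakest, power-limiting edge.
* **Composite FFLs** are planted with a *negative* TF–miRNA correlation: the
  single TF–miRNA correlation must simultaneously satisfy the TF→miRNA rule
  and the miRNA→TF rule (`rho <= -c`), which is only possible with a
  negative value under `tf_sign = "BOTH"`. Under `tf_sign = "POSITIVE"` a
  composite FFL can never survive refinement; this is inherent to the sign
  rules, not to the generator.
* **Co-regulatory pairs** load the target equally on two independent
  regulators (`+a` on the TF, `-a` on the miRNA); both marginal correlations
  equal `a`, which caps at `1/sqrt(2)` — the generator therefore uses
  `a = min(r, 0.7)`, which only binds for `effect_rho` above about 0.68.
* Planted and decoy edges carry both evidence levels so ground truth
  survives any evidence mode; background edges get a validated/predicted
  mixture (0.5 / 0.4 / 0.1 both).
* Defaults — 30 TFs, 30 miRNAs, 60 genes, background density 0.02 per kind,
  planted counts (5, 3, 2, 2) across the four classes, 50% decoys, 100
  samples, `effect_rho = 0.6` — are the study conditions under which the
  discrimination behaviour is asserted: at these settings every planted edge
  has correlation magnitude ≥ 0.37 and the weakest edge still passes
  `(alpha, c) = (0.05, 0.2)` with high probability, giving ≥ 90% planted
  recall and ≤ 10% decoy retention.

What the generator does **not** emulate: count-distributed (RNA-Seq)
marginals, confounding between motifs that share nodes, batch structure,
dosage compensation, and indirect correlation between a decoy's members via
the real network. Passing tests therefore demonstrate that the machinery is
correct under its own model, not that real TCGA-scale networks will show
these recovery rates.

## Numerical and policy choices

* Inequalities exactly as the defaults are stated: `p < alpha` strict;
  `|rho| >= c`, `rho <= -c` non-strict.
* Midranks for ties; pairwise-complete deletion; fewer than 3 complete pairs
  (or constant ranks) is "unmeasured", handled by `drop_unmeasured`.
* Power iteration start vector is uniform, making the converged vector
  reproducible; the degeneracy warning relies on a dense eigenvalue
  computation, which is cheap at co-regulatory-network sizes.
* Determinism: all enumeration output is sorted; rerunning a pipeline with
  the same configuration and seed produces byte-identical output files.
* Test problem sizes: the enumeration oracle sweep uses 200 seeded networks
  (most 24 nodes, ten at 60 nodes); HITS agreement uses 50-node digraphs;
  discrimination uses three seeded studies of 120 nodes and 100 samples.

## Known limitations

* No identifier mapping beyond miRNA case-folding; symbol aliases must be
  reconciled upstream (the load report surfaces duplicate collapsing).
* Evidence is a two-level set; source-database weighting is out of scope.
* Refinement uses marginal pairwise correlation; partial-correlation or
  conditional approaches would distinguish direct from routed association.
* Hub/authority scores on near-degenerate networks (e.g. unions of disjoint
  motifs of equal size) are flagged but not disambiguated.
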
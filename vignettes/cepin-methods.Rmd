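---
title: "Comparative co-expressed interaction networks: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative co-expressed interaction networks: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cepin)
```

This vignette is the package's account of its statistical machinery: the
models behind each stage, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the design
choices made where more than one reasonable convention exists.

## The network model

The static protein interaction network (PIN) is an undirected simple graph;
self-loops and duplicate records are removed at parse time. A **co-expressed
protein interaction (CePPI)** in condition *c* is a PIN edge whose two genes'
expression profiles, restricted to condition *c*'s samples, correlate with
two-sided significance p ≤ `alpha_edge`. The condition's **CePIN** is the
set of its CePPIs; its node set is the endpoints of retained edges, so a
CePIN is always a subgraph of the PIN and growing `alpha_edge` can only grow
it.

Correlation significance uses the standard r-to-t transform,
t = r√(n−2)/√(1−r²) with n−2 degrees of freedom. The method's source only
fixes the threshold ("p ≤ 0.05", inclusive), not the test; the t test is
what mainstream statistical software reports for a Pearson correlation and
is exact under bivariate normality. Missing values are handled
pairwise-complete: an edge's score uses the samples where both genes are
finite, and an edge is ineligible (flagged, never an error) below 3 usable
samples or with a constant profile. This is also why designs require at
least 3 samples per condition.

## Topology conventions

Four per-node measures feed the SDEG/topology comparison:

* **degree** — edge count, on the full graph;
* **betweenness centrality** — fractional shortest-path counting (each
  shortest path between a pair contributes 1/#shortest-paths), normalized
  by C(N, 2). Path multiplicity makes "number of shortest paths through
  *i*" ambiguous; the fractional convention is the standard one and is what
  the brute-force oracle in the test suite enumerates;
* **closeness centrality** — reciprocal mean shortest-path length;
* **clustering coefficient** — realized fraction of links among a node's
  neighbours, reported as 0 with a `clustering_defined = FALSE` flag for
  degree < 2.

Betweenness and closeness are computed within the largest connected
component only (nodes outside it carry `NA`); ties in component size break
toward the component holding the lexicographically smallest node name, so
results are deterministic.

SDEGs are called by a two-sided Wilcoxon rank-sum test. The implementation
enumerates the exact permutation distribution (a subset-sum dynamic program
over doubled midranks) whenever C(nx+ny, nx) ≤ 10⁶ and falls back to the
tie-corrected normal approximation with continuity correction otherwise;
the two-sided p is P(|W − μ| ≥ |w − μ|), which the midrank distribution's
symmetry makes equivalent to doubling the smaller tail. Hubs are nodes
strictly above the (100−p)-th degree percentile (type-7 linear
interpolation, default top 1 %); strictness mirrors the "more than
threshold" reading and makes an all-equal degree distribution yield no hubs.

## Two-stage enrichment

Gene-level enrichment of a CePIN against a term uses the exact
hypergeometric upper tail P(X ≥ k) computed in log space (log-gamma
binomials), where N is the background (annotated genes present in both the
expression matrix and the PIN), m the CePIN genes in the background, n the
term's genes in the background, and k the overlap. The method's printed
formula is the point mass P(X = k); an enrichment test needs the tail, so
the tail is the default and `mode = "point"` is kept for forensic
comparison.

The edge-level stage replaces genes by **functional dyads**: CePPIs whose
two proteins share the term. The background Nₑ is the PIN edges both of
whose endpoints are background genes — mirroring the gene test's background
restriction, which the source leaves unstated — mₑ the CePPIs among them,
nₑ the term's dyads in the background, kₑ the term's dyads among CePPIs.
Terms with nₑ = 0 get p = 1 and a `no_dyad` flag rather than an error.
Whether a dyad requires the term among direct or ancestor-propagated
annotations is configurable; the default is propagated (true-path rule over
`is_a`/`part_of`, the convention of ontology enrichment tools), applied by
`propagate_annotations()`, which is idempotent and monotone.

Each family (gene-level terms; dyad-level terms) is BH-FDR corrected
separately, dyads only over the gene-significant terms, since dyads are only
tested for functions already enriched. A **candidate** function must pass
both at `alpha_enrich` (default 0.05).

## Exclusive modules

A-exclusive functions are candidates(A) ∖ candidates(B). The surrounding
prose in the method's source inverts the operands of its own displayed
equation; the equation is taken as authoritative, and both directions are
always computed so nothing is lost either way. The ontology-level filter
(keep level ≥ `min_go_level`, default 5, root = 1, shortest-path levels as
in BiNGO) runs *after* the set difference, matching the published pipeline
order. Note that with propagated annotations a planted term's deep ancestors
can carry the same gene set and therefore co-appear in the exclusive list;
no redundancy pruning is applied, deliberately.

## Module evaluation

* **Root-split classification.** Samples are clustered on member-gene
  expression (Euclidean distance; linkage configurable, default average/
  UPGMA — the source does not state one) and the tree is cut at the root.
  The branch with more positive-condition samples is "positive"; exact ties
  break toward the branch holding the lexicographically smallest sample id,
  with a message. Accuracy is (TP+TN)/N. The source prints
  (sensitivity+specificity)/N, which is dimensionally inconsistent; that
  literal formula is available behind `accuracy_mode = "printed"` only.
* **ROC/AUC.** Threshold sweep over module activity scores (per-sample mean
  member expression, unstandardized by default; a z-score mode can be
  applied upstream by scaling the matrix). AUC equals the Mann–Whitney
  concordance probability with half-credit for ties; orientation is chosen
  so AUC ≥ 0.5 and recorded.
* **Dynamics.** Observed statistics — mean |pairwise PCC| within each
  condition, mean |per-gene condition-mean difference|, mean |ΔPCC| over
  member interactions — are compared with `n_null` uniform random gene sets
  of equal size drawn from the measured genes (degree-agnostic, since no
  sampling scheme is prescribed by the source; null sets use all
  within-set pairs for the ΔPCC statistic because a random gene set has no
  canonical edge set). Z = (obs − null mean)/null sd; the empirical p uses
  the add-one estimator (1 + #{null ≥ obs})/(1 + n_null) so it can never be
  zero. Both the Z and the empirical p are reported because one-sided
  versus two-sided conventions vary.
* **Re-sampling robustness.** For each subsample size, samples are redrawn
  without replacement within each condition and the whole discovery re-run;
  reported are the fraction of full-data CePPIs recovered per condition and
  the fraction of full-data exclusive modules re-identified.

## The synthetic generator

`synthetic_spec()` defines the simulated study. The default — 300 genes,
800 interactions, 15+15 samples, one condition-A-exclusive term (ρ_A = 0.8,
ρ_B = 0, 20 genes, mean shift δ = 1.5 in A) and one both-condition term
(ρ = 0.8 in each condition with independent per-condition factors), decoy
terms of matched size covering every gene, ontology depth 6 — is desk
scale: large enough that enrichment backgrounds and degree distributions
behave realistically, small enough that a full comparison runs in well
under a second, which is what lets the test suite run hundreds of
independent replications.

Member genes follow a one-factor Gaussian model per condition,
x = √ρ·f_sample + √(1−ρ)·ε, so the expected within-condition pairwise
correlation is exactly ρ and effect sizes are interpretable as target
correlations; the factors are redrawn per condition, which is what makes
the both-condition term's co-expression "rewired" between states at the
sample level. Background genes are i.i.d. standard normal. The PIN is a
uniform random graph constrained by a global spanning tree (connectedness)
and a spanning tree within each planted member set (each planted module is
an induced connected subgraph). Every generator output is a pure function
of the spec, including its seed; identical specs write byte-identical
fixture bundles.

What the generator does **not** emulate: microarray probe-level noise and
normalization artifacts, the scale-free degree structure and annotation
bias of real interactomes, the real GO DAG's breadth and multiple
parenthood, and correlated backgrounds. Passing tests therefore demonstrate
that the machinery is correct and calibrated under a clean generative
model — not that any particular biological dataset will yield stable
modules.

## Problem sizes and numerical choices

The validation suite uses: exhaustive hypergeometric enumeration to N = 25;
100 random graphs of up to 40 nodes against brute-force BFS oracles; 20
independent seeds for planted-module recovery, classification power,
detection Z, and re-sampling (sizes 15/10/5 per condition); and 200
independent replications for type-I control and null-Z calibration. The
classification-power fixture plants the δ = 1.5 activity shift *without*
co-expression: a strong shared factor (ρ = 0.8) inflates within-condition
spread, and hierarchical-clustering root splits then lose a few samples
whose factor value is extreme — a real limitation of root-split
classification worth knowing about, and the reason the shift is studied
unconfounded. Null-Z calibration draws each trial from its own simulated
dataset; trials sharing one dataset are positively correlated and their
mean Z no longer shrinks at the 1/√trials rate.

Numerical details: correlations are clipped to [−1, 1] against rounding;
|r| = 1 reports p = 0 with the degeneracy implied; hypergeometric tails are
summed from the largest log term to avoid underflow; BH adjustment
delegates to `stats::p.adjust`; empirical p-values are add-one; every
stochastic routine takes an explicit integer seed and restores the caller's
RNG state.

## Known limitations

* Identifier spaces are the caller's problem: expression rows, PIN nodes
  and annotation genes must share one namespace (a two-column mapping can
  be applied upstream).
* Enrichment backgrounds condition on the measured-and-interacting gene
  universe; a biased universe biases both stages in the same direction.
* The dyad test treats edges as exchangeable; degree structure is ignored
  in its null, as in the original formulation.
* Root-split classification is sensitive to outlying samples (see above);
  the activity-score ROC is the more robust summary.
* The exclusive-set operation is sharp: a term marginally significant in
  both conditions disappears from both exclusive lists even if its two
  CePPI sets barely overlap. The edge-dynamics classification
  (`classify_edge_dynamics()`) is the complementary, threshold-based view
  of such rewiring.
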
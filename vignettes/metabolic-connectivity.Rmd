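---
title: "Metabolic connectivity profiling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic connectivity profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metconnect)
```

## The readout

A metabolome under stress can look unchanged metabolite-by-metabolite
while its coordination collapses. Connectivity profiling captures that:
for each experimental condition we estimate the matrix of Spearman
correlations among all metabolite abundance profiles plus one phenotype
trait (tumor volume or cell number), reduce it to a signed network of
strong, significant associations, extract the locally dense modules that
organize it, and ask how drug treatment rewires all of the above.

Spearman's rho is used throughout because relative MS abundances are on
arbitrary, often heavy-tailed per-metabolite scales; a rank statistic is
invariant to any monotone recalibration and robust to single outlier
samples, which matters at the small per-condition sample sizes (5–10) of
xenograft studies. The cost is statistical: with n = 10, only strong
correlations are detectable at all, which shapes everything below.

## Networks

For a condition with n samples, ties receive average ranks and each pair
uses its complete observations (missing values are never imputed). The
two-sided p-value comes from the t approximation
`t = rho * sqrt((n-2)/(1-rho^2))` on n−2 degrees of freedom; an exact
permutation p (via `cor.test`) is available behind `p_method = "exact"`
for n ≤ 9, but the approximation is the default so that all sample sizes
are treated uniformly. Pairs with fewer than 4 complete observations or a
constant vector have undefined rho: they are excluded from the
false-discovery adjustment and can never form an edge — a zero-variance
metabolite carries no evidence of independence, so coercing rho to 0
would be wrong.

Multiplicity is controlled by Benjamini–Hochberg over the strict upper
triangle of each condition's matrix, trait pairs included: the trait is
an ordinary node, tested and thresholded exactly like a metabolite. The
adjustment is per matrix (per condition, per tissue), matching how the
analyses are partitioned; a joint adjustment across tissues would couple
networks that are interpreted separately.

An edge requires `|rho| > threshold` **and** `q < fdr`, both strict, with
defaults 0.6 and 0.05. Strictness follows the rule's wording ("greater
than", "< 0.05"); at these sample sizes the measure-zero boundary cases
are irrelevant in practice but the semantics are pinned down for
reproducibility. Edge sign is the sign of rho, preserved through every
export (edge-list TSV, GraphML, SIF) so a viewer can render positive and
negative associations differently.

Two networks built with the same settings are contrasted by unordered
node pair: shared edges, condition-specific edges, and shared edges whose
sign flips — the generic form of a glucose–tumor-volume polarity
inversion. Comparing networks built with different settings warns rather
than errors: the operation is well defined, but the asymmetry is recorded
because it biases the specific-edge counts.

## MCODE

Module detection reimplements the Molecular Complex Detection algorithm.
Vertex weight is the *core-clustering coefficient*: take the closed
neighborhood of v, find its highest k-core, and multiply that k by the
core's edge density. Compared with the plain clustering coefficient this
discounts vertices whose neighborhoods are only accidentally dense.
Vertices with degree below the degree cutoff (default 2) weigh 0 and
cannot seed.

Complex growth is breadth-first from the highest-weight unvisited vertex;
a neighbor joins when its weight is at least
`seed_weight * (1 - node_score_cutoff)` (default cutoff 0.2), never
farther than `max_depth` (default 100) hops from the seed. Every vertex
belongs to at most one module. Post-processing optionally removes singly
connected vertices until none remain (haircut, on by default), optionally
adds dense boundary neighbors (fluff, off by default — the common viewer
defaults), and discards any module without an internal 2-core, so no
tree-like cluster survives and every module has at least 3 nodes.

Density is `D = |E| / (n(n-1)/2)` over the module's own possible edges,
keeping D in [0,1], and the score is `D * n`; the alternative convention
of normalizing by the whole network's edge count is available via
`density_denominator = "network"` for comparison, but it makes scores
depend on network size and is not the default. The original plugin's
output depends on vertex iteration order; here ties are broken by score,
then module size, then lexicographically smallest seed id, so identical
inputs always give identical ranked lists. Edge signs and weights are
ignored by design — module detection is purely topological, as in a
viewer-based workflow on a correlation network.

## Pathway eigenmetabolites

Each pathway is condensed to the first principal component of its
members' z-scored profiles. Z-scoring (correlation-scale PCA) is
essential with relative abundances: raw-covariance PCA would let an
arbitrarily scaled metabolite dominate the component. The loading vector
has unit norm, and `variance_explained` is the top eigenvalue over the
trace of the member correlation matrix, reaching 1 exactly when the
member matrix is rank 1 (always for single-member pathways).

Principal components are defined only up to sign, which would make
heatmaps irreproducible across platforms. The sign is therefore fixed so
the mean correlation between the eigenmetabolite and its members is
non-negative; an exact tie resolves toward a positive loading on the
lexicographically first member. Metabolites mapping to several pathways
contribute to each of them — hub metabolites such as ADP genuinely belong
to many pathways. Samples with a missing member value are dropped for
that pathway (PCA needs complete columns); zero-variance members are
pruned with a warning.

Pathway–pathway connectivity is the Spearman correlation between
eigenmetabolite score vectors (Pearson by flag), *unthresholded*: the
0.6/FDR rule is a metabolite-network concept, while pathway heatmaps are
read as continuous shade and color.

The control-vs-treated contrast reports, per pathway, the number of
partner pathways whose correlation changes sign and the mean change in
|rho|. The "disrupted" flag averages the |rho| drop only over partners
the pathway was *connected to in the control condition* (|rho| >
`baseline`, default 0.6, reusing the edge threshold): treatment can only
dismantle connectivity that existed, and averaging over near-zero control
pairs would dilute a genuine collapse below any detection limit. The flag
fires when that mean drop exceeds `drop_cutoff`, default 0.3 — half the
baseline, i.e., a connected pathway pair must on average lose at least
half its qualifying correlation strength. Both constants are exposed and
were fixed once, from this rationale, not fitted.

## The synthetic generator

Real data for this design — two tissues by {control, single, combined}
arms with caliper traits — are rarely deposited, so the package ships a
generator that emulates the *statistical* structure the analysis assumes.
On the log scale, each planted block b has a latent factor per sample,
and member i is `sign_i * loading_b * factor_b + noise_sd * eps`;
unassigned metabolites are standard-normal noise; the trait equals the
trait block's factor plus noise; values are exponentiated so abundances
are positive and log-normal (cosmetic under rank statistics, but it keeps
file-level round trips honest). Under the treated condition, disrupted
blocks have their loading set to 0 and listed members flip loading sign.
A single integer seed drives one generator stream; identical spec and
seed give byte-identical output.

Defaults mirror a small xenograft metabolomics study: 2 conditions with
8 samples each, 100 metabolites of which 4 blocks of 8 are coordinately
regulated at loading 0.95 with noise SD 0.3, the trait driven by the
first block, and treatment disrupting that same trait-linked block. The
default pathway map splits each block across two 4-member pathways, with
everything else "unassigned". That split is deliberate: in real
metabolomes a coordinated process (and its latent regulation) spans
several KEGG pathways, and cross-pathway correlation is precisely what
the pathway-connectivity contrast is supposed to detect; mapping each
block to a single pathway would make between-pathway correlation
vacuously near zero and the contrast untestable.

What the generator does **not** emulate: batch effects, intensity-
dependent missingness, isotope labeling, inter-block correlation,
compositional closure, or realistic pathway size imbalance. Passing tests
on this generator therefore demonstrate that the pipeline recovers the
structure it targets under idealized block-latent structure and Gaussian
noise — not that any particular real dataset will yield stable networks
at n = 10.

## Problem sizes and numerical behavior

The test suite and the acceptance script exercise a benchmark at 32
metabolites (four blocks of 8, all planted), loading 0.95, noise SD 0.3,
10 samples per condition, over 20 replicate generations — small enough
that the full suite runs in about a minute while the per-edge recovery
question is genuinely hard: a planted pair's population Spearman is about
0.90, and after BH adjustment over the ~500 pairs an edge needs a sample
rho around 0.87, so recovery sits near 80%, not near 100%. Two
consequences are worth knowing. First, module completeness: a block
member that loses most of its edges to sampling noise scores below the
MCODE expansion cutoff and is (correctly) left out of the module, so
detected modules typically carry 6–8 of 8 planted members; the benchmark
reports this as the block–module Jaccard overlap. Second,
condition-specific edge sets inherit the same recovery ceiling — the
package reports disruption relative to the edges actually observed, and
the all-noise calibration run verifies that essentially no edges arise
when nothing is planted.

Other numerical choices: Spearman p-values of |rho| = 1 are set to 0
rather than left to the t formula's singularity; BH is delegated to
`stats::p.adjust`; PCA uses the singular value decomposition of the
z-scored member matrix (never an explicit covariance eigendecomposition,
which is less stable for n < p); TGI aggregates animals by the arithmetic
mean of per-animal fold changes within each arm before taking the ratio
of arm means — the alternative (ratio of mean final over mean initial
sizes) is not scale-free per animal — and negative TGI values are
reported as-is.

## Known limitations

- Marginal correlations only: no partial correlations or graphical
  models, so a hub metabolite's neighbors appear directly connected.
- The FDR is controlled per condition matrix; cross-condition contrasts
  of two FDR-thresholded networks have no joint error guarantee.
- MCODE's expansion rule depends on the seed's weight, so module
  membership near the weight cutoff is sensitive to single edges at
  small n (see the benchmark notes above).
- The exact Spearman p option is limited to n ≤ 9 without ties, as in
  the underlying implementation.
- Pathway assignment is by exact, case-sensitive metabolite id; no
  identifier normalization or ontology lookup is attempted.
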
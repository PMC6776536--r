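---
title: "Comparative GIN analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative GIN analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
models and their assumptions, the parameters that matter, what the
synthetic generators do and do not emulate, and the choices made where the
design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. From colony sizes to interaction calls

### Model

Arrayed colony growth is treated as multiplicative: a colony's size is a
baseline times plate-level effects, times the treatment effect, times the
gene-specific interaction effect, times lognormal noise. Under that model
the treated/control growth ratio of gene $g$ isolates the interaction
term, and log2 ratios are symmetric in it. The score is

$$z(g) = \frac{\mathrm{center} - \log_2 r(g)}{\mathrm{spread}},
\qquad p(g) = 1 - \Phi(z(g)),$$

with center/spread the mean/SD of the log-ratios (median and
1.4826·MAD in robust mode). The sign convention makes growth *defects*
positive, so the `Z > 2` hit direction selects hypersensitivity —
negative genetic interaction. The p-value is one-sided because only
defects are called; note that at `z = 2` the one-sided tail is
$p \approx 0.023 < 0.05$, so the conjunction `Z > 2 ∧ P < 0.05` is
driven by the Z cutoff.

### Assumptions and their consequences

* **Most genes are non-interactors.** Center and spread are estimated
  from all scorable genes, so a screen where a large fraction of genes
  respond would shrink sensitivity. At the study's planted fraction
  (50/1536 ≈ 3%) this bias is negligible, as the acceptance suite
  verifies (sensitivity ≥ 0.95, specificity ≥ 0.98 at effect size 0.5 and
  10% colony noise, averaged over ten seeds).
* **Plate effects are multiplicative and position-independent** apart
  from the border. Border colonies grow larger from reduced competition;
  they are excluded from the normalising median and from the
  center/spread estimate but are still scored.
* **Replicates are exchangeable**: quadruplicate pins are collapsed by
  median before the ratio is formed.

### Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `z_threshold` | 2.0 | SD | hit cutoff used by the study design |
| `p_threshold` | 0.05 | — | companion significance cutoff |
| `use_log_ratio` | TRUE | — | symmetrises multiplicative noise; plain-ratio mode retained for hand-checkable examples |
| `robust_center` | FALSE | — | mean/SD by default; median/MAD for heavy-tailed plates |
| `linkage_window_bp` | 25 000 | bp | no window is stated in the source methodology; ±25 kb covers the handful of genes flanking a query locus at typical gene spacing and is exposed in the configuration |
| `min_genes` | 20 | genes | minimum scorable genes for a meaningful spread estimate |

Degenerate inputs fail loudly: an all-zero plate, a zero-spread ratio
distribution, or a control colony of size zero (the gene is flagged
`missing`, never an infinite ratio).

## 2. Augmented networks

Screen hits are sparse; to analyse topology they are expanded into a
global interaction network. Edges of the global network are first
filtered at stringent digenic cutoffs — $|w| \ge 0.12$ (boundary
inclusive) and $p < 0.05$ — and every gene within BFS hop distance ≤ 2 of
a seed (three nodes on a path, "path length 3") joins the augmented GIN,
which is the induced subgraph on those genes. The hop bound is
configurable; reading the expansion as ≤ 3 edges instead is defended by
setting `hop_bound = 3`. Node strength uses $|w|$ throughout: negative
interaction scores are evidence of interaction and must contribute
connectivity. Seeds absent from the global network are dropped with a
warning rather than an error, since screens and reference networks never
share a namespace perfectly.

Whether a network's seed set occupies unusual positions is tested by
comparing the seeds' centrality values against `n_boot = 1000` same-size
uniform random node sets with a two-sided Mann–Whitney test; networks
with $p \ge 0.05$ would be excluded from topology claims. The normal
approximation with tie correction is used (the pooled null has thousands
of values); the package also exposes an exact small-sample Mann–Whitney
for verification (e.g. {1,2} vs {3,4} gives $U = 0$, $p = 1/3$).

## 3. Modularity and Louvain

Weighted modularity is

$$M = \frac{1}{2m} \sum_{ij} \left[ A_{ij} - \frac{k_i k_j}{2m} \right]
\delta(c_i, c_j)$$

with $A$ the absolute edge weights, $k_i$ node strength and
$2m = \sum_{ij} A_{ij}$. The move gain $\Delta M$ is *defined
operationally* as the difference of $M$ after and before the move; the
implementation uses the standard analytic Louvain gain, and the identity
`gain ≡ recomputation` is enforced to 1e-10 over hundreds of random
(graph, move) instances in the tests. This operational contract is
deliberately typo-proof: the analytic bracketing of published gain
formulas varies (and is sometimes corrupted in print), while the identity
is unambiguous.

The optimiser is the standard two-phase Louvain: sweeps of local moves to
the neighbouring community of largest positive gain, then aggregation of
communities into super-nodes (internal weight becomes a self-loop),
iterated until the improvement falls below `min_gain = 1e-7`. Because the
result depends on sweep order, the order is shuffled under a seeded RNG,
and the whole search is restarted `n_restarts = 5` times from derived
sub-seeds, keeping the best-modularity partition — deterministic for a
fixed seed. Restarts mainly matter on small graphs, where a single greedy
run can stall several percent below the exhaustive-partition optimum; the
tiny-graph tests use 20 restarts (free at that size) while study-scale
runs keep 5 to bound runtime. Community ids are renumbered 0..k−1 by
decreasing size. The resolution parameter multiplies the null term and
defaults to 1.0 (plain modularity); it is exposed but not used by the
study design. An edgeless graph has no defined modularity and errors.

Community function is summarised by *coverage*: the percentage of a GO
term's dataset genes found in the community, with a one-sided
hypergeometric probability given the community size, the term's
dataset-restricted total and the dataset size. Dataset-restricted
denominators are used (not genome-wide totals); the alternative reading
exists but the dataset-restricted one matches "genes known for that
GO-term in a given dataset".

## 4. Centralities and bottleneck clusters

Shortest paths run on hops, not on $1/|w|$ lengths: the edge weights are
interaction *scores*, similarity-like quantities, and treating them as
distances would invert their meaning. A weighted-distance mode exists
behind `weighted = TRUE` for users whose networks carry true lengths.

* **BC** — Brandes betweenness, normalised by $(n-1)(n-2)/2$.
* **CC** — Wasserman–Faust component-scaled closeness,
  $\frac{n_c - 1}{n - 1}\cdot\frac{n_c - 1}{\sum d}$, which makes values
  comparable across disconnected networks; isolated nodes get 0.
* **EC** — power iteration on $|A| + I$ of the largest component
  (the identity shift prevents oscillation on bipartite graphs without
  changing the eigenvector), stopped at successive-iterate change
  < 1e-12, scaled to unit Euclidean norm; nodes outside the largest
  component get 0.

All three match dense brute-force definitions (path enumeration,
Floyd–Warshall, `eigen`) on hundreds of random ≤ 8-node graphs to 1e-8 in
the acceptance suite.

Cluster counts are scanned over k = 2..10 on standardised (z-scored)
centrality features for both Ward agglomerative and k-means; the
silhouette score decides the optimum (ties to the smaller k), with
Calinski–Harabasz reported alongside. Silhouette uses Euclidean distance
on the standardised features, matching the k-means geometry. The study
design fixes k = 4 and labels clusters α–δ by ascending mean betweenness;
"δ = highest-betweenness cluster" operationalises the idea that the
bottleneck cluster is the one defined by betweenness, since the α–δ order
is otherwise arbitrary. k-means uses 50 seeded restarts; ranking ties in
`top_bottleneck_genes()` break lexicographically so output is
deterministic.

## 5. Enrichment, FDR, semantics, SAFE

**Hypergeometric enrichment** is the one-sided tail
$P(X \ge k)$ for the term overlap; terms with zero study overlap are
skipped (they carry no evidence either way under a one-sided
over-representation question).

**Two-stage BKY FDR**: stage one runs Benjamini–Hochberg at
$\alpha' = \alpha/(1+\alpha)$; the rejection count estimates the number
of true nulls $m_0 = m - r_1$; stage two reruns the step-up at
$\alpha' m / m_0$. The rejection set — not any adjusted value — is the
procedure's contract, because the recalibrated level makes "adjusted
p-values" non-monotone in general; the reported adjusted values are the
BH-adjusted values scaled by $m_0/m$, a convention shared with common
reference implementations. The adaptive procedure never rejects less
than plain BH, which is property-tested.

**Lin similarity** needs an information content per term:
$IC(t) = -\ln p(t)$, where $p(t)$ is the annotated fraction *of the
analysis corpus* (annotations propagated to ancestors, so the root has
IC 0). The corpus is the dataset's own annotation set, not a genome-wide
reference, because uniqueness values are meant to describe the result
list at hand; the corpus is a parameter for users who want otherwise.
Uniqueness is $1 -$ mean Lin similarity to the other reported terms,
with singletons defined as 1.

**SAFE-style enrichment** measures where on the network *map* an
attribute concentrates: edge lengths are Euclidean distances between
endpoint embedding coordinates, a node's neighbourhood is everything
within weighted shortest-path radius 7.5 map units, and each attribute is
tested hypergeometrically in each neighbourhood at α = 0.05. Scores are
$-\log_{10} p$ capped at $10^{-16}$ and divided by 16, giving a [0, 1]
scale. When no embedding is supplied a seeded Fruchterman–Reingold layout
is computed on topology only (signed scores are not spring weights) and
rescaled to a 100-unit bounding-box diagonal, so the default radius reads
as 7.5% of the map span — a local patch, which is the only reading of a
fixed radius that transfers across maps of arbitrary coordinate scale.
Supplied embeddings are used exactly as given, and results are then fully
deterministic. The published 18 functional map regions are configuration,
not code: any attribute file (region → gene list) plays that role.

## 6. Profile clustering

Profiles are compared on min–max-normalised Z-scores per gene across the
design cells ([0, 1]; constant columns become 0 — a gene that never
discriminates carries no signal rather than maximal signal). Genes
unscored in a cell are masked and imputed with the column median for
distance computation only; dropping whole genes across 20 cells would
discard most of the matrix. The default tree is average-linkage on
Euclidean distances, cut into 3 clades; Ward linkage and correlation
distance are options since the source methodology names both families
without parameters. "Ten contiguous genes around a focal gene" is read as
the focal gene's nearest dendrogram neighbours, not chromosomal
neighbours — the surrounding analysis is about co-scoring, not position.
Focused panels are re-normalised after column subsetting and clustered in
both directions.

## 7. What the synthetic generators emulate — and what they do not

The generators exist so every stage has ground truth:

* **Library**: 384/1536 rectangular plates, border flags, 16 synthetic
  chromosomes with uniform 12 kb gene spacing (which makes
  linkage-window arithmetic exactly checkable).
* **Screens**: lognormal colony noise around a 500-unit baseline median
  (strictly positive, right-skewed like real colony areas), a global
  treatment inhibition (default 0.4, emulating doses chosen to inhibit
  growth ~40%), planted hypersensitive genes at effect size 0.5, a 1.2×
  border growth boost, and exact determinism per seed. In the noise-free
  limit the treated/control ratio equals the analytic product
  $(1-\mathrm{inhibition})(1-\mathrm{effect})$ to 1e-12.
* **Global network**: a planted-partition SBM (default 2000 genes, 8
  blocks, $p_{in} = 0.05$, $p_{out} = 0.003$, mean degree ≈ 18 — chosen
  once as a realistic density for a stringently filtered interaction
  network and to land the augmented GINs at the ~2000-node scale);
  weights $|N(0.25, 0.1)|$ with 10% negated, straddling the 0.12 cutoff;
  edge p-values 90% below 0.05.
* **GO DAG**: a rooted multi-parent hierarchy with direct annotations at
  the deepest level, propagated by the true-path rule.
* **Study design**: 4 backgrounds × 5 probes (two drug-like, three
  query-gene probes with linkage exclusion), 50 planted hits per cell
  with a deliberate overlap structure — a core shared by all
  backgrounds, a slice shared by the non-reference ("resistant")
  backgrounds, the rest background-specific — so hit-set algebra has a
  known answer.

Not emulated: spatial plate gradients beyond the border, batch effects,
competition between neighbouring colonies, realistic chromosome-level
linkage disequilibrium, scale-free degree structure, and — importantly —
**functional coherence between GO annotations and network blocks**: the
GO generator draws annotations independently of the SBM partition, so
community GO enrichment on synthetic data is correctly null after FDR and
demonstrates the machinery, not a biological signal. The planted blocks
themselves are the signal-bearing attribute for coverage and SAFE
demonstrations. Consequently, passing tests show the pipeline recovers
*planted* structure under the stated noise; they do not certify
performance on real screens with spatial artefacts or correlated
annotation structure.

## 8. Problem sizes and determinism

The test suite runs the study at its full synthetic scale — 1536-gene
screens, a 2000-gene global network, 20 design cells — once, end to end,
plus the brute-force and property checks at small n (≤ 8-node graphs for
exhaustive partitions and path enumeration, Bell(8) = 4140 partitions).
These sizes were chosen so the whole chain demonstrates the study's
actual geometry while the exhaustive oracles stay exact. Every stochastic
step takes an explicit integer seed, sub-seeds are derived through a
single documented helper, and rerunning any stage with the same seed
reproduces byte-identical tables (tested via md5 on the written files).

## 9. Known limitations

* Louvain is order-dependent and greedy; restarts mitigate but do not
  eliminate suboptimality, and the resolution limit of modularity (small
  natural communities absorbed into larger ones) is inherited by design.
* Community counts on dense synthetic SBMs sit at the planted block
  count; real augmented GINs, with heavier-tailed structure, can
  fragment further — which is exactly why the centrality-cluster view is
  computed alongside.
* The bootstrap centrality test uses a pooled null; very small seed sets
  (< 3) are refused rather than approximated.
* The BKY "adjusted" values are a reporting convenience; decisions
  should use the rejection flags.
* SAFE significance is unadjusted per (node, attribute) as in the
  original method; interpreting counts of significant nodes across many
  attributes needs the same caution as any multiplicity-laden screen.
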
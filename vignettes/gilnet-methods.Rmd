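---
title: "Layered co-expression networks with genetic trait integration: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layered co-expression networks with genetic trait integration: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gilnet)
```

# The model

`gilnet` operates on an $m \times n$ expression matrix ($m$ samples, $n$
probesets, log2 intensity scale). Its central premise is statistical, not
biological: the Pearson correlation of a gene pair computed across a
heterogeneous compendium is a mixture over conditions, so a relationship
confined to one condition is diluted towards zero by the samples in which
it is absent. Partitioning the samples into condition groups *before*
computing correlations recovers these relationships at the price of fewer
samples per estimate. The package makes that trade explicit: a K-means
partition of the samples (each sample a point in probe space, Hartigan–Wong
algorithm, seeded restarts), one co-expression network per group, and a
hard floor on group size (default 25 arrays) below which no network is
attempted because the correlation estimates become too unstable to
threshold.

The number of groups defaults to the rule of thumb $k = \lfloor\sqrt{n/2}
\rfloor$. We chose `stats::kmeans` with the Hartigan–Wong algorithm rather
than a hand-rolled Lloyd/k-means++ loop: it is the canonical R
implementation of the named algorithm, any within-cluster-sum-of-squares
minimizer satisfies the contract, and the seed and restart count are
recorded in the output for provenance.

## RMT thresholding

For one group, all-pairs Pearson correlations form a symmetric similarity
matrix $S$ with unit diagonal. For a candidate cutoff $t$, entries with
$|r| < t$ are zeroed, genes without any surviving off-diagonal entry are
dropped, and the eigenvalues of the surviving matrix are examined. Random
matrix theory supplies the decision rule: a noise-dominated symmetric
matrix shows GOE level repulsion (Wigner-surmise spacings), while a
modular matrix — approximately block-diagonal — behaves as a superposition
of independent spectra whose nearest-neighbour spacing distribution (NNSD)
is Poisson, $P(s) = e^{-s}$. The chosen threshold is the smallest $t$ at
which a chi-square test *accepts* the Poisson law.

Numerical choices, all configurable:

* **Unfolding.** Spacings are meaningful only after the spectrum is
  rescaled to unit local density. We fit a monotone (Hyman) cubic spline
  to the empirical cumulative spectral function at every 10th distinct
  eigenvalue (at least 5 knots) and map $\lambda_i \mapsto n\,
  \hat F(\lambda_i)$. Coarser knots over-smooth genuine repulsion; finer
  knots absorb it into the trend.
* **Degeneracy.** Eigenvalues closer than $10^{-6}$ are collapsed before
  spacing computation. Thresholded matrices contain many exactly repeated
  eigenvalues (e.g. at 1, from structurally equivalent low-degree nodes)
  which would otherwise put a spurious spike at $s = 0$.
* **The test.** Spacings are rescaled to mean 1, binned into 60 bins on
  $[0, 3]$ with the tail pooled into the last bin, and compared with the
  exponential bin masses by chi-square with 59 degrees of freedom at
  $p = 0.001$. At least 100 distinct eigenvalues are required; below that
  the scan reports `too_few_genes` as a data outcome, mirroring real
  collections in which some sample groups yield no network.
* **The scan.** Coarse steps of 0.01 from $t_{start} = 0.50$, refined to
  0.001 between the last rejecting and first accepting coarse cutoffs.
  Correlations are thresholded on $|r|$ by default (the sign is kept as an
  edge attribute); a signed mode is available.

A property worth knowing when interpreting scans on clean synthetic data:
a fixture consisting of disjoint near-cliques plus a *sparse* noise
overlay is already Poisson at moderate cutoffs, because superposing many
independent block spectra washes out repulsion. On such fixtures the scan
legitimately accepts at its starting cutoff — we measured the Poisson/GOE
transition of the 20-block calibration fixture (30 genes per block,
$\rho = 0.95$, 40 samples) at $t \approx 0.40$, below the default scan
start. Real compendia, with pervasive moderate correlations, reject far
longer; the published rice collection's thresholds run 0.91–0.99.

## Link communities

Modules are communities of *edges*, so genes may be multifunctional.
Adjacent edges $(i,k)$ and $(j,k)$ are scored by the Jaccard similarity of
the closed neighbourhoods of their outer endpoints,
$S = |n^+(i) \cap n^+(j)| / |n^+(i) \cup n^+(j)|$, on the unweighted
graph. Similarity is undefined (not zero) for non-adjacent pairs. Edges
are clustered by exact single linkage and the dendrogram is cut at the
height maximizing the partition density

$$D = \frac{2}{M} \sum_c m_c\,\frac{m_c - (n_c - 1)}{(n_c - 2)(n_c - 1)},$$

where community $c$ has $m_c$ edges and $n_c$ induced nodes, and
two-node communities contribute zero. Ties among heights are broken
toward the lowest height (the finest partition), which is deterministic
and suits downstream trait filtering; edge clusters smaller than 2 edges
are treated as unclustered. The dense single-linkage implementation is
exact and deliberately refuses networks above 20,000 edges — the layers
this package targets are far smaller, and an approximate solver would
compromise the exhaustive-cut test oracle.

Module names follow `{collection}_{layer}_LCM{nnnn}` with a 1-based index
in deterministic order (descending edge count, ties by smallest gene id).

## Enrichment, module similarity, and the meta-network

Term enrichment is the one-sided Fisher exact test (hypergeometric upper
tail via `phyper`) of the 2×2 table (in module / not) × (has term / not)
against a background that defaults to all annotated genes. Raw $p < 0.01$
defines "enriched", with no multiple-testing cutoff — a deliberate echo of
the DAVID-style convention this field uses for descriptive module
annotation; a Benjamini–Hochberg column is emitted for information only.
GO terms are not propagated to ancestors.

Modules with ≥ 30 genes are compared pairwise: Jaccard on gene sets,
Cohen's kappa on enriched-term presence vectors. The kappa universe is the
union of terms enriched anywhere in the collection (a `pairwise` mode
restricts it to each pair); the collection-wide default makes kappa
comparable across pairs. Modules with no enriched terms have undefined
kappa and never form meta-network edges. The meta-network joins pairs with
kappa ≥ 0.5 **and** Jaccard ≥ 0.3, both bounds inclusive; requiring both
follows the stricter of the two published readings and both cutoffs are
configurable.

## Genetic features and trait overlap

Coordinates are 1-based inclusive throughout (GFF3 convention; BED input
is converted on read). QTLs shorter than 5 bp — single-marker placements —
are replaced by a 2 Mb interval centred on the original midpoint and
clamped to the chromosome; placement at the midpoint is our choice, the
span is the field's median QTL size. GWAS SNPs at $p \le 10^{-4}$ become
windows of 300 kb *total* span (±150 kb), the reported average extent of
linkage disequilibrium for the organism; a per-side mode (±300 kb) is
available. A gene inherits a trait when its interval overlaps a feature
interval by ≥ 1 bp.

Module–trait correspondence is again a one-sided Fisher test: module genes
versus trait-overlapping genes over a background defaulting to all genes
that are nodes in at least one layer (the sampling frame from which
modules arise). The test counts *genes*; the distinct features hit are
reported separately. This p-value is a false-positive guide, not a causal
claim: large QTLs, many QTLs per trait, and tandem gene arrays all inflate
overlap, and no correction for those is attempted. Edge highlighting
requires the union of an edge's two endpoint feature sets to contain at
least `min_features` distinct features, a monotone filter. Biomarker
queries return known SNPs within 50 kb of trait-overlapping module genes.

# The synthetic generators

`generate_compendium()` emulates exactly the data regime the layered
method is designed for. Genes follow a single-latent-factor model within
their home condition group: value = baseline + group offset + loading ×
latent + noise, with loading $= \sigma\sqrt{\rho/(1-\rho)}$ so the
expected within-module correlation is exactly $\rho$ (default 0.95) in the
home group and zero elsewhere. Defaults: 4 groups × 40 samples, 800
genes, 5 disjoint planted modules of 25 genes per group. Per-gene noise
defaults to $\sigma = 0.4$ on the log2 scale and per-gene condition
offsets to sd 1.5 — values chosen once as representative of residual
array noise and of typical between-condition fold changes; the offsets
are what makes sample clustering able to recover the groups and what
makes pooled correlations misleading, the two sides of the dilution
premise. All randomness derives from one root seed through fixed
per-stage offsets, so every stage is independently reproducible.

`generate_genome()` places the genes without overlap on a 5 × 30 Mb toy
genome. One planted module per group is "targeted": its genes occupy
consecutive positional slots so a single QTL can cover them (the package
asserts ≥ 80% coverage), with two significant GWAS SNPs planted inside
the region; decoy QTLs with their own traits are placed uniformly, as are
trait-less marker SNPs for biomarker queries. Files are emitted in the
standard formats the readers consume (GFF3 via rtracklayer, TSV, VCF).

What the generators do **not** emulate: probe-level artifacts (mismatch
probes, saturation), heavy-tailed intensity distributions, batch effects
within a condition group, correlated noise between modules, overlapping
planted modules, and realistic linkage-disequilibrium structure. Passing
the recovery and calibration suites therefore demonstrates correctness of
the machinery under the stated model, not performance on real arrays.

# Validation strategy and problem sizes

The test suite validates each layer of machinery against an independent
oracle: correlations against a two-pass textbook implementation;
enrichment and trait p-values against direct log-space hypergeometric
tail summation (to $10^{-12}$, backgrounds up to 2,000 genes); the
link-community cut against exhaustive partition-density maximization over
all dendrogram heights (graphs up to 30 edges, with single-linkage
clusters recomputed independently as connected components); edge
highlighting against per-edge brute force. Statistical calibration uses
100 seeded replicates each of Exponential(1) spacings (must accept
Poisson) and 500 × 500 GOE spectra (must reject), 200 random placements
of trait features over 20 random modules (the fraction of $p < 0.05$
must sit near the nominal level), and 10 replicate compendia for the
dilution contrast (a pooled network must recover strictly fewer planted
within-module edges than the per-group layers summed). End-to-end runs
use the default fixture above; these sizes keep the whole suite in the
low minutes on a single CPU while leaving every statistical check
adequately powered.

Arithmetic conventions for collection summaries follow the published
rice collection that `inst/extdata/` ships for cross-checking: means to
one decimal, medians as the midpoint of the two central sorted values,
average degree $2E/N$ to two decimals, and redundancy fractions as whole
percentages of distinct nodes but of summed (per-layer) edges.

# Known limitations

* The three sample-level outlier statistics (mean distance to other
  samples, Kolmogorov–Smirnov distance to the pooled intensity
  distribution, one minus median correlation), each fenced at
  Q3 + 1.5 IQR with removal on ≥ 2 of 3 failures, are a stated stand-in
  for the unnamed tests of the original array-QC tooling. Like that
  tooling they are fooled by strong imbalance: a small minority condition
  group in an otherwise homogeneous compendium can be flagged wholesale.
  With three or more comparably sized groups the fences adapt correctly.
* The dense single-linkage edge clustering is exact but quadratic in
  edge count; it is intended for per-layer networks, not for pooled
  compendium-scale graphs.
* Fisher trait overlap inherits every caveat of interval-based trait
  assignment; in particular tandem arrays of co-expressed paralogs make
  module genes non-exchangeable and the p-values anticonservative.
* The pipeline assumes probe-level normalization has already produced a
  log2-scale matrix; only a `log2(x+1)` convenience transform is offered.
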
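---
title: "Metacell partitioning of UMI matrices: model, algorithm and diagnostics"
author: "metacellr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metacell partitioning of UMI matrices: model, algorithm and diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metacellr)
```

## The model: metacells as multinomial pools

Droplet scRNA-seq counts unique molecules (UMIs). For a cell `i` with
depth `u_i` (total molecules) sampled from a transcriptional state with
gene frequencies `p_g`, the count vector `u_.i` is well approximated by a
multinomial draw of `u_i` molecules from `p`. A *metacell* is a group of
cells intended to be statistically indistinguishable from repeated
multinomial draws from one shared pool: within a metacell, all residual
variation should be sampling noise. A metacell partition is a set of
disjoint cell groups `M_k` plus an outlier set `O` whose union is the
whole dataset (the *cover law*). Downstream, each metacell is summarized
by one regularized frequency profile, which turns sparse noisy single-cell
vectors into a modest number of robust expression states without forcing
a global low-dimensional model.

No global parametric model of the full dataset is assumed: similarity is
modeled non-parametrically, and the multinomial assumption is only
applied *within* candidate metacells, where it is testable (see
Diagnostics).

## Feature genes

Similarities are computed over a feature gene set `F`, never over
principal components, so that downstream tests can reason about
individual genes. `gene_stats()` computes, per gene:

* **total UMIs** and the number of cells carrying at least 3 UMIs;
* a **normalized size correlation**: the Pearson correlation of the
  gene's counts with cell depth, minus the mean correlation of
  expression-matched genes (20 equal-occupancy bins by gene total). The
  binning removes the mechanical trend that ties raw depth-correlation to
  mean expression; strongly negative values mark genes whose expression
  is decoupled from depth.
* a **niche score**: the fraction of the gene's UMIs carried by its top
  5% highest-count cells, minus the expectation of that fraction under
  multinomial sampling. The expectation is computed deterministically
  from a Poisson order-statistic threshold form at the gene's mean rate:
  with `t` the count level where roughly `0.05 n` cells are expected
  above it, the expected top fraction takes all mass above `t` plus the
  remainder at `t`. For sparse genes this expectation is itself near 1
  (all molecules land in few cells even under the null), which keeps the
  score calibrated across expression levels. Genes expressed in a small
  cell niche score high.
* a **variance/mean ratio** of depth-equalized counts, an alternative
  selection criterion (`var_mean_min`) for designs — such as continuous
  gradients — where expression varies broadly rather than in niches.

The default thresholds (total ≥ 300 UMIs, ≥ 3 UMIs in ≥ 3 cells,
normalized size correlation < −0.1 or niche score > 0.1) follow the
published whole-organism analyses. The exact statistics are surrogates
with documented definitions, deliberately isolated behind the statistics
table so alternatives can be swapped in.

## The balanced K-nn similarity graph

Counts restricted to `F` are transformed as `log2(eps + u_gi)` (default
`eps = 1`) and cells are compared by Pearson correlation, giving `R`.
Optionally the matrix is first down-sampled to the minimum depth; with
highly variable depth distributions this is skipped and the rank
transform absorbs the bias. Each row of `R` is then rank-transformed
(rank 1 = most similar neighbor; ties break toward the lower cell index)
and balanced in three steps:

1. `s1_ij = max(alpha*K^2 − s_ij * s_ji, 0)` — the rank *product*
   symmetrizes the structure; only mutually well-ranked pairs survive
   (`alpha = 10`). Rank 1 must mean "most similar" for this clipping to
   retain mutual best neighbors, which fixes the rank orientation.
2. `s2_ij = max(beta*K − rank_i(s1_ij), 0)` — each node keeps at most
   `beta*K` incoming edges (`beta = 3`).
3. `a_ij = max(K − rank_j(s2_ij), 0)` — each node keeps at most `K`
   outgoing edges.

Zero entries are deleted edges and are never ranked. Since ranks are
1-based, at most `K − 1` outgoing edges carry positive weight. Outlier
cells lose their edges during balancing and may disconnect entirely —
that is a feature: attraction of outliers to large homogeneous groups is
exactly the effect the balancing suppresses, and the in-degree variance
of the balanced graph is measurably lower than a naive top-K graph's on
hub-and-satellite structures.

## Seeded graph partitioning

The graph is partitioned by an adaptation of k-means to graphs, in two
stages (implemented in C++ for the resampling loop; every random draw
goes through R's RNG, so a single integer seed reproduces a run exactly).

**Seeding.** The cover-free score `f(i)` counts a cell's outgoing
neighbors not yet covered. While any uncovered cell has `f > size_min`, a
seed is drawn from the uncovered cells with probability proportional to
`f^3` and claims itself plus its uncovered out-neighbors. Cubing the
score strongly favors seeds in untouched dense territory.

**Optimization.** Cells are visited in a reshuffled random order each
pass and reassigned to the subgraph maximizing
`w_ik = wi_ik * wo_ik / |M_k|^2`, the product of incoming and outgoing
edge-weight association normalized by subgraph size. The current
subgraph's score is inflated by `stickiness^pass` (default 1.01), which
turns potential oscillations between equally good subgraphs into
geometric convergence; ties break toward the current subgraph, then the
lowest label. Cells whose association products are all zero (for
instance, a cell with only outgoing edges into one subgraph) fall back to
the additive score `wi + wo`, so every cell in a seedable component is
eventually absorbed; only cells in connected components smaller than
`size_min` stay unassigned and become outliers. A pass touches each edge
a bounded number of times, so the whole procedure is linear in the edge
count.

## Bootstrap consensus

A single partition is sensitive to seeding. `resample_partitions()` runs
the partitioner on `n_boot = 500` resamples (each cell kept independently
with probability `rho = 0.75`), tallying for each cell pair how often it
was co-sampled (`o_ij`) and co-assigned (`c_ij`). Each resample consumes
its own derived RNG stream, so the tallies are independent of execution
order. The co-occurrence frequencies `s_boot = c/o` (0 for pairs never
co-sampled, which carry no evidence) are thresholded into a consensus
graph: `T_i` is cell `i`'s `k_core`-th largest frequency (its smallest
positive one if fewer exist), and a pair keeps an edge iff
`s_boot_ij > max(T_i, T_j) * 0.5`. Degrees are intentionally not capped —
diffuse clusters earn higher degrees than tight ones, and `k_core`
(default 30) is the user's control over that. The final cover comes from
re-running the partitioner on this graph (each undirected edge handed to
it as two unit arcs), with `size_min = 30` and, by default, dissolution
and reassignment of any subgraph that ends below `size_min` — the
published whole-organism runs use an explicit minimum metacell size, and
the optimizer can otherwise shrink a seeded subgraph below it.

Convergence on dense consensus graphs takes up to ~90 passes at
stickiness 1.01, hence `max_passes = 100` in the pipeline configuration;
small graphs converge in far fewer.

## Outlier filtering and homogeneity splitting

Given a cover, pool frequencies are `p_gk = sum_i u_gi / sum_i u_i` over
members. Each cell is screened by the regularized observed/expected fold

`f_gi = log2((1 + u_gi) / (1 + u_i * p_g,mc(i)))`

and cells with any gene at `f_gi >= t_lfc` (default 3, i.e. 8-fold or
more; inclusive) are moved to the outlier set in a single pass — pool
frequencies are deliberately not re-estimated iteratively. The `+1`
regularization caps attainable enrichment for low-count genes (a gene
observed at ≤ 3 copies can never exceed `f = 2`), so flags require real
molecular support. Doublets — droplets with two lysates — appear as cells
with a coherent foreign signature and are this filter's main target.
When many identical doublets exist they can instead aggregate into a
doublet *metacell* that the filter rightly finds internally consistent;
such metacells are curated manually via `drop_metacells()`, and the
package's doublet-recovery validation therefore embeds spiked doublets in
their parent-type metacells to measure the detector itself.

`split_heterogeneous()` guards against two distinct states glued into one
metacell: per metacell, genes with intra-metacell variance/mean > 1.2 (on
depth-equalized counts) are selected, cells are clustered by DBSCAN on
correlation distances over those genes, and a detected multi-cluster
structure splits the metacell. The DBSCAN radius defaults to the largest
per-cell `min_pts`-th nearest-neighbor distance (with `min_pts = 4`):
every cell is then a core point, noise is impossible, and a split occurs
only when sub-populations are separated by more than any local
neighborhood radius. This choice is robust both to balanced 50/50
mixtures and to small planted minorities, while homogeneous multinomial
metacells essentially never split; quantile-of-all-distances radii were
evaluated and discarded because they adapt to the dominant cluster and
miss minorities. Split pieces smaller than the minimum metacell size
become outliers — they are exactly the rare states too scarce to support
a metacell.

## Expression profiles

Metacell expression uses a regularized geometric mean,

`p_gk = (exp[mean_{i in M_k} log(1 + u_gi)] − 1) / mean_{i in M_k}(u_i)`,

which maps genes absent from a metacell to exactly 0 and damps
single-cell outliers relative to the arithmetic pool. The printed form of
this expression is typographically ambiguous about whether the `− 1`
sits inside or outside the exponent; the outside reading is the default
because the inside one merely rescales every value by `exp(−1)`, and both
are available behind a switch. Relative expression is

`lfp_gk = log2((p_gk + eps) / median_k'(p_gk' + eps))`

with `eps = 1e-4` by default, to be adapted to the typical metacell
molecule total. With an odd number of metacells each gene's median lfp is
exactly 0, and changing the metacell composition shifts a gene's lfp row
by an additive constant as long as the median metacell is preserved. The
practical resolution of lfp is set by pool sampling noise: the relative
error of `p_gk` for a gene with mean count `m` per cell in a pool of `n`
cells scales like `1/sqrt(n m)`, so flatness bounds such as
`|lfp| < 0.05` are only meaningful when pools reach millions of molecules
(the packaged uniform-profile validation uses 3 pools of 16M).

## Diagnostics

**Closure.** Per metacell, the fraction of incident balanced-graph edges
with both endpoints inside. Isolated states approach 1; metacells tiling
a large connected population sit much lower without being wrong.

**Multinomial adherence.** Within each metacell, cells are down-sampled
to common totals `T` and each gene is scored by the binomial
log-likelihood of its per-cell counts and by over-dispersion
(observed/expected binomial variance, averaged over 10 independent
down-samples). The empirical p-value is an *exact conditional test*:
conditional on the gene's total `s` in the down-sampled metacell,
multinomial sampling makes the cells exchangeable and the placement of
the `s` molecules is multivariate hypergeometric — independent of the
unknown pool frequency. The likelihood then reduces, up to a constant in
`s`, to `sum_i lchoose(T, c_i)`, and the observed value is ranked among
`n_null = 999` placements (sampled exactly; a multinomial approximation
is used for sparse genes where it is indistinguishable). Parametric
alternatives that draw fake matrices from *estimated* pool frequencies
were evaluated and found miscalibrated at desk scale — conservative when
the likelihood is evaluated at a fixed plug-in frequency, underdispersed
when re-profiled per draw — while the conditional construction is uniform
by design. Ties are resolved by randomized p-values (uniform under the
null for discrete statistics) floored at `1/(n_null + 1)`; genes absent
from a down-sampled pool get NA. Per-metacell coefficient-of-variation
and zero-fraction curves against Poisson expectations round out the
report.

Calibration is a property of the statistic given a *data-independent*
cover. When the cover is estimated from the same data, cells are grouped
partly because their noise aligns, and the p-values become conservative —
expected behavior, not a defect. The packaged null calibration therefore
scores an arbitrary block cover of a pure multinomial dataset.

**Residual correlations.** Gene-gene Pearson correlations of
log-transformed, depth-equalized counts, averaged across metacells, are
compared with the same computation after a seeded permutation of the
metacell labels. Between-state covariation reappears under permutation,
so structure visible only in the unpermuted within-metacell average is
residual intra-state biology the cover failed to absorb.

**Cross-validated expression prediction.** Genes are split into
`n_folds` folds (100 by default; the packaged studies use 20). Per fold,
the raw similarity matrix — and for the metacell strategy a fresh direct
(seed + optimize) partition — is rebuilt on the remaining genes only, and
each held-out gene's per-cell frequency is predicted from a pool around
the cell: the cell's metacell, or its top-50 neighbors in the raw
similarity matrix. A cell is never in its own pool. Pool frequencies use
`(exp[mean log2(1 + 7 u_gi)] − 1) / mean depth`; the literal 7 follows
the printed formula and is exposed as `pool_multiplier` (it affects the
monotone transform only, not the ranking of predictions). Rebuilding the
full bootstrap consensus per fold would multiply cost ~500-fold for no
change in the compared quantity, so the fold-level cover is the direct
partition; feature selection is likewise held fixed across folds.
Per-gene Pearson correlations between predicted and observed frequencies
rise with expression (sampling variance falls), and the no-CV minus CV
gap is systematically larger for raw k-nn pooling than for metacell
pooling — the metacell cover is the less over-fit local approximation.

## 2D projection

Balanced-graph edges are projected onto metacell pairs,
`b_ml = K^2 / (|M_m||M_l|) * sum ceil(a_ij / C)` with `C` the median
metacell size, symmetrized as the sum of the row- and column-normalized
forms. Each metacell contributes its `d_max = 4` best candidate edges
above `t_edge = 0.08` (defaults; the construction bounds the added
degree, not the received one). The metacell graph is embedded by a seeded
Fruchterman-Reingold layout, components laid out independently and
packed on a grid; a single metacell sits at the origin. Cells are placed
at the unweighted average of their neighbors' metacell coordinates after
discarding neighbors whose metacell is neither the cell's own nor
adjacent in the metacell graph; cells with no admissible neighbor fall
back to their metacell's position, and outliers adopt the position of
their strongest neighbor's metacell (flagged as such).

## The synthetic generator

`synth_generate()` draws each cell as a multinomial sample of its depth
from a type profile; depths default to lognormal(log 800, 0.4) to
exercise the no-down-sampling similarity path. Gradients mix two anchor
profiles with `lambda ~ Uniform(0,1)`; doublets average two distinct type
profiles at double depth (two lysates); rare outlier populations get
their own profile. The versioned presets fix the study conditions:
`five_types` (5 profiles at pairwise total variation ≥ 0.4, 300 cells
each, 600 genes), `gradient` (two anchors of 150 cells plus 600 mixture
cells), `doublet_spike` (2 × 490 cells, 2% doublets), `null_multinomial`
(one type, 1000 cells, fixed depth 800). Profiles are built
deterministically from a power-law backbone with boosted type-private
blocks.

What the generator does *not* emulate: batch effects, ambient RNA
contamination, gene-length or capture biases, transcriptional bursting
beyond multinomial noise, and continuous depth-state confounding. Tests
passing on these fixtures therefore demonstrate algorithmic correctness
and calibration under the stated model, not robustness to every real-data
artifact.

## Numerical and design choices

* Ties everywhere (ranks, argmax) break toward the lower index /
  current assignment, making every stage deterministic given its seed.
* One explicit integer seed per stochastic operation; derived streams
  (`seed + b`) for resamples keep tallies order-independent. All seeds
  stay below 2^31.
* Degenerate inputs: all-zero genes yield zero statistics (never NaN);
  zero-variance cells get zero similarity with a warning; metacells
  emptied by filtering are dropped with a warning; an empty feature
  selection or an all-removed cell filter is an explicit error.
* Matrix orientation is genes × cells throughout; readers normalize.
* Problem sizes in the packaged studies (1,000–6,000 cells, 600 genes,
  20 CV folds, 100–500 resamples) were chosen so the full validation
  suite runs in minutes on one CPU while keeping every statistical
  property measurable at its stated tolerance.

## Known limitations

* Feature-selection statistics are documented surrogates; niche-style
  selection is weak for smooth gradients (use `var_mean_min` there).
* The parametric outlier filter cannot flag doublet *metacells*; those
  require curation (`drop_metacells()`).
* `lfp` values are comparable within one cover only, up to an additive
  constant across covers.
* The partition offers no formal guarantees on subgraph size
  distribution; the minimum-size enforcement is a post-processing
  contract, not an optimality statement.
* With very small metacells (< ~5 cells) the adherence diagnostics lose
  power and are skipped below 3 cells.
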
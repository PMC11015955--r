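---
title: "Graph-regularized multi-view ensemble clustering: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-regularized multi-view ensemble clustering: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grmec)
```

## The problem

Single-cell multi-omics assays (CITE-seq, paired scRNA-seq/scATAC-seq)
measure several feature modalities on the same cells. Each modality carries
partial, noisy information about cell identity, and no single clustering
method is reliable across modalities and data sets. `grmec` clusters cells by
combining two complementary sources of evidence in one optimization:

* the omics matrices themselves, through a **weighted joint nonnegative
  matrix factorization** that learns one shared low-dimensional cell
  representation, and
* a collection of **base clustering results** (any methods, run per
  modality), through a weighted consensus over their binary co-cluster
  indicator matrices.

## Model

Let $X^v \in \mathbb{R}_{\ge 0}^{n \times p_v}$, $v = 1, \dots, m$, be the
omics views over the same $n$ cells, and let $P^{rv}$, $r = 1, \dots, q$, be
base clustering labelings of those cells, encoded as binary co-cluster
indicators $S^{rv}_{ij} = \mathbb{1}[p^{rv}_i = p^{rv}_j]$. The model jointly
learns

* $W \in \mathbb{R}_{\ge 0}^{n \times k}$ — consensus cell representation,
* $V^v \in \mathbb{R}_{\ge 0}^{k \times p_v}$ — per-view bases,
* $S \in \mathbb{R}_{\ge 0}^{n \times n}$ — consensus co-cluster affinity,
* $H \in \mathbb{R}_{\ge 0}^{n \times C}$ — soft cluster indicator with
  $\sum_c H_{ic} = 1$,

by minimizing

$$
\mathcal{L} \;=\; \sum_v w_v \lVert X^v - W V^v \rVert_F^2
\;+\; \lambda_1\, \mathrm{tr}(W^\top L_H W)
\;+\; \sum_{r,v} \alpha_{rv} \lVert S - S^{rv} \rVert_F^2
\;+\; \lambda_2\, \mathrm{tr}(H^\top L_S H),
$$

where $L_H$ is the graph Laplacian of $S_H = H H^\top$ and $L_S$ that of
$S$. The first coupling pulls cells that $H$ considers co-clustered toward
nearby rows of $W$; the second pulls cells with high consensus affinity
toward equal rows of $H$. The view weights and base-result reliabilities are
self-tuned, $w_v = 1/(2\lVert X^v - W V^v\rVert_F)$ and $\alpha_{rv} =
1/(2\lVert S - S^{rv}\rVert_F)$, so poorly reconstructed views and outlying
base results are down-weighted without extra hyper-parameters. Hard labels
are the row-wise argmax of $H$ (ties to the lowest column index).

## Optimization

All four factors are updated by multiplicative rules, one sweep being
$W \to \{V^v\} \to S \to H \to (w, \alpha)$, followed by evaluation of
$\mathcal{L}$:

* $W \leftarrow W \circ \dfrac{\sum_v w_v X^v V^{v\top} + \lambda_1 S_H W}
  {W \sum_v w_v V^v V^{v\top} + \lambda_1 D_H W}$ — the Laplacian is split
  into its degree part (denominator) and affinity part (numerator), the
  standard construction that keeps the update nonnegative while leaving the
  fixed points unchanged;
* $V^v \leftarrow V^v \circ (W^\top X^v) / (W^\top W V^v)$;
* $S \leftarrow S \circ \dfrac{4\sum_{rv} \alpha_{rv} S^{rv}}
  {4\sum_{rv}\alpha_{rv} S + \lambda_2 D^h}$ with
  $D^h_{ij} = \lVert H_{i\cdot} - H_{j\cdot}\rVert_2^2$, then symmetrized;
* $H \leftarrow H \circ \dfrac{\lambda_2 S H}
  {(\tfrac{\lambda_1}{2} D^W + \lambda_2 D_S) H}$ with
  $D^W_{ij} = \lVert W_{i\cdot} - W_{j\cdot}\rVert_2^2$, then each row is
  divided by its sum (rows that collapse to zero are reset to the uniform
  $1/C$ and counted; `fit` warns if any occur).

Every denominator is floored at `denom_floor` ($10^{-10}$) via `pmax`, so
the algebraic cancellations of the rules (e.g. a single base result is
reproduced exactly by one $S$-update when $\lambda_2 = 0$) hold bit-exactly.
Weight residuals are floored at `residual_floor` so an exact fit keeps the
weights finite.

### Two safeguards the update rules need

Two failure modes of the plain update loop surfaced during development, and
the defaults guard against both; each can be switched off.

**Scale drift (`normalize_W = TRUE`).** The factorization $W V^v$ is
invariant to $W \to W D$, $V^v \to D^{-1} V^v$, but the graph penalty
$\lambda_1 \mathrm{tr}(W^\top L_H W)$ is not: it is cheapest when $W$ is
small, so the updates steadily push scale out of $W$ into the $V^v$. As
$\lVert W\rVert \to$ small, $D^W \to 0$ and the $H$-update degenerates into
pure diffusion on $S$, whose fixed point has all rows of $H$ equal — the
clustering dissolves even when $W$ and $S$ carry perfect structure. The
remedy is the usual one in multi-view factorization: after each sweep the
columns of $W$ are rescaled to unit Euclidean norm and the inverse scaling
is pushed into every $V^v$. Reconstructions are unchanged; the coupling
keeps its strength.

**Column lock-in (`init = "spectral"`).** Multiplicative updates can only
rescale entries of $H$; they cannot re-mix its columns. Starting from a
structure-blind uniform random $H$, the early sweeps smooth $H$ through a
still-random $S$, and whichever column pattern survives is then locked in —
partitions that merge two well-supported clusters (and split another to keep
$C$ columns) are stable fixed points that restarts do not escape. The
default therefore seeds $H$ from the ensemble's own signal: k-means on the
top $C$ eigenvectors of the mean base co-cluster indicator, softened as
$0.9\,\mathbb{1}[\cdot] + 0.1/C$ so no entry starts at a multiplicatively
locked zero. `init = "random"` restores the plain seeded uniform(0,1)
initialization of all factors.

### Monotonicity of the objective trace

Each factor update is a majorization step and does not increase
$\mathcal{L}$ at fixed weights; this is asserted per-step in the tests. Two
bookkeeping steps are not descent steps for the *evaluated* trace: re-tuning
$(w, \alpha)$ changes the value of the weighted terms (upward when residuals
just shrank), and the $W$-normalization changes the $\lambda_1$ term. In
practice the recorded trace decreases monotonically on the battery of random
instances in the test suite; transient relative increases of order $10^{-5}$
can occur for large $\lambda_2$, and `grmec()` warns whenever one exceeds
the $10^{-8}$ band. The trace stores the initial objective (at weights
$w_v = 1/m$, $\alpha_{rv} = 1/(qm)$) followed by one value per sweep.

### Stopping

The loop stops when $|\mathcal{L}_{t-1} - \mathcal{L}_t| \le
\texttt{tol}\,|\mathcal{L}_t|$ (default $10^{-6}$) or after `max_iter`
(default 200) sweeps. The reconstruction term dominates the objective, so
the relative change mainly tracks the factorization; the indicator keeps
refining at small objective decrements, which is why the default tolerance
is not larger.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `lambda1` | 0.1 | strength of the representation–indicator coupling |
| `lambda2` | 0.01 | strength of the affinity–indicator coupling |
| `k` | 50 | latent dimension of the consensus representation |
| `C` | — | number of clusters (required) |
| `tol`, `max_iter` | 1e-6, 200 | stopping rule |
| `denom_floor`, `residual_floor` | 1e-10 | numerical floors |
| `init` | `"spectral"` | `H` initialization (see above) |
| `normalize_W` | `TRUE` | per-sweep unit-norm columns of `W` |

The defaults for `lambda1` and `lambda2` are the recommended operating
point; both graph terms lose their influence when set to 0 and dominate the
factorization when set very large. `k` should comfortably exceed `C`; values
above `min(n, p_v)` trigger an over-parameterization warning.

## Preprocessing

`preprocess_views()` applies, per view: removal of cells whose zero fraction
exceeds `zero_cutoff` (default 0.95 — conservative, removing only near-empty
cells; survivors are intersected across views), selection of the `n_hvg`
most variable features (default 1000) by mean-binned standardized dispersion
on the log1p scale (dispersions `var/mean`, z-scored within 20
equal-frequency mean bins; ties broken by higher mean then feature id;
constant features are never selected), and library-size normalization to the
median library followed by `log1p` (recommended for count views; `none` for
small antibody panels). ATAC peak matrices are accepted as provided; peak
calling and selection are out of scope.

## The synthetic-data generator

`simulate_multiomics()` draws data from exactly the structure the model
assumes: a planted partition of $n$ cells into $C$ clusters, a shared
nonnegative latent representation whose cluster means differ by `separation`
in one latent coordinate per cluster (baseline uniform(0.05, 0.25), log-normal
cell jitter of sd 0.1), per-view nonnegative bases, log-normal multiplicative
noise (`noise_sd`, default 0.1), Poisson counts scaled to a mean library of
`count_scale` (default 2000; negative binomial available via `nb_size`), and
independent dropout zeroing. Every component draws from its own named
random stream, so adding a view never changes earlier views.

`corrupt_labeling()`/`simulate_base_set()` manufacture base clusterings by
independently replacing each cell's label with a uniform different one at a
given error rate — controlled-quality stand-ins for external tools.

What the generator does **not** emulate: realistic mean–variance
relationships beyond Poisson/NB, batch effects, doublets, spatially
correlated base-clustering errors (real tools err on boundary cells, not
uniformly), or the heavy feature-count asymmetry of real ATAC panels.
Passing tests on this generator demonstrate the optimizer's correctness and
the pipeline's mechanics, not performance on real tissue.

The recovery battery in the tests uses $n = 300$, $C = 4$, $m = 2$,
$p = (500, 200)$, $q = 3$, base error rate 0.1, separation 3, dropout
$(0.3, 0)$, and $k = 20$, ten seeds; the built-in-clusterer checks use
$n \le 80$; the scaling check times single sweeps at
$n \in \{250, 500, 1000, 2000\}$. These sizes keep the whole suite at a few
minutes on one CPU while leaving the $n^2$ terms clearly visible.

## Numerical choices and degenerate inputs

* Labels are encoded to 0-based contiguous integers in order of first
  appearance, with the original strings retained; writing and re-reading a
  label file reproduces the encoding exactly.
* `select_hvg` errors on an all-constant matrix (no variability signal);
  `filter_cells_by_zero_count` errors when every cell would be dropped;
  `normalize_counts` errors on cells with zero total count, naming them.
* `assign_labels` breaks argmax ties toward the lowest column index.
* An exact factorization or an exact consensus match floors the
  corresponding weight at $1/(2 \cdot 10^{-10})$ rather than diverging.
* With $\lambda_2 = 0$ the $H$-update numerator vanishes; all rows are reset
  to the uniform $1/C$ (with a warning), which is the update's literal
  limit.
* The consensus matrix is stored dense; the practical ceiling is around
  $n \approx 10^4$ cells, consistent with the $O(n^2)$ per-sweep terms.

## Evaluation tools

`adjusted_rand_index()` implements the permutation-model ARI from the
contingency table; `normalized_mutual_information()` normalizes mutual
information by the arithmetic mean of the two entropies, with the convention
that a single-cluster partition scores 0. `rank_markers()` ranks features
per cluster (one vs rest) by two-sided Wilcoxon rank-sum tests in the normal
approximation with tie and continuity correction, reporting the in-cluster
rank sum, raw p-values (no multiple-testing correction — the use case is
ranking), and in/out means.

## Known limitations

* No automatic choice of $C$, $\lambda_1$, $\lambda_2$; no convergence proof
  for the full loop (see the monotonicity discussion above).
* The dense $n \times n$ consensus limits scalability; no mini-batching or
  GPU path.
* Base clusterings must share the target $C$ across runs only in the sense
  that the ensemble consumes co-membership; labelings with any number of
  clusters are accepted.
* Cell matching across views is by shared identifiers only (intersection +
  reorder); no imputation of missing cells.
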
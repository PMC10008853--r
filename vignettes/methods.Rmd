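---
title: "Methods: semi-supervised multi-objective clustering with constraint selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-supervised multi-objective clustering with constraint selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical machinery inside `ssmoc`, the
choices made where the design was genuinely open, and what the synthetic
benchmarks do and do not demonstrate.

## The model

The input is an expression matrix of $n$ genes in $d$ conditions, min-max
normalized per condition so every value and every cluster prototype lives
in $[0,1]^d$. A fuzzy partition is a membership matrix $U \in
\mathbb{R}^{n\times k}$ with unit row sums and prototypes $V \in
[0,1]^{k\times d}$. Two objectives are minimized jointly:

* the **Xie–Beni index**
  $XB = \sum_c \sum_i u_{ic}^2 \lVert x_i - v_c\rVert^2 \big/
  \big(n\,\min_{f\neq c}\lVert v_f - v_c\rVert^2\big)$,
  a ratio of fuzzy within-cluster scatter to worst-case prototype
  separation (coincident prototypes get an $\infty$ sentinel so the
  evolutionary selection discards them);
* a **quadratic-regularized fuzzy c-means objective with a
  constraint-violation penalty**
  $J_P = \sum_c\sum_i u_{ic}\lVert x_i - v_c\rVert^2
  + \tfrac{\eta}{2}\sum u_{ic}^2
  - \tfrac{\beta}{2}\sum_{ij} w_{ij}\,\langle u_i, u_j\rangle$,
  where $w_{ij}$ is positive for must-link pairs (rewarding aligned
  membership rows) and negative for cannot-link pairs.

Memberships come from the closed-form stationary condition of the
quadratic regularization:
$u_{ic} = \tfrac1k + \tfrac1\eta u^{FCM}_{ic} + \beta\, u^{P}_{ic}$ with
$u^{FCM}_{ic} = \tfrac1k\sum_f (d_{if}^2 - d_{ic}^2)$ and
$u^{P}_{ic} = \sum_j w_{ij} u_{jc} - \tfrac1k \sum_f \sum_j w_{ij}u_{jf}$.
Both deviation terms sum to zero over clusters, so rows sum to one
*analytically* — this identity is asserted in the tests at $10^{-9}$.
Because $u^P$ depends on $U$ itself, the update is iterated as a fixed
point: $u^P$ starts at zero, and sweeps stop when the largest membership
change falls below $10^{-6}$ or after 10 sweeps. The cap exists because
the stationary condition is circular and no iteration count is canonical;
in practice the affine map contracts in 2–4 sweeps at the default
$\beta$ values.

### Signed memberships and the prototype step

With small $\eta$ (default $0.001$) the data term is amplified a
thousandfold and memberships are strongly signed; we deliberately do
**not** clip them, because clipping destroys the exact row-sum identity
and the analytic form of the update. Crisp labels use the row argmax,
which is invariant to the amplification.

The prototype step, however, cannot use the raw signed weighted mean
$v_c=\sum_i u_{ic}x_i / \sum_i u_{ic}$: column sums of a signed $U$ pass
through zero and the quotient is unbounded (in experiments a
density-peak-initialized solution with ARI 0.96 collapsed to 0.48 after a
single such update). `recompute_prototypes()` therefore applies the
active-set projection standard for quadratic-regularized c-means: the
weighted mean is taken over the positive part $\max(U, 0)$, which
coincides with the textbook formula for every non-negative (crisp or
classical fuzzy) membership matrix. A cluster whose positive mass is zero
keeps its incoming prototype rather than producing NaNs.

## Constraint mining

**Density tracking.** `density_model()` computes densities (reciprocal
$b$-NN radius), successor chains (step to the closest strictly denser gene
within the current gene's $b$-neighbourhood), endpoints, groups (chains
sharing an endpoint), centralities and impurities. Ties — equidistant
neighbours, equal impurities — break toward the lowest gene index so runs
are reproducible. `expression_constraints()` then emits CL pairs
(high-impurity genes paired with their nearest out-group gene), boundary
ML pairs (chain successors passing the density drop test
$\text{Density}(x_j) \ge \varepsilon\,\text{Density}(x_e)$) and skeleton
ML pairs (chains walked at a stride, default 2). The stride and the
quotas are open parameters: no stopping rule is canonical, so a single ML
quota is consumed by the boundary pass first (ordered by impurity) and the
skeleton pass second (ordered by chain centrality), with
$n_{CL}=n_{ML}=\max(10, \lfloor n/20\rfloor)$ by default.

A structural caveat worth knowing: a chain endpoint is any gene with no
denser gene among its $b$ nearest neighbours, so a single Gaussian cluster
of ~50 genes routinely contains more than one endpoint and splits into
several density groups. Nearest-out-group CL pairs can then connect two
fragments of the *same* true cluster. This is intrinsic to the
construction, not a defect of the separation between clusters — and it is
exactly the kind of noisy constraint the selection mechanism downstream
exists to neutralise. The acceptance suite measures this honestly: ML
consistency on well-separated blobs is ~1.0, CL consistency is far below 1
whenever a blob fragments.

**Ontology similarity.** Term frequencies follow the true-path rule over
the loaded annotation set (the denominator is the number of annotated
genes, keeping the artifact self-contained rather than referencing an
external corpus). $IC=-\log p$, $SW = 1/(1+e^{-1/IC})$ with $SW:=1$ at
$IC=0$ by continuity (the root), $SV$ sums $SW$ over ancestors including
the term itself. Gene similarity is the best-match average; thresholds
0.9/0.1 are strict inequalities. Unannotated genes contribute no pairs
and `gene_similarity()` refuses them explicitly instead of returning a
silent 0.

**Fusion.** Pairs present only in the ontology set remain selectable but
carry weight 0 — every non-zero case of the fusion table requires
membership in the expression set. $\theta$ is constrained to $(0,1)$ by
default (values $\ge 1$ flip the sign of unconfirmed weights and only
produce a warning). Contradictory pairs are removed from both sets before
the candidate pool is formed.

## The evolutionary layer

Chromosomes concatenate a $k\times d$ real prototype block with $s$
distinct integers indexing a candidate pool of $2s$ constraints drawn
uniformly without replacement from the fused union. Initialization places
$\lceil N/2\rceil$ individuals on the density-peak prototypes (density
times distance-to-denser-gene, the standard peak score) and the rest
uniformly in $[0,1]^{k\times d}$.

Per generation: decode, restrict the weight matrix to each individual's
selected constraints, run the membership fixed point, write the
recomputed prototypes back into the chromosome (one Lamarckian step, so
the encoding stays consistent with its memberships), evaluate $(XB, J_P)$,
non-dominated sort with crowding, roulette selection with score
$\alpha(1-\alpha)^{rank-1}$ normalized over the population, normal
crossover on prototypes (one shared $|N(0,1)|$ draw per coordinate, which
makes the two offspring sum exactly to the parents pre-clamp),
single-point crossover with duplicate repair on selection blocks,
polynomial mutation (index $\eta_m$) and single-site random mutation, then
merge-and-truncate elitism. $\beta$ doubles at $\lceil 0.5L\rceil$ and
$\lceil 0.8L\rceil$; survivor fitness is re-evaluated at those points so
ranks stay comparable. With $s=0$ the penalty term is identically zero
and the algorithm reduces exactly to unsupervised two-objective
clustering — the test suite checks bit-identity of that reduction.

Default parameters: $\varepsilon=0.8$, $b=10$, $\eta=0.001$, $\beta=0.1$,
$N=100$, $L_{max}=300$, $\alpha=0.3$, $\eta_m=5$, $p_c=0.8$, $p_m=0.1$,
and $\theta=0.5$ (the midpoint of the useful range; the silhouette is
quite insensitive to $\theta$). One RNG seed drives pool sampling,
initialization and all genetic operators, so a run reproduces exactly.

## Final-solution selection and validation

The silhouette index ($a$ = mean within-cluster distance, $b$ = smallest
mean distance to another cluster, width $(b-a)/\max(a,b)$, singleton
clusters scored 0 since the width is undefined there; plain Euclidean
distances) selects the front member to report; ties break toward lower
$XB$, then lower $J_P$. Front members whose crisp labelling collapses to
one cluster are skipped. The adjusted Rand index scores recovery against
simulated ground truth.

## What the synthetic generator emulates

`simulate_expression()` draws $k$ isotropic Gaussian blobs whose means sit
at pairwise distance $\ge$ `separation`·$\sigma$, balanced across
clusters, then min-max normalizes. `simulate_ontology()` builds a
root–branch–leaf DAG whose branches mirror the clusters; each gene gets
2–4 terms from its own branch, a noise fraction from another branch, and
every leaf is guaranteed at least one annotation so information content is
defined everywhere. `simulate_constraints()` plus
`inject_constraint_noise()` give constraint sets with an exact, controlled
count of label-inconsistent pairs.

These fixtures deliberately omit features of real expression data:
time-course autocorrelation, heavy-tailed noise, unequal cluster sizes,
cluster overlap, and the incomplete, uneven depth of real GO annotation.
Passing the synthetic benchmarks shows the machinery is implemented
correctly and that constraint selection mitigates injected noise; it does
not by itself establish performance on microarray compendia.

Benchmark problem sizes used by the tests and the acceptance script —
chosen to exercise every code path while a full run stays in the minutes
range — are $n=200$, $d=10$, $k=4$ blobs at $6\sigma$ with population 40
and 50 generations (the full-scale defaults remain $N=100$, $L=300$). At
these sizes the unsupervised run already sits at the silhouette ceiling,
so constraints improve ARI (the constrained run reaches 1.0 where the
unsupervised stops at ~0.98) but not SI: the true labelling's silhouette
can be a few $10^{-4}$ *below* the SI-optimal labelling, a useful reminder
that SI is a proxy for, not a measure of, accuracy.

## Known limitations

* $k$ is fixed by the user; no variable-length encoding or automatic
  model-order selection.
* The membership update is the closed form as printed, with $\eta$
  controlling the magnitude of the (signed) memberships; alternative
  scalings from the quadratic-regularization literature are not offered.
* GO namespace filtering and evidence-code filtering are out of scope; all
  loaded terms form one DAG and only `is_a` edges are honoured.
* Density-group fragmentation (above) bounds the purity of mined
  cannot-link sets on diffuse clusters; treat mined CL constraints as
  noisy by default and keep constraint selection on.
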
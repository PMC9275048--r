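---
title: "Methods: differential gene-gene interaction networks"
author: "deggnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential gene-gene interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deggnet)
```

## The model

`deggnet` asks a different question than differential expression: not
*which genes change level between patient subgroups*, but *which
gene-gene relationships change*. The unit of inference is an edge of a
curated interaction network, and the quantity of interest is the
within-subgroup linear relationship between the two genes' log-scale
expressions.

For an edge between genes $x$ and $y$ (the lexicographically later gene
is always taken as the response; the orientation is recorded), with
subgroup $k$ and optional additive covariates $c_j$:

$$y_i = \beta_0 + \beta_1 x_i + \gamma_{k(i)} + \delta_{k(i)} x_i +
  \textstyle\sum_j \theta_j c_{ij} + \varepsilon_i$$

using treatment coding with the largest subgroup as reference. The
differential-interaction hypothesis is $H_0: \delta_k = 0\ \forall k$,
tested jointly by a Wald statistic on the interaction block with
$\mathrm{df} = G - 1$ for $G$ subgroups. For two groups this reduces to
the squared t of the single interaction coefficient.

### Robust estimation

Bulk RNA-Seq expression of individual patients is heavy-tailed relative
to the Gaussian, and a single outlying sample can fabricate or destroy
a slope difference. Fits therefore use the Huber M-estimator
(`huber_fit()`): IRLS with weights $\min(1, k s/|r_i|)$, tuning
constant $k = 1.345$ (95% Gaussian efficiency), residual scale $s$
re-estimated each iteration as the MAD about zero with consistency
factor 1.4826, convergence when the maximum relative coefficient change
drops below $10^{-8}$ (cap: 50 iterations). An exactly collinear
response degenerates the scale; it is floored at a machine-epsilon
multiple and flagged, and the least-squares solution is returned.

Coefficient covariance uses the classical sandwich-free M-estimator
formula $s^2 \kappa (X'X)^{-1}$ with
$\kappa = \frac{n}{n-p}\,\overline{\psi^2}/\overline{\psi'}^2$,
multiplied by the square of Huber's small-sample correction
$1 + p\,\mathrm{var}(\psi')/(n\,\overline{\psi'}^2)$. When no residual
is downweighted this reduces *exactly* to the OLS covariance, so the
test inherits least-squares behaviour on clean data (the test suite
asserts this equivalence against a closed-form solve).

### Why an F reference

The interaction p-value uses $F(W/\mathrm{df};\, \mathrm{df},\, n-p)$
rather than the asymptotic $\chi^2_\mathrm{df}$. At realistic cohort
sizes (tens of samples per subgroup) the chi-square reference is
visibly anti-conservative: in the package's own null simulations at 83
samples across three subgroups the chi-square version rejects at
~0.08 against a nominal 0.05, while the F version sits near the
nominal level. The acceptance suite recomputes this calibration (500
null replicates at 200 samples per group).

A residual limitation survives the F correction: the slope *contrast*
between subgroups draws most of its information from the smallest
subgroup, so the statistic's effective degrees of freedom are smaller
than $n - p$ and the far tail ($p \lesssim 10^{-3}$) of the null
distribution remains mildly heavy — roughly 1.5–2× the nominal
exceedance in our simulations with subgroup-shifted baselines. Where
this matters is Benjamini–Hochberg selection in scans with one strong
signal, whose effective per-edge threshold lives in exactly that tail:
the measured false-discovery proportion of a 1-planted/99-null scan
averages ≈0.07 rather than the ≤0.05 BH would guarantee for exactly
valid p-values. Permutation p-values would close the gap but are out
of scope; users needing strict FDR control at small $n$ should treat
`p_adj` near the threshold with caution.

## Network construction

* **Merging.** Curated networks are undirected simple graphs; merging
  unions nodes and edges and accumulates per-edge provenance tags.
  Direction of source relations (e.g. TF→target) is deliberately
  dropped: the edge test treats pairs symmetrically up to the recorded
  orientation convention.
* **Weighting.** Node weight in subgroup $k$ is the arithmetic mean
  log-expression of the gene over that subgroup's samples. The same
  global network is replicated per subgroup; only weights differ.
* **Percentile threshold.** `filter_by_weight()` removes nodes with
  weight *strictly below* the threshold (ties at the threshold are
  kept). The threshold is the linear-interpolation percentile
  (`quantile` type 7) of the node weights. The convention is fixed and
  documented because different percentile definitions change node sets.
  The default percentile is 75.
* **Percolation scan.** `percolation_scan()` profiles, along a
  percentile grid, the retained node count, the giant-connected-
  component (GCC) fraction and the second-largest component size. Two
  selection rules are exposed: the largest grid percentile whose GCC
  fraction still exceeds a floor (default 0.5), and the argmax of the
  second-component size (the classical percolation-transition
  diagnostic). Retained node count is non-increasing along the grid and
  the suite asserts that; the GCC *fraction* is deliberately not
  asserted monotone — pruning an isolated low-weight node shrinks the
  denominator without touching the GCC, so the fraction can rise.
* **Specific networks.** An edge belongs to subgroup $k$'s specific
  network iff it survives filtering in $k$ and in no other subgroup;
  edges surviving in two or more are discarded from all. Disjointness
  and conservation (specific sets + discarded = union of filtered sets)
  are asserted on every run of the property suite.

## Response models

Samples labelled *Moderate* (or unlabelled) are excluded; the outcome
is Good = 1, None = 0, each class requiring at least 3 samples. For a
gene pair the model is

$$\mathrm{logit}\,P(\mathrm{Good}) = \beta_0 + \beta_1 g_1 + \beta_2 g_2
 + \beta_3 (g_1-\bar g_1)(g_2-\bar g_2) + \textstyle\sum_j \theta_j c_j$$

fitted by Newton/IRLS (tolerance $10^{-8}$, 100 iterations max; the
suite checks the score vector's max-norm at the optimum). The
"gene-ratio" interaction defaults to the centered product of the two
log-expressions: on log-scale data a literal log-ratio $g_1 - g_2$ is
exactly collinear with the two additive terms and cannot carry
independent signal, so the product is the only non-degenerate reading;
a raw-scale ratio covariate ($2^{g_1}/2^{g_2}$) is available via
`term = "ratio"`. Suspected perfect separation (a standardized
coefficient beyond 50, or non-convergence) flags the result, blanks
the p-value and still reports AUCs.

Model quality is summarised by in-sample AUC of the fitted
probabilities with and without the interaction term. In-sample AUC is
optimistic and not monotone in model nesting (only the log-likelihood
is, and that is what the invariant suite asserts); the AUC difference
is a descriptive effect size, not a test. AUC itself is computed by the
rank (Mann–Whitney) formula with ties counted one half; the ROC curve
is a threshold sweep over unique scores whose trapezoidal integral
equals the rank AUC to $10^{-12}$ (asserted).

## Clusters and enrichment

Specific networks are partitioned by greedy modularity maximization
with vertices iterated in lexicographic order, making the partition
deterministic; the merge dendrogram is cut at maximum modularity with
near-ties ($<10^{-12}$) broken toward fewer communities. Clusters
below `min_size` (default 3) pool into an "unassigned" bucket. The
algorithm choice is a package decision — cluster labels are
descriptive and downstream statistics do not depend on reproducing any
particular partition.

Enrichment of a cluster against a gene set is the upper-tail
hypergeometric probability of the observed overlap, with the term
intersected with the universe first (default universe: the analyzed
network's nodes, configurable to all measured genes). The headline
statistic is the percentage of cluster genes inside the term,
$100\,k/n$, rounded to one decimal with ties rounded half to even —
the convention that reproduces published enrichment tables of this
form exactly (a half-up rule fails on counts like 13/16 = 81.25).
P-values are BH-adjusted across terms within a cluster.

## The synthetic-study generator

`simulate_study()` emulates the statistical structure the pipeline
assumes, with defaults mirroring the target study design:

| parameter | default | meaning |
|---|---|---|
| `group_sizes` | 49/18/16 | three unequal subgroups |
| `n_genes` | 120 | gene panel size |
| baseline $\mu_g$ | Uniform(2, 10) | gene-specific log-scale level |
| `group_shift_sd` | 1 | per-gene per-subgroup baseline shift (log units) |
| `slope_per_group` | 1/0/0 | planted edge slope in each subgroup |
| `noise_sd` | 1 | residual sd of planted relations |
| `response_effect` | 2 | log-odds on the planted pair's standardized product |
| `age_mean`, `age_sd` | 52, 16 | age covariate (years) |
| `age_effect` | 0.5 | log-odds on standardized age |

The subgroup baseline shift is what makes subgroup mean expression —
and therefore the weight-filtered networks — differ between subgroups,
as distinct disease pathotypes do; without it every filtered network
coincides and no subgroup-specific edge survives overlap removal. One
global seed drives a single generator stream, so studies are
reproducible end-to-end and byte-identical across reruns.

What the generator does **not** emulate: negative-binomial count noise,
library-size and normalization effects, batch structure, or correlated
co-expression modules beyond the planted edges. Passing tests
demonstrate that the pipeline recovers the structure it is designed to
detect under its own assumptions — Gaussian log-scale noise and linear
within-subgroup relations — not that those assumptions hold in any
particular RNA-Seq cohort.

## Problem sizes and numerical conventions

The test and acceptance simulations use: 500 null replicates at 200
samples/group for type-I calibration; 100 replicates of a
1-planted/99-null scan for FDR; 200 seeds at subgroups of 49 and 18
for edge-detection power; 100 replicates of a 1-planted-pair versus 30
null pairs ranking experiment; and 200 seeds for the AUC-gain summary.
These sizes give Monte-Carlo standard errors of roughly 0.01–0.02 on
the reported proportions.

Other fixed conventions: gene symbols are uppercased everywhere and
matched as strings (no alias resolution — mismatches are reported, not
guessed); duplicate expression rows collapse to the highest-mean row
with a logged warning; edges are stored in canonical lexicographic
order; BH adjustment is applied within each scanned network; treatment
coding uses the largest group (most frequent level for categorical
covariates) as reference.

## Known limitations

* Far-tail calibration of the robust Wald p-value at cohort-scale $n$,
  and hence strict BH/FDR control in boundary designs, as discussed
  above; detection power at a slope difference equal to the residual
  sd with subgroups of 49 and 18 is ≈0.89.
* In-sample AUC overstates out-of-sample discrimination; no
  cross-validation is built into the headline path.
* The percolation threshold selection rules are heuristics over the
  profile; the default remains the fixed 75th percentile.
* Expression must arrive normalized and log-scale (log2(TPM+1) or
  variance-stabilized values are sensible choices); upstream
  normalization is out of scope and unmodeled.
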
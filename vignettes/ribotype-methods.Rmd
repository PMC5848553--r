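---
title: "Methods: RPT expression pattern discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RPT expression pattern discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its methods: the statistical model
behind each stage, the parameters that matter, the numerical choices, and
what the synthetic benchmarks do and do not demonstrate.

## Relative RPT expression

All analyses operate on the composition of ribosomal protein transcripts:
for sample $i$ and RP gene $g$ with linear-scale RPKM $x_{ig}$,
$$r_{ig} = \frac{x_{ig}}{\sum_{g'} x_{ig'}}, \qquad \sum_g r_{ig} = 1 .$$
The statistic is invariant to per-sample scaling (library size, overall
ribosome abundance), which is exactly why it is informative about
stoichiometry and why downstream models must tolerate its compositional
constraint (one structural zero eigenvalue; fractions are negatively
correlated by construction).

Expression tables are read in an explicitly declared storage dialect.
Public repositories store log-transformed RPKM, but whether the transform
was $\log_2(x)$ or $\log_2(x+1)$ is not always recorded, and the $+1$
offset changes the fractions of weakly expressed transcripts. The dialect
is therefore an argument (`log2_plus1`, the common convention, is the
default), never inferred from the data. Gene symbols match exactly and
case-sensitively after whitespace stripping; no alias resolution is
attempted, because silent aliasing is a reproducibility hazard. The
packaged registry lists 80 canonical human cytoplasmic RP genes
(`RPL*`, `RPS*`, `RPLP0–2`, `RPSA`, `FAU`, `UBA52`, `RPS4Y1`); it is a
plain editable text file and can be replaced by the user. Extraction fails
below 95% registry coverage by default.

## Exact t-SNE with calibrated perplexity

Pairwise squared Euclidean distances between compositions feed per-sample
Gaussian conditional distributions
$p_{j|i} \propto \exp(-\beta_i d_{ij}^2)$, with the precision $\beta_i$
found by bisection so that the Shannon entropy $H_i$ satisfies
$2^{H_i} = \text{perplexity}$ (tolerance $10^{-5}$, max 100 bisection
steps; unreachable targets — perplexity at or above the neighbor count —
are an error). A uniform row over $n$ equidistant neighbors has perplexity
exactly $n$, so no smaller target is attainable there; the calibration
reports non-convergence with the achieved value in that degenerate case.

Conditionals are symmetrized, $P = (P_{j|i} + P_{i|j})/2n$, and the
embedding minimizes $KL(P\|Q)$ with the Student-t kernel
$q_{ij} \propto (1 + \|y_i - y_j\|^2)^{-1}$ by gradient descent. The
optimization protocol: learning rate (epsilon) 10; up to 5000 iterations or
until stabilized, operationalized as a maximum per-coordinate update below
$10^{-7}$; early exaggeration 12 for the first 250 iterations; momentum 0.5
switching to 0.8 at iteration 250; adaptive per-coordinate gains
(±0.2/×0.8, floor 0.01); Gaussian initialization with $\sigma = 10^{-4}$
from the config seed (PCA initialization behind a flag). In short runs the
exaggeration phase is capped at half the iteration budget so that the
recorded KL (always computed on the unexaggerated $P$) can settle below its
starting value. Perplexity is conventionally swept over 6–15 for
single-cohort analyses and 10–30 for grouped analyses; the pipeline reports
the sweep member with the best mean silhouette on the discovered clusters
instead of a visual choice, and retains all runs.

The implementation is exact ($O(n^2)$ per iteration), not Barnes–Hut:
cohorts of up to ~1,000 samples make exactness affordable, and an exact
objective is directly checkable against brute-force oracles. Embeddings are
bitwise reproducible from the seed.

## Cluster discovery

"Clusters that separate visually" is made computable as density
connectivity: samples are linked when their embedding distance is at most a
radius $\varepsilon$, connected components with at least `min_size = 10`
members become clusters (numbered by decreasing size), everything else is
`NOISE` rather than force-assigned. The default radius is the elbow of the
sorted k-nearest-neighbor distance curve ($k =$ `min_size`), located as the
point furthest from the chord joining the curve's endpoints — a
maximum-curvature proxy that removes a per-cohort hand-tuned knob while
staying inspectable (the radius is reported alongside the assignment).

## Differential patterns

Across-cluster screening uses per-gene one-way fixed-effects ANOVA on
relative expression, excluding noise samples. $-\log_{10} p$ is computed on
the log scale from the F distribution, so p-values far below double
underflow (the $10^{-220}$ regime reached with many samples) are
representable. The volcano effect size is the signed difference of the two
cluster means for $K = 2$ and the range of cluster means for $K > 2$ — a
single monotone summary; the per-cluster signed differences remain
available from the contrasts. A constant gene is reported as degenerate
with $p = 1$. No multiple-testing correction is applied inside the volcano
(p-values are reported raw); FDR control is used only where the analysis
prescribes it (copy number).

Cluster-vs-rest contrasts use the Welch (unequal-variance) two-sample test,
matching the heteroskedastic-t convention for continuous comparisons, and
record the direction of change. Cross-cohort co-regulated sets are then the
transcripts significantly changed (at $\alpha = 0.01$) in the *same
direction in every* cluster sharing the anchor pattern; a sign-only mode
(consistency "on average", no per-cluster significance) is available behind
a flag, since the membership rule can reasonably be read either way. A
pattern requires at least two member clusters — recurrence is definitional.

## Copy number, clinical covariates, survival

GISTIC-thresholded calls are classified by sign (positive = amplification,
negative = deletion). For every gene × alteration type × cluster, a
chi-squared test compares in-cluster against out-of-cluster incidence;
Benjamini–Hochberg is applied jointly across all tests within a cohort at
$q = 0.05$ (the conservative, readable scope); and an association is
*flagged* only when BH-significant **and** above 90% in-cluster incidence.
The strict `> 0.90` inequality matters in small clusters: a 95%-incidence
amplicon realized in an 80-member cluster lands at or below 90% about 7% of
the time, and such draws are correctly refused — benchmark fixtures
therefore use clusters of ~200 members where the realized incidence
concentrates.

Categorical clinical fields use raw-$\alpha$ ($0.01$) chi-squared tests.
Continuous fields are gated per group by Shapiro–Wilk at 0.05: both groups
normal → Welch t; otherwise the two-sample Wilcoxon rank-sum with mid-rank
ties (the comparison is between independent tumor groups, so the
"sign-rank" reading — a paired test — does not apply; both interpretations
were considered and the unpaired test is the default). All tests are
two-tailed.

Survival uses the Kaplan–Meier product-limit estimator and a K-group
weighted log-rank framework over pooled event times: weights 1 give the
Mantel–Haenszel log-rank test; weights equal to the total number at risk
give the Gehan–Breslow–Wilcoxon test (emphasizing early events). Tied
events are handled within one risk-set evaluation; the variance is the
standard hypergeometric form, and the statistic is
$U^\top V^{-} U \sim \chi^2_{K-1}$. The Gehan variant is implemented
in-package because the common `rho`-family weighting available elsewhere is
the Peto–Peto survivor-function weight, not the at-risk count; the plain
log-rank path is cross-checked against an independent implementation in the
tests.

## Classifiers

Splits are balanced by cohort: every cohort contributes the same number of
samples (capped by the smallest cohort), split 60/10/30 into
train/validation/test with floor rounding and the remainder to train,
deterministically from a seed. Binary problems use maximum-likelihood
logistic regression with the c-statistic (rank-based AUC), sensitivity and
specificity at a 0.5 threshold reported on the test set only; complete
separation or IRLS non-convergence is reported as a status, not an
exception. With 80 compositional features, in-sample separation is common
at desk scale — the status makes that visible, and the multi-class network
is the documented fallback for such models.

The network is a fully connected ReLU multilayer perceptron with a softmax
output, trained by plain mini-batch gradient descent (the optimizer is a
visible config choice) on cross-entropy with optional inverted dropout and
L2 weight decay; a hidden layer of size 0 is treated as absent, so the
no-hidden-layer configuration is multinomial logistic regression. The sweep
trains every grid combination — learning rate {0.001, 0.002, 0.005, 0.01},
batch size {100, 500, full}, dropout keep {0.9, 0.95, 1}, one or two hidden
layers of 0–200 units in steps of 25, L2 {1e-5, 1e-4, 1e-3} — and selects
by validation accuracy, reporting test metrics for the selected model only.
"Plateau" is operationalized as 20 consecutive validation evaluations
(every 25 epochs, up to 4000 epochs) without a gain above $10^{-3}$; among
ties the most recent weights are kept, since the decision margin keeps
improving after a small validation set saturates. Features enter
unstandardized (the models classify RPT content as-is); standardization is
available behind a flag and is useful for the no-hidden-layer limit, where
plain gradient descent on raw $10^{-2}$-scale fractions converges slowly.

## The synthetic cohort generator

Real pan-cancer compositions are emulated by a Dirichlet-composition model:
a tissue's baseline is a concentration vector $\alpha$ (log-normal weights,
sdlog 0.5, scaled to a total of 2000 — per-gene coefficient of variation
near 20%, reflecting the tight regulation of RP transcripts); each sample's
composition is Dirichlet($\alpha$ element-wise scaled by $2^{\text{shift}}$
for its subcluster), and RPKM rows are the composition times a log-normal
library size (meanlog log 2000, sdlog 0.4). Planted subclusters occupy
deterministic sample counts (rounded proportions over a random
permutation). Amplicon members receive their GISTIC call at the stated
incidence inside the subcluster and at a 2% background rate elsewhere
(random ±1 sign), with an optional expression effect for carriers — the
sharp contrast between >90% in-cluster incidence and near-absence outside
mirrors what cluster-defining amplicons look like. Survival is exponential
with independent exponential censoring (baseline hazard $5\times10^{-4}$
per day ≈ 3.8-year median, censoring $4\times10^{-4}$ per day — plausible
cohort-scale figures chosen once). The bundled `recurring_patterns()`
templates plant the four recurring pattern archetypes (high *RPL8*/*RPL30*,
low *RPL3*, high *RPS4X*, high *RPL13*) with anchors at $|\log_2| = 1$ and
7–11 co-regulated transcripts at $0.75$, reflecting the breadth of observed
co-regulated sets.

What the generator does *not* emulate: correlated noise between transcripts
beyond the compositional constraint, dosage calibration between copy number
and expression beyond a single log2 effect, batch effects, tumor purity
gradients, or overlapping/hierarchical subclusters. Passing benchmarks on
these cohorts therefore demonstrates the *machinery* — calibration,
optimization, test statistics, filters, recovery under a known truth — not
performance on real tumors, whose cluster structure is messier.

## Benchmark problem sizes

The test suite and the acceptance script run at desk scale, chosen to keep
the full suite in minutes on one CPU: statistical oracles on 100 random
small instances each; embedding checks on a 500-sample five-tissue fixture;
cluster recovery over ten seeds with 2–4 planted subclusters of 50 samples;
co-regulation over five 100-tumor cohorts; CNV filtering on a 500-tumor
cohort (200-member cluster) plus null cohorts; survival power over
simulated hazard-ratio-3 cohorts of 150 tumors; classifiers on five cohorts
of 120 tumors + 80 normals with a global tumor shift of $|\log_2| = 0.75$
in six transcripts. Known limitation: at a planted tumor shift of exactly
0.5, unpenalized logistic regression at these sample sizes reaches complete
separation and generalizes erratically (≈0.85–0.94 accuracy) even though
the planted signal is strong; the reported fixtures use 0.75, and the
separation status is always surfaced.
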
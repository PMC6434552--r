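---
title: "Methods: a Gaussian-copula pathway for community count data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Gaussian-copula pathway for community count data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copulacomm)
```

This vignette explains the statistical model implemented by
`copulacomm`, its assumptions, the tunable parameters that matter, the
numerical choices behind the estimators, what the synthetic-data
generators do and do not emulate, and the package's known limitations.

## The model

A community sample is an $N \times p$ table $\mathbf{Y}$ of counts of
$p$ species over $N$ sampling units, with a group label (time, site,
treatment) per unit. The joint model couples arbitrary discrete
marginals through a Gaussian copula: with marginal cdfs $F_j$ and a
$p \times p$ correlation matrix $\Sigma$,

$$F(y_1,\dots,y_p) \;=\; \Phi_\Sigma\!\big(\Phi^{-1}(F_1(y_1)),\dots,
\Phi^{-1}(F_p(y_p))\big).$$

Each species keeps its own interpretable univariate model; association
is carried entirely by $\Sigma$ on the latent Gaussian scale. Both the
marginal parameters and $\Sigma$ are allowed to differ among a priori
groups — the model makes no assumption that dispersion, zero-inflation
or association structure is stable across groups, which is exactly the
flexibility that motivates the pathway.

### Marginals

Four count families are supported: Poisson, zero-inflated Poisson,
negative binomial and zero-inflated negative binomial. The NB is
parameterized by mean $\mu$ and dispersion $\theta$ with variance
$\mu + \mu^2/\theta$; $\pi \in [0,1)$ is the structural-zero mixture
weight, so e.g. the ZINB pmf is
$\pi\,\mathbb{1}(y=0) + (1-\pi)\,\mathrm{NB}(y;\mu,\theta)$. Families
are compared by the corrected information criterion
$\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$; candidates with
$n \le k+1$ are inadmissible and are excluded with a warning. Ties are
broken toward fewer parameters, then the fixed order Poisson, ZIP, NB,
ZINB. By default family selection uses each group's own $n$
(`aicc_scope = "group"`); selecting once on pooled counts and refitting
parameters per group is available (`"pooled"`) because with group sizes
near 15–20 the per-group AICc can be noisy — the choice is exposed
rather than hidden.

A species never seen in a group is represented by a point mass at zero,
simulated as constant zero, and barred from copula estimation: its cdf
step at 0 is 1, so its latent hyper-rectangle is the whole real line
and it carries no information about association.

### Association screen

The index of association between species $k$ and $\ell$,

$$I_{k\ell} = 1 - \tfrac12 \sum_{i=1}^{N}
\left| \frac{y_{ik}}{\sum_j y_{jk}} - \frac{y_{i\ell}}{\sum_j y_{j\ell}} \right|
\in [0,1],$$

compares relative-abundance profiles and discounts joint absences
(all-zero rows contribute nothing). Its null distribution is obtained by
permuting one species' values across units, which preserves both
marginal profiles while destroying association; of each pair, the
species whose name sorts later is the one permuted, which makes the
screen exactly invariant to the column order of the input. The
two-tailed p-value is $\min(1, 2\min(p_{\mathrm{lower}},
p_{\mathrm{upper}}))$ with the $(b+1)/(B+1)$ convention throughout the
package — the convention under which $B$ permutations can resolve
p-values no smaller than $1/(B+1)$, and the screen refuses to run when
`error_rate * (n_perm + 1) < 1`.

Multiplicity is handled either per comparison (PCER: a pair is declared
when its observed $I$ falls outside its own two-tailed empirical
permutation bounds at the nominal rate) or family-wise (FWER) by a
max-statistic construction: the same row permutations are shared across
all pairs; per permutation the most extreme within-pair two-tailed tail
probability across pairs is recorded; a pair is declared when its
observed tail probability beats the nominal quantile of that
extreme-value distribution. This min-p construction is our
implementation choice for an exact family-wise filter; it is always at
least as conservative as PCER on the same input, which the test suite
asserts.

### Copula estimation by Monte Carlo EM

Discreteness means an observation constrains its latent Gaussian vector
$\mathbf z_i$ only to the hyper-rectangle
$\prod_j (\Phi^{-1}(F_j(y_{ij}-1)),\ \Phi^{-1}(F_j(y_{ij}))]$.
`mcem_fit()` treats the $\mathbf z_i$ as missing data, holding the
marginals fixed (conditioning on step-one fits keeps each species'
univariate fit intact and makes the problem tractable):

* **E-step** — for each observation, `n_mc` latent vectors are drawn
  from $N(0, \Sigma^{(t)})$ truncated to the rectangle, by
  coordinate-wise Gibbs sampling (each full-conditional is univariate
  truncated normal, sampled by inverse-cdf). The chains are
  warm-started between EM iterations; the first iteration takes
  `burnin` sweeps (default 10), later iterations `sweeps` (default 2).
* **M-step** — $\Sigma^{(t+1)}$ is the average of latent outer products
  across observations and draws, normalized to unit diagonal
  ($D^{-1/2} S D^{-1/2}$); if any eigenvalue is negative it is clipped
  at $10^{-8}$ and the matrix renormalized, so every iterate is a valid
  correlation matrix by construction.

Numerical choices: $\Sigma^{(0)}$ is the normal-scores rank correlation
(midranks for ties) shrunk 10% toward the identity — cheap and
consistent under the model; `n_mc` grows geometrically
($\times 1.2$ per iteration, capped at 200) so late iterations average
away Monte Carlo noise; convergence is declared when the Polyak average
of the last five iterates moves less than `tol` (default 0.005) in
maximum absolute entry, which absorbs the residual MC jitter that would
otherwise keep a raw-iterate criterion oscillating. Non-convergence is
a warning carried in the result, never silent. Inverse-cdf truncated
sampling clamps the uniform at $[10^{-12}, 1-10^{-12}]$; a numerically
empty interval falls back to the nearest bound.

Only the species selected by the screen (those in at least one declared
pair) enter $\Sigma$ jointly; the estimated block is embedded in the
identity (`expand_correlation()`), so unscreened and rare species remain
in the model as independent. No shrinkage or regularization of $\Sigma$
is attempted: the screen is the dimensionality-control device, and the
package refuses nothing if you screen nothing — but $m$ approaching $N$
is then your responsibility.

### Simulation and the quantile clamp

`simulate_counts()` draws $\mathbf z \sim N(0,\hat\Sigma)$ and returns
$y_j = F_j^{-1}(\Phi(z_j))$, the smallest integer with
$F_j(y_j) \ge \Phi(z_j)$. Since $\Phi(z)$ can be within floating-point
distance of 1, quantiles clamp $q$ at $1-10^{-12}$: the draw is the
smallest $y$ with $1 - F(y) < 10^{-12}$, keeping every simulated count
finite without perceptibly distorting the distribution. The map from
copula correlation $\rho$ to the index of association is smooth and
monotone; `rho_to_I_curve()` traces it by simulation (defaults: 100
replicate datasets of 5,000 bivariate counts per $\rho$; both are
parameters because the literature describing such curves is ambiguous
about which of the two numbers is the dataset size) and
`rho_for_index()` inverts it by linear interpolation, for choosing a
$\rho$ that targets a desired $I$.

## Dissimilarity stage

Bray–Curtis on square-root-transformed counts is the default recipe
throughout (`none` and fourth-root are available); a pair of all-zero
units is defined to have dissimilarity 0, with the count of such pairs
logged on the result. Distances among group centroids are computed
directly from squared dissimilarities,

$$d^2(c_a, c_b) = \frac{1}{n_a n_b}\sum_{i \in a}\sum_{j \in b} d^2_{ij}
- \frac{1}{2n_a^2}\sum_{i,i' \in a} d^2_{ii'}
- \frac{1}{2n_b^2}\sum_{j,j' \in b} d^2_{jj'},$$

without ever constructing coordinates. For a semi-metric measure like
Bray–Curtis a squared centroid distance can come out negative; it is
clamped to 0 and counted (the signed-root alternative was rejected
because it would make the centroid matrix fail to be a dissimilarity).
For Euclidean input the formula is exact, which the tests verify against
arithmetic-mean centroids at $10^{-8}$.

PCoA retains and reports negative eigenvalues rather than dropping or
correcting them — they are informative about how non-Euclidean the
measure is, and CAP needs to know which axes are genuinely positive.
MDS wraps a stress-majorization engine: metric mode regresses
configuration distances linearly on dissimilarities, non-metric mode
uses monotone regression (Kruskal stress-1); normalized stress on the
dissimilarities themselves is the reported variant. The best of a PCoA
start plus `n_starts = 8` random starts is kept, and the achieved
stress is always surfaced — a high stress (say $> 0.24$) on a centroid
plot is itself diagnostic of weak group structure and must not be
hidden. Metric MDS is the default for centroid clouds (centroid
geometry is what the plot is asserting); non-metric remains available
for raw-data diagnostics. Kernel density contours over each centroid
cloud use a bivariate normal kernel with the classical plug-in
bandwidth, drawn at 0.5/0.75/0.95 mass levels.

## Inference stage

The one-way PERMANOVA pseudo-F is computed from sums of squared
dissimilarities,
$F = \frac{SS_A/(g-1)}{SS_W/(N-g)}$ with
$SS_T = \frac1N \sum_{i<j} d^2_{ij}$ and
$SS_W = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d^2_{ij}$, and coincides
exactly with the classical ANOVA F for univariate Euclidean input
(asserted at $10^{-10}$, and against an independent PERMANOVA
implementation). Degenerate input (all units identical) defines the
statistic as 0 with p = 1; $SS_W = 0$ yields an infinite statistic whose
p-value still comes from the permutation distribution.

The model-based null draws each simulated unit's generating group from a
multinomial with probabilities $1/g$ (or $n_i/N$ under the
`prob = "size"` option), keeps the nominal group sizes, recomputes the
statistic per dataset, and uses $(b+1)/(B+1)$. When the data really come
from the fitted model this null distribution agrees with the
permutation null — a distributional check the test suite performs, and
a model diagnostic users should perform too.

CAP performs canonical discriminant analysis on the first $m$ PCoA axes.
The test statistic is the trace of squared canonical correlations (the
squared first correlation is also reported; which of the two the
original CAP literature used for power is not stated, so both are
computed and trace is the default). For permutations the trace is
evaluated as $\|U_x' P\, U_g\|_F^2$ with orthonormal bases precomputed
once — algebraically identical to the canonical-correlation definition
(asserted at $10^{-10}$) and an order of magnitude faster inside power
loops. Leave-one-out allocation refits the discriminant without each
unit on the fixed PCoA axes and classifies it to the nearest group
centroid in the canonical space; when `m_axes` is not given it is chosen
to maximize LOO success (ties to fewer axes).

Power curves model the null-to-alternative continuum as mixture
probabilities $P_k = (1-f_k)P_0 + f_k P_A$ over which group's model
generates each unit, rather than sliding marginal parameters — sliding
$\mu, \theta, \pi$ separately can produce unrealistic parameter
combinations, whereas mixtures always generate data the fitted models
consider realistic, and they yield smooth monotone curves. Group sizes
follow the nominal design; only the generating model is random.

## Synthetic data

`synthetic_spec()`/`generate_community()` produce communities with known
ground truth in the regime that motivates the pathway: log-normal spread
of species means, NB/ZINB-dominated families, a configurable fraction
(default 40%) of rare species, and one block of positively associated
species per group built from one-factor loadings
($\Sigma_{k\ell} = \lambda_k \lambda_\ell$), which guarantees a valid
correlation matrix with pairwise correlations in the requested range.
The default dimensions (47 species; groups of 15/21/20) match the
motivating survey design so that tests exercise realistic shapes in
seconds. `make_mock_null()` implements the null-true diagnostic: fit one
pooled model ignoring groups, simulate labeled groups from it, and treat
the result as observed data for which the null hypothesis is known to be
true.

What the generators do *not* emulate: spatial or temporal
autocorrelation among sampling units, environmental gradients within
groups, non-random co-occurrence of rare species, and any
marginal family outside the four supported ones. Tests passing on these
fixtures therefore demonstrate correctness of the estimators and tests
under the stated model, not robustness to violations of it.

`power_demo_model()` is a fixed 14-species fixture used for the
scaled-down PERMANOVA-vs-CAP comparison. It encodes the two mechanisms
that separate the tests: ten independent over-dispersed species carry
diffuse multiplicative mean shifts (power accrues to PERMANOVA, which
integrates raw dissimilarities over all species, while fixed-dimension
CAP dilutes the signal across canonical axes), and four strongly
associated species (pairwise $\rho = 0.85$) carry opposing mean
contrasts pointing along a direction of low within-group variance
(power accrues to CAP, whose canonical standardization finds that
direction, while the contrast barely moves Bray–Curtis distances).
Restricting the analysis to `power_block()` isolates the second regime.
The fixture's effect sizes were chosen once so that at the scale used in
the acceptance checks (5 mixture steps, 200 simulated datasets per step,
199 permutations per test) the curves rise well clear of the size but do
not saturate — the regime where an ordering is interpretable.

## Problem sizes used in the checks

The package's own test suite runs marginal-recovery at $n = 2000$ over
50 replicates per family; MCEM recovery on a planted $4\times4$
correlation at $n = 1000$ over 10 seeds; screening size on roughly a
thousand independent pair-tests at PCER 0.01 with 999 permutations;
PERMANOVA and CAP size at 1,000 null simulations with 199 permutations
each; and the power comparison at 5 steps $\times$ 200 simulations per
step. These sizes make the distributional checks sharp enough to be
meaningful (99% binomial bands) while keeping the whole suite fast.

## Known limitations

* Marginals are unconditioned: no covariates or gradients enter the
  marginal models, and only the four named families are available.
* $\Sigma$ is unregularized; with many associated species and small
  groups the MCEM estimate is noisy, and the screen is the only
  dimension-control device offered.
* Marginals and copula are estimated in two stages; joint estimation
  (and the efficiency it could buy) is out of scope.
* The FWER filter is a max-statistic construction chosen here; other
  exact family-wise procedures exist and may differ at the margin.
* The Gaussian copula cannot represent tail-asymmetric association;
  vine and other copula families are out of scope.
* One-way designs only: no nested or multi-factor decompositions, and
  no dispersion (PERMDISP-style) test.
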
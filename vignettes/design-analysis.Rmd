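---
title: "Design analysis for unsupervised clustering: models, procedures, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design analysis for unsupervised clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clustsim)
```

## The question the package answers

Researchers in cognitive and psychological research increasingly apply
unsupervised clustering (including latent profile analysis) to continuous
indicators, hoping to discover sub-populations of individuals. Whether that
can work depends on quantities a researcher can reason about *before*
collecting data: the number of indicators, their mutual correlation, the
plausible standardized group difference, and the sample size. `clustsim`
implements a Monte-Carlo design analysis over exactly those quantities: it
simulates cohorts with known structure, runs the three most common
clustering procedures with their standard cluster-number selection rules,
and measures both power (the probability of selecting the true number of
clusters, and the Rand agreement of the classification) and false-positive
risk (the probability of "discovering" multiple clusters in a homogeneous
population).

## The generating model

A cohort of $N$ units on $p$ indicators is drawn from

$$Y \mid G = g \sim N_p\!\left(\mu_g,\ \Sigma(\rho)\right),$$

where $G$ is the latent group. With one true group, $\mu_1 = 0$. With two
true groups, $\mu_2 = d\,\mathbf{1}$: the standardized mean difference $d$
is applied to *every* indicator of group 2, and each unit belongs to either
group with probability $1/2$ independently (so the groups are equally
numerous only on average — a binomial split, not a forced exact half).
$\Sigma(\rho)$ is compound symmetric: unit diagonal, common correlation
$\rho$ off the diagonal. Because indicators have unit variance by
construction, no standardization step precedes clustering and $d$ is
directly a Cohen's $d$.

To reflect the uncertainty of a real a priori analysis, $d$ and $\rho$ are
not fixed but drawn per replicate from uniform distributions: $d \sim
U(a,b)$ with $(a,b) \in \{(0.20, 0.60), (0.60, 1.00), (1.00, 2.00)\}$
(plausible, large, implausibly large effects) and $\rho \sim U(c,d)$ with
$(c,d) \in \{(-0.10, 0.10), (0.10, 0.30), (0.40, 0.60)\}$ (negligible,
modest, strong correlation — an exactly-zero correlation being considered
implausible for behavioral measures). Crossed with $p \in \{3, 6, 12\}$ and
$N \in \{50, 100, 250, 500, 1000, 2000\}$, this yields 54 one-group and 162
two-group scenarios (`build_grid()`).

```{r}
length(build_grid(1))
length(build_grid(2))
```

**Admissibility corner.** Compound symmetry is positive definite only for
$\rho > -1/(p-1)$. At $p = 12$ the range $(-0.10, 0.10)$ can produce
inadmissible draws ($-1/11 \approx -0.091$). Such draws are truncated to
$-1/(p-1) + 10^{-6}$ with a warning. This is the package's own choice for a
corner the generating description leaves open; it affects roughly 4–5% of
draws in that one cell and keeps the drawn correlation inside the stated
range.

## The three clustering procedures

**Gaussian mixture clustering (MGC).** A finite mixture of multivariate
normals fitted by EM, sweeping the number of components $g = 1..5$ and six
covariance parameterizations — spherical/diagonal/full crossed with
equal/varying across components (EII, VII, EEI, VVI, EEE, VVV). The model
with maximal BIC ($2\log L - m\log N$, maximized) wins; $m$ counts $(g-1)$
mixing proportions, $gp$ means, and the family's covariance parameters.
Six families cover the constraint spectrum from 1 covariance parameter to
$g\,p(p+1)/2$ at tractable cost; reference mixture software sweeps up to 14
(adding orientation-constrained ellipsoidal families), so quantitative
agreement with analyses run under such sweeps is approximate by design.

Numerical choices: EM stops when the relative log-likelihood change falls
below $10^{-5}$ or at 500 iterations; responsibilities are computed by
log-sum-exp; component covariance eigenvalues are floored at $10^{-6}$, and
a fit that hits the floor is flagged degenerate and excluded from model
selection (as is a fit whose components empty out). Each $(g,
\text{family})$ pair is fitted from two deterministic initializations — the
complete-linkage hierarchical cut at $g$, and a Lloyd refinement of
farthest-point seeds — keeping the better log-likelihood; both depend only
on the data, so a fit is reproducible given the cohort. Ties in BIC break
toward smaller $g$, then toward the simpler family (parsimony).

**PAM.** Partitioning around medoids (classic BUILD + SWAP, SWAP capped at
the `cluster` package default) on the Euclidean distance matrix of the raw
indicators.

**HAC.** Hierarchical agglomerative clustering with complete linkage on the
same distances, cut at each candidate $k$.

For PAM and HAC the number of clusters is the argmax of the average
silhouette width over $k = 2..5$ (ties toward smaller $k$; units in
singleton clusters score 0, the standard convention). The silhouette is
undefined at $k = 1$, so the one-cluster possibility is tested first with
the Duda-Hart test at $\alpha = .05$, applied to the method's own 2-cluster
partition: homogeneity is rejected when $J_e(2)/J_e(1)$ — pooled
within-cluster over total sum of squares — falls below

$$1 - \frac{2}{\pi p} - z_{1-\alpha}\sqrt{\frac{2\left(1 - 8/(\pi^2 p)\right)}{N p}}.$$

If homogeneity is not rejected the method reports $k = 1$; the test gates
only the 1-vs-many decision and never overrides the silhouette's choice
among $k \ge 2$.

**A calibration caveat worth knowing.** The published critical value above
is *conservative* in this usage: simulating homogeneous spherical Gaussian
data and feeding the test a 2-partition (whether from HAC, PAM, k-means, or
a mean-split hyperplane) yields a rejection rate near 0%, not the nominal
5%, because the normal-approximation standard deviation in the formula
overstates the sampling variability of the ratio by a factor of roughly
2.5. The package implements the published formula faithfully — it is the
form in standard software and the one the performance surfaces depend on —
and the test suite asserts the direction of the miscalibration
(conservative) rather than pretending the nominal level is attained. In
practice the conservatism *helps* one-cluster detection with orthogonal
indicators and is part of why the partitional methods look well behaved
there.

## Evaluation

Each replicate is scored by (i) whether the selected $k$ equals the true
number of groups and (ii) the plain (unadjusted) Rand index between the
hard assignment and the truth — the proportion of unit pairs co-clustered
in both partitions or separated in both. For two balanced groups, chance
corresponds to Rand $\approx 0.5$, which is how chance-level classification
is flagged. Scenario summaries report the distribution of selected $k$
(1, 2, 3, $>3$, plus full counts to 5), the proportion correct, and the
mean and population SD of the Rand index. For one-group scenarios the Rand
index against the all-ones truth is reported too; it is well-defined (it
equals the proportion of co-clustered pairs, driven by the spurious
clusters' sizes) but is best read alongside the selected-$k$ distribution.
Replicates that fail outright (e.g., every mixture fit degenerate) are
counted and excluded from the proportions; the summary reports the
denominator.

## Seeding and reproducibility

A master seed spawns an independent child seed for every (scenario,
replicate) pair through an integer hash modulo $2^{31}-1$, so any scenario
can be re-run alone — or scenarios can run in any order, or in parallel —
and produce bit-identical results. The replicate count defaults to the
reference 500; the shipped analyses and tests run 25–200 replicates per
scenario so that a full check completes in minutes on one core, at the cost
of wider Monte-Carlo error (binomial SE at 60 replicates is about 6
percentage points at $p = 0.5$).

## What the generator does and does not emulate

The generator reproduces the statistical structure the design analysis
assumes: Gaussian indicators, compound-symmetric correlation, all
indicators equally informative, equal mixing proportions, and a common
effect size across indicators. Real cognitive data violate most of these in
some degree — skewness, floor/ceiling effects, outliers, unequal
sub-population sizes, uninformative indicators, and correlation structure
richer than compound symmetry. Passing tests therefore certify the
procedures under *favorable idealized* conditions; performance on real data
is expected to be no better, which is the conservative direction for the
package's central warning (the false-positive risk with correlated
indicators is demonstrated under conditions otherwise friendly to the
methods).

## The effect-size side of the argument

The design argument closes with closed-form utilities: conversions
$d = 2r/\sqrt{1-r^2}$ and $r = d/\sqrt{d^2+4}$; exact noncentral-$t$ power
for the two-sided two-sample $t$-test; Fisher-$z$ approximate power for a
single correlation (entirely adequate at the benchmark $N = 193$, where the
approximation sits within half a point of the simulated truth); and the
median-split artifact — splitting one variable at its median fabricates a
standardized difference of $-\sqrt{12} \approx -3.5$ (uniform) or
$-2\sqrt{2/\pi}/\sqrt{1-2/\pi} \approx -2.6$ (normal), with a simulation
mode confirming the closed forms. Together these quantify the argument that
effects too small for clustering to detect are comfortably within reach of
confirmatory tests, and that post-clustering effect sizes can be wildly
inflated.

```{r}
ttest_power(0.40, n_per_group = 100)
corr_power(0.20, n = 193)
r_to_d(c(0.36, 0.16))
median_split_d("uniform"); median_split_d("normal")
```

## A worked false-positive demonstration

```{r, eval = FALSE}
res <- reproduce_intro_example(reps = 200, seed = 2026)
res$k_counts
#>   1   2   3   4   5
#>   0 105  95   0   0
res$proportion
#> [1] 1
```

Two hundred homogeneous cohorts (8 indicators correlated at 0.30,
$N = 200$): the mixture/BIC procedure selects 2–4 clusters in 100% of them
and never the correct single cluster. The spurious clusters differ mainly
in overall level across all indicators simultaneously — the "overall low vs
overall high" profile that should be read as a warning flag, not a
discovery.

## Known limitations

- The six-family covariance sweep is a deliberate subset of the fullest
  reference sweep; selected models (not the selected *number* of clusters,
  which is the quantity of interest) can differ from software sweeping
  orientation-constrained families.
- PAM's BUILD + SWAP is a local search; on small configurations it can
  (and on ~1/3 of random 8-point sets does) miss the exhaustive k-medoid
  optimum. The test suite pins equality on fixtures where the optimum is
  attained and the local $\ge$ global inequality everywhere.
- The Duda-Hart critical value is conservative (see above); rejection rates
  on homogeneous data sit near 0 rather than at the nominal $\alpha$.
- One-group Rand indices are reported but their interpretation is
  delicate; the selected-$k$ distribution is the primary false-positive
  metric.
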
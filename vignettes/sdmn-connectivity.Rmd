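---
title: "Contest behavior and SDMN functional connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contest behavior and SDMN functional connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdmnet)
```

## The scientific setting

Staged same-sex zebrafish dyads fight until one opponent surrenders
(conflict resolution: a stable behavioral asymmetry in which only the
winner attacks and the loser submits). Two data tables describe such an
experiment. The **ethogram table** records every scored behavioral event —
the eight displays `r paste(ethogram_behaviors(), collapse = ", ")` — with
its dyad, actor and timestamp, alongside per-dyad latency and resolution
time. The **activation table** records, for every fish (isolated control,
winner, or loser), the number of pS6-immunoreactive cells — a marker of
recent neuronal activity — in each of 19 brain nuclei of the social
decision-making network (SDMN) and habenula, summed over five consecutive
coronal sections.

`sdmnet` implements the full analysis chain over these tables, plus a
synthetic-data module that generates both with known planted structure so
that every downstream stage can be validated against ground truth.

## Behavioral statistics

`summarize_dyads()` reduces events to per-dyad metrics: latency to the
first aggressive act, per-behavior totals until resolution, per-minute
frequencies (totals divided by resolution time), and aggregate aggressive
(antiparallel display, circle, bite, chase, strike) and submissive (freeze,
flee, retreat) frequencies. A dyad with no aggressive act has an undefined
latency, reported as `NA` and excluded from latency tests.

`gated_two_group_test()` mirrors the conventional univariate battery: each
group is screened with the Shapiro-Wilk test at $\alpha_{gate} = 0.05$ (the
level is a package convention; it is a tunable argument); if both groups
pass, a two-sided Welch $t$-test is used, otherwise a two-sided
Mann-Whitney $U$ test. The $t$-test is Welch's by deliberate choice — it is
R's default and does not assume equal variances. The Mann-Whitney result
carries both conventions: $U$ (the `wilcox.test` statistic) and the
rank-sum statistic $W = U + n_1(n_1+1)/2$, with $W$ the headline value. A
constant sample makes Shapiro-Wilk undefined; the gate is then recorded as
failed and the rank test used — the conservative route for degenerate data.

`behavior_pca()` square-root transforms display totals (variance
stabilization for overdispersed counts), centers the columns, and
eigen-decomposes the **covariance** matrix. Covariance rather than
correlation PCA is the default because component standard deviations on a
count-like scale are only meaningful without per-variable rescaling;
`scale = TRUE` switches to correlation PCA. Eigenvector sign is arbitrary,
so a fixed rule is applied: within each component the largest-magnitude
loading is made negative (ties broken by the first behavior in ethogram
order). This is purely a reproducibility convention.

`permanova()` is a from-scratch distance-based permutation MANOVA on
Euclidean distances. With $N$ individuals in $a$ groups,

$$SS_{total} = \frac{1}{N}\sum_{i<j} d_{ij}^2, \qquad
  SS_{within} = \sum_{g}\frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2, \qquad
  F = \frac{(SS_{total}-SS_{within})/(a-1)}{SS_{within}/(N-a)}.$$

Raw observations (not residuals) are permuted, matching the common
vegan-style default, and the $p$-value uses the add-one correction
$p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})$, so it is never zero and has
resolution $1/(n_{perm}+1)$. Degenerate inputs are guarded: an all-equal
data matrix reports $F = 0$, $p = 1$; a group of size one is an error
because the within-group partition is undefined. For the sex comparison
the pipeline applies the test to square-root-transformed display totals.
The test suite checks the implementation against an independent
centroid-based oracle, against exhaustive label enumeration on a small
design, and against `vegan::adonis2`.

## Activation testing

`kruskal_fdr()` applies, per region and within sex, the tie-corrected
Kruskal-Wallis test across the three social conditions, then
Benjamini-Hochberg across the 19 regions. FDR is controlled within sex (19
tests) rather than across both sexes; the two sexes are analyzed as
separate families, matching the per-sex reporting structure of the
analysis. Regions passing $q \le 0.05$ receive Dunn's rank-based post hoc
comparisons (tie-corrected variance, BH over the three condition pairs).
Dunn's procedure is the package's choice of "pairwise comparisons among
ranks"; no specific procedure is mandated by the analysis it mirrors. A
region with identical counts everywhere is guarded to $H = 0$, $p = 1$.

A practical note on design sizes: with three groups of five, a rank test
in which only one group separates has a hard $p$-value floor near 0.009,
which cannot survive a 19-region BH correction. Seven fish per condition
is the smallest size at which a fully separated condition clears the FDR
gate; power claims below that size are vacuous regardless of effect size.

## Bootstrapped functional connectivity

For each sex $\times$ condition stratum of $n$ fish:

1. **Subsampling.** All $\binom{n}{s}$ subsamples of size $s = 7$ are
   enumerated (lexicographic order). Because strata of 6–9 fish can be no
   larger than $s$, the effective size falls back to
   $s_{eff} = \min(s, n-1)$ — leave-one-out in the worst case — which
   guarantees at least $n$ subsamples; `strict_s = TRUE` errors instead.
   For very large strata the `random_m` policy draws $m$ distinct seeded
   subsamples.
2. **Instance networks.** Each subsample yields a Pearson (optionally
   Spearman) correlation matrix over the 19 regions. A density threshold
   $\rho = 0.23$ keeps exactly $k = \mathrm{round}(\rho \cdot 171) = 39$
   edges of largest absolute weight — both strong positive and strong
   negative correlations survive. Rounding is round-half-to-even (base R's
   `round`); floor/ceiling are available. Ties at the cutoff break by
   lexicographic edge order. A region with zero variance inside a
   subsample has its correlations set to 0 and cannot be retained — never
   a propagated `NaN`.
3. **Aggregation.** Instances are averaged element-wise, with non-retained
   entries contributing 0. This shrinks edges that are retained only
   sporadically toward zero, which is the point of density thresholding:
   only consistently strong co-activation survives averaging. The
   alternative rule (mean over retaining instances only) is available via
   `aggregation = "retained"`.

The aggregated treatment network splits by sign (`split_signed()`) into an
**excitation** subnetwork (positive co-activation) and an **inhibition**
subnetwork (negative co-activation) — statistical constructs, not synaptic
physiology. `robustness_scan()` reports the Spearman rank correlation of
aggregated edge weights between neighboring values of $s$, the standard
check that conclusions do not hinge on the subsample size.

## Edge-weight comparisons and balance

`compare_weight_distributions()` reports, for two edge-weight samples, the
two-sample Kolmogorov-Smirnov $D$, the two-sided Mann-Whitney $U$, and
Cohen's $d$ with pooled SD (first minus second). Effect-size labels follow
the conventional Cohen bands (0.2/0.5/0.8), configurable. The sample unit
is the nonzero edge of the aggregated network; edges sharing nodes are not
independent, and the tests treat them as i.i.d. samples — implemented as
is standard in this literature, with that caveat. `balance_analysis()`
compares excitation weights against the **absolute values** of inhibition
weights (otherwise the sign difference dominates trivially): $d > 0$ means
excitation overcomes inhibition in magnitude.

Degenerate guards: $d$ is `NA` for samples of fewer than two values,
signed infinite for separated constant samples, 0 for identical constant
samples; an empty subnetwork flags the balance result `one_sided` and runs
no tests.

## Hub ranking

`eigencentrality()` scores regions by the leading eigenvector of the
absolute-weight matrix — absolute values preserve non-negativity, so the
Perron-Frobenius theorem applies. The solver is power iteration with a
deterministic uniform start, tolerance $10^{-10}$, and a cap of 10,000
iterations; it iterates on $A + I$, which has the same eigenvectors as $A$
but a strictly dominant leading eigenvalue, so near-bipartite weight
patterns cannot stall convergence. In a disconnected network only the
component with the largest leading eigenvalue is scored (others get 0, and
the scored component is recorded). Scores are normalized to unit Euclidean
norm; ranking ties break lexicographically by region name. The default
hub-set size is $k = 8$; `hub_intersection()` reports shared and
sex-specific hubs for two rankings. Rostral/caudal versus
anterior/posterior naming variants of the ventral telencephalic nuclei are
reconciled by `canonical_region()`, which treats the suffixes as synonyms
without asserting anatomical claims.

## The synthetic-data generator

The generator produces data with the statistical shape the pipeline
assumes — no more.

**Contests.** Latency and fight duration are log-normal (positive,
right-skewed, matching the shape of contest-time data); resolution time is
their sum. Behavior totals per opponent are negative binomial with mean
rate $\times$ duration and a common dispersion; default rates encode the
reported direction of sex differences (males: more bites, strikes, chases,
retreats, longer fights; females: more antiparallel displays, faster
resolution). The opponent with more aggressive acts at resolution wins
(ties: coin flip); during a two-minute confirmation window only the winner
emits aggressive acts. All defaults are conventions — the source study
publishes boxplots, not distributions — and are documented as such on
`behavior_model()`.

**Activation.** Counts are negative binomial through a Gaussian copula:
latent multivariate-normal draws with a per-condition correlation matrix
are mapped through `pnorm` and the negative-binomial quantile function.
Planted structure enters the latent correlation matrix as:

* *equicorrelated blocks*, optionally signed ($\Sigma_{ij} = r s_i s_j$
  with $s_i \in \{\pm 1\}$): a plain block at $r < -1/(k-1)$ is not
  positive semi-definite and is rejected by name at construction — mutual
  strong negative correlation among three or more variables is
  mathematically impossible, which is why planted "inhibition" uses signed
  blocks whose opposite-sign pairs carry the negative correlations;
* *hub stars*, a one-factor model in which the hub correlates at $r_{hub}$
  (default 0.6) with its partners and partners correlate at $r_{hub}^2$ —
  positive semi-definite by construction and the generative definition of
  a "globally connected" region.

Every condition's assembled matrix is eigenvalue-checked at construction.
The copula discretization attenuates the realized count correlation
slightly below the latent target (about 0.85–0.88 observed for a 0.9
target at the default means), which recovery tolerances account for.

**What passing tests do and do not show.** The generator emulates
overdispersed counts with controllable correlation and sex-biased rates.
It does not emulate contest dynamics within a fight, inter-individual
rate heterogeneity, anatomical covariates, sectioning noise, or
condition-dependent dispersion. Green recovery tests demonstrate that the
pipeline's machinery recovers structure that is present; they do not
certify that real pS6 data at $n = 6$–$9$ per stratum contains recoverable
structure. Indeed, at stratum size 8 the per-instance correlations
($s_{eff} = 7$) are noisy enough that single planted edges are sometimes
outranked by sampling noise; recovery tests therefore run at the
generator's recovery scale of $n = 500$ (with 100 seeded random
subsamples), where bootstrap averaging suppresses noise edges and planted
structure is recovered essentially always.

## Problem sizes and numerical choices

The shipped test-and-validation runs use: 200 dyads per sex for rate
recovery; $n = 500$ strata for correlation, block, hub and balance
recovery (100 seeds for recovery, 200 per balance scenario); 1,000 null
simulations with 199 permutations each for type-I calibration of the
perMANOVA and 1,000 for the gated test; 100 random 19-node networks for
the eigensolver oracle. These sizes are chosen so Monte-Carlo error is
small relative to the tolerances asserted, and the whole suite runs in
about 90 seconds.

Other numerical conventions, collected: retained-edge count uses
round-half-to-even; correlation of a zero-variance region is 0, never
`NaN`; permutation $p$-values use the add-one correction; PCA proportions
over all components sum to 1 with zero-variance components reporting 0;
power iteration shifts by $+I$; seeds fix every stochastic path
bit-for-bit, and the pipeline derives per-stage seeds from the single
global seed.

## Orchestration

`run_pipeline()` drives the six stages from one YAML config (or an
equivalent list), validates input paths before any stage runs, writes all
stage outputs as CSV plus a `manifest.yaml` (package version, config hash,
seed, file list), and serves reruns with an identical config from cache.
`run_demo()` wires a complete synthetic study through every stage:

```{r demo, eval = FALSE}
mf <- run_demo(file.path(tempdir(), "sdmn-demo"), seed = 42)
read.csv(file.path(tempdir(), "sdmn-demo", "hub_intersections.csv"))
```

## Known limitations

* Edge-weight samples violate independence (edges share nodes); the
  comparison battery follows the published convention. A
  permutation-of-individuals alternative would be the principled fix and
  is out of scope here.
* Statistical thresholding of correlations ($p$-value based), partial
  correlations, and directed connectivity are out of scope.
* The behavioral generator's distributional defaults are conventions;
  only their qualitative structure (signs of sex differences, positivity,
  right skew) is anchored.
* With strata no larger than $s$, the leave-one-out fallback yields
  highly overlapping subsamples, so "bootstrap" averaging removes little
  noise; results at such sizes should be read accordingly.
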
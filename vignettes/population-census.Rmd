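---
title: "Estimating human population size from mixed microbiome samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating human population size from mixed microbiome samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microcensus)
```

## The problem

A sewage sample is, to a first approximation, a mixture of the gut
microbiomes of the people who contributed to it. Wastewater-based
epidemiology needs to know *how many* people that was: biomarker loads are
meaningless without a denominator, and the census population of a catchment
can differ badly from the population that actually contributed at sampling
time. This package estimates the number of contributors `n` from the mixed
taxon-abundance profile alone, given a reference cohort of individual gut
microbiome profiles.

## Model

Let $X_i = (X_{i,1},\dots,X_{i,p})^\top$ be the relative abundances of $p$
taxa in individual $i$'s gut community, i.i.d. across hosts with mean $\mu$
and per-taxon standard deviations $\sigma_j$. An idealised sewage sample
from $n$ contributors is the equal-weight average
$\bar X_n = \sum_{i=1}^n X_i / n$. The census statistic is

$$T_n \;=\; \bigl\lVert \hat\Lambda_0^{-1}(\bar X_n - \hat\mu)\bigr\rVert_2^2
      \;=\; \sum_{j=1}^{p}\left(\frac{\bar X_{n,j}-\hat\mu_j}{\hat\sigma_j}\right)^{\!2},$$

where $\hat\mu_j$ is the cohort mean and
$\hat\sigma_j^2 = \sum_i (X_{ij}-\bar X_j)^2/n_0$ the cohort
population-variance estimate (divisor $n_0$). This is the diagonal analogue
of Hotelling's $T^2/n$: the full covariance is deliberately not estimated,
because with $p$ of order hundreds and cohorts of order a thousand the
sample covariance is ill-conditioned or singular, while the diagonal is
estimated well at any $p$. Because averaging $n$ independent profiles
shrinks every coordinate's variance by $1/n$, $T_n$ decreases
stochastically in $n$ — that monotone signal is what the estimator inverts.
Asymptotically $nT_n$ converges (under true parameters and mild moment
conditions) to $\lVert Z\rVert_2^2$ for a Gaussian vector $Z$ whose
covariance is the taxon correlation matrix; with independent coordinates
this is $\chi^2_p$, and the scaled statistic no longer depends on $n$.

## Estimation procedure

1. **Reference fit** (`fit_reference()`): $\hat\mu$, $\hat\sigma$ on the
   top-`k` most abundant taxa (`select_top_features()`; taxa with zero
   cross-sample variance are skipped because $\hat\Lambda_0^{-1}$ must
   exist). A median/MAD variant (`robust = TRUE`) is available for
   heavy-tailed cohorts.
2. **Bootstrap nulls** (`build_null()`): for each candidate size
   $n = 1..N$, draw `B` bootstrap mixtures of $n$ cohort members and record
   $T$, giving the sampling distribution of the statistic at that size.
   Each null carries a Gaussian-kernel density estimate.
3. **Maximum likelihood** (`estimate_population()`): for a query profile
   $W$, compute $T_0 = \lVert\hat\Lambda_0^{-1}(W-\hat\mu)\rVert_2^2$ and
   pick the $n$ whose null density at $T_0$ is highest, on the discrete
   grid $1..N$ with no interpolation; the smallest $n$ wins exact ties
   (conservative: the sample is at least that mixed).
4. **Confidence interval**: the $1-\alpha$ interval is
   $[1,\; \hat q_{1-\alpha}/T_0]$, where $\hat q_{1-\alpha}$ is the
   empirical quantile of the scaled statistic $n\,T_n$ pooled across all
   sizes — legitimate because the scaled statistic is asymptotically free
   of $n$. `pool = FALSE` instead uses the null at $\hat n$.

Two null constructions are provided. `plain_bootstrap` (default, used for
estimation) draws contributors with replacement and centres on $\hat\mu$.
`subsample_corrected` draws distinct-member subsets, centres on the cohort
grand mean and divides by $(1-n/n_0)$ — the finite-population-corrected
empirical law whose validity is what the subsampling theory establishes; it
requires $N < n_0$ and is used to cross-validate the plain bootstrap (the
acceptance suite checks the two agree in Kolmogorov–Smirnov distance at
$n = 20$, $n_0 = 2000$).

```{r example}
cohort <- cohort_preset("small", seed = 1)           # 200 hosts x 50 taxa
ref <- fit_reference(cohort, select_top_features(cohort, 20))
census <- build_null(ref, cohort, N = 60, B = 500, seed = 2)
query <- sample_mixtures(cohort, n = 25, reps = 1, seed = 3)
est <- estimate_population(otu_matrix(query)[1, ], census)
glance(est)
```

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 120 | top-abundance taxa used as features; tune with `tune_features()` (repeated 50–50 holdouts, smallest `k` on ties). Validation error is typically flat in `k`. |
| `N` | 300 | largest candidate size. Must stay well below $n_0$; `build_null()` warns when $N > n_0/3$. |
| `B` | 10,000 | bootstrap replicates per size. Desk-scale analyses and this package's tests use 400–3,000; the statistic's quantiles stabilise quickly. |
| `alpha` | 0.05 | one minus the CI level. |
| `depth` | 4,000 | rarefaction depth for count tables; samples below it are dropped and reported. |

## Numerical choices

* **KDE bandwidth**: Silverman's rule of thumb per null, floored at
  `1e-12`; the bandwidth is recorded in the null for reproducibility. A
  degenerate all-equal null falls back to the floor with a message.
* **$T_0 = 0$** (query exactly at the reference mean): every per-size
  Gaussian KDE evaluated at exactly zero sees only tail leakage, and the
  wide-bandwidth $n=1$ null would win on that artifact. The estimator
  instead reports the maximally-mixed limit $\hat n = N$, CI upper bound
  $N$, with a warning.
* **Incremental bootstrap**: replicate $b$'s $n$-person mixture extends its
  $(n-1)$-person mixture by one contributor. Marginally each stored value
  is an exact $n$-mixture statistic (each null is only ever used through
  its marginal law); this makes $N \times B$ simulation linear rather than
  quadratic in $N$.
* **Coverage caveat**: pooling $nT_n$ across sizes borrows the asymptotic
  $n$-free limit. At small true $n$ the finite-sample law of $nT_n$ is
  heavier-tailed than the pooled mixture, so one-sided intervals
  undercover somewhat there; the acceptance suite measures overall
  coverage across $n \in \{10, 50, 150\}$ against a 90% floor for the
  nominal 95% interval.
* **Rarefaction** is without replacement (hypergeometric, via
  `vegan::rrarefy()`), the standard ecological convention, wrapped for
  seed determinism. The pipeline rarefies before any family-level
  filtering; both steps are exposed separately so the order can be
  changed.

## Sewage preprocessing

Real sewage contains non-gut organisms. `build_family_filter()` ranks
families by their share of reference-cohort reads, keeps the smallest
prefix covering 99% of reads, and removes Enterobacteriaceae and
Burkholderiaceae (plausible tap-water niches); taxa without a family
mapping sit in a sentinel `"unknown"` family excluded by default.
`apply_family_filter()` drops everything else and renormalizes, reporting
the retained read fraction per sample. `welch_retain()` then keeps OTUs
whose means do not differ detectably from the reference cohort (Welch's
two-sample t, two-sided, raw $p > \alpha$). No multiple-testing correction
is applied, deliberately: the test screens features for compatibility with
the gut reference rather than controlling discoveries, so each OTU is
judged at raw $p$; its null calibration is verified in the acceptance
suite. Which sample sets enter the test (pooled vs per-site) is the
caller's choice; the default pipeline pools.

## Companion analyses

**Species abundance distributions** (`fit_sad()`, `compare_sads()`):
multi-person communities are built by *summing counts* (unlike census
mixtures, which average relative abundances), then five classic SAD models
are fitted by maximum likelihood — lognormal (closed form),
zero-truncated Poisson-lognormal (order-50 Gauss–Hermite quadrature),
Fisher's log-series (the MLE condition solved by `uniroot`, which makes
$S = \alpha\ln(1+N/\alpha)$ hold to numerical precision), Zipf as a
rank-multinomial with exponent bounded in $(0.01, 20)$, and the
parameter-free broken stick. Models are compared by ordinary least-squares
$R^2$ (with intercept) between observed and predicted rank-abundance
curves; a constant prediction scores 0 by convention. Log-likelihoods use
per-model support conventions and are for within-model diagnostics only.

**Sub-species diversity** (`nucleotide_diversity()`,
`polymorphic_sites()`, `diversity_vs_population()`): from per-site allele
counts, site heterozygosity is $h = \frac{D}{D-1}(1-\sum_a f_a^2)$ — the
probability two reads drawn without replacement differ, with the
small-depth correction since the exact estimator variant is a choice the
data do not fix; $\pi$ averages $h$ over covered sites (depth $\ge 2$ by
default) and then over genes. A site is polymorphic when its minor-allele
count reaches 1 at depth $\ge 2$; both thresholds are parameters since no
canonical values exist. Pooling hosts can only add alleles, so the
polymorphic count is monotone under aggregation — checked by enumeration
in the tests. Whether the polymorphic-site curve rises more slowly than
$\pi$ toward saturation depends on these threshold choices and on the
strain structure; it is not asserted as universal.

## What the synthetic generators emulate

`synth_cohort()` draws each host's taxon abundances as independent
zero-inflated lognormals and normalizes to the simplex. Defaults (chosen
once, as the package's standing study conditions): per-taxon mean
log-abundances are descending normal quantiles (mean −3, sd 2), so the
community's underlying abundance distribution is itself lognormal; log-sd
ramps 1.5 → 0.7 so abundant taxa vary more across hosts and different taxa
shrink at visibly different rates in mixtures; zero-inflation ramps 5% →
30%. Presets: `"small"` (200 × 50) for fast tests, `"large"`
(1,100 × 300) matching a large single-center cohort. The generator returns
its analytic pre-normalization moments for oracle tests. What it does
*not* reproduce: inter-taxon ecological correlation beyond the mild
negative correlation induced by closure (kept intentionally — the
statistic ignores covariance and should be exercised against it),
within-host temporal variation, diet or geography effects, and sequencing
noise other than multinomial resampling (`synth_counts()`). Passing tests
therefore demonstrate correctness of the machinery and of the asymptotic
approximations under the stated assumptions, not field accuracy on real
sewage.

`synth_snv_population()` builds, per gene, a reference sequence and a pool
of strains each differing from it at a `divergence` fraction of sites
(default 2% — strains of one species are closely related and carry small
private variant sets); hosts carry one strain each, with optional
within-host noise. Uneven strain frequencies can be supplied; the
saturation ceiling of polymorphic sites is exactly enumerable from the
pool (`pool_polymorphic_ceiling()`), which the tests exploit.

## Problem sizes used in validation

The test and acceptance runs use cohorts up to 1,000–2,000 hosts with
120–300 taxa, nulls with $B$ = 2,000–3,000 over $N$ = 300 sizes, 200
queries per recovery size, ~1,000 coverage trials, 5,000-replicate
asymptotic checks, and 15 communities per size for the SAD comparison —
sizes at which the Monte-Carlo error of each checked quantity is small
relative to its acceptance band, chosen so the whole suite runs on a
laptop-class single core.

## Limitations

* The method presumes an equal-weight, decay-free mixture of resident gut
  communities; unequal fecal loading and in-sewer growth/death are not
  modelled.
* Accuracy hinges on the reference cohort matching the catchment
  population's marginal taxon distributions.
* $N$ cannot meaningfully exceed a fraction of the reference cohort size.
* Estimates are reported on the discrete grid $1..N$; there is no
  between-integer interpolation.
* Serialized models and tables are plain text; no binary/BIOM container is
  written (a BIOM reader would slot behind the same `read_otu_table()`
  contract).
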
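# microcensus

Estimate **how many people contributed to a mixed gut microbiome sample**
(e.g. municipal or building-level sewage) from its taxon-abundance profile
alone, given a reference cohort of individual gut microbiome profiles. The
package is aimed at wastewater-based epidemiology, where biomarker
measurements need a real-time population denominator: the census (*de
jure*) population of a catchment can differ badly from the (*de facto*)
population that actually contributed at sampling time.

## The statistic

An idealised sewage sample from $n$ contributors is the equal-weight
average of their relative-abundance profiles,
$\bar X_n = \sum_{i=1}^n X_i / n$. Averaging shrinks each taxon's
cross-host variance by $1/n$, so the standardised deviation of the mixture
from the population mean carries the population size. The census statistic
is the diagonal Hotelling-type quantity

$$T_n = \bigl\lVert \hat\Lambda_0^{-1}(\bar X_n - \hat\mu) \bigr\rVert_2^2
      = \sum_{j=1}^{p} \left( \frac{\bar X_{n,j} - \hat\mu_j}{\hat\sigma_j} \right)^{2},$$

with $\hat\mu_j$, $\hat\sigma_j$ the reference cohort's per-taxon mean and
(population-divisor) standard deviation. Only the diagonal of the
covariance is used — essential when the number of taxa rivals or exceeds
the cohort size. Estimation is nonparametric maximum likelihood: per-size
bootstrap null distributions of $T$ (with Gaussian-kernel density
estimates) are built from the cohort for $n = 1..N$, and a query's $T_0$
is assigned the size with the highest estimated likelihood, with a
one-sided confidence interval $[1, \hat q_{1-\alpha}/T_0]$ from the
asymptotically size-free scaled statistic $nT_n$.

Alongside the estimator the package ships the surrounding pipeline:
abundance-table I/O, rarefaction and normalization; sewage preprocessing
(99%-coverage family filter excluding tap-water families, Welch t-test OTU
screening); an evaluation harness (subject-level splits, feature-count
tuning by repeated holdout, simulation benchmarks with MAPE); species
abundance distribution model comparison (lognormal, Poisson-lognormal,
log-series, Zipf, broken stick; rank-by-rank $R^2$); sub-species diversity
from SNV allele counts (nucleotide diversity, polymorphic sites,
aggregation simulations); and seed-deterministic synthetic-data generators
so everything is testable without external data.

## Worked example

Train on half of a synthetic 1,100-host cohort, estimate a 25-person
mixture built from the *held-out* half, then benchmark:

```r
library(microcensus)

cohort <- cohort_preset("large", seed = 1)  # 1,100 hosts x 300 taxa
halves <- split_cohort(cohort, 0.5, seed = 2)     # 550 train / 550 test subjects
ref    <- fit_reference(halves$train, select_top_features(halves$train, 120))
census <- build_null(ref, halves$train, N = 300, B = 2000, seed = 3)

query <- sample_mixtures(halves$test, n = 25, reps = 1, seed = 4)
estimate_population(otu_matrix(query)[1, ], census)
#> <census_estimate>
#>   T0 = 4.896  n_hat = 25
#>   95% CI: [1, 32.1]

benchmark_census(census, halves$test, sizes = c(5, 25, 100), reps = 200, seed = 5)
#> <census_benchmark> overall MAPE: 29.74 %
#> # A tibble: 3 x 4
#>   actual mean_predicted sd_predicted mean_delta
#>    <int>          <dbl>        <dbl>      <dbl>
#> 1      5           5.13         2.01       31.4
#> 2     25          20.2          5.16       24.1
#> 3    100          66.5         11.6        33.7
```

The point estimate recovers the true 25 contributors exactly here; the
interval's upper bound says the sample is compatible with at most ~32
people. On held-out subjects the mean error is ~30% across sizes 5–100 —
population-scale mixtures are identifiable, with accuracy limited by how
well the training subjects represent the test subjects.

Fitted objects follow broom conventions (`tidy()`, `glance()`) and have
`autoplot()` methods; a command-line wrapper (`inst/scripts/microcensus`)
exposes the pipeline as subcommands (`synthesize`, `build-reference`,
`fit-null`, `estimate`, `benchmark`, `tune`, `filter-sewage`,
`sad-compare`, `snv-diversity`), each writing a JSON manifest for
reproducibility.

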
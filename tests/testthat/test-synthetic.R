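test_that("cohort generator is deterministic and degenerate cases collapse", {
  a <- synth_cohort(n0 = 30, p = 10, seed = 60)
  b <- synth_cohort(n0 = 30, p = 10, seed = 60)
  expect_identical(otu_matrix(a), otu_matrix(b))
  expect_true(is_relative_table(a))
  # zero log-sd, zero inflation: every host identical after normalization
  flat <- synth_cohort(n0 = 5, p = 4, sdlog = 1e-12, zero_prob = 0, seed = 61)
  m <- otu_matrix(flat)
  expect_lt(max(apply(m, 2, stats::sd)), 1e-9)
})

test_that("generator truth matches an independent Monte-Carlo oracle", {
  # the analytic pre-normalization mean of a zero-inflated lognormal taxon,
  # checked against direct simulation of the same law
  truth <- attr(synth_cohort(n0 = 5, p = 6, seed = 62), "truth")
  set.seed(63)
  for (j in c(1, 4, 6)) {
    draws <- stats::rlnorm(5000, truth$meanlog[j], truth$sdlog[j]) *
      (stats::runif(5000) > truth$zero_prob[j])
    se <- stats::sd(draws) / sqrt(5000)
    expect_lt(abs(mean(draws) - truth$mean_pre[j]), 3 * se)
  }
  # heavy tail: cross-host skewness of a high log-sd taxon is positive
  co <- synth_cohort(n0 = 2000, p = 10, sdlog = 1.5, zero_prob = 0, seed = 64)
  x <- otu_matrix(co)[, 1]
  skew <- mean((x - mean(x))^3) / stats::sd(x)^3
  expect_gt(skew, 0)
})

test_that("per-taxon variance of mixtures shrinks at taxon-specific rates", {
  co <- synth_cohort(n0 = 400, p = 12, sdlog = c(2, rep(0.6, 11)),
                     zero_prob = 0, seed = 65)
  v1 <- apply(otu_matrix(sample_mixtures(co, 1, 3000, seed = 66)), 2, var)
  v25 <- apply(otu_matrix(sample_mixtures(co, 25, 3000, seed = 67)), 2, var)
  ratio <- v1 / v25
  # all shrink ~25-fold but not identically across taxa
  expect_true(all(ratio > 10))
  expect_gt(max(ratio) - min(ratio), 1)
})

test_that("count sampling respects depth and expected proportions", {
  co <- synth_cohort(n0 = 40, p = 15, seed = 68)
  counts <- synth_counts(co, depth = 3000, seed = 69)
  expect_true(all(rowSums(otu_matrix(counts)) == 3000))
  expect_identical(otu_matrix(counts),
                   otu_matrix(synth_counts(co, depth = 3000, seed = 69)))
  pr <- otu_matrix(co)[1, 1]
  k <- otu_matrix(counts)[1, 1]
  expect_lt(abs(k - 3000 * pr), 3 * sqrt(3000 * pr * (1 - pr)) + 1)
})

test_that("rarefying deeper counts is distributionally equivalent to direct sampling", {
  co <- synth_cohort(n0 = 200, p = 12, seed = 70)
  deep <- synth_counts(co, depth = 2000, seed = 71)
  direct <- synth_counts(co, depth = 1000, seed = 72)
  rare <- suppressMessages(rarefy(deep, 1000, seed = 73))
  j <- select_top_features(co, 1)
  ks <- suppressWarnings(
    stats::ks.test(otu_matrix(rare)[, j], otu_matrix(direct)[, j]))
  expect_gt(ks$p.value, 0.01)
})

test_that("synthetic sewage mixes gut signal with a controlled background", {
  co <- fixture_cohort()
  pure <- synth_sewage(co, n = 6, background_fraction = 0, reps = 2, seed = 74)
  m <- otu_matrix(pure$table)
  expect_equal(unname(rowSums(m)), c(1, 1))
  expect_true(all(m[, grepl("^bg_", colnames(m))] == 0))
  sw <- synth_sewage(co, n = 6, background_fraction = 0.3, reps = 3, seed = 75)
  ff <- build_family_filter(co, sw$taxonomy)
  ap <- apply_family_filter(sw$table, sw$taxonomy, ff)
  # construction oracle: retained fraction ~ 1 - background_fraction
  expect_equal(ap$retained$retained_fraction, rep(0.7, 3), tolerance = 0.02)
})

test_that("census estimates agree between filtered sewage and the pure mixture", {
  co <- fixture_cohort()
  census <- fixture_census()
  sw <- synth_sewage(co, n = 10, background_fraction = 0.3, reps = 4,
                     seed = 76)
  ff <- build_family_filter(co, sw$taxonomy)
  ap <- apply_family_filter(sw$table, sw$taxonomy, ff)
  pure <- t(vapply(sw$contributors, function(ids) {
    colMeans(otu_matrix(co)[ids, , drop = FALSE])
  }, numeric(ncol(co) - 1)))
  rownames(pure) <- paste0("pure_", seq_len(nrow(pure)))
  e_pure <- estimate_populations(as_otu_table(pure), census)
  e_filt <- estimate_populations(ap$table, census)
  expect_equal(e_filt$n_hat, e_pure$n_hat)
})

test_that("haplotype populations behave as constructed", {
  solo <- synth_snv_population(hosts = 6, genes = 2, sites_per_gene = 25,
                               haplotype_pool_size = 1, depth = 10, seed = 77)
  pooled <- aggregate_profiles(solo)
  expect_equal(as.integer(polymorphic_sites(pooled)), 0)
  pop <- synth_snv_population(hosts = 10, genes = 2, sites_per_gene = 30,
                              haplotype_pool_size = 4, depth = 15, seed = 78)
  single_pi <- nucleotide_diversity(pop[[1]], min_depth = 2)$pi
  pooled_pi <- nucleotide_diversity(aggregate_profiles(pop))$pi
  expect_lte(single_pi, pooled_pi)
  # saturation equals the enumerated number of variable pool sites when
  # every pool haplotype is carried by at least one host
  truth <- attr(pop, "truth")
  carried <- all(vapply(seq_len(2), function(g) {
    length(unique(truth$assignment[, g])) == 4
  }, logical(1)))
  if (carried) {
    expect_equal(as.integer(polymorphic_sites(aggregate_profiles(pop))),
                 pool_polymorphic_ceiling(truth))
  }
})
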
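test_that("T statistic matches hand arithmetic and the diagonal Hotelling form", {
  ref <- new_census_ref(c("A", "B"), c(0.5, 0.5), c(0.1, 0.2), n0 = 100)
  expect_equal(t_statistic(c(A = 0.6, B = 0.3), ref), 2)
  expect_equal(t_statistic(c(A = 0.5, B = 0.5), ref), 0)
  expect_error(t_statistic(c(A = 0.5), ref), "B")

  # with a diagonal covariance, T equals the Hotelling quadratic form / n:
  # brute-force matrix computation on a 3-taxon cohort
  set.seed(8)
  x <- cbind(a = runif(40, 0.1, 0.3), b = runif(40, 0.2, 0.4),
             c = runif(40, 0.3, 0.5))
  mu <- colMeans(x)
  sig2 <- colMeans(sweep(x, 2, mu)^2)
  ref3 <- new_census_ref(colnames(x), mu, sqrt(sig2), n0 = 40)
  w <- c(a = 0.22, b = 0.31, c = 0.41)
  sigma_mat <- diag(sig2)
  hotelling_over_n <- drop(t(w - mu) %*% solve(sigma_mat) %*% (w - mu))
  expect_equal(t_statistic(w, ref3), hotelling_over_n)
})

test_that("T is invariant to rescaling a taxon in cohort and query together", {
  set.seed(9)
  x <- cbind(a = runif(30), b = runif(30))
  make_ref <- function(m) {
    new_census_ref(colnames(m), pmin(colMeans(m), 1),
                   sqrt(colMeans(sweep(m, 2, colMeans(m))^2)), nrow(m))
  }
  w <- c(a = 0.4, b = 0.6)
  t1 <- t_statistic(w, make_ref(x))
  cc <- 0.35
  x2 <- x; x2[, "a"] <- x2[, "a"] * cc
  w2 <- w; w2["a"] <- w2["a"] * cc
  expect_equal(t_statistic(w2, make_ref(x2)), t1)
})

test_that("plain bootstrap at n = 1 draws from the per-individual statistics", {
  co <- fixture_cohort()
  census <- fixture_census()
  singles <- t_statistic(co, census$reference)
  expect_true(all(census$nulls[[1]]$t_samples %in% singles))
})

test_that("scaled statistic has mean p under true parameters", {
  # independent gamma coordinates with known moments, modest scale; the
  # full-scale version of this identity lives in the acceptance suite
  set.seed(10)
  p <- 8; n <- 50; reps <- 2000
  shape <- 4; rate <- 40
  ref <- new_census_ref(paste0("f", 1:p), rep(shape / rate, p),
                        rep(sqrt(shape) / rate, p), n0 = 1e6)
  draws <- matrix(stats::rgamma(reps * n * p, shape, rate), nrow = reps * n)
  mix <- rowsum(draws, rep(seq_len(reps), each = n)) / n
  colnames(mix) <- paste0("f", 1:p)
  nt <- n * t_statistic(mix, ref)
  expect_lt(abs(mean(nt) - p), 3 * stats::sd(nt) / sqrt(reps))
})

test_that("null medians decrease with population size", {
  census <- fixture_census()
  med <- vapply(c(1, 5, 25, 60),
                function(n) stats::median(census$nulls[[n]]$t_samples),
                numeric(1))
  expect_true(all(diff(med) < 0))
})

test_that("kernel density estimates are normalized, symmetric and unimodal-faithful", {
  null2 <- microcensus:::new_t_stat_null(1, c(1, 3), "plain_bootstrap")
  expect_equal(density_at(null2, 1), density_at(null2, 3))
  census <- fixture_census()
  nl <- census$nulls[[5]]
  grid <- seq(min(nl$t_samples) - 10 * nl$bandwidth,
              max(nl$t_samples) + 10 * nl$bandwidth, length.out = 4000)
  mass <- sum(density_at(nl, grid)) * diff(grid[1:2])
  expect_equal(mass, 1, tolerance = 1e-3)
  med <- stats::median(nl$t_samples)
  far <- max(nl$t_samples) + 5 * nl$bandwidth
  expect_gt(density_at(nl, med), density_at(nl, far))
})

test_that("degenerate all-equal null falls back to the minimum bandwidth", {
  expect_message(nl <- microcensus:::new_t_stat_null(3, rep(2, 50), "plain_bootstrap"),
                 "minimum bandwidth")
  expect_gte(nl$bandwidth, 1e-12)
  expect_true(is.finite(density_at(nl, 2)))
})

test_that("estimation picks the most likely size; degenerate cases handled", {
  co <- fixture_cohort()
  census <- fixture_census()
  # single-candidate model must return that candidate
  solo <- census
  solo$nulls <- census$nulls[1]
  solo$N <- 1L
  w <- otu_matrix(sample_mixtures(co, 3, 1, seed = 11))[1, ]
  expect_equal(estimate_population(w, solo)$n_hat, 1L)
  # query at the cohort grand mean: T0 = 0, highest density at the largest n
  gm <- colMeans(otu_matrix(co))
  expect_warning(est <- estimate_population(gm, census), "T0 = 0")
  expect_equal(est$n_hat, census$N)
  expect_equal(est$ci[2], as.numeric(census$N))
  expect_error(estimate_population(w, census, alpha = 2), "alpha")
})

test_that("census model building and estimation are seed-reproducible", {
  co <- fixture_cohort()
  ref <- fit_reference(co, select_top_features(co, 10))
  a <- suppressWarnings(build_null(ref, co, N = 30, B = 200, seed = 12))
  b <- suppressWarnings(build_null(ref, co, N = 30, B = 200, seed = 12))
  expect_identical(lapply(a$nulls, `[[`, "t_samples"),
                   lapply(b$nulls, `[[`, "t_samples"))
  w <- otu_matrix(sample_mixtures(co, 7, 1, seed = 13))[1, ]
  ea <- estimate_population(w, a)
  eb <- estimate_population(w, b)
  expect_identical(ea$n_hat, eb$n_hat)
  expect_identical(ea$loglik, eb$loglik)
  expect_identical(ea$ci, eb$ci)
})

test_that("subsample mode enforces N < n0 and applies the finite-population correction", {
  co <- fixture_cohort()
  ref <- fit_reference(co, select_top_features(co, 10))
  expect_error(build_null(ref, co, N = nrow(co), B = 200,
                          mode = "subsample_corrected"), "N <")
  expect_error(build_null(ref, co, N = 10, B = 50), "at least 100")
  # at n = 1 the corrected values are the centred singles / (1 - 1/n0)
  cm <- suppressWarnings(build_null(ref, co, N = 5, B = 150,
                                    mode = "subsample_corrected", seed = 14))
  m <- otu_matrix(co)[, ref$feature_ids]
  centred <- colSums(((t(m) - colMeans(m)) / ref$sigma_hat)^2)
  corrected <- centred / (1 - 1 / nrow(co))
  expect_true(all(vapply(cm$nulls[[1]]$t_samples, function(v) {
    any(abs(v - corrected) < 1e-12)
  }, logical(1))))
})

test_that("census model serialization round-trips estimates", {
  census <- fixture_census()
  path <- tempfile()
  write_census_model(census, path)
  back <- read_census_model(path)
  expect_equal(back$N, census$N)
  expect_equal(back$mode, census$mode)
  expect_equal(back$nulls[[10]]$t_samples, census$nulls[[10]]$t_samples)
  co <- fixture_cohort()
  w <- otu_matrix(sample_mixtures(co, 9, 1, seed = 15))[1, ]
  expect_identical(estimate_population(w, back)$n_hat,
                   estimate_population(w, census)$n_hat)
})
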
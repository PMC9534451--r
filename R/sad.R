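#' Fit a species abundance distribution model by maximum likelihood
#'
#' Fits one of five classic SAD models to a vector of species abundances
#' (positive counts, one per observed species):
#'
#' * `lognormal` — continuous lognormal on abundances; closed-form MLE.
#' * `poisson_lognormal` — zero-truncated Poisson-lognormal; the likelihood
#'   marginalises the lognormal mean by Gauss-Hermite quadrature (order 50)
#'   and is maximised numerically. Zero truncation because unobserved
#'   species are unknowable.
#' * `logseries` — Fisher's log-series; the MLE for x solves the mean-count
#'   condition \eqn{N/S = -x/((1-x)\log(1-x))}, and \eqn{\alpha = N(1-x)/x}.
#' * `zipf` — discrete power law on ranks with a multinomial likelihood;
#'   exponent bounded in (0.01, 20) for optimiser stability.
#' * `brokenstick` — MacArthur's broken stick; no free parameters.
#'
#' Log-likelihoods are comparable within a model (used for optimality
#' checks), not across models with different support conventions; model
#' comparison uses [rank_r2()] on predicted rank-abundance curves.
#'
#' @param counts positive integer abundances, one per species.
#' @param model one of `"lognormal"`, `"poisson_lognormal"`, `"logseries"`,
#'   `"brokenstick"`, `"zipf"`.
#' @return a `sad_fit`: model name, named parameter vector (empty for the
#'   broken stick), `logLik`, `converged`, and the observed `S` and `N`.
#' @export
fit_sad <- function(counts, model = c("lognormal", "poisson_lognormal",
                                      "logseries", "brokenstick", "zipf")) {
  model <- match.arg(model)
  counts <- as.numeric(counts)
  if (any(counts <= 0) || any(counts != round(counts))) {
    stop("counts must be positive integers (drop unobserved species first)",
         call. = FALSE)
  }
  S <- length(counts)
  N <- sum(counts)
  if (model != "brokenstick" && S < 3) {
    stop("parametric SAD fits need at least 3 species", call. = FALSE)
  }
  fit <- switch(model,
    lognormal = fit_sad_lognormal(counts),
    poisson_lognormal = fit_sad_pln(counts),
    logseries = fit_sad_logseries(counts, S, N),
    zipf = fit_sad_zipf(counts, S),
    brokenstick = fit_sad_brokenstick(counts, S)
  )
  structure(c(fit, list(model = model, S = S, N = N)), class = "sad_fit")
}

fit_sad_lognormal <- function(x) {
  meanlog <- mean(log(x))
  sdlog <- sqrt(mean((log(x) - meanlog)^2))   # MLE divisor S
  list(parameters = c(meanlog = meanlog, sdlog = sdlog),
       logLik = sum(stats::dlnorm(x, meanlog, sdlog, log = TRUE)),
       converged = TRUE)
}

# zero-truncated Poisson-lognormal pmf on the unique counts, by
# Gauss-Hermite quadrature over the lognormal latent mean
pln_log_pmf <- function(k, mu, sig, gh) {
  # lambda_i = exp(mu + sig * sqrt(2) * t_i); weights w_i / sqrt(pi)
  lam <- exp(mu + sig * sqrt(2) * gh$x)
  w <- gh$w / sqrt(pi)
  pk <- vapply(k, function(ki) sum(w * stats::dpois(ki, lam)), numeric(1))
  p0 <- sum(w * exp(-lam))
  log(pmax(pk, 1e-300)) - log(pmax(1 - p0, 1e-300))
}

fit_sad_pln <- function(x, order = 50) {
  gh <- pracma::gaussHermite(order)
  tab <- table(x)
  k <- as.numeric(names(tab))
  nk <- as.numeric(tab)
  nll <- function(par) {
    -sum(nk * pln_log_pmf(k, par[1], exp(par[2]), gh))
  }
  init <- c(mean(log(x)), log(max(stats::sd(log(x)), 0.1)))
  opt <- stats::optim(init, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000))
  list(parameters = c(mu = opt$par[1], sigma = exp(opt$par[2])),
       logLik = -opt$value, converged = opt$convergence == 0)
}

fit_sad_logseries <- function(x, S, N) {
  mean_k <- N / S
  if (mean_k <= 1 + 1e-12) {
    # all (or nearly all) singletons: x -> 0 boundary
    xs <- 1e-12
  } else {
    f <- function(xx) -xx / ((1 - xx) * log1p(-xx)) - mean_k
    xs <- stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-14)$root
  }
  alpha <- N * (1 - xs) / xs
  list(parameters = c(alpha = alpha, x = xs),
       logLik = sum(log(-xs^x / (x * log1p(-xs)))),
       converged = TRUE)
}

fit_sad_zipf <- function(x, S) {
  n_sorted <- sort(x, decreasing = TRUE)
  ranks <- seq_len(S)
  nll <- function(g) {
    lp <- -g * log(ranks) - log(sum(ranks^(-g)))
    -sum(n_sorted * lp)
  }
  opt <- stats::optimize(nll, c(0.01, 20))
  list(parameters = c(exponent = opt$minimum),
       logLik = -opt$objective, converged = TRUE)
}

fit_sad_brokenstick <- function(x, S) {
  n_sorted <- sort(x, decreasing = TRUE)
  # expected proportion at rank i: (1/S) * sum_{k=i..S} 1/k
  p <- rev(cumsum(1 / rev(seq_len(S)))) / S
  list(parameters = numeric(0),
       logLik = sum(n_sorted * log(p)),
       converged = TRUE)
}

#' @export
print.sad_fit <- function(x, ...) {
  cat("<sad_fit>", x$model, " S =", x$S, " N =", x$N, "\n")
  if (length(x$parameters)) print(round(x$parameters, 4))
  cat("  logLik:", format(x$logLik, digits = 6),
      if (!x$converged) " (NOT converged)" else "", "\n")
  invisible(x)
}

#' Tidy a SAD fit
#'
#' @param x a `sad_fit`.
#' @param ... unused.
#' @export
tidy.sad_fit <- function(x, ...) {
  tibble::tibble(term = names(x$parameters),
                 estimate = unname(x$parameters))
}

#' @rdname tidy.sad_fit
#' @export
glance.sad_fit <- function(x, ...) {
  tibble::tibble(model = x$model, logLik = x$logLik,
                 converged = x$converged, S = x$S, N = x$N)
}

#' Expected rank-abundance curve under a fitted SAD model
#'
#' Tabulates the fitted model as a rank abundance distribution with `S`
#' ranks scaled to total abundance `N`. Parametric models are tabulated at
#' the rank plotting positions `(i - 0.5)/S` of their fitted quantile
#' function; the broken stick has the closed form
#' \eqn{E[rank\ i] = (N/S) \sum_{k=i}^{S} 1/k}; Zipf is
#' \eqn{N i^{-\gamma} / \sum_j j^{-\gamma}}.
#'
#' @param fit a `sad_fit`.
#' @param S number of ranks (defaults to the fitted S).
#' @param N total abundance to scale to (defaults to the fitted N).
#' @return numeric vector of expected abundances, rank 1 (largest) first.
#' @export
expected_rad <- function(fit, S = fit$S, N = fit$N) {
  stopifnot(inherits(fit, "sad_fit"))
  i <- seq_len(S)
  pp <- (S - i + 0.5) / S   # rank 1 -> highest quantile
  rad <- switch(fit$model,
    brokenstick = (N / S) * rev(cumsum(1 / rev(i))),
    zipf = {
      g <- fit$parameters[["exponent"]]
      N * i^(-g) / sum(i^(-g))
    },
    lognormal = {
      q <- stats::qlnorm(pp, fit$parameters[["meanlog"]],
                         fit$parameters[["sdlog"]])
      q * N / sum(q)
    },
    poisson_lognormal = {
      q <- discrete_quantile(pln_cdf_fun(fit$parameters[["mu"]],
                                         fit$parameters[["sigma"]]), pp)
      q * N / sum(q)
    },
    logseries = {
      q <- discrete_quantile(logseries_cdf_fun(fit$parameters[["x"]]), pp)
      q * N / sum(q)
    }
  )
  unname(rad)
}

# returns function(kmax) -> cdf over 1..kmax for the zero-truncated PLN
pln_cdf_fun <- function(mu, sigma, order = 50) {
  gh <- pracma::gaussHermite(order)
  function(kmax) cumsum(exp(pln_log_pmf(seq_len(kmax), mu, sigma, gh)))
}

logseries_cdf_fun <- function(xs) {
  function(kmax) {
    k <- seq_len(kmax)
    cumsum(-xs^k / (k * log1p(-xs)))
  }
}

# quantiles of a discrete distribution on 1, 2, ... given its cdf generator
discrete_quantile <- function(cdf_fun, probs) {
  kmax <- 256L
  cdf <- cdf_fun(kmax)
  while (max(cdf) < max(probs) && kmax < 2^22) {
    kmax <- kmax * 4L
    cdf <- cdf_fun(kmax)
  }
  vapply(probs, function(p) {
    idx <- which(cdf >= p)
    if (length(idx)) as.numeric(idx[1]) else as.numeric(kmax)
  }, numeric(1))
}

#' Rank-by-rank goodness of fit of a predicted RAD
#'
#' Least-squares regression (with intercept) of observed on predicted
#' abundances, matched rank by rank; returns the coefficient of
#' determination. A constant predicted vector is a degenerate regressor and
#' scores 0 by convention.
#'
#' @param observed observed abundances (any order; sorted internally).
#' @param predicted predicted abundances, same length.
#' @return R-squared, at most 1.
#' @export
rank_r2 <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted RADs differ in length", call. = FALSE)
  }
  obs <- sort(as.numeric(observed), decreasing = TRUE)
  pred <- sort(as.numeric(predicted), decreasing = TRUE)
  if (stats::var(pred) == 0 || stats::var(obs) == 0) return(0)
  # a perfect fit triggers a harmless precision warning in summary.lm
  suppressWarnings(summary(stats::lm(obs ~ pred))$r.squared)
}

#' Compare SAD models across multi-person community sizes
#'
#' For each population size, builds `reps` multi-person communities by
#' summing the counts of randomly drawn individuals (with replacement, as in
#' bootstrap mixture generation — note this sums raw abundances, unlike the
#' census mixtures which average relative abundances), fits all five SAD
#' models to each community, scores each by [rank_r2()] against the observed
#' RAD, and reports the mean R-squared per model and the winner per size.
#'
#' @param tbl an OTU table of integer counts, one row per individual.
#' @param sizes population sizes to evaluate.
#' @param reps communities per size.
#' @param seed integer seed.
#' @param models subset of models to fit (default all five).
#' @return a list: `summary` (one row per size x model: mean/sd R-squared,
#'   wins) and `winner` (one row per size).
#' @export
compare_sads <- function(tbl, sizes, reps = 100L, seed = 1L,
                         models = c("lognormal", "poisson_lognormal",
                                    "logseries", "brokenstick", "zipf")) {
  validate_otu_table(tbl)
  m <- otu_matrix(tbl)
  if (any(m != round(m))) stop("compare_sads needs integer counts", call. = FALSE)
  n0 <- nrow(m)
  records <- with_seed_local(seed, {
    purrr::map_dfr(sizes, function(n) {
      purrr::map_dfr(seq_len(reps), function(r) {
        idx <- sample.int(n0, n, replace = TRUE)
        community <- colSums(m[idx, , drop = FALSE])
        counts <- sort(community[community > 0], decreasing = TRUE)
        purrr::map_dfr(models, function(mod) {
          r2 <- tryCatch({
            fit <- fit_sad(counts, mod)
            rank_r2(counts, expected_rad(fit))
          }, error = function(e) NA_real_)
          tibble::tibble(size = n, rep = r, model = mod, r2 = r2)
        })
      })
    })
  })
  wins <- records |>
    dplyr::filter(!is.na(.data$r2)) |>
    dplyr::group_by(.data$size, .data$rep) |>
    dplyr::slice_max(.data$r2, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::count(.data$size, .data$model, name = "wins")
  summary <- records |>
    dplyr::group_by(.data$size, .data$model) |>
    dplyr::summarise(mean_r2 = mean(.data$r2, na.rm = TRUE),
                     sd_r2 = stats::sd(.data$r2, na.rm = TRUE),
                     n_ok = sum(!is.na(.data$r2)), .groups = "drop") |>
    dplyr::left_join(wins, by = c("size", "model")) |>
    dplyr::mutate(wins = dplyr::coalesce(.data$wins, 0L))
  winner <- summary |>
    dplyr::group_by(.data$size) |>
    dplyr::slice_max(.data$mean_r2, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("size", best_model = "model", "mean_r2")
  list(summary = summary, winner = winner, records = records)
}
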
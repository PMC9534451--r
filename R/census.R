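#' The census T statistic
#'
#' For a mixture profile `w` and a reference model with per-taxon means
#' \eqn{\hat\mu_j} and standard deviations \eqn{\hat\sigma_j}, the statistic is
#' \deqn{T = \sum_j \left(\frac{w_j - \hat\mu_j}{\hat\sigma_j}\right)^2,}
#' the squared Euclidean norm of the standardised deviation of the mixture
#' from the population mean. It is the diagonal analogue of Hotelling's
#' \eqn{T^2/n}: because an n-person mixture averages n independent profiles,
#' T shrinks stochastically as the number of contributors grows, which is the
#' signal the population-size estimator exploits.
#'
#' @param w a named relative-abundance vector, a matrix with taxon columns
#'   (one row per profile), or an OTU table; must contain every model feature.
#' @param model a `census_ref` reference model.
#' @return a non-negative number, or a vector with one value per row when `w`
#'   holds several profiles.
#' @examples
#' ref <- new_census_ref(c("A", "B"), c(0.5, 0.5), c(0.1, 0.2), n0 = 100)
#' t_statistic(c(A = 0.6, B = 0.3), ref)  # (0.1/0.1)^2 + (0.2/0.2)^2 = 2
#' @export
t_statistic <- function(w, model) {
  stopifnot(inherits(model, "census_ref"))
  single <- FALSE
  if (is.data.frame(w)) {
    w <- otu_matrix(w)
  } else if (!is.matrix(w)) {
    single <- TRUE
    w <- matrix(w, nrow = 1, dimnames = list(NULL, names(w)))
  }
  feats <- model$feature_ids
  if (is.null(colnames(w))) {
    if (ncol(w) != length(feats)) {
      stop("unnamed profile length ", ncol(w), " does not match the ",
           length(feats), " model features", call. = FALSE)
    }
    colnames(w) <- feats
  }
  missing <- setdiff(feats, colnames(w))
  if (length(missing)) {
    stop("profile lacks model feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  z <- (t(w[, feats, drop = FALSE]) - model$mu_hat) / model$sigma_hat
  out <- colSums(z^2)
  if (single) unname(out) else out
}

#' Build per-size bootstrap null distributions of the T statistic
#'
#' For every candidate number of contributors `n = 1..N`, simulates `B`
#' n-person mixtures from the reference cohort and records the T statistic of
#' each, giving the sampling distribution ("null") of T at that population
#' size. Two constructions are available:
#'
#' * `plain_bootstrap` (default): contributors drawn with replacement,
#'   statistic centred on the cohort estimates in `model` — the procedure used
#'   for estimation.
#' * `subsample_corrected`: distinct-member subsets, statistic
#'   \eqn{\|\hat\Lambda_0^{-1}(\bar X_A - \bar X_{n_0})\|_2^2 / (1 - n/n_0)}
#'   centred on the cohort grand mean with a finite-population correction, the
#'   construction whose empirical law provably tracks the distribution of
#'   \eqn{T_n}; used to cross-validate the plain bootstrap.
#'
#' For speed, replicate b's n-person mixture extends its (n-1)-person mixture
#' by one additional contributor; each stored value is still an exact
#' n-mixture statistic, and each per-size null is used only through its
#' marginal distribution.
#'
#' @param model a `census_ref` fitted on (or consistent with) `tbl`.
#' @param tbl the relative-abundance reference cohort.
#' @param N largest candidate population size.
#' @param B bootstrap replicates per size (>= 100).
#' @param mode `"plain_bootstrap"` or `"subsample_corrected"`.
#' @param seed integer seed; the model is bit-reproducible given the seed.
#' @return a `census_model`: the reference plus, for each n, the B statistic
#'   values and the Gaussian-kernel bandwidth used by [density_at()].
#' @export
build_null <- function(model, tbl, N = 300L, B = 10000L,
                       mode = c("plain_bootstrap", "subsample_corrected"),
                       seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "census_ref"))
  assert_relative(tbl)
  if (B < 100) stop("B must be at least 100", call. = FALSE)
  m <- otu_matrix(tbl)[, model$feature_ids, drop = FALSE]
  n0 <- nrow(m)
  if (mode == "subsample_corrected" && N >= n0) {
    stop("subsample_corrected needs N < cohort size (correction factor ",
         "1 - n/n0 must stay positive); N = ", N, ", n0 = ", n0, call. = FALSE)
  }
  if (N > n0 / 3) {
    warning("N = ", N, " is not small relative to the cohort size n0 = ", n0,
            "; null distributions at the largest sizes may be distorted",
            call. = FALSE)
  }
  center <- if (mode == "plain_bootstrap") model$mu_hat else colMeans(m)
  sigma <- model$sigma_hat
  p <- ncol(m)

  t_mat <- with_seed_local(seed, {
    out <- matrix(NA_real_, nrow = B, ncol = N)
    S <- matrix(0, nrow = B, ncol = p)
    if (mode == "subsample_corrected") {
      # per-replicate random orderings of distinct members; taking the first n
      # of an ordering gives a uniform size-n subset for every n
      perm <- t(vapply(seq_len(B), function(b) sample.int(n0, N),
                       integer(N)))
    }
    for (n in seq_len(N)) {
      idx <- if (mode == "plain_bootstrap") {
        sample.int(n0, B, replace = TRUE)
      } else {
        perm[, n]
      }
      S <- S + m[idx, , drop = FALSE]
      z <- (t(S) / n - center) / sigma
      tn <- colSums(z^2)
      if (mode == "subsample_corrected") tn <- tn / (1 - n / n0)
      out[, n] <- tn
    }
    out
  })

  nulls <- lapply(seq_len(N), function(n) {
    samp <- t_mat[, n]
    new_t_stat_null(n, samp, mode)
  })
  structure(
    list(reference = model, nulls = nulls, N = as.integer(N),
         B = as.integer(B), mode = mode, seed = as.integer(seed),
         train_sample_ids = rownames(m)),
    class = "census_model"
  )
}

new_t_stat_null <- function(n, t_samples, mode) {
  bw <- max(stats::bw.nrd0(t_samples), 1e-12)
  if (stats::sd(t_samples) == 0) {
    message("degenerate null at n = ", n,
            ": all bootstrap values equal; minimum bandwidth used")
  }
  list(n = as.integer(n), t_samples = t_samples, bandwidth = bw, mode = mode)
}

#' @export
print.census_model <- function(x, ...) {
  cat("<census_model>\n")
  cat("  candidate sizes: 1..", x$N, "  B = ", x$B, " (", x$mode, ")\n",
      sep = "")
  cat("  reference: p =", length(x$reference$feature_ids),
      "features, n0 =", x$reference$n0, "\n")
  invisible(x)
}

#' Tidy the per-size null distributions of a census model
#'
#' @param x a `census_model`.
#' @param ... unused.
#' @return one row per candidate size with summary quantiles of the
#'   bootstrap T values and the KDE bandwidth.
#' @export
tidy.census_model <- function(x, ...) {
  purrr::map_dfr(x$nulls, function(nl) {
    q <- stats::quantile(nl$t_samples, c(0.25, 0.5, 0.75), names = FALSE)
    tibble::tibble(n = nl$n, t_q25 = q[1], t_median = q[2], t_q75 = q[3],
                   bandwidth = nl$bandwidth)
  })
}

#' @rdname tidy.census_model
#' @export
glance.census_model <- function(x, ...) {
  tibble::tibble(N = x$N, B = x$B, mode = x$mode,
                 p = length(x$reference$feature_ids), n0 = x$reference$n0,
                 seed = x$seed)
}

#' Gaussian kernel density of a bootstrap null at a point
#'
#' Evaluates the Gaussian-kernel density estimate of one per-size null at the
#' value(s) `t`, using the bandwidth fixed when the null was built
#' (Silverman's rule of thumb, floored at 1e-12).
#'
#' @param null one element of `census_model$nulls`.
#' @param t numeric value(s) at which to evaluate.
#' @return strictly positive density value(s).
#' @export
density_at <- function(null, t) {
  vapply(t, function(ti) {
    mean(stats::dnorm(ti, mean = null$t_samples, sd = null$bandwidth))
  }, numeric(1))
}

# log density of every per-size null at each query statistic:
# rows = queries, columns = n. Vectorised over queries for speed.
null_logdensity_matrix <- function(census, t0) {
  out <- matrix(NA_real_, nrow = length(t0), ncol = census$N)
  chunk <- max(1L, floor(4e6 / max(lengths(lapply(census$nulls, `[[`,
                                                  "t_samples")))))
  starts <- seq(1L, length(t0), by = chunk)
  for (j in seq_len(census$N)) {
    nl <- census$nulls[[j]]
    for (s in starts) {
      idx <- s:min(s + chunk - 1L, length(t0))
      d <- rowMeans(stats::dnorm(outer(t0[idx], nl$t_samples, "-"),
                                 sd = nl$bandwidth))
      out[idx, j] <- log(pmax(d, .Machine$double.xmin))
    }
  }
  out
}

# empirical (1 - alpha) quantile of n * T_n, pooled across sizes (the scaled
# statistic is asymptotically size-free) or taken from the null at n_hat
pooled_scaled_quantile <- function(census, alpha, pool = TRUE, n_hat = NULL) {
  if (pool) {
    scaled <- unlist(lapply(census$nulls, function(nl) nl$n * nl$t_samples),
                     use.names = FALSE)
  } else {
    nl <- census$nulls[[n_hat]]
    scaled <- nl$n * nl$t_samples
  }
  stats::quantile(scaled, 1 - alpha, names = FALSE)
}

#' Estimate the number of contributors to a mixture profile
#'
#' Computes the observed statistic \eqn{T_0} of the query profile, evaluates
#' its likelihood under every per-size bootstrap null (via the stored kernel
#' density estimates), and returns the size with the highest likelihood
#' (smallest size on exact ties). The one-sided confidence interval is
#' \eqn{[1, \hat q_{1-\alpha}/T_0]}, where \eqn{\hat q_{1-\alpha}} is the
#' empirical quantile of the scaled statistic \eqn{n T_n} pooled across sizes
#' (asymptotically the scaled statistic does not depend on n).
#'
#' @param w a named relative-abundance query profile (or OTU table row).
#' @param census a `census_model` from [build_null()].
#' @param alpha one minus the confidence level, in (0, 1).
#' @param pool pool `n * T_n` across all sizes for the CI quantile (default);
#'   otherwise use the null at the point estimate only.
#' @return a `census_estimate` with fields `t0`, `n_hat`, `loglik` (log
#'   likelihood over n = 1..N), `alpha` and `ci = c(1, upper)`.
#' @export
estimate_population <- function(w, census, alpha = 0.05, pool = TRUE) {
  stopifnot(inherits(census, "census_model"))
  if (length(census$nulls) == 0) stop("census model has no nulls", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  t0 <- t_statistic(w, census$reference)
  if (length(t0) != 1) {
    stop("estimate_population() takes a single profile; see ",
         "estimate_populations() for batches", call. = FALSE)
  }
  ll <- drop(null_logdensity_matrix(census, t0))
  n_hat <- which.max(ll)   # which.max returns the smallest index on ties
  if (t0 == 0) {
    # a query exactly at the reference mean is the maximally-mixed limit:
    # every null's density at 0 is tail leakage, so report the largest size
    warning("T0 = 0 (query exactly at the reference mean); ",
            "n_hat and the CI upper bound reported as N", call. = FALSE)
    n_hat <- census$N
    upper <- as.numeric(census$N)
  } else {
    upper <- max(1, pooled_scaled_quantile(census, alpha, pool, n_hat) / t0)
  }
  structure(
    list(t0 = unname(t0), n_hat = as.integer(n_hat), loglik = unname(ll),
         alpha = alpha, ci = c(1, upper), N = census$N),
    class = "census_estimate"
  )
}

#' Estimate contributor counts for many query profiles at once
#'
#' Batch version of [estimate_population()], sharing the per-size density
#' evaluations across queries.
#'
#' @param queries an OTU table (or matrix) of query profiles, one per row.
#' @inheritParams estimate_population
#' @return a tibble with one row per query: `sample_id`, `t0`, `n_hat`,
#'   `ci_lower`, `ci_upper`.
#' @export
estimate_populations <- function(queries, census, alpha = 0.05, pool = TRUE) {
  stopifnot(inherits(census, "census_model"))
  ids <- if (is.data.frame(queries)) queries$sample_id
         else rownames(queries) %||% paste0("q", seq_len(nrow(queries)))
  t0 <- t_statistic(queries, census$reference)
  ll <- null_logdensity_matrix(census, t0)
  n_hat <- apply(ll, 1, which.max)
  n_hat[t0 == 0] <- census$N
  q <- pooled_scaled_quantile(census, alpha, pool = TRUE)
  upper <- ifelse(t0 == 0, as.numeric(census$N), pmax(1, q / t0))
  tibble::tibble(sample_id = ids, t0 = unname(t0),
                 n_hat = as.integer(n_hat),
                 ci_lower = 1, ci_upper = unname(upper))
}

#' @export
print.census_estimate <- function(x, ...) {
  cat("<census_estimate>\n")
  cat("  T0 =", format(x$t0, digits = 4),
      " n_hat =", x$n_hat, "\n")
  cat("  ", format(100 * (1 - x$alpha)), "% CI: [1, ",
      format(x$ci[2], digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Tidy the likelihood curve of a census estimate
#'
#' @param x a `census_estimate`.
#' @param ... unused.
#' @export
tidy.census_estimate <- function(x, ...) {
  tibble::tibble(n = seq_along(x$loglik), loglik = x$loglik)
}

#' @rdname tidy.census_estimate
#' @export
glance.census_estimate <- function(x, ...) {
  tibble::tibble(n_hat = x$n_hat, t0 = x$t0, ci_lower = x$ci[1],
                 ci_upper = x$ci[2], alpha = x$alpha)
}

#' Serialize and restore a census model
#'
#' The model (reference parameters plus every per-size bootstrap sample) is
#' written to a versioned plain-text archive so estimation can run later
#' without re-simulation.
#'
#' @param census a `census_model`.
#' @param path output path.
#' @export
write_census_model <- function(census, path) {
  stopifnot(inherits(census, "census_model"))
  con <- file(path, "w")
  on.exit(close(con))
  ref <- census$reference
  writeLines(c(
    "#microcensus_model\tv1",
    paste0("#N\t", census$N), paste0("#B\t", census$B),
    paste0("#mode\t", census$mode), paste0("#seed\t", census$seed),
    paste0("#n0\t", ref$n0),
    paste0("#train_samples\t", paste(census$train_sample_ids, collapse = ",")),
    paste0("#features\t", paste(ref$feature_ids, collapse = ",")),
    paste0("#mu_hat\t", paste(format(ref$mu_hat, digits = 17), collapse = ",")),
    paste0("#sigma_hat\t",
           paste(format(ref$sigma_hat, digits = 17), collapse = ","))
  ), con)
  for (nl in census$nulls) {
    writeLines(paste0(nl$n, "\t", format(nl$bandwidth, digits = 17), "\t",
                      paste(format(nl$t_samples, digits = 17),
                            collapse = ",")), con)
  }
  invisible(path)
}

#' @rdname write_census_model
#' @export
read_census_model <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#microcensus_model\tv1")) {
    stop("not a v1 census model file: ", path, call. = FALSE)
  }
  meta <- list()
  i <- 2
  while (startsWith(lines[i], "#")) {
    kv <- strsplit(sub("^#", "", lines[i]), "\t")[[1]]
    meta[[kv[1]]] <- kv[2]
    i <- i + 1
  }
  split_num <- function(s) as.numeric(strsplit(s, ",")[[1]])
  ref <- new_census_ref(strsplit(meta$features, ",")[[1]],
                        split_num(meta$mu_hat), split_num(meta$sigma_hat),
                        as.integer(meta$n0))
  nulls <- lapply(lines[i:length(lines)], function(ln) {
    parts <- strsplit(ln, "\t")[[1]]
    list(n = as.integer(parts[1]), t_samples = split_num(parts[3]),
         bandwidth = as.numeric(parts[2]), mode = meta$mode)
  })
  structure(
    list(reference = ref, nulls = nulls, N = as.integer(meta$N),
         B = as.integer(meta$B), mode = meta$mode,
         seed = as.integer(meta$seed),
         train_sample_ids = strsplit(meta$train_samples, ",")[[1]]),
    class = "census_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
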
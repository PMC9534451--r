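#' Percentage error of a population-size prediction
#'
#' \eqn{\delta = |N_{pred} - N_{actual}| / N_{actual} \times 100\%}.
#'
#' @param predicted predicted size(s), positive.
#' @param actual true size(s), >= 1.
#' @return non-negative percentage(s).
#' @examples
#' percentage_error(12, 10)  # 20
#' @export
percentage_error <- function(predicted, actual) {
  if (any(actual < 1)) stop("actual size must be >= 1", call. = FALSE)
  abs(predicted - actual) / actual * 100
}

#' Mean absolute percentage error over paired predictions
#'
#' @param predictions vector of predicted sizes.
#' @param actuals vector of true sizes, same length.
#' @return the arithmetic mean of the per-pair [percentage_error()] values.
#' @examples
#' mape(c(12, 6), c(10, 10))  # mean of 20% and 40% = 30
#' @export
mape <- function(predictions, actuals) {
  if (length(predictions) != length(actuals)) {
    stop("predictions and actuals differ in length", call. = FALSE)
  }
  if (length(predictions) == 0) stop("need at least one pair", call. = FALSE)
  mean(percentage_error(predictions, actuals))
}

#' Split a cohort into disjoint train and test subject sets
#'
#' @param tbl an OTU table, one row per subject.
#' @param fraction fraction of subjects assigned to the training part.
#' @param seed integer seed; the partition is seed-stable.
#' @return a list with OTU tables `train` and `test`; no subject appears in
#'   both.
#' @export
split_cohort <- function(tbl, fraction = 0.5, seed = 1L) {
  validate_otu_table(tbl)
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must be in (0, 1)", call. = FALSE)
  }
  n <- nrow(tbl)
  n_train <- round(n * fraction)
  idx <- with_seed_local(seed, sample.int(n, n_train))
  list(train = tbl[sort(idx), , drop = FALSE],
       test = tbl[sort(setdiff(seq_len(n), idx)), , drop = FALSE])
}

#' Tune the number of top-abundance features by repeated holdout validation
#'
#' For each candidate k, and in each of `holdouts` repeated 50-50 subject
#' splits of the training cohort: fit the reference on one half, build the
#' bootstrap nulls, simulate mixtures of the listed sizes from the other
#' half, estimate each, and record the validation MAPE. The chosen k
#' minimises the mean validation MAPE across holdouts (smallest k on ties).
#'
#' @param tbl the training cohort (relative abundances).
#' @param k_grid candidate feature counts.
#' @param sizes true contributor counts to simulate, e.g. `c(5, 25, 100)`.
#' @param reps query mixtures per size per holdout.
#' @param holdouts number of repeated 50-50 splits.
#' @param seed integer seed.
#' @param B,N bootstrap replicates and largest candidate size for the nulls
#'   built inside each holdout.
#' @return a list: `best_k`, and `errors` (one row per holdout x k with the
#'   validation MAPE).
#' @export
tune_features <- function(tbl, k_grid, sizes, reps = 50, holdouts = 5,
                          seed = 1L, B = 1000L, N = NULL) {
  assert_relative(tbl)
  if (length(k_grid) == 0) stop("k_grid is empty", call. = FALSE)
  if (holdouts < 1) stop("need at least one holdout", call. = FALSE)
  N <- N %||% max(sizes)
  errors <- purrr::map_dfr(seq_len(holdouts), function(h) {
    halves <- split_cohort(tbl, 0.5, seed = seed + h)
    purrr::map_dfr(k_grid, function(k) {
      feats <- select_top_features(halves$train, k)
      ref <- fit_reference(halves$train, feats)
      census <- suppressWarnings(
        build_null(ref, halves$train, N = N, B = B, seed = seed + 1000L * h))
      res <- purrr::map_dfr(sizes, function(n) {
        qs <- sample_mixtures(halves$test, n = n, reps = reps,
                              seed = seed + 1000L * h + n)
        est <- estimate_populations(qs, census)
        tibble::tibble(actual = n, predicted = est$n_hat)
      })
      tibble::tibble(holdout = h, k = k,
                     mape = mape(res$predicted, res$actual))
    })
  })
  mean_err <- errors |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(mean_mape = mean(.data$mape), .groups = "drop") |>
    dplyr::arrange(.data$mean_mape, .data$k)
  list(best_k = mean_err$k[1], errors = errors, summary = mean_err)
}

#' Benchmark a census model on held-out subjects
#'
#' Simulates `reps` bootstrap mixtures at each true size from the test
#' cohort, estimates each with the fitted model, and summarises the error.
#' The test subjects must be disjoint from the subjects the model's nulls
#' were built on.
#'
#' @param census a `census_model`.
#' @param tbl the held-out test cohort (relative abundances).
#' @param sizes true contributor counts to evaluate.
#' @param reps mixtures per size.
#' @param seed integer seed.
#' @param allow_overlap permit shared subjects between training and test
#'   (used deliberately to measure training error).
#' @return a `census_benchmark`: per-prediction records, a per-size summary
#'   (mean, sd, mean delta), and the overall MAPE.
#' @export
benchmark_census <- function(census, tbl, sizes, reps = 1000L, seed = 1L,
                             allow_overlap = FALSE) {
  stopifnot(inherits(census, "census_model"))
  assert_relative(tbl)
  overlap <- intersect(census$train_sample_ids, tbl$sample_id)
  if (length(overlap) && !allow_overlap) {
    stop("test subjects overlap the model's training subjects (e.g. ",
         overlap[1], "); pass allow_overlap = TRUE to measure training error",
         call. = FALSE)
  }
  records <- purrr::map_dfr(seq_along(sizes), function(i) {
    n <- sizes[i]
    qs <- sample_mixtures(tbl, n = n, reps = reps, seed = seed + i)
    est <- estimate_populations(qs, census)
    tibble::tibble(actual = as.integer(n), predicted = est$n_hat,
                   t0 = est$t0,
                   delta = percentage_error(est$n_hat, n))
  })
  summary <- records |>
    dplyr::group_by(.data$actual) |>
    dplyr::summarise(mean_predicted = mean(.data$predicted),
                     sd_predicted = stats::sd(.data$predicted),
                     mean_delta = mean(.data$delta), .groups = "drop")
  structure(
    list(records = records, summary = summary,
         mape = mape(records$predicted, records$actual),
         settings = list(sizes = sizes, reps = reps, seed = seed,
                         B = census$B, N = census$N,
                         k = length(census$reference$feature_ids))),
    class = "census_benchmark"
  )
}

#' @export
print.census_benchmark <- function(x, ...) {
  cat("<census_benchmark> overall MAPE:", format(x$mape, digits = 4), "%\n")
  print(x$summary)
  invisible(x)
}

#' Tidy a benchmark into its per-size summary
#'
#' @param x a `census_benchmark`.
#' @param ... unused.
#' @export
tidy.census_benchmark <- function(x, ...) x$summary

#' @rdname tidy.census_benchmark
#' @export
glance.census_benchmark <- function(x, ...) {
  tibble::tibble(mape = x$mape, sizes = length(x$settings$sizes),
                 reps = x$settings$reps, k = x$settings$k,
                 B = x$settings$B, N = x$settings$N)
}

#' Write a benchmark result as TSV (per-size rows plus a summary line)
#'
#' @param x a `census_benchmark`.
#' @param path output path.
#' @export
write_benchmark <- function(x, path) {
  stopifnot(inherits(x, "census_benchmark"))
  readr::write_tsv(x$summary, path)
  cat("# overall_MAPE\t", format(x$mape, digits = 10), "\n",
      sep = "", file = path, append = TRUE)
  invisible(path)
}
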
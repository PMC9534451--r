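#' Select the top-k most abundant taxa of a reference cohort
#'
#' Taxa are ranked by their mean relative abundance across reference samples
#' (descending, ties broken lexicographically by taxon id). Taxa with zero
#' variance across samples are skipped regardless of abundance: a constant
#' coordinate would make the diagonal scale matrix singular.
#'
#' @param tbl a relative-abundance OTU table (the reference cohort).
#' @param k number of taxa to keep.
#' @param rank_by `"mean"` (default) or `"median"` cross-sample abundance.
#' @return character vector of `k` taxon ids, most abundant first.
#' @export
select_top_features <- function(tbl, k, rank_by = c("mean", "median")) {
  rank_by <- match.arg(rank_by)
  assert_relative(tbl)
  m <- otu_matrix(tbl)
  vars <- apply(m, 2, stats::var)
  eligible <- colnames(m)[vars > 0]
  if (k > length(eligible)) {
    stop("k = ", k, " exceeds the ", length(eligible),
         " taxa with nonzero cross-sample variance", call. = FALSE)
  }
  score <- if (rank_by == "mean") colMeans(m[, eligible, drop = FALSE])
           else apply(m[, eligible, drop = FALSE], 2, stats::median)
  ord <- order(-score, eligible)   # descending score, lexicographic tie-break
  eligible[ord][seq_len(k)]
}

#' Fit the reference model: per-taxon population mean and standard deviation
#'
#' Estimates, for each selected taxon, the cohort mean relative abundance
#' \eqn{\hat\mu_j} and the population standard deviation
#' \eqn{\hat\sigma_j = \sqrt{\sum_i (X_{ij} - \bar X_j)^2 / n_0}} (divisor
#' \eqn{n_0}, not \eqn{n_0 - 1}). These standardise the census T statistic.
#' With `robust = TRUE` the median and scaled MAD replace the moment
#' estimators, for heavy-tailed cohorts.
#'
#' @param tbl a relative-abundance OTU table (the reference cohort).
#' @param features taxon ids to model, e.g. from [select_top_features()].
#' @param robust use median / scaled MAD instead of mean / SD.
#' @return an object of class `census_ref` with fields `feature_ids`,
#'   `mu_hat`, `sigma_hat` and `n0`.
#' @examples
#' cohort <- synth_cohort(n0 = 50, p = 20, seed = 1)
#' ref <- fit_reference(cohort, select_top_features(cohort, 10))
#' tidy(ref)
#' @export
fit_reference <- function(tbl, features, robust = FALSE) {
  assert_relative(tbl)
  m <- otu_matrix(tbl)
  if (nrow(m) < 2) stop("need at least 2 reference samples", call. = FALSE)
  missing <- setdiff(features, colnames(m))
  if (length(missing)) {
    stop("features absent from the table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m <- m[, features, drop = FALSE]
  n0 <- nrow(m)
  if (robust) {
    mu <- apply(m, 2, stats::median)
    sigma <- apply(m, 2, stats::mad)   # scaled MAD, consistent for the SD
  } else {
    mu <- colMeans(m)
    sigma <- sqrt(colMeans(sweep(m, 2, colMeans(m))^2))  # divisor n0
  }
  zero <- features[sigma == 0]
  if (length(zero)) {
    stop("zero-variance feature(s): ", paste(zero, collapse = ", "),
         call. = FALSE)
  }
  new_census_ref(features, mu, sigma, n0)
}

#' Construct a reference model from known parameters
#'
#' Mostly useful for simulations where the true per-taxon means and standard
#' deviations are known analytically.
#'
#' @param feature_ids taxon identifiers (length p).
#' @param mu_hat per-taxon means, in `[0, 1]`.
#' @param sigma_hat per-taxon standard deviations, all `> 0`.
#' @param n0 nominal reference cohort size.
#' @return a `census_ref` object.
#' @export
new_census_ref <- function(feature_ids, mu_hat, sigma_hat, n0) {
  p <- length(feature_ids)
  stopifnot(length(mu_hat) == p, length(sigma_hat) == p,
            all(sigma_hat > 0), all(mu_hat >= 0 & mu_hat <= 1), n0 >= 1)
  structure(
    list(feature_ids = as.character(feature_ids),
         mu_hat = unname(as.numeric(mu_hat)),
         sigma_hat = unname(as.numeric(sigma_hat)),
         n0 = as.integer(n0)),
    class = "census_ref"
  )
}

#' @export
print.census_ref <- function(x, ...) {
  cat("<census_ref> reference model\n")
  cat("  features:", length(x$feature_ids), " cohort size n0:", x$n0, "\n")
  cat("  mu_hat range: [", format(min(x$mu_hat), digits = 3), ", ",
      format(max(x$mu_hat), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a reference model into one row per taxon
#'
#' @param x a `census_ref` object.
#' @param ... unused.
#' @export
tidy.census_ref <- function(x, ...) {
  tibble::tibble(taxon_id = x$feature_ids, mu_hat = x$mu_hat,
                 sigma_hat = x$sigma_hat)
}

#' @rdname tidy.census_ref
#' @export
glance.census_ref <- function(x, ...) {
  tibble::tibble(p = length(x$feature_ids), n0 = x$n0)
}

#' Serialize a reference model to a plain-text file
#'
#' The format is a versioned key-value header followed by a tab-separated
#' per-taxon table, so a fitted model is portable between runs and readable
#' by eye.
#'
#' @param ref a `census_ref` object.
#' @param path output path.
#' @export
write_reference <- function(ref, path) {
  stopifnot(inherits(ref, "census_ref"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#microcensus_reference\tv1",
               paste0("#n0\t", ref$n0),
               paste0("#p\t", length(ref$feature_ids)),
               "taxon_id\tmu_hat\tsigma_hat"), con)
  utils::write.table(
    data.frame(ref$feature_ids, format(ref$mu_hat, digits = 17),
               format(ref$sigma_hat, digits = 17)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#microcensus_reference\tv1")) {
    stop("not a v1 reference model file: ", path, call. = FALSE)
  }
  n0 <- as.integer(strsplit(lines[2], "\t")[[1]][2])
  tab <- utils::read.delim(text = lines[-(1:3)], stringsAsFactors = FALSE)
  new_census_ref(tab$taxon_id, tab$mu_hat, tab$sigma_hat, n0)
}
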
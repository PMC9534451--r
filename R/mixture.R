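#' Ideal mixture of individual microbiome profiles
#'
#' The idealised model of a sewage sample contributed by `n` people is the
#' equal-weight element-wise mean of their relative-abundance profiles,
#' \eqn{\bar X_n = \sum_{i=1}^n X_i / n}.
#'
#' @param profiles a numeric matrix (rows = individual profiles) or an OTU
#'   table of relative abundances.
#' @return a numeric vector, the element-wise mean profile.
#' @examples
#' ideal_mixture(rbind(c(1, 0), c(0, 1)))
#' @export
ideal_mixture <- function(profiles) {
  if (is.data.frame(profiles)) profiles <- otu_matrix(profiles)
  if (!is.matrix(profiles)) profiles <- matrix(profiles, nrow = 1)
  if (nrow(profiles) < 1) stop("need at least one profile", call. = FALSE)
  colMeans(profiles)
}

#' Simulate multi-person mixture profiles from a cohort
#'
#' Draws `reps` independent `n`-person mixtures from a reference cohort.
#' Under `with_replacement` the n contributors are drawn i.i.d. uniformly
#' (bootstrap mixtures, the scheme used to train and benchmark the census
#' model); under `without_replacement` each mixture averages a uniform random
#' size-`n` subset of distinct cohort members.
#'
#' @param tbl a relative-abundance OTU table (the cohort).
#' @param n contributors per mixture.
#' @param reps number of mixtures.
#' @param scheme `"with_replacement"` (default) or `"without_replacement"`.
#' @param seed integer seed; identical seeds give bit-identical batches.
#' @return an OTU table of `reps` mixture profiles (sample ids `mix_1`, ...),
#'   with attributes `n`, `scheme` and `seed`.
#' @export
sample_mixtures <- function(tbl, n, reps,
                            scheme = c("with_replacement", "without_replacement"),
                            seed = 1L) {
  scheme <- match.arg(scheme)
  assert_relative(tbl)
  m <- otu_matrix(tbl)
  n0 <- nrow(m)
  if (n < 1 || n != round(n)) stop("n must be a positive integer", call. = FALSE)
  if (scheme == "without_replacement" && n > n0) {
    stop("n = ", n, " exceeds cohort size ", n0,
         " under without_replacement sampling", call. = FALSE)
  }
  out <- with_seed_local(seed, {
    vapply(seq_len(reps), function(b) {
      idx <- if (scheme == "with_replacement") {
        sample.int(n0, n, replace = TRUE)
      } else {
        sample.int(n0, n)
      }
      colMeans(m[idx, , drop = FALSE])
    }, numeric(ncol(m)))
  })
  out <- t(out)
  dimnames(out) <- list(paste0("mix_", seq_len(reps)), colnames(m))
  res <- as_otu_table(out)
  attr(res, "n") <- as.integer(n)
  attr(res, "scheme") <- scheme
  attr(res, "seed") <- as.integer(seed)
  res
}
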
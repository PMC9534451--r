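#' Build a family-level taxonomic filter from a reference gut cohort
#'
#' Families are ranked by their total share of reference reads; the smallest
#' prefix reaching at least `coverage` of the reads is retained, and families
#' with a plausible ecological niche in tap water (by default
#' Enterobacteriaceae and Burkholderiaceae) are removed afterwards. Taxa
#' absent from the taxonomy are grouped under the sentinel family
#' `"unknown"`, which is excluded from the retained set unless
#' `include_unknown = TRUE`.
#'
#' @param tbl the reference cohort OTU table (counts or relative abundances).
#' @param taxonomy a taxonomy tibble (`taxon_id`, `family`).
#' @param coverage cumulative read-share target, in (0, 1].
#' @param exclude families removed after the coverage cut.
#' @param include_unknown keep the sentinel `"unknown"` family if it falls in
#'   the coverage prefix.
#' @return a `family_filter`: retained families, the share table, coverage
#'   target and exclusions.
#' @export
build_family_filter <- function(tbl, taxonomy, coverage = 0.99,
                                exclude = c("Enterobacteriaceae",
                                            "Burkholderiaceae"),
                                include_unknown = FALSE) {
  validate_otu_table(tbl)
  taxonomy <- validate_taxonomy(taxonomy)
  if (coverage <= 0 || coverage > 1) {
    stop("coverage must be in (0, 1]", call. = FALSE)
  }
  fam <- taxon_families(tbl, taxonomy)
  totals <- colSums(otu_matrix(tbl))
  shares <- tapply(totals, fam, sum) / sum(totals)
  shares <- sort(shares, decreasing = TRUE)
  n_keep <- which(cumsum(shares) >= coverage - 1e-12)[1]
  retained <- names(shares)[seq_len(n_keep)]
  drop <- exclude
  if (!include_unknown) drop <- c(drop, "unknown")
  retained <- setdiff(retained, drop)
  structure(
    list(retained = retained, coverage = coverage, excluded = exclude,
         shares = tibble::tibble(family = names(shares),
                                 share = unname(as.numeric(shares)),
                                 retained = names(shares) %in% retained)),
    class = "family_filter"
  )
}

# family of every taxon column, with sentinel "unknown" for unmapped taxa
taxon_families <- function(tbl, taxonomy) {
  fam <- taxonomy$family[match(taxon_ids(tbl), taxonomy$taxon_id)]
  fam[is.na(fam)] <- "unknown"
  fam
}

#' @export
print.family_filter <- function(x, ...) {
  cat("<family_filter> ", length(x$retained), " families retained (target ",
      100 * x$coverage, "% of reads; excluded: ",
      paste(x$excluded, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Tidy a family filter into its share table
#'
#' @param x a `family_filter`.
#' @param ... unused.
#' @export
tidy.family_filter <- function(x, ...) x$shares

#' Apply a family filter to a sample table and renormalize
#'
#' Drops taxa outside the retained families, renormalizes every sample over
#' the remaining taxa, and reports the fraction of reads each sample kept.
#' Samples with no retained reads are dropped with a warning.
#'
#' @param tbl a sample OTU table (counts or relative abundances).
#' @param taxonomy a taxonomy tibble.
#' @param filter a `family_filter` from [build_family_filter()].
#' @return a list: `table` (filtered, renormalized OTU table) and `retained`
#'   (tibble `sample_id`, `retained_fraction`).
#' @export
apply_family_filter <- function(tbl, taxonomy, filter) {
  stopifnot(inherits(filter, "family_filter"))
  validate_otu_table(tbl)
  fam <- taxon_families(tbl, taxonomy)
  keep <- fam %in% filter$retained
  m <- otu_matrix(tbl)
  kept <- m[, keep, drop = FALSE]
  frac <- rowSums(kept) / rowSums(m)
  ok <- rowSums(kept) > 0
  if (any(!ok)) {
    warning("sample(s) with zero retained reads dropped: ",
            paste(rownames(m)[!ok], collapse = ", "), call. = FALSE)
  }
  out <- kept[ok, , drop = FALSE]
  list(table = to_relative(as_otu_table(out)),
       retained = tibble::tibble(sample_id = rownames(m),
                                 retained_fraction = unname(frac)))
}

#' Welch t-test screening of OTUs against the reference cohort
#'
#' For every OTU present in both tables, computes Welch's two-sample t
#' statistic \eqn{t = (\bar x_1 - \bar x_2) / \sqrt{s_1^2/n_1 + s_2^2/n_2}}
#' with Welch-Satterthwaite degrees of freedom and a two-sided p-value, and
#' retains OTUs whose means do not differ detectably (p > alpha). The screen
#' deliberately applies no multiple-testing correction: its role is to keep
#' features that behave like the reference gut community, not to control an
#' error rate over discoveries, so each OTU is judged at raw p.
#'
#' @param sewage a sewage OTU table (relative abundances after filtering).
#' @param reference the reference cohort OTU table on the same scale.
#' @param alpha retention threshold on the raw p-value.
#' @return a tibble, one row per shared OTU: `taxon_id`, `t`, `df`,
#'   `p_value`, `retained`; OTUs absent from either table (or with fewer
#'   than two observations) are listed in the `"excluded"` attribute.
#' @export
welch_retain <- function(sewage, reference, alpha = 0.05) {
  validate_otu_table(sewage)
  validate_otu_table(reference)
  shared <- intersect(taxon_ids(sewage), taxon_ids(reference))
  excluded <- setdiff(union(taxon_ids(sewage), taxon_ids(reference)), shared)
  if (nrow(sewage) < 2 || nrow(reference) < 2) {
    stop("need at least 2 samples per side for Welch's t-test", call. = FALSE)
  }
  x <- otu_matrix(sewage)[, shared, drop = FALSE]
  y <- otu_matrix(reference)[, shared, drop = FALSE]
  n1 <- nrow(x); n2 <- nrow(y)
  m1 <- colMeans(x); m2 <- colMeans(y)
  v1 <- apply(x, 2, stats::var); v2 <- apply(y, 2, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  # identical constant columns on both sides: define t = 0, p = 1
  degen <- se2 == 0
  t[degen & (m1 == m2)] <- 0
  df[degen] <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(t), df)
  p[degen & (m1 == m2)] <- 1
  p[degen & (m1 != m2)] <- 0
  out <- tibble::tibble(taxon_id = shared, t = unname(t), df = unname(df),
                        p_value = unname(p), retained = unname(p > alpha))
  attr(out, "excluded") <- excluded
  out
}
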
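#' SNV allele-count profiles
#'
#' A sub-species profile is a long tibble of per-site allele counts for one
#' species: columns `species`, `gene`, `site` (1-based position within the
#' gene), `allele` (one of A, C, G, T) and `count` (non-negative integer).
#' A site's depth is the sum of its allele counts. Profiles are the input
#' boundary of the sub-species module: they may come from any upstream SNV
#' caller, or from [synth_snv_population()].
#'
#' @param df a data frame with the five columns above.
#' @return a validated `snv_profile` tibble.
#' @export
snv_profile <- function(df) {
  need <- c("species", "gene", "site", "allele", "count")
  if (!all(need %in% names(df))) {
    stop("snv profile needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df <- tibble::as_tibble(df[need])
  if (length(unique(df$species)) != 1) {
    stop("an snv profile holds exactly one species", call. = FALSE)
  }
  if (!all(df$allele %in% c("A", "C", "G", "T"))) {
    stop("alleles must be A, C, G or T", call. = FALSE)
  }
  if (any(df$count < 0) || any(df$count != round(df$count))) {
    stop("allele counts must be non-negative integers", call. = FALSE)
  }
  if (anyDuplicated(df[c("gene", "site", "allele")])) {
    stop("duplicate (gene, site, allele) records", call. = FALSE)
  }
  class(df) <- c("snv_profile", class(df))
  df
}

#' @rdname snv_profile
#' @param path a long-format TSV with the profile columns.
#' @export
read_snv_profile <- function(path) {
  snv_profile(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname snv_profile
#' @param profile an `snv_profile`.
#' @export
write_snv_profile <- function(profile, path) {
  readr::write_tsv(tibble::as_tibble(unclass(profile)), path)
  invisible(path)
}

# per-site summary: depth, heterozygosity, minor-allele count
site_table <- function(profile) {
  profile |>
    dplyr::filter(.data$count > 0) |>
    dplyr::group_by(.data$gene, .data$site) |>
    dplyr::summarise(
      depth = sum(.data$count),
      het = {
        d <- sum(.data$count)
        if (d > 1) (d / (d - 1)) * (1 - sum((.data$count / d)^2)) else 0
      },
      minor = sum(.data$count) - max(.data$count),
      .groups = "drop")
}

#' Nucleotide diversity of a pooled SNV profile
#'
#' Per covered site (depth >= `min_depth`) the heterozygosity is
#' \eqn{h = \frac{D}{D-1}\left(1 - \sum_a f_a^2\right)} with depth D and
#' allele fractions \eqn{f_a} — the probability that two reads drawn without
#' replacement differ at that site. A gene's diversity \eqn{\pi} is the mean
#' h over its covered sites, and the species diversity is the mean over
#' genes.
#'
#' @param profile an `snv_profile`.
#' @param min_depth minimum site depth to count a site as covered.
#' @return a list: `pi` (species-level diversity, in `[0, 1]`) and
#'   `per_gene` (tibble `gene`, `covered_sites`, `pi`).
#' @export
nucleotide_diversity <- function(profile, min_depth = 2) {
  sites <- site_table(profile) |> dplyr::filter(.data$depth >= min_depth)
  if (nrow(sites) == 0) {
    stop("no site reaches min_depth = ", min_depth, call. = FALSE)
  }
  per_gene <- sites |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(covered_sites = dplyr::n(), pi = mean(.data$het),
                     .groups = "drop")
  list(pi = mean(per_gene$pi), per_gene = per_gene)
}

#' Count polymorphic sites in a pooled SNV profile
#'
#' A covered site (depth >= `min_depth`) is polymorphic when its minor-allele
#' count (depth minus the majority allele's count) reaches
#' `min_minor_count`.
#'
#' @inheritParams nucleotide_diversity
#' @param min_minor_count minimum minor-allele reads to call a site
#'   polymorphic.
#' @return an integer count, with per-gene counts in the `"per_gene"`
#'   attribute.
#' @export
polymorphic_sites <- function(profile, min_minor_count = 1, min_depth = 2) {
  sites <- site_table(profile) |> dplyr::filter(.data$depth >= min_depth)
  per_gene <- sites |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(polymorphic = sum(.data$minor >= min_minor_count),
                     covered_sites = dplyr::n(), .groups = "drop")
  out <- sum(per_gene$polymorphic)
  attr(out, "per_gene") <- per_gene
  out
}

#' Aggregate SNV profiles of several hosts into one pooled profile
#'
#' Allele counts are summed coordinate-wise, emulating the pooling of reads
#' when several hosts' samples mix (as in sewage).
#'
#' @param profiles a list of `snv_profile` objects for the same species.
#' @return a pooled `snv_profile`.
#' @export
aggregate_profiles <- function(profiles) {
  if (!length(profiles)) stop("no profiles to aggregate", call. = FALSE)
  species <- unique(vapply(profiles, function(p) p$species[1], character(1)))
  if (length(species) != 1) {
    stop("profiles span several species: ", paste(species, collapse = ", "),
         call. = FALSE)
  }
  pooled <- dplyr::bind_rows(lapply(profiles, function(p) {
    tibble::as_tibble(unclass(p))
  })) |>
    dplyr::group_by(.data$species, .data$gene, .data$site, .data$allele) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  snv_profile(pooled)
}

#' Sub-species diversity as a function of aggregated population size
#'
#' For each size, draws `reps` without-replacement subsets of hosts,
#' aggregates their profiles, and summarises nucleotide diversity and the
#' polymorphic-site count. Reports the Pearson correlation between the mean
#' polymorphic-site count and the population size.
#'
#' @param profiles a list of single-host `snv_profile`s (one species).
#' @param sizes population sizes to evaluate (each at most
#'   `length(profiles)`).
#' @param reps subsets per size; when size equals the host count the single
#'   possible subset is used once.
#' @param seed integer seed.
#' @inheritParams polymorphic_sites
#' @return a list: `curve` (tibble `size`, `mean_pi`, `sd_pi`,
#'   `mean_polymorphic`, `sd_polymorphic`) and `pearson_r`.
#' @export
diversity_vs_population <- function(profiles, sizes, reps = 20L, seed = 1L,
                                    min_minor_count = 1, min_depth = 2) {
  n_hosts <- length(profiles)
  if (any(sizes > n_hosts)) {
    stop("sizes exceed the ", n_hosts, " available hosts", call. = FALSE)
  }
  curve <- with_seed_local(seed, {
    purrr::map_dfr(sizes, function(n) {
      r_eff <- if (n == n_hosts) 1L else reps
      vals <- purrr::map_dfr(seq_len(r_eff), function(r) {
        pooled <- aggregate_profiles(profiles[sample.int(n_hosts, n)])
        tibble::tibble(
          pi = nucleotide_diversity(pooled, min_depth)$pi,
          polymorphic = as.integer(
            polymorphic_sites(pooled, min_minor_count, min_depth)))
      })
      tibble::tibble(size = n,
                     mean_pi = mean(vals$pi), sd_pi = stats::sd(vals$pi),
                     mean_polymorphic = mean(vals$polymorphic),
                     sd_polymorphic = stats::sd(vals$polymorphic))
    })
  })
  curve$sd_pi[is.na(curve$sd_pi)] <- 0
  curve$sd_polymorphic[is.na(curve$sd_polymorphic)] <- 0
  r <- if (nrow(curve) > 1) {
    stats::cor(curve$size, curve$mean_polymorphic, method = "pearson")
  } else NA_real_
  list(curve = curve, pearson_r = r)
}
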
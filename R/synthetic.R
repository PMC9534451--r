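#' Generate a synthetic reference cohort of gut microbiome profiles
#'
#' Each individual's pre-normalization abundance of taxon j is an
#' independent zero-inflated lognormal draw,
#' \eqn{X_{ij} = Z_{ij}\exp(m_j + s_j \epsilon_{ij})} with
#' \eqn{Z_{ij} \sim Bernoulli(1 - z_j)}, and rows are then normalized to the
#' simplex — a logistic-normal-like composition that reproduces the
#' heavy-tailed inter-host variation of real gut communities (and the mild
#' negative inter-taxon correlation that closure induces). By default the
#' per-taxon mean log-abundances are the descending quantiles of a normal
#' distribution (the community's underlying species abundance distribution
#' is then itself lognormal, as in real gut communities), log-sd ramps from
#' 1.5 down to 0.7 (abundant taxa more variable across hosts), and
#' zero-inflation from 5% to 30% (rare taxa more often absent).
#'
#' @param n0 number of individuals.
#' @param p number of taxa (>= 2).
#' @param meanlog,sdlog,zero_prob per-taxon parameter vectors (recycled to
#'   length p); `sdlog > 0`, `zero_prob` in `[0, 1)`.
#' @param seed integer seed; the cohort is bit-reproducible.
#' @return a relative-abundance OTU table (samples `host_1..n0`, taxa
#'   `taxon_001..p`) with attribute `"truth"`: a tibble of the generator
#'   parameters and the analytic pre-normalization mean and variance of
#'   each taxon. Any all-zero row is redrawn; the redraw count is in
#'   attribute `"redraws"`.
#' @examples
#' cohort <- synth_cohort(n0 = 100, p = 30, seed = 7)
#' attr(cohort, "truth")
#' @export
synth_cohort <- function(n0 = 200, p = 50,
                         meanlog = sort(stats::qnorm(stats::ppoints(p),
                                                     mean = -3, sd = 2),
                                        decreasing = TRUE),
                         sdlog = seq(1.5, 0.7, length.out = p),
                         zero_prob = seq(0.05, 0.30, length.out = p),
                         seed = 1L) {
  stopifnot(p >= 2, n0 >= 1)
  meanlog <- rep_len(meanlog, p)
  sdlog <- rep_len(sdlog, p)
  zero_prob <- rep_len(zero_prob, p)
  stopifnot(all(sdlog > 0), all(zero_prob >= 0 & zero_prob < 1))
  redraws <- 0L
  m <- with_seed_local(seed, {
    one_batch <- function(k) {
      eps <- matrix(stats::rnorm(k * p), k, p)
      x <- exp(sweep(sweep(eps, 2, sdlog, `*`), 2, meanlog, `+`))
      z <- matrix(stats::runif(k * p) < rep(zero_prob, each = k), k, p)
      x[z] <- 0
      x
    }
    x <- one_batch(n0)
    repeat {
      zero_rows <- which(rowSums(x) == 0)
      if (!length(zero_rows)) break
      redraws <- redraws + length(zero_rows)
      x[zero_rows, ] <- one_batch(length(zero_rows))
    }
    x
  })
  dimnames(m) <- list(paste0("host_", seq_len(n0)),
                      sprintf("taxon_%03d", seq_len(p)))
  out <- to_relative(as_otu_table(m))
  mean_ln <- exp(meanlog + sdlog^2 / 2)
  var_ln <- (exp(sdlog^2) - 1) * exp(2 * meanlog + sdlog^2)
  attr(out, "truth") <- tibble::tibble(
    taxon_id = colnames(m), meanlog = meanlog, sdlog = sdlog,
    zero_prob = zero_prob,
    mean_pre = (1 - zero_prob) * mean_ln,
    var_pre = (1 - zero_prob) * (var_ln + mean_ln^2) -
      ((1 - zero_prob) * mean_ln)^2)
  attr(out, "redraws") <- redraws
  out
}

#' Fixture cohort presets
#'
#' `"small"` is a 200-host, 50-taxon cohort for fast tests; `"large"`
#' is 1,100 hosts by 300 taxa, the scale of a large single-center gut
#' microbiome survey.
#'
#' @param preset `"small"` or `"large"`.
#' @param seed integer seed.
#' @return a relative-abundance OTU table (see [synth_cohort()]).
#' @export
cohort_preset <- function(preset = c("small", "large"), seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
         small = synth_cohort(n0 = 200, p = 50, seed = seed),
         large = synth_cohort(n0 = 1100, p = 300, seed = seed))
}

#' Draw sequencing counts from a relative-abundance cohort
#'
#' Each sample's reads are a multinomial draw of `depth` reads from its
#' relative abundances, emulating fixed-depth amplicon sequencing.
#'
#' @param cohort a relative-abundance OTU table.
#' @param depth reads per sample.
#' @param seed integer seed.
#' @return an OTU table of integer counts with rows summing to `depth`.
#' @export
synth_counts <- function(cohort, depth = 4000L, seed = 1L) {
  assert_relative(cohort)
  m <- otu_matrix(cohort)
  counts <- with_seed_local(seed, {
    t(apply(m, 1, function(pr) stats::rmultinom(1, depth, pr)[, 1]))
  })
  dimnames(counts) <- dimnames(m)
  as_otu_table(counts)
}

#' Generate a synthetic sewage sample with non-gut background
#'
#' Mixes the profiles of `n` randomly chosen cohort members (equal-weight
#' ideal mixture) and dilutes the gut signal so that `background_taxa`
#' additional taxa, assigned to non-gut families, occupy
#' `background_fraction` of the reads — emulating the tap-water and
#' environmental fraction of real sewage. The returned taxonomy assigns
#' cohort taxa to common gut families and background taxa to families with
#' a tap-water niche.
#'
#' @param cohort a relative-abundance OTU table.
#' @param n contributors per sewage sample.
#' @param background_fraction fraction of reads from non-gut taxa, in
#'   `[0, 1)`.
#' @param background_taxa number of background taxa.
#' @param reps number of sewage samples.
#' @param seed integer seed.
#' @return a list: `table` (sewage OTU table, rows `sewage_1..reps`),
#'   `taxonomy` (covering gut and background taxa), and `contributors`
#'   (list of host ids per sample).
#' @export
synth_sewage <- function(cohort, n, background_fraction = 0.25,
                         background_taxa = 10L, reps = 1L, seed = 1L) {
  assert_relative(cohort)
  if (background_fraction < 0 || background_fraction >= 1) {
    stop("background_fraction must be in [0, 1)", call. = FALSE)
  }
  m <- otu_matrix(cohort)
  n0 <- nrow(m)
  gut_families <- c("Lachnospiraceae", "Ruminococcaceae", "Bacteroidaceae",
                    "Bifidobacteriaceae", "Prevotellaceae",
                    "Erysipelotrichaceae", "Akkermansiaceae",
                    "Veillonellaceae", "Rikenellaceae", "Oscillospiraceae",
                    "Christensenellaceae", "Methanobacteriaceae")
  bg_families <- c("Enterobacteriaceae", "Burkholderiaceae",
                   "Comamonadaceae", "Moraxellaceae")
  bg_ids <- sprintf("bg_taxon_%02d", seq_len(background_taxa))
  res <- with_seed_local(seed, {
    rows <- lapply(seq_len(reps), function(r) {
      idx <- sample.int(n0, min(n, n0))
      gut <- colMeans(m[idx, , drop = FALSE])
      bg <- exp(stats::rnorm(background_taxa))
      bg <- bg / sum(bg) * background_fraction
      list(profile = c(gut * (1 - background_fraction), bg), idx = idx)
    })
    rows
  })
  vals <- do.call(rbind, lapply(res, `[[`, "profile"))
  dimnames(vals) <- list(paste0("sewage_", seq_len(reps)),
                         c(colnames(m), bg_ids))
  taxonomy <- tibble::tibble(
    taxon_id = c(colnames(m), bg_ids),
    family = c(rep_len(gut_families, ncol(m)),
               rep_len(bg_families, background_taxa)))
  list(table = as_otu_table(vals), taxonomy = taxonomy,
       contributors = lapply(res, function(r) rownames(m)[r$idx]))
}

#' Generate a synthetic host population with sub-species haplotype structure
#'
#' For each gene, a reference sequence is drawn and a pool of
#' `haplotype_pool_size` population haplotypes is derived from it, each
#' site of each haplotype mutating to a random other base with probability
#' `divergence` — strains of one species are closely related, differing at
#' a few percent of sites, and each haplotype carries its own small set of
#' private variants. Every host is assigned one pool haplotype (with
#' frequencies `haplotype_freq`), optionally with within-host minor-allele
#' noise at rate `error_rate` per read. Inter-host haplotype variation is
#' thus the sole systematic source of pooled diversity, so the saturation
#' level of polymorphic sites is exactly enumerable from the pool, and
#' aggregating more hosts accumulates private variants gradually rather
#' than jumping to the ceiling at two hosts.
#'
#' @param hosts number of hosts.
#' @param genes number of marker genes.
#' @param sites_per_gene sites per gene.
#' @param haplotype_pool_size distinct population haplotypes per gene
#'   (>= 1; >= 2 for any polymorphism).
#' @param depth reads per site per host.
#' @param divergence per-site mutation probability of each pool haplotype
#'   relative to the gene's reference sequence.
#' @param error_rate per-read probability of a random non-haplotype allele
#'   (default 0: noise-free).
#' @param haplotype_freq relative frequencies of the pool haplotypes
#'   (recycled and normalized internally); default uniform. A skewed vector
#'   (e.g. `0.6^(0:(H-1))`) makes rare strains enter aggregates late.
#' @param seed integer seed.
#' @return a list of single-host `snv_profile`s with attribute `"truth"`:
#'   the haplotype pool (`pool[[gene]]` is a pool-by-site allele matrix) and
#'   each host's assignment.
#' @export
synth_snv_population <- function(hosts = 20L, genes = 3L,
                                 sites_per_gene = 100L,
                                 haplotype_pool_size = 5L, depth = 50L,
                                 divergence = 0.02, error_rate = 0,
                                 haplotype_freq = rep(1, haplotype_pool_size),
                                 seed = 1L) {
  stopifnot(haplotype_pool_size >= 1, hosts >= 1, depth >= 1,
            divergence >= 0, divergence < 1)
  haplotype_freq <- rep_len(haplotype_freq, haplotype_pool_size)
  stopifnot(all(haplotype_freq > 0))
  alleles <- c("A", "C", "G", "T")
  out <- with_seed_local(seed, {
    pool <- lapply(seq_len(genes), function(g) {
      reference <- sample(alleles, sites_per_gene, replace = TRUE)
      t(vapply(seq_len(haplotype_pool_size), function(k) {
        hap <- reference
        hit <- stats::runif(sites_per_gene) < divergence
        if (any(hit)) {
          hap[hit] <- vapply(hap[hit], function(a) {
            sample(setdiff(alleles, a), 1)
          }, character(1))
        }
        hap
      }, character(sites_per_gene)))
    })
    assignment <- matrix(sample.int(haplotype_pool_size, hosts * genes,
                                    replace = TRUE,
                                    prob = haplotype_freq /
                                      sum(haplotype_freq)),
                         nrow = hosts)
    profiles <- lapply(seq_len(hosts), function(h) {
      recs <- purrr::map_dfr(seq_len(genes), function(g) {
        hap <- pool[[g]][assignment[h, g], ]
        n_err <- if (error_rate > 0) {
          stats::rbinom(sites_per_gene, depth, error_rate)
        } else rep(0L, sites_per_gene)
        purrr::map_dfr(seq_len(sites_per_gene), function(s) {
          counts <- stats::setNames(rep(0L, 4), alleles)
          counts[hap[s]] <- depth - n_err[s]
          if (n_err[s] > 0) {
            err_al <- sample(setdiff(alleles, hap[s]), n_err[s],
                             replace = TRUE)
            et <- table(err_al)
            counts[names(et)] <- counts[names(et)] + as.integer(et)
          }
          keep <- counts > 0
          tibble::tibble(gene = paste0("gene_", g), site = s,
                         allele = names(counts)[keep],
                         count = as.integer(counts[keep]))
        })
      })
      snv_profile(dplyr::mutate(recs, species = "synthetic_species",
                                .before = 1))
    })
    list(profiles = profiles, pool = pool, assignment = assignment)
  })
  profiles <- out$profiles
  attr(profiles, "truth") <- list(pool = out$pool,
                                  assignment = out$assignment)
  profiles
}

#' Enumerate the saturation level of polymorphic sites of a haplotype pool
#'
#' The number of sites at which the pool haplotypes of a gene are not all
#' identical — the ceiling the polymorphic-site count of any aggregate
#' approaches as hosts accumulate (when every pool haplotype is carried by
#' at least one host and there is no sequencing noise).
#'
#' @param truth the `"truth"` attribute of [synth_snv_population()] output.
#' @return integer: total variable sites across genes.
#' @export
pool_polymorphic_ceiling <- function(truth) {
  sum(vapply(truth$pool, function(pm) {
    sum(apply(pm, 2, function(col) length(unique(col)) > 1))
  }, numeric(1)))
}
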
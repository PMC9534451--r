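mk_profile <- function(records, species = "sp") {
  snv_profile(dplyr::mutate(records, species = species, .before = 1))
}

test_that("heterozygosity and the toy diversity example are exact", {
  # one biallelic site at depth 2 (counts 1,1) + nine monomorphic covered
  # sites: gene pi = ((2/1) * (1 - 0.5)) / 10 = 0.1
  recs <- dplyr::bind_rows(
    tibble::tibble(gene = "g", site = 1, allele = c("A", "C"), count = c(1, 1)),
    tibble::tibble(gene = "g", site = 2:10, allele = "G", count = 2))
  div <- nucleotide_diversity(mk_profile(recs))
  expect_equal(div$pi, 0.1)
  expect_equal(div$per_gene$covered_sites, 10)
  # a single-allele site has h = 0
  mono <- mk_profile(tibble::tibble(gene = "g", site = 1, allele = "A",
                                    count = 30))
  expect_equal(nucleotide_diversity(mono)$pi, 0)
  expect_error(nucleotide_diversity(mono, min_depth = 50), "min_depth")
})

test_that("pooled-pair diversity equals brute-force pairwise differences", {
  # two explicit haplotypes over 8 sites; pooling them at depth 1 each
  hapA <- c("A", "C", "G", "T", "A", "C", "G", "T")
  hapB <- c("A", "C", "C", "T", "T", "C", "G", "T")
  prof <- function(h) {
    mk_profile(tibble::tibble(gene = "g", site = seq_along(h), allele = h,
                              count = 1))
  }
  pooled <- aggregate_profiles(list(prof(hapA), prof(hapB)))
  # brute force: fraction of differing sites between the two sequences;
  # with D = 2 the (D/(D-1)) correction makes h = 1 at differing sites
  expect_equal(nucleotide_diversity(pooled)$pi,
               mean(hapA != hapB))
})

test_that("polymorphic site counting respects thresholds and invariances", {
  recs <- dplyr::bind_rows(
    tibble::tibble(gene = "g", site = 1, allele = c("A", "G"), count = c(9, 1)),
    tibble::tibble(gene = "g", site = 2, allele = "C", count = 10),
    tibble::tibble(gene = "g", site = 3, allele = c("T", "A"), count = c(7, 3)))
  p <- mk_profile(recs)
  expect_equal(as.integer(polymorphic_sites(p)), 2)
  expect_equal(as.integer(polymorphic_sites(p, min_minor_count = 2)), 1)
  # all monomorphic -> 0
  expect_equal(as.integer(polymorphic_sites(
    mk_profile(tibble::tibble(gene = "g", site = 1:4, allele = "A",
                              count = 5)))), 0)
  # invariant to relabeling alleles and to depth scaling
  relab <- recs
  relab$allele <- chartr("ACGT", "TGCA", relab$allele)
  expect_equal(as.integer(polymorphic_sites(mk_profile(relab))), 2)
  scaled <- recs; scaled$count <- scaled$count * 5
  expect_equal(as.integer(polymorphic_sites(mk_profile(scaled))), 2)
  div1 <- nucleotide_diversity(p)$pi
  expect_equal(nucleotide_diversity(mk_profile(relab))$pi, div1)
})

test_that("aggregation sums depths and can only create polymorphism", {
  a <- mk_profile(tibble::tibble(gene = "g", site = 1:3, allele = "A",
                                 count = 4))
  b <- mk_profile(tibble::tibble(gene = "g", site = 1:3,
                                 allele = c("A", "C", "A"), count = 4))
  expect_equal(aggregate_profiles(list(a)), a)
  ab <- aggregate_profiles(list(a, b))
  depths <- tapply(ab$count, ab$site, sum)
  expect_true(all(depths == 8))
  expect_equal(as.integer(polymorphic_sites(ab)), 1)  # site 2: A4 + C4
  other <- mk_profile(tibble::tibble(gene = "g", site = 1, allele = "A",
                                     count = 1), species = "other")
  expect_error(aggregate_profiles(list(a, other)), "species")
})

test_that("polymorphic count is non-decreasing as profiles accumulate", {
  pop <- synth_snv_population(hosts = 8, genes = 2, sites_per_gene = 40,
                              haplotype_pool_size = 4, depth = 12, seed = 50)
  for (ord_seed in 1:3) {
    set.seed(ord_seed)
    ord <- sample(seq_along(pop))
    counts <- vapply(seq_along(ord), function(k) {
      as.integer(polymorphic_sites(aggregate_profiles(pop[ord[seq_len(k)]])))
    }, integer(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("diversity grows with aggregated population size on haplotype populations", {
  pop <- synth_snv_population(hosts = 12, genes = 2, sites_per_gene = 50,
                              haplotype_pool_size = 5, depth = 20, seed = 51)
  div <- diversity_vs_population(pop, sizes = c(1, 3, 6, 12), reps = 8,
                                 seed = 52)
  curve <- div$curve
  # single possible subset at the full size -> zero spread
  expect_equal(curve$sd_pi[curve$size == 12], 0)
  expect_equal(curve$sd_polymorphic[curve$size == 12], 0)
  # mean polymorphic count rises toward the enumerated pool ceiling
  expect_true(all(diff(curve$mean_polymorphic) > 0))
  ceiling_sites <- pool_polymorphic_ceiling(attr(pop, "truth"))
  expect_lte(max(curve$mean_polymorphic), ceiling_sites)
  # pi at size 1 is zero here (fixed haplotypes) and grows with pooling
  expect_lte(curve$mean_pi[curve$size == 1],
             curve$mean_pi[curve$size == 12])
  expect_error(diversity_vs_population(pop, sizes = 13), "exceed")
})

test_that("snv profile validation and TSV round-trip", {
  bad <- tibble::tibble(species = "s", gene = "g", site = 1, allele = "X",
                        count = 1)
  expect_error(snv_profile(bad), "alleles")
  dup <- tibble::tibble(species = "s", gene = "g", site = c(1, 1),
                        allele = "A", count = c(1, 2))
  expect_error(snv_profile(dup), "duplicate")
  p <- mk_profile(tibble::tibble(gene = "g", site = 1:2,
                                 allele = c("A", "C"), count = c(3, 4)))
  path <- tempfile(fileext = ".tsv")
  write_snv_profile(p, path)
  back <- read_snv_profile(path)
  expect_equal(tibble::as_tibble(unclass(back)),
               tibble::as_tibble(unclass(p)))
})
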
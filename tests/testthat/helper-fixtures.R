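# shared in-code fixtures; everything is generated, nothing read from disk

tiny_table <- function() {
  as_otu_table(matrix(c(2, 1, 2, 3, 4, 6), nrow = 2,
                      dimnames = list(c("s1", "s2"), c("A", "B", "C"))))
}

# a small cohort reused across tests (deterministic)
fixture_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synth_cohort(n0 = 120, p = 40, seed = 101)
    cache
  }
})

# reference + null model on the fixture cohort, built once
fixture_census <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- fixture_cohort()
      ref <- fit_reference(co, select_top_features(co, 20))
      cache <<- suppressWarnings(
        build_null(ref, co, N = 60, B = 400, seed = 102))
    }
    cache
  }
})

# write a table to a temp TSV and return the path
tmp_tsv <- function(tbl) {
  path <- tempfile(fileext = ".tsv")
  write_otu_table(tbl, path)
  path
}

expect_tables_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$sample_id, b$sample_id)
  expect_equal(names(a), names(b))
  expect_equal(otu_matrix(a), otu_matrix(b), tolerance = tol)
}
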
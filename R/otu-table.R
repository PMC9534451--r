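#' OTU abundance tables
#'
#' Throughout the package an abundance table is an ordinary tibble whose first
#' column, `sample_id`, holds unique sample identifiers and whose remaining
#' columns are numeric per-taxon abundances (counts or relative abundances),
#' one column per taxon in samples-by-taxa orientation. The helpers here
#' construct, validate and convert such tables.
#'
#' @param x a matrix with row names (samples) and column names (taxa), or a
#'   data frame with a `sample_id` column.
#' @return `as_otu_table()` returns a validated tibble in samples-by-taxa
#'   orientation.
#' @examples
#' m <- matrix(c(2, 1, 2, 3, 4, 6), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("A", "B", "C")))
#' as_otu_table(m)
#' @export
as_otu_table <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      stop("matrix input needs row names (samples) and column names (taxa)",
           call. = FALSE)
    }
    x <- tibble::as_tibble(x, rownames = "sample_id")
  }
  x <- tibble::as_tibble(x)
  validate_otu_table(x)
  x
}

validate_otu_table <- function(tbl, arg = "table") {
  if (!is.data.frame(tbl) || ncol(tbl) < 2L || names(tbl)[1] != "sample_id") {
    stop(arg, " must be a data frame with a leading `sample_id` column ",
         "followed by one numeric column per taxon", call. = FALSE)
  }
  if (anyDuplicated(tbl$sample_id)) {
    stop("duplicate sample ids: ",
         paste(unique(tbl$sample_id[duplicated(tbl$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(names(tbl))) {
    stop("duplicate taxon ids: ",
         paste(unique(names(tbl)[duplicated(names(tbl))]), collapse = ", "),
         call. = FALSE)
  }
  vals <- otu_matrix(tbl)
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    stop(arg, " contains non-numeric or non-finite abundances", call. = FALSE)
  }
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1, ]
    stop("negative abundance at sample '", rownames(vals)[bad[1]],
         "', taxon '", colnames(vals)[bad[2]], "'", call. = FALSE)
  }
  invisible(tbl)
}

#' Extract the numeric abundance matrix from an OTU table
#'
#' @param tbl an OTU table tibble (see [as_otu_table()]).
#' @return a numeric matrix, rows named by sample, columns by taxon.
#' @export
otu_matrix <- function(tbl) {
  m <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(m) <- tbl$sample_id
  storage.mode(m) <- "double"
  m
}

#' @rdname otu_matrix
#' @export
taxon_ids <- function(tbl) names(tbl)[-1]

#' Is a table already on the relative-abundance scale?
#'
#' A table is treated as relative when every row sums to 1 within `tol`.
#'
#' @param tbl an OTU table.
#' @param tol absolute tolerance on row sums.
#' @export
is_relative_table <- function(tbl, tol = 1e-6) {
  rs <- rowSums(otu_matrix(tbl))
  all(abs(rs - 1) <= tol)
}

assert_relative <- function(tbl, arg = "table") {
  if (!is_relative_table(tbl)) {
    stop(arg, " must hold relative abundances (rows summing to 1); ",
         "call to_relative() first", call. = FALSE)
  }
  invisible(tbl)
}

#' Read an abundance table from a tab-separated file
#'
#' The file must have one header row of identifiers and one identifier column;
#' the remaining cells must parse as non-negative numbers. Input may be stored
#' either samples-by-taxa or taxa-by-samples; the returned tibble is always
#' samples-by-taxa.
#'
#' @param path path to a TSV file.
#' @param orientation `"samples_by_taxa"` (default) or `"taxa_by_samples"`.
#' @return an OTU table tibble.
#' @export
read_otu_table <- function(path,
                           orientation = c("samples_by_taxa", "taxa_by_samples")) {
  orientation <- match.arg(orientation)
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("malformed header in ", path, call. = FALSE)
  ids <- raw[[1]]
  num <- raw[, -1, drop = FALSE]
  for (j in seq_along(num)) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    bad <- which(is.na(v) | v < 0)
    if (length(bad)) {
      stop("non-numeric or negative cell at row '", ids[bad[1]],
           "', column '", names(num)[j], "' in ", path, call. = FALSE)
    }
    num[[j]] <- v
  }
  m <- as.matrix(num)
  rownames(m) <- ids
  if (orientation == "taxa_by_samples") m <- t(m)
  as_otu_table(m)
}

#' Write an abundance table to a tab-separated file
#'
#' @param tbl an OTU table.
#' @param path output path.
#' @export
write_otu_table <- function(tbl, path) {
  validate_otu_table(tbl)
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Read and write taxon-to-family taxonomy maps
#'
#' A taxonomy map is a two-column tibble (`taxon_id`, `family`) assigning each
#' taxon to a family-level lineage; taxa of unknown lineage carry the sentinel
#' family `"unknown"`.
#'
#' @param path path to a two-column TSV (taxon_id, family).
#' @return a tibble with columns `taxon_id` and `family`.
#' @export
read_taxonomy <- function(path) {
  tax <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  names(tax)[1:2] <- c("taxon_id", "family")
  validate_taxonomy(tibble::as_tibble(tax[1:2]))
}

validate_taxonomy <- function(tax) {
  if (!all(c("taxon_id", "family") %in% names(tax)) || nrow(tax) == 0) {
    stop("taxonomy must be a non-empty table with columns taxon_id, family",
         call. = FALSE)
  }
  if (anyDuplicated(tax$taxon_id)) {
    stop("duplicate taxon ids in taxonomy", call. = FALSE)
  }
  if (any(!nzchar(tax$family))) stop("empty family names in taxonomy", call. = FALSE)
  tibble::as_tibble(tax)
}

#' @rdname read_taxonomy
#' @param tax a taxonomy tibble.
#' @export
write_taxonomy <- function(tax, path) {
  readr::write_tsv(validate_taxonomy(tax), path)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' Divides each sample row by its total. Already-relative tables pass through
#' unchanged (the operation is idempotent).
#'
#' @param tbl an OTU table.
#' @return an OTU table with every row summing to 1.
#' @export
to_relative <- function(tbl) {
  validate_otu_table(tbl)
  m <- otu_matrix(tbl)
  rs <- rowSums(m)
  if (any(rs == 0)) {
    stop("all-zero sample(s): ",
         paste(rownames(m)[rs == 0], collapse = ", "), call. = FALSE)
  }
  as_otu_table(m / rs)
}

#' Rarefy a count table to a fixed sequencing depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads (hypergeometric rarefaction, via [vegan::rrarefy()]). Samples whose
#' total is below `depth` are dropped; their ids are attached as the
#' `"dropped"` attribute and reported in a message.
#'
#' @param tbl an OTU table of integer counts.
#' @param depth target depth (positive integer).
#' @param seed integer seed; the result is deterministic given the seed.
#' @return a rarefied OTU table whose rows each sum to `depth`, with attribute
#'   `"dropped"` listing removed sample ids.
#' @export
rarefy <- function(tbl, depth, seed = 1L) {
  validate_otu_table(tbl)
  if (is_relative_table(tbl)) {
    stop("rarefy() needs integer counts, not relative abundances", call. = FALSE)
  }
  if (length(depth) != 1L || depth <= 0 || depth != round(depth)) {
    stop("depth must be a positive integer", call. = FALSE)
  }
  m <- otu_matrix(tbl)
  if (any(m != round(m))) stop("counts must be integers", call. = FALSE)
  totals <- rowSums(m)
  keep <- totals >= depth
  dropped <- rownames(m)[!keep]
  if (length(dropped)) {
    message(length(dropped), " sample(s) below depth ", depth, " dropped: ",
            paste(dropped, collapse = ", "))
  }
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0) stop("no sample reaches depth ", depth, call. = FALSE)
  out <- with_seed_local(seed, suppressWarnings(vegan::rrarefy(m, depth)))
  out <- as_otu_table(out)
  attr(out, "dropped") <- dropped
  out
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed_local <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
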
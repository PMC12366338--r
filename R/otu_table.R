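#' Construct and validate an OTU count table
#'
#' The central container of the package: a nonnegative integer matrix with
#' samples as rows and OTUs as columns, both uniquely named. OTUs with zero
#' total count carry no information for any downstream statistic and are
#' dropped with a warning; all-zero samples are an error (they indicate a
#' failed library, not an analyzable community).
#'
#' @param counts numeric matrix, samples x OTUs, nonnegative integers.
#' @param sample_ids,otu_ids optional identifier vectors; default to the
#'   dimnames of `counts`.
#' @return an `otu_table`: an integer matrix with class attribute.
#' @export
otu_table <- function(counts, sample_ids = rownames(counts), otu_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(counts)))
  if (is.null(otu_ids)) otu_ids <- paste0("OTU", seq_len(ncol(counts)))
  assert_that(length(sample_ids) == nrow(counts) && length(otu_ids) == ncol(counts),
              "identifier lengths do not match matrix dimensions")
  assert_that(!anyDuplicated(sample_ids), "duplicate sample identifiers")
  assert_that(!anyDuplicated(otu_ids), "duplicate OTU identifiers")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-integer or negative count at row '%s', column '%s'",
                 sample_ids[bad[1, 1]], otu_ids[bad[1, 2]]), call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(sample_ids, otu_ids)
  empty_samples <- rowSums(counts) == 0
  assert_that(!any(empty_samples),
              paste("all-zero samples:", paste(sample_ids[empty_samples], collapse = ", ")))
  empty_otus <- colSums(counts) == 0
  if (any(empty_otus)) {
    warning(sprintf("dropping %d OTU(s) with zero total count", sum(empty_otus)),
            call. = FALSE)
    counts <- counts[, !empty_otus, drop = FALSE]
  }
  class(counts) <- c("otu_table", class(counts))
  counts
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs, %s reads, fill %.1f%%\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ","), 100 * mean(x > 0)))
  invisible(x)
}

# strip class so vegan/matrix code sees a plain integer matrix
unclass_table <- function(x) {
  x <- unclass(x)
  attr(x, "class") <- NULL
  x
}

#' Relative abundances
#'
#' Computed on the fly from counts, never stored, so every statistic sees one
#' canonical normalization. `margin = "sample"` divides each row by its read
#' depth (the usual community profile); `margin = "otu"` divides each column
#' by the OTU's total count (the Levins convention, summing to 1 per OTU).
#'
#' @param x an [otu_table()] or count matrix (samples x OTUs).
#' @param margin `"sample"` or `"otu"`.
#' @return a numeric matrix of the same shape.
#' @export
rel_abund <- function(x, margin = c("sample", "otu")) {
  margin <- match.arg(margin)
  x <- unclass_table(x)
  if (margin == "sample") x / rowSums(x) else sweep(x, 2L, colSums(x), "/")
}

#' Read an OTU table from tab-delimited text
#'
#' Expects a header row of OTU identifiers and a first column of sample
#' identifiers (`orientation = "samples_rows"`, the default). With
#' `orientation = "auto"` the longer dimension is taken to be the OTUs, the
#' common shape of amplicon tables.
#'
#' @param path file path.
#' @param orientation `"samples_rows"`, `"samples_cols"`, or `"auto"`.
#' @return an [otu_table()].
#' @export
read_otu_table <- function(path, orientation = c("samples_rows", "samples_cols", "auto")) {
  orientation <- match.arg(orientation)
  df <- read.delim(path, header = TRUE, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  if (orientation == "auto" && nrow(m) > ncol(m)) orientation <- "samples_cols"
  if (orientation == "samples_cols") m <- t(m)
  otu_table(m)
}

#' Write an OTU table as tab-delimited text
#'
#' @param x an [otu_table()].
#' @param path file path; first column `sample_id`, header row OTU ids.
#' @export
write_otu_table <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), unclass_table(x), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata and align it to an OTU table
#'
#' Tab-delimited, one row per sample with a `sample_id` column; remaining
#' columns are coordinates (`x`, `y`) and named covariates. If `table` is
#' supplied the metadata is checked against it and reordered to match.
#'
#' @param path file path.
#' @param table optional [otu_table()] to align against.
#' @return a data.frame of metadata.
#' @export
read_metadata <- function(path, table = NULL) {
  meta <- read.delim(path, header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
  assert_that("sample_id" %in% names(meta), "metadata must have a sample_id column")
  if (!is.null(table)) meta <- align_metadata(meta, table)
  meta
}

#' Align metadata rows to the samples of an OTU table
#'
#' @param meta metadata data.frame with `sample_id`.
#' @param table an [otu_table()].
#' @return `meta` reordered to the table's sample order.
#' @export
align_metadata <- function(meta, table) {
  missing <- setdiff(rownames(table), meta$sample_id)
  extra <- setdiff(meta$sample_id, rownames(table))
  if (length(missing) || length(extra)) {
    stop(sprintf("metadata/table sample mismatch; missing from metadata: [%s]; absent from table: [%s]",
                 paste(missing, collapse = ", "), paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  meta[match(rownames(table), meta$sample_id), , drop = FALSE]
}

#' Write sample metadata
#' @param meta metadata data.frame.
#' @param path file path.
#' @export
write_metadata <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Newick phylogeny and check its tips against an OTU table
#'
#' @param path Newick file.
#' @param table optional [otu_table()]; an error lists OTUs without tips.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_tree <- function(path, table = NULL) {
  tree <- ape::read.tree(path)
  if (!is.null(table)) check_tree_tips(tree, table)
  tree
}

check_tree_tips <- function(tree, table) {
  missing <- setdiff(colnames(table), tree$tip.label)
  assert_that(length(missing) == 0,
              paste("OTUs missing from the tree:", paste(head(missing, 10), collapse = ", ")))
  invisible(TRUE)
}

#' Per-sample observed richness
#'
#' Count of OTUs with nonzero abundance in each sample, optionally restricted
#' to a subset of OTUs.
#'
#' @param x an [otu_table()].
#' @param otus optional character vector of OTU ids.
#' @return named integer vector over samples.
#' @export
sample_richness <- function(x, otus = NULL) {
  m <- unclass_table(x)
  if (!is.null(otus)) m <- m[, intersect(colnames(m), otus), drop = FALSE]
  rowSums(m > 0)
}
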
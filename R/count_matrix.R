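#' Construct a gene-by-sample count matrix with sample metadata
#'
#' The central container for raw expression observations: a numeric
#' genes-by-samples matrix with unique gene and sample identifiers, plus
#' per-sample metadata recording the genotype (`"wt"` or `"mut"`) and whether
#' the sample is a pooled library (mixed from several biological replicates)
#' or an individually sequenced replicate.
#'
#' Counts must be nonnegative. Simulated and multinomially pooled columns are
#' integral; expectation-mode pooled columns (see [pool_replicates()]) are
#' fractional expected counts, which downstream normalisation handles
#' identically.
#'
#' @param counts numeric matrix, genes in rows, samples in columns, with
#'   unique rownames (gene identifiers) and colnames (sample identifiers).
#' @param genotype character vector, one of `"wt"`/`"mut"` per sample.
#' @param pooled logical vector, one flag per sample; `TRUE` marks a pooled
#'   library. Defaults to all `FALSE`.
#' @return an object of class `count_matrix`: a list with elements `counts`
#'   (the matrix) and `samples` (a data.frame `sample_id`, `genotype`,
#'   `pooled`).
#' @examples
#' m <- matrix(c(5, 0, 3, 7, 1, 2), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("wt_1", "mut_1")))
#' cm <- count_matrix(m, genotype = c("wt", "mut"))
#' cm$samples
#' @export
count_matrix <- function(counts, genotype, pooled = rep(FALSE, ncol(counts))) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop_("'counts' must be a numeric matrix")
  gid <- rownames(counts)
  sid <- colnames(counts)
  if (is.null(gid) || anyDuplicated(gid) || any(!nzchar(gid)))
    stop_("'counts' must have unique, nonempty rownames (gene identifiers)")
  if (is.null(sid) || anyDuplicated(sid) || any(!nzchar(sid)))
    stop_("'counts' must have unique, nonempty colnames (sample identifiers)")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop_("'counts' must be finite and nonnegative")
  if (length(genotype) != ncol(counts))
    stop_("'genotype' must have one entry per sample")
  if (!all(genotype %in% c("wt", "mut")))
    stop_("'genotype' entries must be 'wt' or 'mut'")
  if (length(pooled) != ncol(counts) || !is.logical(pooled))
    stop_("'pooled' must be a logical vector with one entry per sample")
  structure(
    list(
      counts = counts,
      samples = data.frame(
        sample_id = sid,
        genotype = as.character(genotype),
        pooled = pooled,
        stringsAsFactors = FALSE
      )
    ),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "count_matrix: %d genes x %d samples (%d wt, %d mut; %d pooled)\n",
    nrow(x$counts), ncol(x$counts),
    sum(x$samples$genotype == "wt"), sum(x$samples$genotype == "mut"),
    sum(x$samples$pooled)
  ))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Append a sample column to a count matrix
#'
#' Used to attach a pooled library produced by [pool_replicates()] to the
#' matrix of its source experiment.
#'
#' @param x a [count_matrix()].
#' @param column numeric vector of expression values, one per gene, in the
#'   matrix's gene order (names, if present, must match).
#' @param sample_id identifier for the new sample.
#' @param genotype `"wt"` or `"mut"`.
#' @param pooled logical flag, default `TRUE`.
#' @return a new `count_matrix` with the extra column.
#' @export
add_sample <- function(x, column, sample_id, genotype, pooled = TRUE) {
  stopifnot(inherits(x, "count_matrix"))
  if (length(column) != nrow(x$counts))
    stop_("'column' must have one value per gene")
  if (!is.null(names(column)) && !identical(names(column), rownames(x$counts)))
    stop_("'column' names do not match the matrix gene order")
  if (sample_id %in% x$samples$sample_id)
    stop_("sample_id '%s' already present", sample_id)
  counts <- cbind(x$counts, unname(column))
  colnames(counts) <- c(x$samples$sample_id, sample_id)
  count_matrix(counts,
               genotype = c(x$samples$genotype, genotype),
               pooled = c(x$samples$pooled, pooled))
}

#' Read and write count matrices as tab-separated text
#'
#' The on-disk dialect is two plain-text files: the counts table with a
#' header row `gene_id<TAB>sample1<TAB>...` and one row per gene, and a
#' companion metadata table with columns `sample_id`, `genotype`
#' (`wt`/`mut`) and `pooled` (0/1).
#'
#' @param x a [count_matrix()].
#' @param counts_path path for the counts table.
#' @param meta_path path for the sample metadata table.
#' @return `write_count_matrix` invisibly returns `x`; `read_count_matrix`
#'   returns a `count_matrix`.
#' @export
write_count_matrix <- function(x, counts_path, meta_path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- x$samples
  meta$pooled <- as.integer(meta$pooled)
  write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(counts_path, meta_path) {
  df <- read.delim(counts_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop_("first column must be 'gene_id'")
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$gene_id
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "genotype", "pooled")
  if (!all(need %in% names(meta)))
    stop_("metadata table must have columns sample_id, genotype, pooled")
  idx <- match(colnames(counts), meta$sample_id)
  if (anyNA(idx)) stop_("metadata is missing some samples of the counts table")
  meta <- meta[idx, , drop = FALSE]
  count_matrix(counts, genotype = meta$genotype,
               pooled = as.logical(as.integer(meta$pooled)))
}

#' Read and write differential-expression truth tables
#'
#' Tab-separated with columns `gene_id`, `status` (`up`/`down`/`null`) and
#' `true_fold_change`.
#'
#' @param truth a truth-table data.frame as returned by
#'   [simulate_experiment()].
#' @param path file path.
#' @return `write_truth_table` invisibly returns `truth`;
#'   `read_truth_table` returns the data.frame.
#' @export
write_truth_table <- function(truth, path) {
  stopifnot(all(c("gene_id", "status", "true_fold_change") %in% names(truth)))
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(truth)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
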
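#' Normalise a count matrix to counts per million
#'
#' Every DEG criterion in the package compares the same gene across samples,
#' so the only correction needed is for sequencing depth: each column is
#' scaled so it sums to 10^6 (counts per million, CPM). Gene length cancels
#' in within-gene comparisons and is not corrected.
#'
#' @param x a [count_matrix()]; every column must have a positive total.
#' @return an object of class `expression_matrix`: like `count_matrix` but
#'   with `values` (CPM) instead of `counts`.
#' @examples
#' m <- matrix(c(1, 1, 2), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), "s1"))
#' normalize_cpm(count_matrix(m, genotype = "wt"))$values
#' @export
normalize_cpm <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  totals <- colSums(x$counts)
  if (any(totals <= 0))
    stop_("sample(s) with zero total counts cannot be normalised: %s",
          paste(x$samples$sample_id[totals <= 0], collapse = ", "))
  values <- sweep(x$counts, 2, totals, "/") * 1e6
  structure(list(values = values, samples = x$samples),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix (CPM): %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Per-gene group means and the wild-type standard deviation
#'
#' Computes the quantities every DEG criterion operates on: for each gene,
#' the mean wild-type expression, the mean mutant expression, and the sample
#' standard deviation (n - 1 denominator) of the individually sequenced
#' wild-type samples. Pooled columns are never biological replicates, so they
#' never contribute to `sd_wt`; mutant pooled columns do contribute to
#' `mean_mut` (a design with a single pooled mutant library yields
#' `mean_mut` equal to that column). `sd_wt` is 0 when only one wild-type
#' replicate exists.
#'
#' @param x an [normalize_cpm()] `expression_matrix`.
#' @param pooled_policy what to do when the wild-type group consists only of
#'   pooled columns: `"exclude_pooled_from_sd"` summarises it by its mean
#'   with `sd_wt = NA` (no replicate-based spread exists);
#'   `"error_if_pooled_wt"` refuses.
#' @return a data.frame of class `group_summary` with columns `gene_id`,
#'   `mean_wt`, `mean_mut`, `sd_wt`, `n_wt`, `n_mut`; `n_wt`/`n_mut` record
#'   how many columns entered each mean.
#' @examples
#' m <- matrix(c(8, 10, 12, 16), nrow = 1,
#'             dimnames = list("g1", c("wt_1", "wt_2", "wt_3", "mut_1")))
#' em <- normalize_cpm(count_matrix(m, genotype = c("wt", "wt", "wt", "mut")))
#' group_summary(em)
#' @export
group_summary <- function(x, pooled_policy = c("exclude_pooled_from_sd",
                                               "error_if_pooled_wt")) {
  stopifnot(inherits(x, "expression_matrix"))
  pooled_policy <- match.arg(pooled_policy)
  s <- x$samples
  if (!any(s$genotype == "wt")) stop_("no wild-type samples present")
  if (!any(s$genotype == "mut")) stop_("no mutant samples present")
  wt_ind <- which(s$genotype == "wt" & !s$pooled)
  wt_all <- which(s$genotype == "wt")
  mut_all <- which(s$genotype == "mut")
  if (length(wt_ind) == 0) {
    if (pooled_policy == "error_if_pooled_wt")
      stop_("wild-type group contains only pooled samples")
    wt_use <- wt_all
    sd_wt <- rep(NA_real_, nrow(x$values))
  } else {
    wt_use <- wt_ind
    wt_vals <- x$values[, wt_ind, drop = FALSE]
    sd_wt <- if (length(wt_ind) == 1) rep(0, nrow(x$values))
             else apply(wt_vals, 1, sd)
  }
  res <- data.frame(
    gene_id = rownames(x$values),
    mean_wt = rowMeans(x$values[, wt_use, drop = FALSE]),
    mean_mut = rowMeans(x$values[, mut_all, drop = FALSE]),
    sd_wt = sd_wt,
    n_wt = length(wt_use),
    n_mut = length(mut_all),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  class(res) <- c("group_summary", "data.frame")
  res
}

#' Read and write group summaries as tab-separated text
#'
#' Columns `gene_id`, `mean_wt`, `mean_mut`, `sd_wt`, `n_wt`, `n_mut`.
#'
#' @param x a [group_summary()] data.frame.
#' @param path file path.
#' @return `read_group_summary` returns a `group_summary` data.frame.
#' @export
write_group_summary <- function(x, path) {
  stopifnot(inherits(x, "group_summary"))
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' @rdname write_group_summary
#' @export
read_group_summary <- function(path) {
  res <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "mean_wt", "mean_mut", "sd_wt", "n_wt", "n_mut")
  if (!all(need %in% names(res)))
    stop_("group summary table must have columns %s",
          paste(need, collapse = ", "))
  class(res) <- c("group_summary", "data.frame")
  res
}
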
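#' Construct a labelled gene set
#'
#' A set of unique gene identifiers with a label and a namespace tag (for
#' example `"WormBase"`). Set comparisons refuse to mix namespaces — map one
#' set into the other's namespace first with [harmonize_ids()].
#'
#' @param ids character vector of identifiers; duplicates are collapsed,
#'   empty strings and missing values are an error.
#' @param label short name used in reports.
#' @param namespace identifier namespace tag.
#' @return an object of class `gene_set`.
#' @examples
#' gene_set(c("WBGene00001", "WBGene00002"), "exp1", "WormBase")
#' @export
gene_set <- function(ids, label = "set", namespace = "generic") {
  if (length(ids) && (!is.character(ids) || anyNA(ids) || any(!nzchar(ids))))
    stop_("'ids' must be nonempty, non-missing strings")
  structure(list(ids = unique(ids), label = label, namespace = namespace),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s' (%s): %d ids\n", x$label, x$namespace,
              length(x$ids)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$ids)

#' Read or write a gene set as a plain-text list
#'
#' One identifier per line; blank lines are ignored.
#'
#' @param path file path.
#' @param label,namespace passed to [gene_set()]; the label defaults to the
#'   file name without extension.
#' @param x a `gene_set` to write.
#' @return `read_gene_list` returns a `gene_set`.
#' @export
read_gene_list <- function(path, label = NULL, namespace = "generic") {
  if (!file.exists(path)) stop_("cannot read gene list '%s'", path)
  ids <- trimws(readLines(path, warn = FALSE))
  ids <- ids[nzchar(ids)]
  if (length(ids) == 0) stop_("gene list '%s' is empty", path)
  gene_set(ids, label %||% sub("\\.[^.]*$", "", basename(path)), namespace)
}

#' @rdname read_gene_list
#' @export
write_gene_list <- function(x, path) {
  stopifnot(inherits(x, "gene_set"))
  writeLines(x$ids, path)
  invisible(x)
}

check_comparable <- function(a, b) {
  stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"))
  if (length(a$ids) == 0 || length(b$ids) == 0)
    stop_("cannot compare empty gene sets")
  if (!identical(a$namespace, b$namespace))
    stop_("namespace mismatch ('%s' vs '%s'); harmonize identifiers first",
          a$namespace, b$namespace)
}

#' Pairwise overlap between two gene sets
#'
#' Counts the intersection and the genes unique to each set, and reports the
#' percent overlap using the smallest-set denominator:
#' `100 * |A intersect B| / min(|A|, |B|)`. The percentage is kept at full
#' precision and also rounded half-up to the nearest integer for display.
#' When `background_size` is supplied the enrichment fields of
#' [fold_enrichment()] are filled in as well.
#'
#' @param a,b [gene_set()] objects sharing a namespace.
#' @param background_size optional size of the gene universe both sets were
#'   drawn from; enables fold enrichment and the hypergeometric test.
#' @return an object of class `overlap_result` with fields `label_a`,
#'   `label_b`, `n_a`, `n_b`, `n_intersection`, `n_only_a`, `n_only_b`,
#'   `percent_overlap`, `percent_overlap_rounded`, and (with a background)
#'   `background_size`, `expected_intersection`, `fold_enrichment`,
#'   `hypergeometric_p`, `log10_hypergeometric_p`.
#' @examples
#' a <- gene_set(as.character(1:10), "A")
#' b <- gene_set(as.character(6:20), "B")
#' pairwise_overlap(a, b)
#' @export
pairwise_overlap <- function(a, b, background_size = NULL) {
  check_comparable(a, b)
  k <- length(intersect(a$ids, b$ids))
  res <- list(
    label_a = a$label, label_b = b$label,
    n_a = length(a$ids), n_b = length(b$ids),
    n_intersection = k,
    n_only_a = length(a$ids) - k,
    n_only_b = length(b$ids) - k,
    percent_overlap = 100 * k / min(length(a$ids), length(b$ids))
  )
  res$percent_overlap_rounded <- round_half_up(res$percent_overlap)
  if (!is.null(background_size))
    res <- c(res, enrichment_fields(res$n_a, res$n_b, k, background_size,
                                    union_size = res$n_a + res$n_only_b))
  structure(res, class = "overlap_result")
}

enrichment_fields <- function(n_a, n_b, k, background_size, union_size) {
  assert_count(background_size, "background_size")
  if (background_size < union_size)
    stop_("background_size (%d) is smaller than the union of the sets (%d)",
          background_size, union_size)
  expected <- n_a * n_b / background_size
  log_p <- phyper(k - 1, n_b, background_size - n_b, n_a,
                  lower.tail = FALSE, log.p = TRUE)
  list(
    background_size = as.integer(background_size),
    expected_intersection = expected,
    fold_enrichment = k / expected,
    hypergeometric_p = exp(log_p),
    # upper-tail probabilities underflow for strong overlaps ("p = 0");
    # the log10 tail is always reported alongside.
    log10_hypergeometric_p = log_p / log(10)
  )
}

#' Fold enrichment of an overlap over a background universe
#'
#' Measures how much larger the observed intersection is than expected if
#' the two sets were drawn independently from a background of
#' `background_size` genes: `fold = k / (n_a * n_b / N)`. Significance is
#' the hypergeometric upper tail, the probability of an intersection at
#' least as large when `n_a` genes are drawn without replacement from a
#' universe containing the `n_b` genes of the other set (symmetric in the
#' two sets). Underflowing tails are reported on the log10 scale as well.
#'
#' @inheritParams pairwise_overlap
#' @param background_size size of the gene universe (required; must be at
#'   least the size of the union).
#' @return an `overlap_result` with the enrichment fields populated.
#' @examples
#' a <- gene_set(as.character(1:10), "A")
#' b <- gene_set(as.character(6:15), "B")
#' fold_enrichment(a, b, background_size = 100)$fold_enrichment
#' @export
fold_enrichment <- function(a, b, background_size) {
  pairwise_overlap(a, b, background_size = background_size)
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap %s vs %s: |A|=%d |B|=%d, intersection %d (%.1f%%%s)\n",
              x$label_a, x$label_b, x$n_a, x$n_b, x$n_intersection,
              x$percent_overlap,
              sprintf(", rounds to %d%%", x$percent_overlap_rounded)))
  if (!is.null(x$fold_enrichment))
    cat(sprintf("  background %d: fold enrichment %.2f, hypergeometric p %.3g (log10 p %.1f)\n",
                x$background_size, x$fold_enrichment, x$hypergeometric_p,
                x$log10_hypergeometric_p))
  invisible(x)
}

#' Turn an overlap result into a one-row data.frame
#'
#' @param x an `overlap_result`.
#' @param ... unused.
#' @return data.frame with one row per overlap.
#' @export
as.data.frame.overlap_result <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

#' Identification percentage (recall of a reference set)
#'
#' The percentage of a reference DEG set that a candidate set recovers:
#' `100 * |candidate intersect reference| / |reference|`.
#'
#' @param candidate,reference [gene_set()] objects; the reference must be
#'   nonempty.
#' @return a single percentage in \[0, 100\].
#' @seealso [accuracy_fraction()] for the precision counterpart.
#' @export
identification_fraction <- function(candidate, reference) {
  check_comparable(candidate, reference)
  100 * length(intersect(candidate$ids, reference$ids)) /
    length(reference$ids)
}

#' Accuracy percentage (precision against a reference set)
#'
#' The percentage of the candidate set that lies inside the reference:
#' `100 * |candidate intersect reference| / |candidate|`.
#'
#' @inheritParams identification_fraction
#' @return a single percentage in \[0, 100\].
#' @export
accuracy_fraction <- function(candidate, reference) {
  check_comparable(candidate, reference)
  100 * length(intersect(candidate$ids, reference$ids)) /
    length(candidate$ids)
}

#' Multiway Venn partition of two to four gene sets
#'
#' Partitions the union of the sets by membership pattern: every identifier
#' is assigned to exactly one pattern (a string of 0/1 flags, one per set in
#' order), and the count of ids per nonempty pattern is returned. Pattern
#' counts sum to the union size and the margins reconstruct every input
#' set's size exactly.
#'
#' @param sets list of 2 to 4 [gene_set()] objects sharing a namespace.
#' @return an object of class `multiway_overlap`: list with `labels`,
#'   `counts` (named integer vector keyed by pattern, e.g. `"110"`), and
#'   `n_union`.
#' @examples
#' s <- lapply(1:3, function(i) gene_set(as.character(i:(i + 3)), paste0("S", i)))
#' multiway_overlap(s)$counts
#' @export
multiway_overlap <- function(sets) {
  if (!is.list(sets) || length(sets) < 2 || length(sets) > 4)
    stop_("'sets' must be a list of 2 to 4 gene sets")
  for (s in sets) stopifnot(inherits(s, "gene_set"))
  ns <- unique(vapply(sets, function(s) s$namespace, character(1)))
  if (length(ns) > 1)
    stop_("namespace mismatch (%s); harmonize identifiers first",
          paste(ns, collapse = ", "))
  universe <- unique(unlist(lapply(sets, function(s) s$ids)))
  membership <- vapply(sets, function(s) universe %in% s$ids,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
  pattern <- apply(membership, 1, function(row)
    paste(as.integer(row), collapse = ""))
  counts <- table(pattern)
  counts <- setNames(as.integer(counts), names(counts))
  structure(list(labels = vapply(sets, function(s) s$label, character(1)),
                 counts = counts, n_union = length(universe)),
            class = "multiway_overlap")
}

#' @export
print.multiway_overlap <- function(x, ...) {
  cat(sprintf("multiway_overlap of %s (union %d):\n",
              paste(x$labels, collapse = ", "), x$n_union))
  for (p in names(x$counts)) {
    members <- x$labels[strsplit(p, "")[[1]] == "1"]
    cat(sprintf("  %s (%s): %d\n", p, paste(members, collapse = "&"),
                x$counts[[p]]))
  }
  invisible(x)
}

#' Map a gene set into another identifier namespace
#'
#' Applies a two-column old-to-new identifier mapping. Identifiers without a
#' mapping are dropped from the set and returned in an unmapped report
#' (mirroring curation churn, where identifiers once reported as genes are
#' retired). Several old identifiers may map to one new identifier; the
#' result is deduplicated. Conflicting duplicate keys are an error.
#'
#' @param x a [gene_set()].
#' @param mapping data.frame whose first two columns are old and new
#'   identifiers (see [read_id_mapping()]).
#' @param namespace namespace tag of the mapped set.
#' @return list with `set` (the mapped `gene_set`) and `unmapped`
#'   (character vector of dropped input ids).
#' @export
harmonize_ids <- function(x, mapping, namespace = "mapped") {
  stopifnot(inherits(x, "gene_set"), is.data.frame(mapping),
            ncol(mapping) >= 2)
  old <- as.character(mapping[[1]])
  new <- as.character(mapping[[2]])
  dup <- duplicated(old)
  if (any(dup)) {
    conflicting <- vapply(unique(old[dup]), function(k)
      length(unique(new[old == k])) > 1, logical(1))
    if (any(conflicting))
      stop_("mapping has conflicting targets for old id(s): %s",
            paste(names(conflicting)[conflicting], collapse = ", "))
    keep <- !dup
    old <- old[keep]; new <- new[keep]
  }
  hit <- match(x$ids, old)
  unmapped <- x$ids[is.na(hit)]
  mapped <- unique(new[hit[!is.na(hit)]])
  list(set = gene_set(mapped, label = x$label, namespace = namespace),
       unmapped = unmapped)
}

#' Read a two-column identifier mapping table
#'
#' Tab-separated, first column old identifiers, second column new; a header
#' row is detected and kept if the file has one named `old_id`/`new_id`.
#'
#' @param path file path.
#' @return data.frame with columns `old_id`, `new_id`.
#' @export
read_id_mapping <- function(path) {
  first <- readLines(path, n = 1, warn = FALSE)
  header <- grepl("^old_id\\t", first)
  df <- read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_("mapping table needs two columns")
  names(df)[1:2] <- c("old_id", "new_id")
  df
}
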
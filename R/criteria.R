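#' Specify a DEG-calling criterion
#'
#' Four kinds of rule decide whether a gene is differentially expressed
#' between mutant and wild type:
#'
#' * `ratio` — the mean mutant expression divided by the mean wild-type
#'   expression exceeds `ratio_threshold` (e.g. 5, 2 or 1.5, i.e. an
#'   increase above 500%, 200% or 150% of the wild-type level);
#' * `stdev` — the difference of the means, expressed in units of the
#'   wild-type replicate standard deviation, exceeds `stdev_multiplier`
#'   (e.g. 3 or 2);
#' * `ratio_and_stdev` — both of the above must hold;
#' * `fdr` — a per-gene Welch t-test on log2(CPM + 1) with
#'   Benjamini-Hochberg adjustment; called when the adjusted p is at most
#'   `alpha` and the change is in the requested direction.
#'
#' All thresholds are strict ("above the threshold"); `direction = "down"`
#' mirrors every rule with the roles of the two group means swapped.
#'
#' Criteria also parse from compact tokens: `"ratio:1.5"`, `"stdev:2"`,
#' `"ratio+stdev:1.5,2"`, `"fdr:0.05"`.
#'
#' @param kind one of `"ratio"`, `"stdev"`, `"ratio_and_stdev"`, `"fdr"`.
#' @param ratio_threshold fold-change threshold (> 0).
#' @param stdev_multiplier standard-deviation multiplier (> 0).
#' @param alpha FDR level in (0, 1).
#' @param direction `"up"` or `"down"`.
#' @return an object of class `criterion`.
#' @examples
#' criterion("ratio_and_stdev", ratio_threshold = 1.5, stdev_multiplier = 2)
#' parse_criterion("ratio+stdev:1.5,2")
#' @export
criterion <- function(kind = c("ratio", "stdev", "ratio_and_stdev", "fdr"),
                      ratio_threshold = NULL, stdev_multiplier = NULL,
                      alpha = NULL, direction = c("up", "down")) {
  kind <- match.arg(kind)
  direction <- match.arg(direction)
  if (kind %in% c("ratio", "ratio_and_stdev"))
    assert_scalar_number(ratio_threshold, "ratio_threshold", positive = TRUE)
  if (kind %in% c("stdev", "ratio_and_stdev"))
    assert_scalar_number(stdev_multiplier, "stdev_multiplier", positive = TRUE)
  if (kind == "fdr") {
    assert_scalar_number(alpha, "alpha")
    if (alpha <= 0 || alpha >= 1) stop_("'alpha' must lie in (0, 1)")
  }
  structure(list(kind = kind, ratio_threshold = ratio_threshold,
                 stdev_multiplier = stdev_multiplier, alpha = alpha,
                 direction = direction),
            class = "criterion")
}

#' @rdname criterion
#' @param token compact text form, e.g. `"ratio:1.5"` or
#'   `"ratio+stdev:1.5,3"`.
#' @export
parse_criterion <- function(token, direction = "up") {
  valid <- "valid tokens: ratio:<t>, stdev:<k>, ratio+stdev:<t>,<k>, fdr:<alpha>"
  parts <- strsplit(token, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop_("cannot parse criterion '%s'; %s", token, valid)
  nums <- suppressWarnings(as.numeric(strsplit(parts[2], ",")[[1]]))
  if (anyNA(nums)) stop_("cannot parse criterion '%s'; %s", token, valid)
  switch(parts[1],
    "ratio" = criterion("ratio", ratio_threshold = nums[1],
                        direction = direction),
    "stdev" = criterion("stdev", stdev_multiplier = nums[1],
                        direction = direction),
    "ratio+stdev" = {
      if (length(nums) != 2)
        stop_("'ratio+stdev' needs two values; %s", valid)
      criterion("ratio_and_stdev", ratio_threshold = nums[1],
                stdev_multiplier = nums[2], direction = direction)
    },
    "fdr" = criterion("fdr", alpha = nums[1], direction = direction),
    stop_("unknown criterion kind '%s'; %s", parts[1], valid)
  )
}

#' @export
format.criterion <- function(x, ...) {
  switch(x$kind,
    ratio = sprintf("ratio:%g", x$ratio_threshold),
    stdev = sprintf("stdev:%g", x$stdev_multiplier),
    ratio_and_stdev = sprintf("ratio+stdev:%g,%g", x$ratio_threshold,
                              x$stdev_multiplier),
    fdr = sprintf("fdr:%g", x$alpha)
  )
}

#' @export
print.criterion <- function(x, ...) {
  cat(sprintf("criterion %s (direction: %s)\n", format(x), x$direction))
  invisible(x)
}

new_deg_calls <- function(crit, scores) {
  stopifnot(is.data.frame(scores))
  structure(list(criterion = crit, scores = scores), class = "deg_calls")
}

#' @export
print.deg_calls <- function(x, ...) {
  cat(sprintf("deg_calls under %s: %d of %d genes called\n",
              format(x$criterion), sum(x$scores$called), nrow(x$scores)))
  invisible(x)
}

#' Extract the identifiers of called genes
#'
#' @param x a `deg_calls` result.
#' @return character vector of gene identifiers.
#' @export
called_genes <- function(x) {
  stopifnot(inherits(x, "deg_calls"))
  x$scores$gene_id[x$scores$called]
}

# Shared score columns. ratio is always mean_mut / mean_wt (NaN when both
# means are zero); sd_units is (mean_mut - mean_wt) / sd_wt.
base_scores <- function(summary) {
  ratio <- ifelse(summary$mean_wt == 0 & summary$mean_mut == 0,
                  NaN, summary$mean_mut / summary$mean_wt)
  data.frame(gene_id = summary$gene_id,
             ratio = ratio,
             sd_units = (summary$mean_mut - summary$mean_wt) / summary$sd_wt,
             stringsAsFactors = FALSE)
}

ratio_called <- function(summary, threshold, direction) {
  num <- if (direction == "up") summary$mean_mut else summary$mean_wt
  den <- if (direction == "up") summary$mean_wt else summary$mean_mut
  r <- ifelse(num == 0 & den == 0, NaN, num / den)  # x/0 -> Inf: called
  !is.nan(r) & r > threshold
}

stdev_called <- function(summary, k, direction) {
  if (anyNA(summary$sd_wt))
    stop_(paste("standard-deviation criteria require individually sequenced",
                "wild-type replicates (sd_wt is missing)"))
  diff <- if (direction == "up") summary$mean_mut - summary$mean_wt
          else summary$mean_wt - summary$mean_mut
  z <- diff / summary$sd_wt   # 0/0 -> NaN: not called; d/0 -> Inf: called
  !is.nan(z) & z > k
}

#' Call DEGs by fold-change ratio
#'
#' A gene is called when the ratio of group means strictly exceeds the
#' threshold: for `direction = "up"`, `mean_mut / mean_wt > threshold`.
#' A zero wild-type mean with nonzero mutant mean counts as called (the
#' ratio is infinite); a gene silent in both groups is never called.
#'
#' @param summary a [group_summary()].
#' @param threshold fold-change threshold (> 0), e.g. 1.5 for an increase
#'   above 150% of the wild-type level.
#' @param direction `"up"` or `"down"`; down swaps the two means.
#' @return a `deg_calls` object.
#' @seealso [call_by_stdev()], [call_combined()], [call_by_fdr()]
#' @export
call_by_ratio <- function(summary, threshold, direction = c("up", "down")) {
  stopifnot(inherits(summary, "group_summary"))
  if (nrow(summary) == 0) stop_("'summary' is empty")
  direction <- match.arg(direction)
  assert_scalar_number(threshold, "threshold", positive = TRUE)
  scores <- base_scores(summary)
  scores$called <- ratio_called(summary, threshold, direction)
  new_deg_calls(criterion("ratio", ratio_threshold = threshold,
                          direction = direction), scores)
}

#' Call DEGs by standard-deviation units
#'
#' A gene is called when the difference of the group means, divided by the
#' standard deviation of the individually sequenced wild-type replicates,
#' strictly exceeds `k`: for `direction = "up"`,
#' `(mean_mut - mean_wt) / sd_wt > k`. When `sd_wt` is zero, any increase
#' counts as infinitely many standard deviations (called); no change does
#' not.
#'
#' @param summary a [group_summary()] with non-missing `sd_wt`.
#' @param k standard-deviation multiplier (> 0), e.g. 2 or 3.
#' @inheritParams call_by_ratio
#' @return a `deg_calls` object.
#' @export
call_by_stdev <- function(summary, k, direction = c("up", "down")) {
  stopifnot(inherits(summary, "group_summary"))
  if (nrow(summary) == 0) stop_("'summary' is empty")
  direction <- match.arg(direction)
  assert_scalar_number(k, "k", positive = TRUE)
  scores <- base_scores(summary)
  scores$called <- stdev_called(summary, k, direction)
  new_deg_calls(criterion("stdev", stdev_multiplier = k,
                          direction = direction), scores)
}

#' Call DEGs by the conjunction of ratio and standard-deviation rules
#'
#' A gene must satisfy both constituent rules (e.g. an increase above 150%
#' and above 2 wild-type standard deviations). The called set is exactly the
#' intersection of [call_by_ratio()] and [call_by_stdev()] called sets.
#'
#' @inheritParams call_by_ratio
#' @inheritParams call_by_stdev
#' @return a `deg_calls` object.
#' @export
call_combined <- function(summary, threshold, k, direction = c("up", "down")) {
  stopifnot(inherits(summary, "group_summary"))
  if (nrow(summary) == 0) stop_("'summary' is empty")
  direction <- match.arg(direction)
  assert_scalar_number(threshold, "threshold", positive = TRUE)
  assert_scalar_number(k, "k", positive = TRUE)
  scores <- base_scores(summary)
  scores$called <- ratio_called(summary, threshold, direction) &
    stdev_called(summary, k, direction)
  new_deg_calls(criterion("ratio_and_stdev", ratio_threshold = threshold,
                          stdev_multiplier = k, direction = direction),
                scores)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts raw p-values so that rejecting every gene with adjusted value at
#' most alpha controls the false discovery rate at alpha. Output order
#' matches input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop_("p-values must be numbers in [0, 1]")
  p.adjust(p, method = "BH")
}

# Vectorised two-sample Welch t-test across matrix rows. Zero-variance rows
# get p = 1 when the means agree and p = 0 otherwise.
row_welch <- function(x, y) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  d <- my - mx
  t <- d / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * pt(-abs(t), df)
  degen <- se2 == 0
  p[degen] <- ifelse(d[degen] == 0, 1, 0)
  t[degen] <- ifelse(d[degen] == 0, 0, sign(d[degen]) * Inf)
  list(statistic = t, p = p, delta = d)
}

#' Call DEGs by significance with FDR control
#'
#' The significance route: per-gene two-sample Welch t-test on
#' log2(CPM + 1) between the individually sequenced samples of the two
#' genotypes, two-sided p-values adjusted across all genes by
#' Benjamini-Hochberg ([bh_adjust()]); a gene is called when its adjusted p
#' is at most `alpha` and its change points in the requested direction.
#' Pooled columns are excluded: a single library carries no replicate
#' variance.
#'
#' @param x an [normalize_cpm()] `expression_matrix` with at least two
#'   individually sequenced samples per genotype.
#' @param alpha FDR level, default 0.05.
#' @inheritParams call_by_ratio
#' @return a `deg_calls` object whose scores include `p_adj`.
#' @export
call_by_fdr <- function(x, alpha = 0.05, direction = c("up", "down")) {
  stopifnot(inherits(x, "expression_matrix"))
  direction <- match.arg(direction)
  assert_scalar_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) stop_("'alpha' must lie in (0, 1)")
  s <- x$samples
  wt <- which(s$genotype == "wt" & !s$pooled)
  mut <- which(s$genotype == "mut" & !s$pooled)
  if (length(wt) < 2 || length(mut) < 2)
    stop_(paste("significance calls need at least two individually sequenced",
                "samples per genotype"))
  lw <- log2(x$values[, wt, drop = FALSE] + 1)
  lm_ <- log2(x$values[, mut, drop = FALSE] + 1)
  tt <- row_welch(lw, lm_)
  p_adj <- bh_adjust(tt$p)
  summ <- group_summary(x)
  scores <- base_scores(summ)
  scores$p_adj <- p_adj
  sgn <- if (direction == "up") tt$delta > 0 else tt$delta < 0
  scores$called <- p_adj <= alpha & sgn
  new_deg_calls(criterion("fdr", alpha = alpha, direction = direction), scores)
}

#' Apply a criterion object to data
#'
#' Dispatches to the matching `call_by_*` function. Ratio/stdev criteria run
#' on a [group_summary()]; the `fdr` criterion needs the full
#' `expression_matrix` (replicate-level values), which can be supplied via
#' `matrix` while `summary`-based criteria ignore it.
#'
#' @param crit a [criterion()] or a token string for [parse_criterion()].
#' @param summary a [group_summary()] (required for non-fdr kinds).
#' @param matrix an `expression_matrix` (required for the fdr kind).
#' @return a `deg_calls` object.
#' @export
call_degs <- function(crit, summary = NULL, matrix = NULL) {
  if (is.character(crit)) crit <- parse_criterion(crit)
  stopifnot(inherits(crit, "criterion"))
  switch(crit$kind,
    ratio = call_by_ratio(summary, crit$ratio_threshold, crit$direction),
    stdev = call_by_stdev(summary, crit$stdev_multiplier, crit$direction),
    ratio_and_stdev = call_combined(summary, crit$ratio_threshold,
                                    crit$stdev_multiplier, crit$direction),
    fdr = {
      if (is.null(matrix))
        stop_("the fdr criterion needs the expression matrix, not a summary")
      call_by_fdr(matrix, crit$alpha, crit$direction)
    }
  )
}

#' Write DEG calls to disk
#'
#' Two plain-text artefacts: the called genes as one identifier per line,
#' and the full per-gene score table (`gene_id`, `ratio`, `sd_units`,
#' `p_adj` where applicable, `called`) as tab-separated values.
#'
#' @param x a `deg_calls` object.
#' @param list_path path for the called-gene list (`NULL` to skip).
#' @param table_path path for the score table (`NULL` to skip).
#' @return invisibly, `x`.
#' @export
write_deg_calls <- function(x, list_path = NULL, table_path = NULL) {
  stopifnot(inherits(x, "deg_calls"))
  if (!is.null(list_path)) writeLines(called_genes(x), list_path)
  if (!is.null(table_path))
    write.table(x$scores, table_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(x)
}
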
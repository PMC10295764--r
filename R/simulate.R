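#' Describe a synthetic two-genotype replicate experiment
#'
#' Bundles every parameter of the generative model behind
#' [simulate_experiment()] and validates the joint constraints. The model:
#' per-gene baseline expression levels are drawn log-normally; a chosen
#' fraction of genes is planted as up- or down-regulated in the mutant with
#' true fold changes drawn log-uniformly; each sample's gene means are scaled
#' to its library size (as sequencing depth does, making the counts
#' compositional); counts are drawn negative-binomially with variance
#' `m + dispersion * m^2` (Poisson when `dispersion = 0`).
#'
#' Defaults describe a bulk C. elegans-style design: 12000 genes, six
#' biological replicates per genotype, a wide log-normal baseline, mild
#' overdispersion typical of genetically identical bulk samples, and 10% of
#' genes up-regulated two- to eight-fold.
#'
#' @param n_genes number of genes.
#' @param replicates_wt,replicates_mut biological replicates per genotype,
#'   each sequenced individually.
#' @param baseline_log_mean,baseline_log_sd mean and sd (natural-log scale)
#'   of the log-normal baseline expression law; the absolute scale is
#'   arbitrary since samples are rescaled to their library size.
#' @param dispersion negative-binomial overdispersion phi >= 0, so that the
#'   count variance is `m + phi * m^2` around mean `m`; `0` gives Poisson.
#' @param frac_up,frac_down fractions of genes planted up-/down-regulated;
#'   their sum must not exceed 1.
#' @param fc_low,fc_high bounds (> 1) of the log-uniform law for true fold
#'   changes; down-regulated genes use the reciprocal, symmetric on the log
#'   scale.
#' @param library_size expected total counts of each individually sequenced
#'   sample.
#' @param pooled_library_size total counts of a pooled library built by
#'   [pool_replicates()].
#' @param pooling_mode `"expectation"` (noise-free mixing arithmetic) or
#'   `"multinomial"` (one multinomial sequencing draw from the pooled
#'   profile).
#' @param seed integer master seed; identical configs give bit-identical
#'   output.
#' @return an object of class `simulation_config` (a validated list).
#' @seealso [simulate_experiment()], [read_simulation_config()]
#' @export
simulation_config <- function(n_genes = 12000L,
                              replicates_wt = 6L,
                              replicates_mut = 6L,
                              baseline_log_mean = 3,
                              baseline_log_sd = 1.5,
                              dispersion = 0.05,
                              frac_up = 0.10,
                              frac_down = 0,
                              fc_low = 2,
                              fc_high = 8,
                              library_size = 2e6,
                              pooled_library_size = 2e6,
                              pooling_mode = c("multinomial", "expectation"),
                              seed = 1L) {
  cfg <- list(
    n_genes = assert_count(n_genes, "n_genes"),
    replicates_wt = assert_count(replicates_wt, "replicates_wt"),
    replicates_mut = assert_count(replicates_mut, "replicates_mut"),
    baseline_log_mean = assert_scalar_number(baseline_log_mean,
                                             "baseline_log_mean"),
    baseline_log_sd = assert_scalar_number(baseline_log_sd, "baseline_log_sd",
                                           nonneg = TRUE),
    dispersion = assert_scalar_number(dispersion, "dispersion", nonneg = TRUE),
    frac_up = assert_fraction(frac_up, "frac_up"),
    frac_down = assert_fraction(frac_down, "frac_down"),
    fc_low = assert_scalar_number(fc_low, "fc_low", positive = TRUE),
    fc_high = assert_scalar_number(fc_high, "fc_high", positive = TRUE),
    library_size = assert_count(library_size, "library_size"),
    pooled_library_size = assert_count(pooled_library_size,
                                       "pooled_library_size"),
    pooling_mode = match.arg(pooling_mode),
    seed = seed
  )
  assert_scalar_number(seed, "seed")
  if (seed != as.integer(seed)) stop_("'seed' must be a whole number")
  cfg$seed <- as.integer(seed)
  if (cfg$frac_up + cfg$frac_down > 1)
    stop_("invalid config: frac_up + frac_down exceeds 1")
  if (cfg$fc_low <= 1)
    stop_("invalid config: fc_low must exceed 1")
  if (cfg$fc_low > cfg$fc_high)
    stop_("invalid config: fc_low must not exceed fc_high")
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config:\n")
  for (k in names(x)) cat(sprintf("  %-20s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Read or write a simulation config as a flat key-value file
#'
#' One `key = value` pair per line; `#` starts a comment. Keys are the
#' arguments of [simulation_config()]; missing keys take the defaults.
#'
#' @param path file path.
#' @param cfg a `simulation_config`.
#' @return `read_simulation_config` returns a validated
#'   `simulation_config`; `write_simulation_config` invisibly returns `cfg`.
#' @export
read_simulation_config <- function(path) {
  kv <- read_keyvalue(path)
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(kv), known)
  if (length(unknown))
    stop_("unknown config key(s): %s", paste(unknown, collapse = ", "))
  num <- setdiff(known, "pooling_mode")
  kv[intersect(names(kv), num)] <-
    lapply(kv[intersect(names(kv), num)], as.numeric)
  do.call(simulation_config, kv)
}

#' @rdname read_simulation_config
#' @export
write_simulation_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "simulation_config"))
  lines <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    sprintf("%s = %s", k, if (is.character(v)) v else format(v, digits = 15))
  }, character(1))
  writeLines(lines, path)
  invisible(cfg)
}

read_keyvalue <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  bad <- !grepl("=", lines, fixed = TRUE)
  if (any(bad)) stop_("malformed config line: '%s'", lines[bad][1])
  parts <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  kv <- lapply(parts, function(p) trimws(p[2]))
  names(kv) <- vapply(parts, function(p) trimws(p[1]), character(1))
  if (anyDuplicated(names(kv)))
    stop_("duplicate config key: '%s'", names(kv)[duplicated(names(kv))][1])
  kv
}

# Gene-level parameters (baseline means, truth labels, fold changes), drawn
# from their own sub-stream so several experiments can share one biology.
draw_gene_params <- function(cfg, seed = cfg$seed) {
  set.seed(derive_seed(seed, 1L))
  n <- cfg$n_genes
  gene_id <- sprintf("gene_%05d", seq_len(n))
  baseline <- exp(rnorm(n, cfg$baseline_log_mean, cfg$baseline_log_sd))
  n_up <- round(cfg$frac_up * n)
  n_down <- round(cfg$frac_down * n)
  status <- rep("null", n)
  fc <- rep(1, n)
  if (n_up + n_down > 0) {
    hit <- sample.int(n, n_up + n_down)
    up <- hit[seq_len(n_up)]
    down <- hit[setdiff(seq_len(n_up + n_down), seq_len(n_up))]
    status[up] <- "up"
    status[down] <- "down"
    fc[up] <- exp(runif(n_up, log(cfg$fc_low), log(cfg$fc_high)))
    fc[down] <- 1 / exp(runif(n_down, log(cfg$fc_low), log(cfg$fc_high)))
  }
  list(
    gene_id = gene_id,
    baseline = baseline,
    truth = data.frame(gene_id = gene_id, status = status,
                       true_fold_change = fc, stringsAsFactors = FALSE)
  )
}

# One sample's counts: gene means scaled to the library size, then NB noise.
draw_sample_counts <- function(mean_profile, library_size, dispersion) {
  mu <- mean_profile / sum(mean_profile) * library_size
  n <- length(mu)
  if (dispersion == 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / dispersion)
}

draw_counts <- function(cfg, params, seed = cfg$seed) {
  set.seed(derive_seed(seed, 2L))
  mut_mean <- params$baseline * params$truth$true_fold_change
  wt_cols <- replicate(cfg$replicates_wt,
                       draw_sample_counts(params$baseline, cfg$library_size,
                                          cfg$dispersion))
  mut_cols <- replicate(cfg$replicates_mut,
                        draw_sample_counts(mut_mean, cfg$library_size,
                                           cfg$dispersion))
  counts <- cbind(wt_cols, mut_cols)
  rownames(counts) <- params$gene_id
  colnames(counts) <- c(sprintf("wt_%d", seq_len(cfg$replicates_wt)),
                        sprintf("mut_%d", seq_len(cfg$replicates_mut)))
  count_matrix(counts,
               genotype = rep(c("wt", "mut"),
                              c(cfg$replicates_wt, cfg$replicates_mut)))
}

#' Simulate a two-genotype replicate RNA-seq experiment with known truth
#'
#' Draws one complete experiment under the generative model described in
#' [simulation_config()]: `replicates_wt + replicates_mut` individually
#' sequenced samples plus a truth table recording, per gene, its planted
#' status (`up`, `down`, `null`) and true fold change (mutant relative to
#' wild type; 1 for null genes). Identical configs (including the seed) give
#' bit-identical output.
#'
#' @param config a [simulation_config()].
#' @return a list with elements `counts` (a [count_matrix()]) and `truth`
#'   (a data.frame `gene_id`, `status`, `true_fold_change`).
#' @examples
#' sim <- simulate_experiment(simulation_config(n_genes = 100, seed = 7))
#' table(sim$truth$status)
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  params <- draw_gene_params(config)
  list(counts = draw_counts(config, params), truth = params$truth)
}

#' Pool replicate samples into a single equal-mass library
#'
#' Emulates mixing equal masses of RNA from several biological replicates
#' before sequencing. Each selected column is first converted to relative
#' abundance (divided by its column total, so every replicate contributes the
#' same mass regardless of its sequencing depth); the pooled profile is the
#' unweighted mean of these proportion vectors. In `"expectation"` mode the
#' returned column is that profile times `pooled_library_size` — the exact
#' mixing arithmetic, useful for separating pooling from sequencing noise. In
#' `"multinomial"` mode it is a single multinomial draw of
#' `pooled_library_size` reads from the profile, i.e. the mixed library as a
#' sequencer would sample it.
#'
#' @param x a [count_matrix()].
#' @param sample_subset character vector of sample identifiers to pool
#'   (nonempty; each must have positive total counts).
#' @param pooled_library_size total reads of the pooled library.
#' @param mode `"expectation"` or `"multinomial"`.
#' @param seed integer seed used (only) for the multinomial draw.
#' @return named numeric vector, one value per gene.
#' @examples
#' m <- matrix(c(10, 30, 60, 1, 1, 2), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("mut_1", "mut_2")))
#' cm <- count_matrix(m, genotype = c("mut", "mut"))
#' pool_replicates(cm, c("mut_1", "mut_2"), 100, mode = "expectation")
#' @export
pool_replicates <- function(x, sample_subset, pooled_library_size,
                            mode = c("expectation", "multinomial"),
                            seed = 1L) {
  stopifnot(inherits(x, "count_matrix"))
  mode <- match.arg(mode)
  assert_count(pooled_library_size, "pooled_library_size")
  if (length(sample_subset) == 0)
    stop_("'sample_subset' must name at least one sample")
  missing <- setdiff(sample_subset, x$samples$sample_id)
  if (length(missing))
    stop_("unknown sample(s): %s", paste(missing, collapse = ", "))
  cols <- x$counts[, sample_subset, drop = FALSE]
  totals <- colSums(cols)
  if (any(totals <= 0))
    stop_("sample(s) with zero total counts cannot be pooled: %s",
          paste(sample_subset[totals <= 0], collapse = ", "))
  props <- sweep(cols, 2, totals, "/")
  profile <- rowMeans(props)
  if (mode == "expectation") {
    profile * pooled_library_size
  } else {
    set.seed(derive_seed(seed, 3L))
    draw <- rmultinom(1, size = pooled_library_size, prob = profile)[, 1]
    setNames(as.numeric(draw), rownames(cols))
  }
}
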
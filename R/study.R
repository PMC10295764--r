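#' Describe one arm of a replicate-versus-pooled study
#'
#' An arm is one independently collected experiment: a number of biological
#' replicates per genotype, with the mutant replicates optionally pooled
#' into a single library before sequencing (the wild-type side is always
#' sequenced individually, so the wild-type standard deviation exists in
#' every arm).
#'
#' @param name arm label used throughout the report.
#' @param replicates_wt,replicates_mut biological replicates collected per
#'   genotype.
#' @param pool_mut if `TRUE`, the mutant replicates are mixed equal-mass
#'   into one pooled library ([pool_replicates()]) and only that library is
#'   "sequenced".
#' @return a `study_arm` list.
#' @export
study_arm <- function(name, replicates_wt, replicates_mut, pool_mut = FALSE) {
  assert_count(replicates_wt, "replicates_wt")
  assert_count(replicates_mut, "replicates_mut")
  stopifnot(is.character(name), nzchar(name), is.logical(pool_mut))
  structure(list(name = name, replicates_wt = as.integer(replicates_wt),
                 replicates_mut = as.integer(replicates_mut),
                 pool_mut = pool_mut),
            class = "study_arm")
}

#' Describe a full simulated study design
#'
#' @param arms list of [study_arm()]s with unique names (at least one).
#' @param criteria character vector of criterion tokens (see
#'   [parse_criterion()]); at least one.
#' @param reference_alpha FDR level used to build the between-arm reference
#'   set (the intersection of the individually sequenced arms' significant
#'   genes), default 0.05.
#' @param direction `"up"` or `"down"` for every criterion.
#' @return a `study_design` list.
#' @export
study_design <- function(arms, criteria, reference_alpha = 0.05,
                         direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(is.list(arms), length(arms) >= 1)
  for (a in arms) stopifnot(inherits(a, "study_arm"))
  nm <- vapply(arms, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop_("arm names must be unique")
  if (length(criteria) < 1) stop_("at least one criterion is required")
  for (tok in criteria) parse_criterion(tok, direction)  # validate early
  assert_fraction(reference_alpha, "reference_alpha")
  structure(list(arms = arms, criteria = criteria,
                 reference_alpha = reference_alpha, direction = direction),
            class = "study_design")
}

#' The default three-arm design
#'
#' Emulates comparing three experiments on the same biology: six replicates
#' per genotype sequenced individually; three replicates per genotype
#' sequenced individually; and six replicates per genotype with the mutant
#' side pooled into a single library. Criteria cover the three fold-change
#' thresholds (5x, 2x, 1.5x), the two standard-deviation thresholds (3, 2),
#' their two conjunctions, and the FDR 0.05 significance route.
#'
#' @return a [study_design()].
#' @export
default_study_design <- function() {
  study_design(
    arms = list(
      study_arm("ind6", 6, 6),
      study_arm("ind3", 3, 3),
      study_arm("pooled6", 6, 6, pool_mut = TRUE)
    ),
    criteria = c("ratio:5", "ratio:2", "ratio:1.5", "stdev:3", "stdev:2",
                 "ratio+stdev:1.5,3", "ratio+stdev:1.5,2", "fdr:0.05")
  )
}

arm_has_fdr <- function(arm) {
  arm$replicates_wt >= 2 && (!arm$pool_mut) && arm$replicates_mut >= 2
}

simulate_arm <- function(config, arm, params, arm_seed) {
  arm_cfg <- config
  arm_cfg$replicates_wt <- arm$replicates_wt
  arm_cfg$replicates_mut <- arm$replicates_mut
  cm <- draw_counts(arm_cfg, params, seed = arm_seed)
  if (arm$pool_mut) {
    mut_ids <- cm$samples$sample_id[cm$samples$genotype == "mut"]
    pooled <- pool_replicates(cm, mut_ids, config$pooled_library_size,
                              mode = config$pooling_mode, seed = arm_seed)
    wt_ids <- cm$samples$sample_id[cm$samples$genotype == "wt"]
    wt_only <- count_matrix(cm$counts[, wt_ids, drop = FALSE],
                            genotype = rep("wt", length(wt_ids)))
    cm <- add_sample(wt_only, pooled, "mut_pooled", "mut", pooled = TRUE)
  }
  cm
}

#' Run a complete simulated replicate-versus-pooled study
#'
#' Simulates one shared biology (gene baselines, truth labels, true fold
#' changes) from the master seed, then one independent experiment per arm
#' (arm seeds derived deterministically), applies in-silico pooling where
#' the arm requests it, normalises to CPM, calls DEGs under every requested
#' criterion, and computes the concordance statistics: pairwise overlaps
#' between arms per criterion, and identification/accuracy of every arm's
#' calls against two reference sets — the planted truth and the
#' intersection of the individually sequenced arms' FDR-significant genes
#' (the benchmark a real study would use, where no truth exists).
#'
#' @param config a [simulation_config()]; its `seed` governs the whole
#'   study.
#' @param design a [study_design()], default [default_study_design()].
#' @return an object of class `study_report`: list with `seed`,
#'   `package_version`, `config`, `design`, `calls` (per arm, per
#'   criterion: called gene ids or `NULL` when the criterion does not apply
#'   to the arm), `arm_table`, `overlaps`, `recovery` (data.frames in which
#'   every percentage is recomputable from the stored counts),
#'   `reference` (the two reference gene-id vectors), and `truth`.
#' @export
run_simulation_study <- function(config, design = default_study_design()) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(design, "study_design"))
  params <- draw_gene_params(config)
  truth <- params$truth
  dirn <- design$direction
  arm_names <- vapply(design$arms, `[[`, character(1), "name")

  calls <- list()
  ref_fdr_calls <- list()
  for (i in seq_along(design$arms)) {
    arm <- design$arms[[i]]
    arm_seed <- derive_seed(config$seed, 100L + i)
    cm <- simulate_arm(config, arm, params, arm_seed)
    em <- normalize_cpm(cm)
    summ <- group_summary(em)
    arm_calls <- list()
    for (tok in design$criteria) {
      crit <- parse_criterion(tok, dirn)
      arm_calls[[tok]] <-
        if (crit$kind == "fdr" && !arm_has_fdr(arm)) NULL
        else called_genes(call_degs(crit, summary = summ, matrix = em))
    }
    calls[[arm$name]] <- arm_calls
    if (arm_has_fdr(arm))
      ref_fdr_calls[[arm$name]] <-
        called_genes(call_by_fdr(em, design$reference_alpha, dirn))
  }

  truth_status <- if (dirn == "up") "up" else "down"
  reference <- list(
    truth = truth$gene_id[truth$status == truth_status],
    fdr_intersection = if (length(ref_fdr_calls))
      Reduce(intersect, ref_fdr_calls) else character(0)
  )

  arm_table <- do.call(rbind, lapply(arm_names, function(an) {
    data.frame(arm = an, criterion = design$criteria,
               applicable = !vapply(calls[[an]][design$criteria], is.null,
                                    logical(1)),
               n_called = vapply(calls[[an]][design$criteria],
                                 function(x) length(x %||% character(0)),
                                 integer(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  }))

  overlaps <- study_overlaps(calls, design, arm_names, config$n_genes)
  recovery <- study_recovery(calls, design, arm_names, reference)

  structure(list(
    seed = config$seed,
    package_version = as.character(packageVersion("pooldeg")),
    config = config, design = design,
    calls = calls, arm_table = arm_table,
    overlaps = overlaps, recovery = recovery,
    reference = reference, truth = truth
  ), class = "study_report")
}

study_overlaps <- function(calls, design, arm_names, background_size) {
  rows <- list()
  if (length(arm_names) >= 2) {
    pairs <- combn(arm_names, 2)
    for (tok in design$criteria) {
      for (j in seq_len(ncol(pairs))) {
        a <- pairs[1, j]; b <- pairs[2, j]
        ga <- calls[[a]][[tok]]; gb <- calls[[b]][[tok]]
        row <- data.frame(criterion = tok, arm_a = a, arm_b = b,
                          n_a = NA_integer_, n_b = NA_integer_,
                          n_intersection = NA_integer_,
                          percent_overlap = NA_real_,
                          fold_enrichment = NA_real_,
                          log10_hypergeometric_p = NA_real_,
                          stringsAsFactors = FALSE)
        if (!is.null(ga) && !is.null(gb) && length(ga) && length(gb)) {
          ov <- pairwise_overlap(gene_set(ga, a), gene_set(gb, b),
                                 background_size = background_size)
          row$n_a <- ov$n_a; row$n_b <- ov$n_b
          row$n_intersection <- ov$n_intersection
          row$percent_overlap <- ov$percent_overlap
          row$fold_enrichment <- ov$fold_enrichment
          row$log10_hypergeometric_p <- ov$log10_hypergeometric_p
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

study_recovery <- function(calls, design, arm_names, reference) {
  rows <- list()
  for (an in arm_names) {
    for (tok in design$criteria) {
      g <- calls[[an]][[tok]]
      for (ref_name in names(reference)) {
        ref <- reference[[ref_name]]
        k <- if (is.null(g)) NA_integer_ else length(intersect(g, ref))
        rows[[length(rows) + 1L]] <- data.frame(
          arm = an, criterion = tok, reference = ref_name,
          n_called = if (is.null(g)) NA_integer_ else length(g),
          n_reference = length(ref),
          n_intersection = k,
          identification = if (is.null(g) || length(ref) == 0) NA_real_
                           else 100 * k / length(ref),
          accuracy = if (is.null(g) || length(g) == 0) NA_real_
                     else 100 * k / length(g),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("study_report (seed %d, pooldeg %s)\n", x$seed,
              x$package_version))
  cat(sprintf("  arms: %s\n",
              paste(vapply(x$design$arms, `[[`, character(1), "name"),
                    collapse = ", ")))
  cat(sprintf("  criteria: %s\n", paste(x$design$criteria, collapse = ", ")))
  cat(sprintf("  reference sets: truth (%d genes), fdr_intersection (%d genes)\n",
              length(x$reference$truth), length(x$reference$fdr_intersection)))
  cat("  recovery vs fdr_intersection:\n")
  r <- x$recovery[x$recovery$reference == "fdr_intersection", ]
  for (i in seq_len(nrow(r)))
    cat(sprintf("    %-8s %-18s identification %5.1f%%  accuracy %5.1f%%\n",
                r$arm[i], r$criterion[i], r$identification[i], r$accuracy[i]))
  invisible(x)
}

#' Write a study report to a directory
#'
#' Emits the machine-readable report as JSON plus tab-separated summary
#' tables (`arm_table.tsv`, `overlaps.tsv`, `recovery.tsv`), the truth
#' table, and one plain-text called-gene list per arm and criterion under
#' `calls/`. Every percentage in the tables is recomputable from the counts
#' stored beside it. Output is byte-identical for identical inputs.
#'
#' @param report a [run_simulation_study()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "calls"), showWarnings = FALSE)
  paths <- character(0)

  json_path <- file.path(dir, "report.json")
  payload <- list(
    seed = report$seed,
    package_version = report$package_version,
    config = unclass(report$config),
    criteria = report$design$criteria,
    arms = lapply(report$design$arms, unclass),
    reference_sizes = lapply(report$reference, length),
    arm_table = report$arm_table,
    overlaps = report$overlaps,
    recovery = report$recovery
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  paths <- c(paths, json_path)

  for (nm in c("arm_table", "overlaps", "recovery")) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    if (!is.null(report[[nm]])) {
      write.table(report[[nm]], p, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  p <- file.path(dir, "truth.tsv")
  write_truth_table(report$truth, p)
  paths <- c(paths, p)

  for (an in names(report$calls)) {
    for (tok in names(report$calls[[an]])) {
      g <- report$calls[[an]][[tok]]
      if (is.null(g)) next
      fn <- sprintf("%s__%s.txt", an, gsub("[^A-Za-z0-9.]+", "_", tok))
      p <- file.path(dir, "calls", fn)
      writeLines(g, p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Compare user-supplied gene lists
#'
#' Reads two or more plain-text gene lists (one identifier per line),
#' optionally maps them through a two-column identifier table first
#' ([harmonize_ids()]), and computes all pairwise overlaps plus — for up to
#' four lists — the multiway Venn partition.
#'
#' @param paths character vector of at least two list files.
#' @param mapping optional mapping table (a data.frame or a path readable by
#'   [read_id_mapping()]).
#' @param background_size optional gene-universe size; enables fold
#'   enrichment and hypergeometric significance on the pairwise overlaps.
#' @param namespace namespace tag assigned to the (possibly mapped) lists.
#' @return list with `sets`, `pairwise` (list of `overlap_result`),
#'   `pairwise_table` (one row per pair), `multiway` (a
#'   [multiway_overlap()] or `NULL` for more than four lists), and
#'   `unmapped` (per input list, ids dropped by the mapping).
#' @export
compare_gene_lists <- function(paths, mapping = NULL, background_size = NULL,
                               namespace = "generic") {
  if (length(paths) < 2) stop_("need at least two gene-list files")
  sets <- lapply(paths, read_gene_list, namespace = namespace)
  unmapped <- setNames(vector("list", length(sets)),
                       vapply(sets, `[[`, character(1), "label"))
  if (!is.null(mapping)) {
    if (is.character(mapping)) mapping <- read_id_mapping(mapping)
    for (i in seq_along(sets)) {
      h <- harmonize_ids(sets[[i]], mapping, namespace = namespace)
      unmapped[[i]] <- h$unmapped
      sets[[i]] <- h$set
      if (length(sets[[i]]$ids) == 0)
        stop_("list '%s' has no identifiers left after mapping",
              sets[[i]]$label)
    }
  }
  pairs <- combn(seq_along(sets), 2)
  pairwise <- lapply(seq_len(ncol(pairs)), function(j)
    pairwise_overlap(sets[[pairs[1, j]]], sets[[pairs[2, j]]],
                     background_size = background_size))
  pairwise_table <- do.call(rbind, lapply(pairwise, as.data.frame))
  list(sets = sets,
       pairwise = pairwise,
       pairwise_table = pairwise_table,
       multiway = if (length(sets) <= 4) multiway_overlap(sets) else NULL,
       unmapped = unmapped)
}
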
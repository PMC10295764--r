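small_config <- function(seed = 42, ...) {
  simulation_config(n_genes = 600, library_size = 200000,
                    pooled_library_size = 200000, seed = seed, ...)
}

small_design <- function() {
  study_design(
    arms = list(study_arm("ind6", 6, 6), study_arm("ind3", 3, 3),
                study_arm("pooled6", 6, 6, pool_mut = TRUE)),
    criteria = c("ratio:2", "ratio:1.5", "stdev:2", "ratio+stdev:1.5,2",
                 "fdr:0.05")
  )
}

test_that("study reports are byte-identical under a fixed master seed", {
  cfg <- small_config()
  dir_a <- withr::local_tempdir()
  dir_b <- withr::local_tempdir()
  write_study_report(run_simulation_study(cfg, small_design()), dir_a)
  write_study_report(run_simulation_study(cfg, small_design()), dir_b)
  for (f in c("report.json", "arm_table.tsv", "overlaps.tsv",
              "recovery.tsv", "truth.tsv")) {
    expect_identical(readLines(file.path(dir_a, f)),
                     readLines(file.path(dir_b, f)))
  }
})

test_that("arms are independent draws from one shared biology", {
  cfg <- small_config()
  rep <- run_simulation_study(cfg, small_design())
  # one truth table for the whole study
  expect_equal(nrow(rep$truth), cfg$n_genes)
  # distinct arms call overlapping but not identical gene sets
  a <- rep$calls$ind6[["ratio:1.5"]]
  b <- rep$calls$ind3[["ratio:1.5"]]
  expect_gt(length(intersect(a, b)), 0)
  expect_false(setequal(a, b))
})

test_that("a no-signal design yields an empty significance reference", {
  cfg <- small_config(seed = 7, frac_up = 0, frac_down = 0)
  rep <- run_simulation_study(cfg, small_design())
  expect_length(rep$reference$truth, 0)
  # BH under the global null nearly always rejects nothing; the
  # intersection across arms is empty or near-empty
  expect_lte(length(rep$reference$fdr_intersection), 2)
  rec <- rep$recovery
  expect_true(all(is.na(
    rec$identification[rec$reference == "truth"])))
})

test_that("the fdr criterion is marked inapplicable for the pooled arm", {
  rep <- run_simulation_study(small_config(), small_design())
  at <- rep$arm_table
  expect_false(at$applicable[at$arm == "pooled6" & at$criterion == "fdr:0.05"])
  expect_true(all(at$applicable[at$arm == "ind6"]))
  expect_null(rep$calls$pooled6[["fdr:0.05"]])
})

test_that("expectation-mode pooling makes the pooled CPM the mean replicate CPM", {
  # pooled from the same replicates an individual analysis would average:
  # linearity makes the pooled column the arithmetic mean of the replicates'
  # relative abundances, so ratio criteria see the same mean profile
  sim <- simulate_experiment(small_config(seed = 9))
  cm <- sim$counts
  mut_ids <- cm$samples$sample_id[cm$samples$genotype == "mut"]
  pooled <- pool_replicates(cm, mut_ids, 1e6, mode = "expectation")
  em <- normalize_cpm(cm)
  mean_cpm_mut <- rowMeans(em$values[, mut_ids])
  expect_equal(unname(pooled), unname(mean_cpm_mut))

  wt_ids <- cm$samples$sample_id[cm$samples$genotype == "wt"]
  wt_only <- count_matrix(cm$counts[, wt_ids], genotype = rep("wt", 6))
  cm_pooled <- add_sample(wt_only, pooled, "mut_pooled", "mut")
  gs_pooled <- group_summary(normalize_cpm(cm_pooled))
  gs_ind <- group_summary(em)
  expect_equal(gs_pooled$mean_mut, gs_ind$mean_mut)
  expect_setequal(called_genes(call_by_ratio(gs_pooled, 1.5)),
                  called_genes(call_by_ratio(gs_ind, 1.5)))
})

test_that("every reported percentage recomputes from its stored counts", {
  rep <- run_simulation_study(small_config(seed = 5), small_design())
  ov <- rep$overlaps[!is.na(rep$overlaps$n_intersection), ]
  expect_gt(nrow(ov), 0)
  expect_equal(ov$percent_overlap,
               100 * ov$n_intersection / pmin(ov$n_a, ov$n_b))
  rec <- rep$recovery[!is.na(rep$recovery$n_called), ]
  has_ref <- rec$n_reference > 0
  expect_equal(rec$identification[has_ref],
               100 * rec$n_intersection[has_ref] / rec$n_reference[has_ref])
  has_calls <- rec$n_called > 0
  expect_equal(rec$accuracy[has_calls],
               100 * rec$n_intersection[has_calls] / rec$n_called[has_calls])
  # overlaps are consistent with the stored call lists
  i <- which(!is.na(rep$overlaps$n_intersection))[1]
  row <- rep$overlaps[i, ]
  expect_equal(row$n_intersection,
               length(intersect(rep$calls[[row$arm_a]][[row$criterion]],
                                rep$calls[[row$arm_b]][[row$criterion]])))
})

test_that("written study reports expose calls as plain-text gene lists", {
  rep <- run_simulation_study(small_config(seed = 6), small_design())
  dir <- withr::local_tempdir()
  write_study_report(rep, dir)
  listed <- readLines(file.path(dir, "calls", "ind6__ratio_1.5.txt"))
  expect_setequal(listed, rep$calls$ind6[["ratio:1.5"]])
  expect_true(file.exists(file.path(dir, "report.json")))
  parsed <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(parsed$seed, rep$seed)
})

test_that("compare_gene_lists reproduces planted overlaps and mappings", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a.txt"); f2 <- file.path(dir, "b.txt")
  writeLines(c("g1", "g2", "g3"), f1)
  writeLines(c("g1", "g2", "g3"), f2)
  res <- compare_gene_lists(c(f1, f2))
  expect_equal(res$pairwise[[1]]$percent_overlap, 100)

  # four lists with a planted Venn partition over a 40-id universe
  set.seed(33)
  universe <- sprintf("id%02d", 1:40)
  sets <- lapply(1:4, function(i) sample(universe, 15))
  paths <- vapply(1:4, function(i) {
    p <- file.path(dir, sprintf("l%d.txt", i)); writeLines(sets[[i]], p); p
  }, character(1))
  res4 <- compare_gene_lists(paths)
  oracle <- table(vapply(unique(unlist(sets)), function(id)
    paste(as.integer(vapply(sets, function(s) id %in% s, logical(1))),
          collapse = ""), character(1)))
  for (p in names(oracle))
    expect_equal(res4$multiway$counts[[p]], as.integer(oracle[[p]]))

  # a mapping that drops one id reports it as unmapped
  mp <- file.path(dir, "map.tsv")
  writeLines(c("old_id\tnew_id", "g1\tN1", "g2\tN2"), mp)
  res_m <- compare_gene_lists(c(f1, f2), mapping = mp)
  expect_setequal(res_m$unmapped$a, "g3")
  expect_setequal(res_m$sets[[1]]$ids, c("N1", "N2"))

  expect_error(compare_gene_lists(f1), "at least two")
})

test_that("the command-line wrapper round-trips compare and call", {
  cli <- system.file("cli", "pooldeg.R", package = "pooldeg")
  expect_true(nzchar(cli))
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a.txt"); f2 <- file.path(dir, "b.txt")
  writeLines(sprintf("g%d", 1:10), f1)
  writeLines(sprintf("g%d", 6:20), f2)
  out <- file.path(dir, "cmp")
  status <- system2("Rscript", c(cli, "compare", "--lists",
                                 paste(f1, f2, sep = ","),
                                 "--out-dir", out),
                    stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(out, "compare.json")))
  tab <- read.delim(file.path(out, "pairwise.tsv"))
  expect_equal(tab$n_intersection, 5)
  expect_equal(tab$percent_overlap, 50)

  gs <- make_summary(c(10, 10), c(16, 12), c(2, 2))
  sp <- file.path(dir, "summary.tsv")
  write_group_summary(gs, sp)
  prefix <- file.path(dir, "calls")
  system2("Rscript", c(cli, "call", "--criterion", "ratio:1.5",
                       "--summary", sp, "--out-prefix", prefix),
          stdout = TRUE, stderr = TRUE)
  expect_equal(readLines(paste0(prefix, "_genes.txt")),
               called_genes(call_by_ratio(gs, 1.5)))

  bad <- suppressWarnings(
    system2("Rscript", c(cli, "call", "--criterion", "bogus:1"),
            stdout = TRUE, stderr = TRUE))
  expect_false(is.null(attr(bad, "status")))
})
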
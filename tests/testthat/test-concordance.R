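test_that("percent overlap uses the smallest-set denominator", {
  # intersection 735, unique 685 and 776: 100 * 735 / 1420 = 51.76 -> 52%
  universe <- sprintf("WBGene%05d", seq_len(4000))
  shared <- universe[1:735]
  a <- gene_set(c(shared, universe[1000 + 1:685]), "exp1", "WormBase")
  b <- gene_set(c(shared, universe[2000 + 1:776]), "exp2", "WormBase")
  ov <- pairwise_overlap(a, b)
  expect_equal(ov$n_intersection, 735)
  expect_equal(ov$n_only_a, 685)
  expect_equal(ov$n_only_b, 776)
  expect_equal(ov$percent_overlap, 100 * 735 / 1420)
  expect_equal(round(ov$percent_overlap, 1), 51.8)
  expect_equal(ov$percent_overlap_rounded, 52)
})

test_that("overlap of a set with itself and of disjoint sets", {
  a <- gene_set(letters[1:6], "A")
  ov <- pairwise_overlap(a, a)
  expect_equal(ov$percent_overlap, 100)
  expect_equal(ov$n_only_a, 0)
  expect_equal(ov$n_only_b, 0)
  b <- gene_set(LETTERS[1:4], "B")
  expect_equal(pairwise_overlap(a, b)$percent_overlap, 0)
})

test_that("overlap statistics are symmetric in the two sets", {
  set.seed(27)
  universe <- as.character(1:300)
  a <- random_gene_set(universe, 60, "A")
  b <- random_gene_set(universe, 90, "B")
  ab <- pairwise_overlap(a, b, background_size = 300)
  ba <- pairwise_overlap(b, a, background_size = 300)
  expect_equal(ab$n_intersection, ba$n_intersection)
  expect_equal(ab$percent_overlap, ba$percent_overlap)
  expect_equal(ab$fold_enrichment, ba$fold_enrichment)
  expect_equal(ab$hypergeometric_p, ba$hypergeometric_p)
})

test_that("full percent overlap means the smaller set is contained", {
  set.seed(28)
  universe <- as.character(1:100)
  for (i in 1:20) {
    a <- random_gene_set(universe, sample(3:30, 1), "A")
    b <- random_gene_set(universe, sample(3:30, 1), "B")
    ov <- pairwise_overlap(a, b)
    smaller <- if (length(a$ids) <= length(b$ids)) a else b
    larger <- if (length(a$ids) <= length(b$ids)) b else a
    expect_equal(ov$percent_overlap == 100,
                 all(smaller$ids %in% larger$ids))
  }
})

test_that("sets from different namespaces refuse to be compared", {
  a <- gene_set("x", "A", namespace = "WormBase")
  b <- gene_set("x", "B", namespace = "Ensembl")
  expect_error(pairwise_overlap(a, b), "harmonize")
  expect_error(pairwise_overlap(a, gene_set(character(0), "E")), "empty")
})

test_that("fold enrichment matches its closed form", {
  universe <- as.character(1:100)
  a <- gene_set(universe[1:10], "A")
  b <- gene_set(universe[6:15], "B")  # intersection 5
  res <- fold_enrichment(a, b, background_size = 100)
  expect_equal(res$expected_intersection, 1.0)
  expect_equal(res$fold_enrichment, 5.0)
  # an intersection exactly at its expectation has enrichment 1
  a2 <- gene_set(universe[1:20], "A2")
  b2 <- gene_set(universe[c(1:4, 21:36)], "B2")  # 20*20/100 = 4 = observed
  expect_equal(fold_enrichment(a2, b2, background_size = 100)$fold_enrichment,
               1.0)
  expect_error(fold_enrichment(a, b, background_size = 10), "smaller")
})

test_that("hypergeometric tails match exhaustive draw enumeration", {
  # all C(20, 5) = 15504 ways of drawing 5 from a background of 20 that
  # contains the 8 ids of the other set
  universe <- as.character(1:20)
  b_ids <- universe[1:8]
  draws <- combn(20, 5)
  k_obs <- 4
  tail_count <- sum(apply(draws, 2, function(d)
    sum(universe[d] %in% b_ids) >= k_obs))
  enum_p <- tail_count / ncol(draws)
  a <- gene_set(c(b_ids[1:4], universe[9]), "A")
  b <- gene_set(b_ids, "B")
  res <- fold_enrichment(a, b, background_size = 20)
  expect_equal(res$n_intersection, 4)
  expect_equal(res$hypergeometric_p, enum_p, tolerance = 1e-12)
  expect_equal(res$log10_hypergeometric_p, log10(enum_p), tolerance = 1e-9)
})

test_that("underflowing tails are reported on the log10 scale", {
  universe <- sprintf("u%d", 1:20000)
  a <- gene_set(universe[1:1400], "A")
  b <- gene_set(universe[1:1500], "B")
  res <- fold_enrichment(a, b, background_size = 20000)
  expect_equal(res$hypergeometric_p, 0)  # double underflow
  expect_true(is.finite(res$log10_hypergeometric_p))
  expect_lt(res$log10_hypergeometric_p, -1000)
})

test_that("identification percentage is the recall of the reference", {
  universe <- sprintf("WBGene%05d", seq_len(2000))
  reference <- gene_set(universe[1:735], "reference")
  candidate <- gene_set(c(universe[1:701], universe[1500 + 1:50]), "pooled")
  id_pct <- identification_fraction(candidate, reference)
  expect_equal(round(id_pct, 1), 95.4)
  expect_equal(round_half_up(id_pct), 95)
  expect_equal(identification_fraction(reference, reference), 100)
  disjoint <- gene_set(universe[1000 + 1:10], "none")
  expect_equal(identification_fraction(disjoint, reference), 0)
  expect_error(identification_fraction(candidate, gene_set(character(0))),
               "empty")
})

test_that("accuracy percentage is the precision of the candidate", {
  universe <- as.character(1:100)
  reference <- gene_set(universe[1:40], "ref")
  inside <- gene_set(universe[5:14], "sub")
  expect_equal(accuracy_fraction(inside, reference), 100)
  mixed <- gene_set(c(universe[1:7], universe[50 + 1:13]), "mixed")  # 7 of 20
  expect_equal(accuracy_fraction(mixed, reference), 35)
  set.seed(29)
  for (i in 1:10) {
    cand <- random_gene_set(universe, sample(5:30, 1), "C")
    brute <- 100 * sum(vapply(cand$ids, function(id)
      id %in% reference$ids, logical(1))) / length(cand$ids)
    expect_equal(accuracy_fraction(cand, reference), brute)
  }
})

test_that("identification and accuracy are the same count over two denominators", {
  set.seed(30)
  universe <- as.character(1:200)
  x <- random_gene_set(universe, 40, "x")
  r <- random_gene_set(universe, 60, "r")
  k <- length(intersect(x$ids, r$ids))
  expect_equal(identification_fraction(x, r), 100 * k / 60)
  expect_equal(accuracy_fraction(x, r), 100 * k / 40)
  expect_equal(accuracy_fraction(x, r), identification_fraction(r, x))
  # recall plus missed fraction is 100
  expect_equal(identification_fraction(x, r) +
                 100 * length(setdiff(r$ids, x$ids)) / length(r$ids), 100)
})

test_that("multiway partitions cover degenerate and random cases", {
  s1 <- gene_set(as.character(1:3), "S1")
  s2 <- gene_set(as.character(4:6), "S2")
  s3 <- gene_set(as.character(7:9), "S3")
  disjoint <- multiway_overlap(list(s1, s2, s3))
  expect_setequal(names(disjoint$counts), c("100", "010", "001"))
  expect_true(all(disjoint$counts == 3))

  same <- multiway_overlap(list(s1, s1, s1))
  expect_equal(names(same$counts), "111")
  expect_equal(unname(same$counts), 3L)

  set.seed(31)
  universe <- sprintf("id%03d", 1:200)
  sets <- lapply(1:4, function(i) random_gene_set(universe, 50, paste0("S", i)))
  mw <- multiway_overlap(sets)
  # per-element enumeration oracle
  union_ids <- unique(unlist(lapply(sets, `[[`, "ids")))
  oracle <- table(vapply(union_ids, function(id)
    paste(as.integer(vapply(sets, function(s) id %in% s$ids, logical(1))),
          collapse = ""), character(1)))
  expect_equal(sum(mw$counts), length(union_ids))
  for (p in names(oracle))
    expect_equal(mw$counts[[p]], as.integer(oracle[[p]]))
  # margins reconstruct each input set exactly
  for (i in 1:4) {
    member <- vapply(names(mw$counts), function(p)
      substr(p, i, i) == "1", logical(1))
    expect_equal(sum(mw$counts[member]), 50)
  }
  expect_error(multiway_overlap(list(s1)), "2 to 4")
})

test_that("identifier harmonisation maps, deduplicates, and reports drops", {
  s <- gene_set(c("a", "b", "c", "d", "e"), "S", namespace = "old")
  ident <- data.frame(old_id = c("a", "b", "c", "d", "e"),
                      new_id = c("a", "b", "c", "d", "e"))
  h <- harmonize_ids(s, ident, namespace = "old")
  expect_setequal(h$set$ids, s$ids)
  expect_length(h$unmapped, 0)

  merge2 <- data.frame(old_id = c("a", "b", "c", "d", "e"),
                       new_id = c("N1", "N1", "N2", "N3", "N4"))
  h2 <- harmonize_ids(s, merge2)
  expect_length(h2$set$ids, 4)  # a and b collapse

  partial <- data.frame(old_id = c("a", "b", "c"),
                        new_id = c("N1", "N2", "N3"))
  h3 <- harmonize_ids(s, partial)
  expect_setequal(h3$set$ids, c("N1", "N2", "N3"))
  expect_setequal(h3$unmapped, c("d", "e"))

  conflict <- data.frame(old_id = c("a", "a"), new_id = c("N1", "N2"))
  expect_error(harmonize_ids(s, conflict), "conflicting")
  benign_dup <- data.frame(old_id = c("a", "a"), new_id = c("N1", "N1"))
  expect_silent(harmonize_ids(s, benign_dup))
})

test_that("gene lists round-trip through plain text", {
  s <- gene_set(c("WBGene1", "WBGene2"), "calls", "WormBase")
  path <- withr::local_tempfile(fileext = ".txt")
  write_gene_list(s, path)
  s2 <- read_gene_list(path, namespace = "WormBase")
  expect_equal(s2$ids, s$ids)
  expect_error(read_gene_list(withr::local_tempfile()), "cannot read")
})
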
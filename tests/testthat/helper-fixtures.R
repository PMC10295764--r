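# Shared fixture builders. Everything is generated in code; no data files.

# A small count matrix with explicit values.
make_cm <- function(counts, genotype, pooled = rep(FALSE, ncol(counts)),
                    gene_ids = sprintf("g%d", seq_len(nrow(counts))),
                    sample_ids = sprintf("s%d", seq_len(ncol(counts)))) {
  m <- as.matrix(counts)
  dimnames(m) <- list(gene_ids, sample_ids)
  count_matrix(m, genotype = genotype, pooled = pooled)
}

# A group_summary data.frame built directly from per-gene numbers.
make_summary <- function(mean_wt, mean_mut, sd_wt,
                         n_wt = 6L, n_mut = 6L,
                         gene_id = sprintf("g%d", seq_along(mean_wt))) {
  res <- data.frame(gene_id = gene_id, mean_wt = mean_wt,
                    mean_mut = mean_mut, sd_wt = sd_wt,
                    n_wt = n_wt, n_mut = n_mut, stringsAsFactors = FALSE)
  class(res) <- c("group_summary", "data.frame")
  res
}

# A randomized group_summary with a realistic spread of means and sds,
# including occasional exact zeros to exercise the degenerate conventions.
random_summary <- function(n = 200) {
  mean_wt <- rlnorm(n, 3, 1.5)
  mean_mut <- mean_wt * rlnorm(n, 0, 0.8)
  sd_wt <- mean_wt * rgamma(n, shape = 2, rate = 10)
  zero <- sample.int(n, max(1, n %/% 20))
  mean_wt[zero] <- 0
  sd_wt[sample.int(n, max(1, n %/% 20))] <- 0
  make_summary(mean_wt, mean_mut, sd_wt)
}

# Random gene sets over a shared universe.
random_gene_set <- function(universe, size, label) {
  gene_set(sample(universe, size), label = label)
}

# Hypergeometric upper tail by the closed-form sum of the counting measure:
# P(X >= k) = sum_i C(K, i) C(N - K, n - i) / C(N, n). Independent of phyper.
hyper_tail_oracle <- function(k, n_draw, n_success, N) {
  i <- k:min(n_draw, n_success)
  if (length(i) == 0 || k > min(n_draw, n_success)) return(0)
  sum(choose(n_success, i) * choose(N - n_success, n_draw - i)) /
    choose(N, n_draw)
}
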
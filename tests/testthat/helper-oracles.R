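# Independent brute-force oracles. These deliberately use the naive
# quadratic / enumerative route so they share no code with the package.

# All-pairs 5' overlap histogram: double loop over plus x minus reads.
brute_overlap_histogram <- function(reads, te_id, max_overlap = 26) {
  sub <- reads[reads$consensus == te_id, , drop = FALSE]
  p5 <- sub$five_prime[sub$strand == "+"]
  m5 <- sub$five_prime[sub$strand == "-"]
  counts <- numeric(max_overlap)
  for (p in p5) for (m in m5) {
    o <- m - p + 1
    if (o >= 1 && o <= max_overlap) counts[o] <- counts[o] + 1
  }
  counts
}

# Per-read secondary status by scanning all opposite-strand partners.
brute_secondary_count <- function(reads, te_id) {
  sub <- reads[reads$consensus == te_id, , drop = FALSE]
  n <- 0
  for (i in seq_len(nrow(sub))) {
    partners <- sub[sub$strand != sub$strand[i], , drop = FALSE]
    o <- if (sub$strand[i] == "+") partners$five_prime - sub$five_prime[i] + 1
         else sub$five_prime[i] - partners$five_prime + 1
    if (any(o == 10)) n <- n + 1
  }
  n
}

# Per-position coverage recount.
brute_coverage <- function(reads, consensus_length, te_id, strand) {
  sub <- reads[reads$consensus == te_id & reads$strand == strand, , drop = FALSE]
  v <- numeric(consensus_length)
  for (pos in seq_len(consensus_length)) {
    v[pos] <- sum(sub$start < pos & sub$end >= pos)  # pos is 1-based
  }
  v
}

# NB log-likelihood for one group at mean mu (size factors all 1 here).
nb_loglik <- function(y, mu, alpha) {
  sum(dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
}

# Likelihood-ratio p for a two-group NB comparison by direct grid
# maximization of the NB likelihood over log-means.
brute_nb_lrt <- function(y_a, y_b, alpha, grid_n = 4000) {
  grid <- exp(seq(log(0.05), log(max(c(y_a, y_b, 1)) * 5), length.out = grid_n))
  ll_a <- max(vapply(grid, function(m) nb_loglik(y_a, m, alpha), 0))
  ll_b <- max(vapply(grid, function(m) nb_loglik(y_b, m, alpha), 0))
  ll_0 <- max(vapply(grid, function(m) nb_loglik(c(y_a, y_b), m, alpha), 0))
  stat <- 2 * (ll_a + ll_b - ll_0)
  pchisq(max(stat, 0), df = 1, lower.tail = FALSE)
}

# Tiny random count_matrix for round-trip properties.
random_count_matrix <- function(n_feat, conditions = c("a", "a", "b", "b")) {
  mat <- matrix(rpois(n_feat * length(conditions), 50),
                nrow = n_feat,
                dimnames = list(sprintf("f%03d", seq_len(n_feat)),
                                sprintf("s%d", seq_along(conditions))))
  count_matrix(mat, setNames(conditions, colnames(mat)))
}

# Hand-built read sets for overlap/coverage checks.
mk_reads <- function(starts, lengths, strands, consensus = "TE1") {
  smallrna_reads(data.frame(consensus = rep_len(consensus, length(starts)),
                            start = starts,
                            end = starts + lengths,
                            read_id = sprintf("r%d", seq_along(starts)),
                            length = lengths, strand = strands,
                            stringsAsFactors = FALSE))
}

# Minimal DE-result row constructor for exercising the inheritance rules
# without running the NB machinery.
de_row <- function(feature, mean_a, mean_b, significant,
                   low_expressed = FALSE) {
  ratio <- (mean_b + 0.5) / (mean_a + 0.5)
  data.frame(feature = feature, mean_a = mean_a, mean_b = mean_b,
             fold_change = pmax(ratio, 1 / ratio), log2fc = log2(ratio),
             pvalue = ifelse(significant, 1e-6, 0.5),
             fdr = ifelse(significant, 1e-5, 0.5),
             low_expressed = low_expressed, significant = significant,
             stringsAsFactors = FALSE)
}
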
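# Shared fixtures and independent oracles for the test suite.

# brute-force decomposition oracle: direct sums over all 4^k types,
# independent of decompose_cv's rowsum path
brute_decompose <- function(counts, k) {
  labels <- eqlen::kmer_labels(k)
  m_of <- vapply(strsplit(labels, ""), function(ch) {
    sum(ch %in% c("A", "T"))
  }, integer(1))
  W <- sum(counts)
  Nbar <- W / 4^k
  M2 <- sum((counts - Nbar)^2) / (4^k * Nbar^2)
  Mnf2 <- 0
  Mf2 <- 0
  for (m in 0:k) {
    idx <- which(m_of == m)
    Nbar_m <- mean(counts[idx])
    Mnf2 <- Mnf2 + length(idx) * (Nbar_m - Nbar)^2
    Mf2 <- Mf2 + sum((counts[idx] - Nbar_m)^2)
  }
  list(M2 = M2, Mnf2 = Mnf2 / (4^k * Nbar^2), Mf2 = Mf2 / (4^k * Nbar^2))
}

# brute-force large-L Mnf2 limit by enumerating words (k small)
brute_nf_limit <- function(p, k) {
  labels <- eqlen::kmer_labels(k)
  probs <- vapply(strsplit(labels, ""), function(ch) {
    n_at <- sum(ch %in% c("A", "T"))
    (p / 2)^n_at * ((1 - p) / 2)^(k - n_at)
  }, numeric(1))
  mean((probs * 4^k - 1)^2)
}

# small deterministic record with a known composition
toy_record <- function() eqlen::seq_record("toy", "AACCGGTTACGT")

letter_counts_test <- function(s) table(strsplit(s, "")[[1]])
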
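# Independent oracles and small fixture builders used across the suite.

# r2 from a 2x2 haplotype table (counts of AB, Ab, aB, ab), computed
# directly from the definition D^2 / (pA pa pB pb)
r2_from_counts <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  pA <- (n11 + n10) / n
  pB <- (n11 + n01) / n
  D <- n11 / n - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# build a two-site phased hap_sample realising a given haplotype table
sample_from_counts <- function(n11, n10, n01, n00,
                               map_m = c(0.001, 0.003)) {
  m <- rbind(
    matrix(rep(c(1L, 1L), n11), ncol = 2, byrow = TRUE),
    matrix(rep(c(1L, 0L), n10), ncol = 2, byrow = TRUE),
    matrix(rep(c(0L, 1L), n01), ncol = 2, byrow = TRUE),
    matrix(rep(c(0L, 0L), n00), ncol = 2, byrow = TRUE))
  hap_sample(m, c(100, 300), map_m)
}

# quick small neutral config for structural tests
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n = 60, sequence_length_bp = 2e5, mutation_rate = 2e-7,
         recomb_rate_cM_Mb = 2, model = "neutral", n_generations = 15,
         sample_size = 20, seed = 11),
    list(...))
  do.call(sim_config, args)
}
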
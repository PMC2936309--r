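# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# pure-ancestry study design: K populations, n_per pure individuals each
pure_ancestry <- function(K = 4L, n_per = 10L) {
  Q <- matrix(0, K * n_per, K)
  for (k in seq_len(K)) Q[(k - 1L) * n_per + seq_len(n_per), k] <- 1
  rownames(Q) <- sprintf("ind%02d", seq_len(nrow(Q)))
  true_ancestry(Q)
}

# the 40 x 195 four-population fixture used in recovery experiments
pure_fixture <- function(seed, K = 4L, L = 195L, divergence = 0.25,
                         n_per = 10L) {
  model <- sample_parental_frequencies(K, L, divergence, seed = seed)
  anc <- pure_ancestry(K, n_per)
  list(model = model, ancestry = anc,
       matrix = simulate_matrix(model, anc, seed = seed + 1L))
}

# brute-force egg-class/m distribution by enumerating all 2^n segregation
# patterns of an n-trivalent triploid (independent oracle for the binomial)
enumerate_m_distribution <- function(n) {
  counts <- integer(n + 1L)
  for (code in 0:(2^n - 1L)) {
    m <- sum(bitwAnd(code, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    counts[m + 1L] <- counts[m + 1L] + 1L
  }
  stats::setNames(counts / 2^n, 0:n)
}
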
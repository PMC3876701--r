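# Shared fixtures and independent reference implementations for the tests.

# {A(1) B(2) C(3) D(4)}: 4 unique, 10 total elements
toy_multiset <- function() {
  seq_multiset(c("A", "C", "G", "T"), 1:4)
}

# ramp library: n unique elements with copy numbers 1..n (5-mer DNA labels)
ramp_multiset <- function(n = 1000L) {
  stopifnot(n <= 1024L)
  combos <- do.call(paste0,
                    expand.grid(rep(list(c("A", "C", "G", "T")), 5),
                                stringsAsFactors = FALSE))
  seq_multiset(combos[seq_len(n)], seq_len(n))
}

# sparse dyadic multiset with copy numbers 1, 2, 4, ..., 64
dyadic_multiset <- function() {
  combos <- do.call(paste0,
                    expand.grid(rep(list(c("A", "C", "G", "T")), 5),
                                stringsAsFactors = FALSE))
  seq_multiset(combos[1:7], as.integer(2^(0:6)))
}

# Independent reference sampler: literal random array indexing over the
# expanded instance vector. Same law as the package's hypergeometric chain,
# via a completely different code path.
ref_sample_counts <- function(counts, size) {
  inst <- rep.int(seq_along(counts), counts)
  tabulate(sample(inst, size), nbins = length(counts))
}

# Hand-crafted confidence band fixture (for unit tests of detect_bias that
# need exact band values independent of any Monte-Carlo run).
make_band <- function(sequences, n_before, lower, upper, fraction,
                      iterations = 10000L, method = "minmax",
                      level = 0.999, seed = NULL) {
  structure(list(sequences = sequences, n_before = as.integer(n_before),
                 lower = as.integer(lower), upper = as.integer(upper),
                 fraction = fraction, iterations = iterations,
                 method = method, level = level, seed = seed),
            class = "confidence_band")
}

# Read-set fixture for filtering tests: a plain list with the fields
# filter_reads() consumes.
make_reads <- function(inserts, window_quals) {
  list(insert = inserts, window_quals = window_quals)
}

# Chi-square GOF against given cell probabilities, pooling low-expectation
# cells (in probability order) so every pooled cell has expectation >= 5.
pooled_chisq_p <- function(obs, probs, min_expected = 5) {
  n <- sum(obs)
  ord <- order(probs)
  obs <- obs[ord]; probs <- probs[ord]
  pooled_o <- numeric(0); pooled_p <- numeric(0)
  acc_o <- 0; acc_p <- 0
  for (i in seq_along(probs)) {
    acc_o <- acc_o + obs[i]; acc_p <- acc_p + probs[i]
    if (acc_p * n >= min_expected) {
      pooled_o <- c(pooled_o, acc_o); pooled_p <- c(pooled_p, acc_p)
      acc_o <- 0; acc_p <- 0
    }
  }
  if (acc_p > 0) {
    pooled_o[length(pooled_o)] <- pooled_o[length(pooled_o)] + acc_o
    pooled_p[length(pooled_p)] <- pooled_p[length(pooled_p)] + acc_p
  }
  suppressWarnings(
    stats::chisq.test(pooled_o, p = pooled_p, rescale.p = TRUE)$p.value)
}
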
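#' Stochastic sampling of a library multiset
#'
#' Draws `round(fraction * m)` element instances uniformly without
#' replacement from the `m` total instances of the multiset (the "random
#' array indexing" view of library sampling). The joint law of the resulting
#' count vector is multivariate hypergeometric. The draw conserves the total
#' (`sum(B) = round(f * m)`), never exceeds any input count, and never
#' creates sequences that were absent (`B_i <= n_i`, `B_i = 0` where
#' `n_i = 0`); these invariants are asserted on every call.
#'
#' @param ms a [seq_multiset()].
#' @param fraction sampling fraction f in `[0, 1]`.
#' @param seed optional integer seed (`set.seed()` is called when supplied);
#'   the same seed reproduces the same draw.
#' @return a [seq_multiset()] over the same sequences (zero counts kept, so
#'   element order is preserved).
#' @export
sample_multiset <- function(ms, fraction, seed = NULL) {
  stopifnot(inherits(ms, "seq_multiset"))
  if (length(fraction) != 1L || is.na(fraction) || fraction < 0 ||
      fraction > 1)
    stop("`fraction` must be a single number in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  m <- sum_total(ms)
  size <- as.integer(round(fraction * m))
  drawn <- cpp_sample_counts(ms$counts, size)
  stopifnot(sum(as.numeric(drawn)) == size, all(drawn <= ms$counts),
            all(drawn >= 0L))
  seq_multiset(ms$sequences, drawn, alphabet = ms$alphabet,
               theoretical_diversity = ms$theoretical_diversity)
}

#' Matrix of repeated sampling draws
#'
#' Stacks `k` independent [sample_multiset()] draws as a `k x N` integer
#' matrix. Intended for small problems (diagnostics, goodness-of-fit
#' checks); the band summaries used for confidence intervals avoid storing
#' the draws.
#'
#' @inheritParams sample_multiset
#' @param k number of draws.
#' @param max_cells guard on `k * length(ms)`.
#' @return integer matrix, draws in rows, sequences in columns.
#' @export
sample_matrix <- function(ms, fraction, k, seed = NULL, max_cells = 5e7) {
  stopifnot(inherits(ms, "seq_multiset"), k >= 1L)
  if (as.numeric(k) * length(ms) > max_cells)
    stop("k * N exceeds `max_cells`; use confidence_interval() summaries")
  if (!is.null(seed)) set.seed(seed)
  size <- as.integer(round(fraction * sum_total(ms)))
  out <- cpp_sample_matrix(ms$counts, size, as.integer(k))
  colnames(out) <- ms$sequences
  out
}

#' Exact outcome distribution of sampling a small multiset
#'
#' Enumerates every achievable outcome of sampling: all integer vectors `B`
#' with `0 <= B_i <= n_i` and `sum(B) = round(f * m)`, each with its
#' multivariate hypergeometric probability
#' `prod(choose(n_i, B_i)) / choose(m, round(f * m))`. This is the
#' brute-force oracle against which the stochastic sampler is validated;
#' it is only feasible for small multisets (the guard rejects larger ones).
#'
#' @inheritParams sample_multiset
#' @param max_total refuse multisets with more than this many total
#'   elements (enumeration grows combinatorially).
#' @return an object of class `outcome_distribution`: list with `outcomes`
#'   (matrix, one outcome per row), `probabilities` (summing to 1 within
#'   1e-12), `size`, `fraction` and `sequences`.
#' @examples
#' toy <- seq_multiset(c("A", "C", "G", "T"), 1:4, alphabet = "dna")
#' od <- enumerate_outcomes(toy, 0.5)
#' nrow(od$outcomes)  # 22 achievable outcomes
#' @export
enumerate_outcomes <- function(ms, fraction, max_total = 30L) {
  stopifnot(inherits(ms, "seq_multiset"))
  m <- sum_total(ms)
  if (m > max_total)
    stop("multiset has ", m, " total elements (> max_total = ", max_total,
         "); enumeration is infeasible - use Monte-Carlo sampling instead")
  n <- ms$counts
  N <- length(n)
  size <- as.integer(round(fraction * m))
  suffix <- rev(cumsum(rev(as.numeric(n))))
  res <- vector("list", 0L)
  B <- integer(N)
  rec <- function(i, s) {
    if (i > N) {
      if (s == 0L) res[[length(res) + 1L]] <<- B
      return(invisible(NULL))
    }
    rest <- if (i < N) suffix[[i + 1L]] else 0
    lo <- max(0L, s - as.integer(rest))
    hi <- min(n[[i]], s)
    if (lo > hi) return(invisible(NULL))
    for (b in lo:hi) {
      B[[i]] <<- b
      rec(i + 1L, s - b)
    }
    invisible(NULL)
  }
  rec(1L, size)
  outcomes <- do.call(rbind, res)
  logp <- vapply(res, function(b)
    sum(lchoose(n, b)) - lchoose(m, size), numeric(1L))
  probabilities <- exp(logp)
  stopifnot(abs(sum(probabilities) - 1) < 1e-12)
  structure(list(sequences = ms$sequences, outcomes = outcomes,
                 probabilities = probabilities, size = size,
                 fraction = fraction),
            class = "outcome_distribution")
}

#' @export
print.outcome_distribution <- function(x, ...) {
  cat(sprintf(
    "outcome_distribution: %d achievable outcomes of drawing %d elements\n",
    nrow(x$outcomes), x$size))
  invisible(x)
}

#' Element-wise mean of repeated sampling draws
#'
#' Averages `k` independent draws. As `k` grows the mean converges to
#' `fraction * n`: repeated sampling "averages out" to a simple dilution of
#' the library.
#'
#' @inheritParams sample_matrix
#' @return numeric vector of per-sequence means, named by sequence.
#' @export
average_of_samples <- function(ms, fraction, k, seed = NULL) {
  stopifnot(inherits(ms, "seq_multiset"), k >= 1L)
  if (!is.null(seed)) set.seed(seed)
  size <- as.integer(round(fraction * sum_total(ms)))
  stats <- cpp_band_stats(ms$counts, size, as.integer(k))
  setNames(stats$sums / k, ms$sequences)
}

#' Empirical distribution of one element's sampled count
#'
#' Histogram over `0..n_i` of element `element`'s count across `k` draws.
#' For small multisets this converges (in total variation) to the exact
#' hypergeometric marginal as `k` grows.
#'
#' @inheritParams sample_matrix
#' @param element sequence name or integer index.
#' @return data.frame with columns `count` (0..n_i) and `frequency`
#'   (empirical probabilities summing to 1).
#' @export
count_distribution <- function(ms, fraction, k, element, seed = NULL) {
  stopifnot(inherits(ms, "seq_multiset"), k >= 1L)
  if (is.character(element)) element <- match(element, ms$sequences)
  if (is.na(element) || element < 1L || element > length(ms))
    stop("`element` not found in the multiset")
  if (!is.null(seed)) set.seed(seed)
  size <- as.integer(round(fraction * sum_total(ms)))
  stats <- cpp_band_stats(ms$counts, size, as.integer(k))
  off <- cumsum(c(0, ms$counts + 1))
  ni <- ms$counts[[element]]
  slice <- stats$tally[(off[[element]] + 1):(off[[element]] + ni + 1)]
  data.frame(count = 0:ni, frequency = slice / k)
}
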
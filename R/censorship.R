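#' Measured sampling fraction of a filtering step
#'
#' If quality filtering removed reads uniformly at random, the step would be
#' indistinguishable from stochastic sampling at fraction
#' `f = sum(after) / sum(before)`. This measured `f` parameterises the null
#' model against which sequence-specific censorship is detected.
#'
#' @param before library multiset before filtering.
#' @param after library multiset after filtering; its sequences must be a
#'   subset of `before`'s and no count may exceed the count before
#'   (filtering cannot create reads).
#' @return the fraction `f` in `[0, 1]`.
#' @export
measure_fraction <- function(before, after) {
  stopifnot(inherits(before, "seq_multiset"), inherits(after, "seq_multiset"))
  m <- sum_total(before)
  if (m == 0) stop("`before` is empty")
  aligned <- .align_counts(before, after)
  if (any(aligned > before$counts))
    stop("`after` has more copies than `before` for sequence ",
         before$sequences[aligned > before$counts][[1L]],
         "; filtering cannot create reads")
  sum(as.numeric(aligned)) / m
}

#' Detect sequence-specific censorship across a filtering step
#'
#' Compares each sequence's post-filtering count with the Monte-Carlo
#' confidence band of random sampling at the measured fraction. Sequences
#' whose counts fall below the band lost significantly more reads than
#' random chance explains; they are flagged `censored_below` and assigned a
#' multiplicative bias factor `B_i = after_i / (f * before_i)` (the diagonal
#' of the censorship operator). Sequences inside the band carry `B = 1`.
#' Sequences above the band are flagged for diagnostics but also keep
#' `B = 1`: the bias factor is defined only for the censored direction.
#' Sequences with fewer than `low_copy_threshold` copies before filtering
#' are too sparse for the band to discriminate sampling noise from bias and
#' are flagged `undetermined_low_copy` with `B = 1`.
#'
#' @inheritParams measure_fraction
#' @param band a [confidence_interval()] built from `before` at the measured
#'   fraction.
#' @param low_copy_threshold minimum pre-filtering copy number for a verdict
#'   (default 10).
#' @return an object of class `bias_vector`: list with `sequences`, `bias`,
#'   `flags` (factor with levels `within_band`, `censored_below`,
#'   `above_band`, `undetermined_low_copy`), `lower`, `upper`, `n_before`,
#'   `n_after`, `fraction`, `low_copy_threshold`.
#' @export
detect_bias <- function(before, after, band, low_copy_threshold = 10L) {
  stopifnot(inherits(band, "confidence_band"))
  if (!identical(band$sequences, before$sequences))
    stop("`band` is not aligned with `before`'s sequences")
  f <- measure_fraction(before, after)
  if (abs(f - band$fraction) > 1e-8)
    warning(sprintf(
      "band was built at f = %.6g but the measured fraction is %.6g",
      band$fraction, f))
  n_after <- .align_counts(before, after)
  n_before <- before$counts
  levels <- c("within_band", "censored_below", "above_band",
              "undetermined_low_copy")
  flags <- rep("within_band", length(n_before))
  bias <- rep(1, length(n_before))
  low <- n_before < low_copy_threshold
  flags[low] <- "undetermined_low_copy"
  below <- !low & n_after < band$lower
  flags[below] <- "censored_below"
  bias[below] <- n_after[below] / (f * n_before[below])
  above <- !low & n_after > band$upper
  flags[above] <- "above_band"
  structure(list(sequences = before$sequences, bias = bias,
                 flags = factor(flags, levels = levels),
                 lower = band$lower, upper = band$upper,
                 n_before = n_before, n_after = n_after,
                 fraction = f,
                 low_copy_threshold = as.integer(low_copy_threshold)),
            class = "bias_vector")
}

#' @export
print.bias_vector <- function(x, ...) {
  tab <- table(x$flags)
  cat(sprintf("bias_vector: %d sequences at f = %.4g\n",
              length(x$sequences), x$fraction))
  for (nm in names(tab)) cat(sprintf("  %-22s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Ranked table of censored sequences
#'
#' One row per `censored_below` sequence, strongest censorship (smallest
#' bias factor) first; ties broken by descending pre-filtering count, then
#' lexicographic sequence. DNA sequences whose length is divisible by 3 also
#' get their peptide translation.
#'
#' @param bias a [detect_bias()] result.
#' @param top_k optionally keep only the first `top_k` rows.
#' @return data.frame with columns `sequence`, `peptide`, `n_before`,
#'   `n_after`, `expected` (`f * n_before`), `loC`, `bias` and `fold_loss`
#'   (`1 / bias`).
#' @export
censored_table <- function(bias, top_k = NULL) {
  stopifnot(inherits(bias, "bias_vector"))
  idx <- which(bias$flags == "censored_below")
  ord <- idx[order(bias$bias[idx], -bias$n_before[idx],
                   bias$sequences[idx])]
  seqs <- bias$sequences[ord]
  peptide <- rep(NA_character_, length(ord))
  translatable <- grepl("^[ACGT]*$", seqs) & nchar(seqs) %% 3L == 0L &
    nzchar(seqs)
  peptide[translatable] <- vapply(seqs[translatable], translate_insert,
                                  character(1L), USE.NAMES = FALSE)
  out <- data.frame(
    sequence = seqs,
    peptide = peptide,
    n_before = bias$n_before[ord],
    n_after = bias$n_after[ord],
    expected = bias$fraction * bias$n_before[ord],
    loC = bias$lower[ord],
    bias = bias$bias[ord],
    fold_loss = 1 / bias$bias[ord],
    stringsAsFactors = FALSE
  )
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  rownames(out) <- NULL
  out
}

#' Write a censorship report as CSV
#'
#' @param tbl a [censored_table()] result.
#' @param path output file.
#' @param fraction measured sampling fraction (written as a comment).
#' @param seed seed used for the confidence band (written as a comment).
#' @return `path`, invisibly.
#' @export
write_cen_csv <- function(tbl, path, fraction = NA, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fraction: %.10g", fraction),
               sprintf("# seed: %s",
                       if (is.null(seed)) "NA" else format(seed))), con)
  write.table(tbl, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
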
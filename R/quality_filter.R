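#' Specification of a Phred-quality read filter
#'
#' Three filtering styles are supported, all evaluated over the 33-nt
#' analysis window only:
#' * `min_phred`: keep a read iff every position has `Q >= min_phred_cutoff`
#'   (the `^1n` / `^13n` / `^30n` family of libraries);
#' * `cumulative`: keep a read iff its cumulative accuracy
#'   ([read_accuracy()]) is at least `cumulative_cutoff`;
#' * `combined`: both conditions.
#'
#' @param style one of `"min_phred"`, `"cumulative"`, `"combined"`.
#' @param min_phred_cutoff integer Phred cutoff (styles `min_phred`,
#'   `combined`).
#' @param cumulative_cutoff probability in `[0, 1]` (styles `cumulative`,
#'   `combined`).
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(style = c("min_phred", "cumulative", "combined"),
                        min_phred_cutoff = NULL, cumulative_cutoff = NULL) {
  style <- match.arg(style)
  if (style %in% c("min_phred", "combined")) {
    if (is.null(min_phred_cutoff))
      stop("style '", style, "' requires `min_phred_cutoff`")
    min_phred_cutoff <- as.integer(min_phred_cutoff)
  }
  if (style %in% c("cumulative", "combined")) {
    if (is.null(cumulative_cutoff))
      stop("style '", style, "' requires `cumulative_cutoff`")
    if (cumulative_cutoff < 0 || cumulative_cutoff > 1)
      stop("`cumulative_cutoff` must be in [0, 1]")
  }
  structure(list(style = style, min_phred_cutoff = min_phred_cutoff,
                 cumulative_cutoff = cumulative_cutoff),
            class = "filter_spec")
}

#' Filter ingested reads by Phred quality
#'
#' Applies a [filter_spec()] to the accepted reads of an [ingest_fastq()]
#' result and tallies the surviving reads into a library multiset (the
#' `^c n` library for a min-Phred cutoff c). Filtering is monotone: raising
#' a cutoff can only remove reads, so `^30n` is an element-wise sub-multiset
#' of `^13n`, which is one of `^1n`; and it never creates sequences that
#' were absent before filtering.
#'
#' @param reads an `ingest_result` (or any list with `insert` and
#'   `window_quals` fields).
#' @param spec a [filter_spec()].
#' @return a [seq_multiset()] of surviving inserts.
#' @export
filter_reads <- function(reads, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  insert <- reads$insert
  wq <- reads$window_quals
  if (length(insert) != length(wq))
    stop("`reads` must carry one quality window per insert")
  keep <- rep(TRUE, length(insert))
  if (spec$style %in% c("min_phred", "combined")) {
    minq <- vapply(wq, function(q) min(q), integer(1L))
    keep <- keep & (minq >= spec$min_phred_cutoff)
  }
  if (spec$style %in% c("cumulative", "combined")) {
    acc <- vapply(wq, read_accuracy, numeric(1L))
    keep <- keep & (acc >= spec$cumulative_cutoff)
  }
  multiset_from_sequences(insert[keep])
}

#' Distribution of cumulative read accuracy
#'
#' Computes [read_accuracy()] for every accepted read and bins the values.
#' Bins are `[low, high)` except the last, which is closed.
#'
#' @param reads an `ingest_result` (or list with `window_quals`).
#' @param bin_edges increasing break points covering `[0, 1]`.
#' @return an object of class `accuracy_histogram`: list with `bin_low`,
#'   `bin_high`, `count` and `mean_accuracy`.
#' @export
accuracy_distribution <- function(reads, bin_edges = seq(0, 1, by = 0.05)) {
  wq <- reads$window_quals
  if (!length(wq)) stop("no reads to summarise")
  acc <- vapply(wq, read_accuracy, numeric(1L))
  nb <- length(bin_edges) - 1L
  idx <- findInterval(acc, bin_edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  structure(list(bin_low = bin_edges[-length(bin_edges)],
                 bin_high = bin_edges[-1L],
                 count = tabulate(idx, nbins = nb),
                 mean_accuracy = mean(acc)),
            class = "accuracy_histogram")
}

#' @export
print.accuracy_histogram <- function(x, ...) {
  cat(sprintf("accuracy_histogram: %d reads, mean accuracy %.4f\n",
              sum(x$count), x$mean_accuracy))
  invisible(x)
}

#' Write an accuracy histogram as CSV
#'
#' @param h an [accuracy_distribution()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_histogram_csv <- function(h, path) {
  stopifnot(inherits(h, "accuracy_histogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mean_accuracy: %.6g", h$mean_accuracy), con)
  writeLines("bin_low,bin_high,count", con)
  writeLines(sprintf("%g,%g,%d", h$bin_low, h$bin_high, h$count), con)
  invisible(path)
}
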
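#' Monte-Carlo confidence band for sampled copy numbers
#'
#' Repeatedly applies [sample_multiset()] at fraction `f` and records, per
#' sequence, either the minimum and maximum count seen over `k` iterations
#' (`method = "minmax"`, the default) or the empirical
#' `(1 - level)/2` and `1 - (1 - level)/2` quantiles
#' (`method = "quantile"`). The minmax band follows the common practice of
#' reporting the extremes of 5,000-10,000 iterations; its effective coverage
#' depends on `k`, which is why the explicit quantile method is also
#' offered.
#'
#' @inheritParams sample_multiset
#' @param k number of Monte-Carlo iterations (default 10,000).
#' @param method `"minmax"` or `"quantile"`.
#' @param level nominal coverage for the quantile method (recorded as
#'   metadata for minmax).
#' @return an object of class `confidence_band`: list with `sequences`,
#'   `n_before`, `lower`, `upper`, `fraction`, `iterations`, `method`,
#'   `level`, `seed`.
#' @export
confidence_interval <- function(ms, fraction, k = 10000L,
                                method = c("minmax", "quantile"),
                                level = 0.999, seed = NULL) {
  stopifnot(inherits(ms, "seq_multiset"), k >= 2L)
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  size <- as.integer(round(fraction * sum_total(ms)))
  stats <- cpp_band_stats(ms$counts, size, as.integer(k))
  if (method == "minmax") {
    lower <- stats$lower
    upper <- stats$upper
  } else {
    off <- cumsum(c(0, ms$counts + 1))
    lower <- integer(length(ms))
    upper <- integer(length(ms))
    a_lo <- k * (1 - level) / 2
    a_hi <- k * (1 - (1 - level) / 2)
    for (i in seq_along(ms$counts)) {
      ni <- ms$counts[[i]]
      cum <- cumsum(stats$tally[(off[[i]] + 1):(off[[i]] + ni + 1)])
      lower[[i]] <- which(cum >= a_lo)[[1L]] - 1L
      upper[[i]] <- which(cum >= a_hi)[[1L]] - 1L
    }
  }
  stopifnot(all(lower >= 0L), all(lower <= upper),
            all(upper <= ms$counts))
  structure(list(sequences = ms$sequences, n_before = ms$counts,
                 lower = lower, upper = upper, fraction = fraction,
                 iterations = as.integer(k), method = method,
                 level = level, seed = seed),
            class = "confidence_band")
}

#' @export
print.confidence_band <- function(x, ...) {
  cat(sprintf(
    "confidence_band (%s, level %.4g): %d sequences, f = %.4g, k = %d\n",
    x$method, x$level, length(x$sequences), x$fraction, x$iterations))
  invisible(x)
}

#' Test whether observed counts fall inside a confidence band
#'
#' @param band a [confidence_interval()] result.
#' @param observed a [seq_multiset()] over exactly the band's sequences, in
#'   the same order.
#' @return list with `inside` (per-sequence logical,
#'   `lower_i <= observed_i <= upper_i`) and `all` (single logical).
#' @export
band_contains <- function(band, observed) {
  stopifnot(inherits(band, "confidence_band"),
            inherits(observed, "seq_multiset"))
  if (!identical(band$sequences, observed$sequences))
    stop("`observed` is not aligned with the band's sequences")
  inside <- band$lower <= observed$counts & observed$counts <= band$upper
  list(inside = inside, all = all(inside))
}

#' Write a confidence band as CSV
#'
#' Columns: sequence, n_before, loC, hiC, with provenance (fraction,
#' iterations, method, level, seed) as `#` comment header lines.
#'
#' @param band a [confidence_interval()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_confidence_csv <- function(band, path) {
  stopifnot(inherits(band, "confidence_band"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# fraction: %.10g", band$fraction),
    sprintf("# iterations: %d", band$iterations),
    sprintf("# method: %s", band$method),
    sprintf("# level: %g", band$level),
    sprintf("# seed: %s",
            if (is.null(band$seed)) "NA" else format(band$seed))), con)
  writeLines("sequence,n_before,loC,hiC", con)
  writeLines(sprintf("%s,%d,%d,%d", band$sequences, band$n_before,
                     band$lower, band$upper), con)
  invisible(path)
}
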
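#' Specification of a synthetic phage-display sequencing experiment
#'
#' Defines a ground-truth library and read-level error model for validating
#' the analysis pipeline end to end. The generator emulates the salient
#' features of real amplicon runs: copy numbers spanning several orders of
#' magnitude, a constant adapter / GGGS-tail read architecture, per-position
#' Phred scores, a background rate of random low-quality positions (so that
#' quality filtering removes a roughly uniform share of reads), reads with
#' corrupted adapters, and planted sequence-specific censorship in which
#' low-quality positions recur at 3-4 fixed sites of the censored
#' sequence's 33-nt window.
#'
#' Under `min_phred` filtering at `censor_cutoff`, a censored sequence with
#' planted factor `B` loses the degraded fraction `1 - B` of its reads in
#' expectation (on top of background losses), so `B` is exactly the
#' survival ratio the censorship detector should recover.
#'
#' @param n_unique number of unbiased unique inserts.
#' @param copy_law `"log_uniform"` (counts log-uniform on
#'   `[min_count, max_count]`), `"ramp"` (counts `1..n_unique`), or
#'   `"explicit"` (use `counts`).
#' @param min_count,max_count bounds for `copy_law = "log_uniform"`.
#' @param counts explicit copy numbers for `copy_law = "explicit"`.
#' @param insert_length variable-insert length in nt (21 for 7-mers).
#' @param adapter an [adapter_config()].
#' @param base_quality Phred score of non-degraded positions.
#' @param n_censored number of additional censored sequences to plant.
#' @param censored_b_range range of planted bias factors `B`, drawn
#'   log-uniformly.
#' @param censored_count_range range of censored sequences' copy numbers,
#'   drawn log-uniformly.
#' @param background_fail_rate probability that any read, regardless of
#'   sequence, carries one random sub-cutoff position (default 0.1,
#'   mirroring a filtering step that removes ~10% of reads).
#' @param flawed_adapter_rate fraction of reads whose upstream adapter gets
#'   one mismatch.
#' @param censor_cutoff Phred cutoff that degraded positions fall below
#'   (degraded scores are drawn uniformly from `1..censor_cutoff-1`, so the
#'   reads still pass a min-Phred-1 filter).
#' @param seed integer RNG seed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_unique,
                           copy_law = c("log_uniform", "ramp", "explicit"),
                           min_count = 1, max_count = 10000,
                           counts = NULL,
                           insert_length = 21L,
                           adapter = adapter_config(),
                           base_quality = 35L,
                           n_censored = 0L,
                           censored_b_range = c(0.01, 0.2),
                           censored_count_range = c(100, 10000),
                           background_fail_rate = 0.1,
                           flawed_adapter_rate = 0,
                           censor_cutoff = 13L,
                           seed = NULL) {
  copy_law <- match.arg(copy_law)
  if (n_unique < 1L) stop("`n_unique` must be >= 1")
  if (copy_law == "log_uniform" && (min_count < 1 || max_count < min_count))
    stop("invalid `min_count` / `max_count` for log_uniform copy law")
  if (copy_law == "explicit" &&
      (is.null(counts) || length(counts) != n_unique))
    stop("`copy_law = \"explicit\"` requires `counts` of length `n_unique`")
  if (any(censored_b_range <= 0) || any(censored_b_range > 1))
    stop("planted B must lie in (0, 1]")
  if (insert_length %% 3L != 0L)
    stop("`insert_length` must be divisible by 3")
  structure(list(n_unique = as.integer(n_unique), copy_law = copy_law,
                 min_count = min_count, max_count = max_count,
                 counts = counts, insert_length = as.integer(insert_length),
                 adapter = adapter, base_quality = as.integer(base_quality),
                 n_censored = as.integer(n_censored),
                 censored_b_range = censored_b_range,
                 censored_count_range = censored_count_range,
                 background_fail_rate = background_fail_rate,
                 flawed_adapter_rate = flawed_adapter_rate,
                 censor_cutoff = as.integer(censor_cutoff),
                 seed = seed),
            class = "synthetic_spec")
}

.random_inserts <- function(n, L) {
  draw <- function(n) {
    m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE),
                nrow = n)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  out <- draw(n)
  while (anyDuplicated(out)) {
    dup <- which(duplicated(out))
    out[dup] <- draw(length(dup))
  }
  out
}

.log_uniform <- function(n, lo, hi) {
  pmax(round(exp(runif(n, log(lo), log(hi)))), ceiling(lo))
}

#' Generate a ground-truth synthetic library
#'
#' Draws `n_unique` collision-free random inserts with copy numbers from
#' the spec's copy-number law, plus `n_censored` censored sequences with
#' planted bias factors and fixed degradation sites. The planted truth is
#' returned alongside the multiset.
#'
#' @param spec a [synthetic_spec()].
#' @return an object of class `synthetic_library`: list with `multiset`
#'   (a [seq_multiset()]), `truth` (data.frame: `sequence`, `true_count`,
#'   `censored`, `planted_B`, `survival_prob`, `cluster_positions`) and
#'   `spec`. Rows of `truth` align with the multiset.
#' @export
generate_library <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n_total <- spec$n_unique + spec$n_censored
  inserts <- .random_inserts(n_total, spec$insert_length)
  counts <- switch(spec$copy_law,
    ramp = seq_len(spec$n_unique),
    log_uniform = .log_uniform(spec$n_unique, spec$min_count,
                               spec$max_count),
    explicit = as.integer(spec$counts))
  planted_B <- rep(1, n_total)
  censored <- rep(FALSE, n_total)
  clusters <- vector("list", n_total)
  if (spec$n_censored > 0L) {
    c_counts <- .log_uniform(spec$n_censored, spec$censored_count_range[[1L]],
                             spec$censored_count_range[[2L]])
    counts <- c(counts, c_counts)
    idx <- spec$n_unique + seq_len(spec$n_censored)
    censored[idx] <- TRUE
    planted_B[idx] <- exp(runif(spec$n_censored,
                                log(spec$censored_b_range[[1L]]),
                                log(spec$censored_b_range[[2L]])))
    clusters[idx] <- lapply(seq_len(spec$n_censored), function(i)
      sort(sample(1:33, sample(3:4, 1L))))
    # shuffle so censored sequences are not clustered at the end
    ord <- sample(n_total)
    inserts <- inserts[ord]; counts <- counts[ord]
    censored <- censored[ord]; planted_B <- planted_B[ord]
    clusters <- clusters[ord]
  }
  survival <- (1 - spec$background_fail_rate) * planted_B
  truth <- data.frame(
    sequence = inserts,
    true_count = as.integer(counts),
    censored = censored,
    planted_B = planted_B,
    survival_prob = survival,
    cluster_positions = vapply(clusters, function(p)
      if (is.null(p)) "" else paste(p, collapse = ";"), character(1L)),
    stringsAsFactors = FALSE
  )
  structure(list(
    multiset = seq_multiset(inserts, counts, alphabet = "dna"),
    truth = truth, spec = spec), class = "synthetic_library")
}

#' @export
print.synthetic_library <- function(x, ...) {
  cat(sprintf(
    "synthetic_library: %d sequences (%d censored), %s total reads\n",
    length(x$multiset), sum(x$truth$censored),
    format(sum_total(x$multiset), big.mark = ",")))
  invisible(x)
}

#' Write synthetic FASTQ reads for a generated library
#'
#' Emits one FASTQ record per library element instance:
#' `upstream + insert + constant_tail`, all positions at `base_quality`
#' except for the planted degradations. Instances of a censored sequence
#' have their 3-4 cluster positions degraded with probability
#' `1 - planted_B`; every read independently suffers one random degraded
#' window position with probability `background_fail_rate`; a
#' `flawed_adapter_rate` fraction of reads get one upstream-adapter
#' mismatch (and are therefore rejected at ingest). Degraded scores are
#' uniform on `1..censor_cutoff-1`, below the censoring cutoff but above
#' zero.
#'
#' @param lib a [generate_library()] result.
#' @param path output FASTQ path.
#' @param truth_path optional path for the ground-truth sidecar CSV.
#' @return `path`, invisibly.
#' @export
generate_fastq <- function(lib, path, truth_path = NULL) {
  stopifnot(inherits(lib, "synthetic_library"))
  spec <- lib$spec
  cfg <- spec$adapter
  ms <- lib$multiset
  n_reads <- sum_total(ms)
  seq_id <- sample(rep.int(seq_along(ms$sequences), ms$counts))
  lu <- nchar(cfg$upstream)
  win_len <- spec$insert_length + 12L

  bases <- paste0(cfg$upstream, ms$sequences[seq_id], cfg$constant_tail)
  base_qual_chr <- intToUtf8(rep(spec$base_quality + 33L, lu + win_len))
  qual <- rep(base_qual_chr, n_reads)

  degrade <- function(qstr, win_pos, scores) {
    q <- utf8ToInt(qstr)
    q[lu + win_pos] <- scores + 33L
    intToUtf8(q)
  }
  low_q <- function(n) sample(seq_len(spec$censor_cutoff - 1L), n,
                              replace = TRUE)

  cen_rows <- which(lib$truth$censored)
  cen_reads <- which(seq_id %in% cen_rows)
  if (length(cen_reads)) {
    hit <- runif(length(cen_reads)) <
      (1 - lib$truth$planted_B[seq_id[cen_reads]])
    for (r in cen_reads[hit]) {
      pos <- as.integer(strsplit(
        lib$truth$cluster_positions[[seq_id[[r]]]], ";")[[1L]])
      qual[[r]] <- degrade(qual[[r]], pos, low_q(length(pos)))
    }
  }
  bg <- which(runif(n_reads) < spec$background_fail_rate)
  for (r in bg)
    qual[[r]] <- degrade(qual[[r]], sample.int(win_len, 1L), low_q(1L))

  flawed <- which(runif(n_reads) < spec$flawed_adapter_rate)
  for (r in flawed) {
    p <- sample.int(lu, 1L)
    old <- substr(bases[[r]], p, p)
    substr(bases[[r]], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old),
                                       1L)
  }

  recs <- character(4L * n_reads)
  recs[seq(1L, by = 4L, length.out = n_reads)] <- paste0("@read", seq_len(n_reads))
  recs[seq(2L, by = 4L, length.out = n_reads)] <- bases
  recs[seq(3L, by = 4L, length.out = n_reads)] <- "+"
  recs[seq(4L, by = 4L, length.out = n_reads)] <- qual
  writeLines(recs, path)
  if (!is.null(truth_path))
    write.table(lib$truth, truth_path, sep = ",", row.names = FALSE,
                quote = FALSE)
  invisible(path)
}

#' Simulate the outcome of quality filtering at the multiset level
#'
#' Marginalises the read-level error model of [generate_fastq()] over reads:
#' under `min_phred` filtering at the spec's `censor_cutoff`, each read of
#' sequence `i` survives independently with probability
#' `(1 - background_fail_rate) * planted_B_i`, so the post-filtering count
#' is Binomial(`n_i`, `survival_prob_i`). Equivalent in distribution to
#' generating the FASTQ, ingesting it and filtering, but tractable for
#' libraries of millions of reads.
#'
#' @param lib a [generate_library()] result.
#' @param seed optional integer seed.
#' @return a [seq_multiset()] of post-filtering counts, aligned with
#'   `lib$multiset` (zero counts kept).
#' @export
simulate_quality_filtering <- function(lib, seed = NULL) {
  stopifnot(inherits(lib, "synthetic_library"))
  if (!is.null(seed)) set.seed(seed)
  after <- rbinom(length(lib$multiset), lib$multiset$counts,
                  lib$truth$survival_prob)
  seq_multiset(lib$multiset$sequences, after, alphabet = "dna",
               theoretical_diversity = lib$multiset$theoretical_diversity)
}
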
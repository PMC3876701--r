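#' Decode a FASTQ quality string into Phred scores
#'
#' @param quality_string single ASCII quality string.
#' @param offset encoding offset: 33 (Sanger / Illumina 1.8+, the default)
#'   or 64 (legacy Illumina 1.3).
#' @return integer vector of Phred scores, one per character.
#' @export
decode_phred <- function(quality_string, offset = 33L) {
  if (length(quality_string) != 1L || is.na(quality_string))
    stop("`quality_string` must be a single string")
  codes <- utf8ToInt(quality_string)
  if (any(codes < offset))
    stop("quality character below the encoding offset (ASCII ", offset, ")")
  as.integer(codes - offset)
}

#' Per-nucleotide accuracy implied by a Phred score
#'
#' The probability that a base call is correct: `1 - 10^(-Q/10)`. Q = 13
#' corresponds to ~95% accuracy, Q = 30 to 99.9%.
#'
#' @param Q vector of non-negative integer Phred scores.
#' @return probabilities in `[0, 1]`.
#' @export
nucleotide_accuracy <- function(Q) {
  if (any(is.na(Q)) || any(Q < 0)) stop("`Q` must be >= 0")
  1 - 10^(-Q / 10)
}

#' Cumulative accuracy of a read window
#'
#' Product of per-nucleotide accuracies over a window: the probability that
#' every base in the window is called correctly. A 33-nt window with all
#' positions at Q = 13 has cumulative accuracy 0.95^33 (about 18%); 27
#' error-free positions plus five at Q = 13 give about 0.77.
#'
#' @param quals integer vector of Phred scores for one read.
#' @param window integer indices into `quals`; default: the whole read.
#' @return a probability in `[0, 1]`.
#' @export
read_accuracy <- function(quals, window = NULL) {
  if (is.null(window)) window <- seq_along(quals)
  if (!length(window)) stop("`window` must not be empty")
  if (any(window < 1L) || any(window > length(quals)))
    stop("`window` out of bounds")
  prod(nucleotide_accuracy(quals[window]))
}

#' Adapter configuration for insert extraction
#'
#' The analysed segment of each read is 33 nt: a 21-nt variable insert
#' (seven NNK-type codons) immediately followed by a 12-nt constant tail
#' encoding the GGGS linker. The insert is located by an exact match of the
#' `upstream` constant region immediately preceding it. The default adapter
#' sequences are configurable placeholders; real runs should supply the
#' primer-specific constants.
#'
#' @param upstream constant DNA immediately preceding the variable insert.
#' @param constant_tail 12-nt constant DNA following the insert; must
#'   translate to `GGGS`.
#' @param max_mismatch edit-distance budget used only to *recognise* (and
#'   report) flawed adapters; flawed reads are never rescued because their
#'   inserts have elevated error rates.
#' @return an object of class `adapter_config`.
#' @export
adapter_config <- function(upstream = "TCTCACTCT",
                           constant_tail = "GGTGGAGGTTCG",
                           max_mismatch = 1L) {
  upstream <- toupper(upstream)
  constant_tail <- toupper(constant_tail)
  if (!grepl("^[ACGT]+$", upstream) || !grepl("^[ACGT]+$", constant_tail))
    stop("adapter sequences must be DNA over {A,C,G,T}")
  if (nchar(constant_tail) != 12L)
    stop("`constant_tail` must be 12 nt")
  if (translate_insert(constant_tail) != "GGGS")
    stop("`constant_tail` must translate to GGGS")
  structure(list(upstream = upstream, constant_tail = constant_tail,
                 max_mismatch = as.integer(max_mismatch)),
            class = "adapter_config")
}

#' A single sequencing read with per-base quality
#'
#' @param bases nucleotide string.
#' @param quals integer Phred scores, same length as `bases`.
#' @param tag adapter annotation, one of `"perfect_adapter"`,
#'   `"flawed_adapter"`, `"unmapped"`.
#' @param insert_start 1-based offset of the 33-nt analysis window within
#'   `bases` (set only for perfect-adapter reads).
#' @return an object of class `quality_read`.
#' @export
quality_read <- function(bases, quals, tag = "unmapped",
                         insert_start = NA_integer_) {
  bases <- toupper(bases)
  if (nchar(bases) != length(quals))
    stop("`quals` must have one score per base")
  if (!is.na(insert_start) && insert_start + 32L > nchar(bases))
    stop("33-nt window exceeds the read")
  structure(list(bases = bases, quals = as.integer(quals), tag = tag,
                 insert_start = as.integer(insert_start)),
            class = "quality_read")
}

# Locate the 33-nt analysis window in one read. Perfect: exact upstream match
# with the exact constant tail 21 nt further on. Flawed: adapter present but
# imperfect (tail mismatch, truncation, or upstream within the edit budget).
.locate_insert <- function(bases, cfg) {
  lu <- nchar(cfg$upstream)
  occ <- gregexpr(cfg$upstream, bases, fixed = TRUE)[[1L]]
  if (occ[[1L]] != -1L) {
    for (o in occ) {
      ist <- o + lu
      if (ist + 32L <= nchar(bases) + 1L &&
          substr(bases, ist + 21L, ist + 32L) == cfg$constant_tail)
        return(list(tag = "perfect_adapter", insert_start = as.integer(ist)))
    }
    return(list(tag = "flawed_adapter", insert_start = NA_integer_))
  }
  if (cfg$max_mismatch > 0L &&
      agrepl(cfg$upstream, bases, max.distance = cfg$max_mismatch,
             fixed = TRUE))
    return(list(tag = "flawed_adapter", insert_start = NA_integer_))
  list(tag = "unmapped", insert_start = NA_integer_)
}

#' Tag a read by adapter quality and locate its insert
#'
#' @param read a [quality_read()].
#' @param cfg an [adapter_config()].
#' @return the read with `tag` and (for perfect adapters) `insert_start` set.
#' @export
map_adapter <- function(read, cfg = adapter_config()) {
  stopifnot(inherits(read, "quality_read"), inherits(cfg, "adapter_config"))
  loc <- .locate_insert(read$bases, cfg)
  read$tag <- loc$tag
  read$insert_start <- loc$insert_start
  read
}

#' Translate a DNA insert with the standard genetic code
#'
#' @param dna DNA string whose length is divisible by 3.
#' @return amino-acid string; stop codons are rendered as `*`.
#' @export
translate_insert <- function(dna) {
  dna <- toupper(dna)
  if (!grepl("^[ACGT]+$", dna))
    stop("`dna` contains characters outside {A,C,G,T}")
  if (nchar(dna) %% 3L != 0L)
    stop("`dna` length must be divisible by 3")
  as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                     no.init.codon = TRUE))
}

#' Ingest an amplicon FASTQ file into a library multiset
#'
#' Parses 4-line FASTQ records (Phred+33 by default), tags every read as
#' perfect-adapter / flawed-adapter / unmapped, and extracts the 21-nt
#' variable insert plus the Phred scores of the full 33-nt analysis window
#' from perfect reads only. Flawed-adapter reads are counted but never
#' rescued.
#'
#' @param path FASTQ file path.
#' @param cfg an [adapter_config()].
#' @param offset Phred encoding offset (33 or 64).
#' @return an object of class `ingest_result`: a list with
#'   * `multiset`: [seq_multiset()] of 21-nt inserts,
#'   * `insert`: per accepted read, its insert,
#'   * `window_quals`: per accepted read, integer Phred scores of the 33-nt
#'     window,
#'   * `report`: named counts `records`, `perfect_adapter`,
#'     `flawed_adapter`, `unmapped`.
#' @export
ingest_fastq <- function(path, cfg = adapter_config(), offset = 33L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ: ", length(lines), " lines is not a multiple of 4")
  n_rec <- length(lines) %/% 4L
  if (n_rec == 0L) {
    return(structure(list(
      multiset = seq_multiset(character(0L), integer(0L)),
      insert = character(0L), window_quals = list(),
      report = c(records = 0L, perfect_adapter = 0L, flawed_adapter = 0L,
                 unmapped = 0L)), class = "ingest_result"))
  }
  heads <- lines[seq(1L, by = 4L, length.out = n_rec)]
  bases <- toupper(lines[seq(2L, by = 4L, length.out = n_rec)])
  seps  <- lines[seq(3L, by = 4L, length.out = n_rec)]
  quals <- lines[seq(4L, by = 4L, length.out = n_rec)]
  bad <- which(!startsWith(heads, "@") | !startsWith(seps, "+") |
                 nchar(bases) != nchar(quals))
  if (length(bad))
    stop("malformed FASTQ record ", bad[[1L]])

  lu <- nchar(cfg$upstream)
  pos <- regexpr(cfg$upstream, bases, fixed = TRUE)
  ist <- ifelse(pos > 0L, pos + lu, NA_integer_)
  fits <- !is.na(ist) & (ist + 32L <= nchar(bases) + 1L)
  tail_obs <- rep(NA_character_, n_rec)
  tail_obs[fits] <- substr(bases[fits], ist[fits] + 21L, ist[fits] + 32L)
  perfect <- fits & !is.na(tail_obs) & tail_obs == cfg$constant_tail
  # a later upstream occurrence may still yield a perfect window
  recheck <- which(!perfect & pos > 0L)
  for (r in recheck) {
    loc <- .locate_insert(bases[[r]], cfg)
    if (loc$tag == "perfect_adapter") {
      perfect[[r]] <- TRUE
      ist[[r]] <- loc$insert_start
    }
  }
  flawed <- !perfect & pos > 0L
  rest <- which(!perfect & !flawed)
  if (length(rest) && cfg$max_mismatch > 0L)
    flawed[rest] <- agrepl(cfg$upstream, bases[rest],
                           max.distance = cfg$max_mismatch, fixed = TRUE)
  unmapped <- !perfect & !flawed

  acc <- which(perfect)
  insert <- substr(bases[acc], ist[acc], ist[acc] + 20L)
  window_quals <- lapply(acc, function(r)
    decode_phred(substr(quals[[r]], ist[[r]], ist[[r]] + 32L), offset))
  structure(list(
    multiset = multiset_from_sequences(insert),
    insert = insert,
    window_quals = window_quals,
    report = c(records = n_rec, perfect_adapter = length(acc),
               flawed_adapter = sum(flawed), unmapped = sum(unmapped))),
    class = "ingest_result")
}

#' @export
print.ingest_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "ingest_result: %d records (perfect %d, flawed %d, unmapped %d)\n",
    r[["records"]], r[["perfect_adapter"]], r[["flawed_adapter"]],
    r[["unmapped"]]))
  cat(sprintf("  insert multiset: %d unique / %s total\n",
              uni_count(x$multiset),
              format(sum_total(x$multiset), big.mark = ",")))
  invisible(x)
}
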
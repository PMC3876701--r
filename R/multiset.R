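#' Sequence multiset: a library as a copy-number vector
#'
#' A deep-sequenced peptide (or DNA) library is represented as a multiset: an
#' ordered set of unique, equal-length sequences together with a vector of
#' non-negative integer copy numbers. The theoretical diversity records how
#' many sequences the library *could* contain (e.g. 20^7 for 7-mer peptides);
#' only observed sequences are stored, so the representation stays sparse.
#'
#' Zero-count entries are allowed: they keep sequence order stable across
#' sampling and filtering operations (a sequence that drops to zero reads is
#' still part of the library's bookkeeping), but they do not contribute to
#' [uni_count()].
#'
#' @param sequences character vector of unique sequences, all the same length,
#'   over `{A,C,G,T}` (`alphabet = "dna"`) or the 20 amino-acid letters plus
#'   `*` (`alphabet = "aa"`).
#' @param counts non-negative integer copy numbers, one per sequence.
#' @param alphabet `"dna"` or `"aa"`.
#' @param theoretical_diversity total number of possible sequences of this
#'   length; defaults to `4^L` (DNA) or `20^L` (amino acids).
#' @return An object of class `seq_multiset` with fields `sequences`,
#'   `counts`, `alphabet`, `theoretical_diversity`.
#' @examples
#' ms <- seq_multiset(c("AAA", "CCC", "GGG", "TTT"), c(1, 2, 3, 4))
#' sum_total(ms)  # 10
#' uni_count(ms)  # 4
#' @export
seq_multiset <- function(sequences, counts,
                         alphabet = c("dna", "aa"),
                         theoretical_diversity = NULL) {
  alphabet <- match.arg(alphabet)
  sequences <- as.character(sequences)
  if (length(sequences) != length(counts))
    stop("`sequences` and `counts` must have the same length")
  if (anyDuplicated(sequences))
    stop("`sequences` must not contain duplicates")
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stop("`counts` must be non-negative integers")
  counts <- as.integer(counts)
  L <- NA_integer_
  if (length(sequences)) {
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1L)
      stop("all sequences must have identical length")
    L <- lens[[1L]]
    bad <- !grepl(.alphabet_regex(alphabet), sequences)
    if (any(bad))
      stop("sequence outside the ", alphabet, " alphabet: ",
           sequences[bad][[1L]])
  }
  base <- if (alphabet == "dna") 4 else 20
  if (is.null(theoretical_diversity)) {
    theoretical_diversity <- if (is.na(L)) NA_real_ else base^L
  } else {
    theoretical_diversity <- as.numeric(theoretical_diversity)
    if (!is.na(theoretical_diversity) &&
        theoretical_diversity < sum(counts > 0L))
      stop("theoretical_diversity is smaller than the number of observed ",
           "sequences")
  }
  structure(
    list(sequences = sequences, counts = counts, alphabet = alphabet,
         theoretical_diversity = theoretical_diversity),
    class = "seq_multiset"
  )
}

.alphabet_regex <- function(alphabet) {
  if (alphabet == "dna") "^[ACGT]+$" else "^[ACDEFGHIKLMNPQRSTVWY*]+$"
}

#' @export
print.seq_multiset <- function(x, ...) {
  cat(sprintf(
    "seq_multiset (%s): %d unique / %s total sequences (diversity %s)\n",
    x$alphabet, uni_count(x), format(sum_total(x), big.mark = ","),
    format(x$theoretical_diversity, big.mark = ",")))
  invisible(x)
}

#' @export
length.seq_multiset <- function(x) length(x$sequences)

#' Total number of sequence copies in a multiset
#'
#' The `sum` function of the multiset formalism: the total number of element
#' instances, i.e. the library size m.
#'
#' @param ms a [seq_multiset()].
#' @return a single number, `sum(counts)`.
#' @export
sum_total <- function(ms) {
  stopifnot(inherits(ms, "seq_multiset"))
  sum(as.numeric(ms$counts))
}

#' Number of unique sequences observed in a multiset
#'
#' The `uni` function of the multiset formalism: how many sequences have a
#' copy number greater than zero. Zero-count placeholders are not counted.
#'
#' @inheritParams sum_total
#' @return a single integer.
#' @export
uni_count <- function(ms) {
  stopifnot(inherits(ms, "seq_multiset"))
  sum(ms$counts > 0L)
}

#' Theoretical diversity of a sequence space
#'
#' Number of distinct sequences of a given length over a given alphabet,
#' `alphabet_size ^ length`. For 7-mer peptides this is 20^7 = 1.28e9.
#'
#' @param alphabet_size number of letters (4 for DNA, 20 for peptides).
#' @param length sequence length.
#' @return `alphabet_size ^ length` as a double (values exceed integer range
#'   already for 21-nt DNA).
#' @export
theoretical_diversity_for <- function(alphabet_size, length) {
  if (length(alphabet_size) != 1L || length(length) != 1L ||
      is.na(alphabet_size) || is.na(length) ||
      alphabet_size < 1 || length < 1 ||
      alphabet_size != floor(alphabet_size) || length != floor(length))
    stop("`alphabet_size` and `length` must be positive integers")
  as.numeric(alphabet_size)^as.numeric(length)
}

#' All single-point-mutation neighbours of a DNA sequence
#'
#' Enumerates every sequence at Hamming distance exactly one from `seq`:
#' 3 * nchar(seq) distinct misspellings. A 21-nt insert, for instance, has 63
#' one-letter misspellings, which is why point mutations of abundant clones
#' can flood a library with spurious low-copy sequences.
#'
#' @param seq a DNA string over `{A,C,G,T}`.
#' @return character vector of `3 * nchar(seq)` distinct sequences, not
#'   including `seq` itself.
#' @export
point_mutation_neighborhood <- function(seq) {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop("`seq` must be a single non-empty string")
  seq <- toupper(seq)
  if (!grepl("^[ACGT]+$", seq))
    stop("`seq` contains characters outside {A,C,G,T}")
  chars <- strsplit(seq, "")[[1L]]
  bases <- c("A", "C", "G", "T")
  out <- character(0L)
  for (pos in seq_along(chars)) {
    for (b in setdiff(bases, chars[[pos]])) {
      mutated <- chars
      mutated[[pos]] <- b
      out <- c(out, paste(mutated, collapse = ""))
    }
  }
  out
}

#' Build a multiset from a vector of observed sequences
#'
#' Tallies repeated observations (e.g. one per sequencing read) into a
#' multiset with sequences in lexicographic order.
#'
#' @param observed character vector of sequences, repeats allowed.
#' @inheritParams seq_multiset
#' @return a [seq_multiset()].
#' @export
multiset_from_sequences <- function(observed, alphabet = c("dna", "aa"),
                                    theoretical_diversity = NULL) {
  alphabet <- match.arg(alphabet)
  if (!length(observed))
    return(seq_multiset(character(0L), integer(0L), alphabet = alphabet,
                        theoretical_diversity = theoretical_diversity))
  tab <- table(observed)
  seq_multiset(names(tab), as.integer(tab), alphabet = alphabet,
               theoretical_diversity = theoretical_diversity)
}

#' Read / write a multiset as tab-separated text
#'
#' One record per line, `<sequence>\t<count>`. Lines beginning `#` are
#' comments; lines beginning `#!` carry metadata (`alphabet`,
#' `theoretical_diversity`) written by [write_multiset_text()] so that a
#' round trip reproduces the multiset exactly, including sequence order.
#' Sequences are case-folded to upper case on read.
#'
#' @param path file path.
#' @param alphabet alphabet to assume when the file carries no metadata.
#' @return `read_multiset_text()` returns a [seq_multiset()];
#'   `write_multiset_text()` returns `path` invisibly.
#' @export
read_multiset_text <- function(path, alphabet = c("dna", "aa")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  diversity <- NULL
  meta <- grepl("^#!", lines)
  for (m in lines[meta]) {
    kv <- sub("^#!\\s*", "", m)
    if (grepl("^alphabet:", kv))
      alphabet <- trimws(sub("^alphabet:", "", kv))
    if (grepl("^theoretical_diversity:", kv))
      diversity <- as.numeric(sub("^theoretical_diversity:", "", kv))
  }
  keep <- which(!meta & !grepl("^#", lines) & nzchar(trimws(lines)))
  sequences <- character(length(keep))
  counts <- integer(length(keep))
  for (j in seq_along(keep)) {
    ln <- keep[[j]]
    fields <- strsplit(trimws(lines[[ln]]), "[\t ]+")[[1L]]
    if (length(fields) != 2L)
      stop(sprintf("line %d: expected 2 fields, found %d",
                   ln, length(fields)))
    if (!grepl("^[0-9]+$", fields[[2L]]))
      stop(sprintf("line %d: count '%s' is not a non-negative integer",
                   ln, fields[[2L]]))
    sq <- toupper(fields[[1L]])
    if (!grepl(.alphabet_regex(alphabet), sq))
      stop(sprintf("line %d: sequence '%s' is outside the %s alphabet",
                   ln, fields[[1L]], alphabet))
    sequences[[j]] <- sq
    counts[[j]] <- as.integer(fields[[2L]])
  }
  if (anyDuplicated(sequences)) {
    dup <- keep[[which(duplicated(sequences))[[1L]]]]
    stop(sprintf("line %d: duplicated sequence", dup))
  }
  seq_multiset(sequences, counts, alphabet = alphabet,
               theoretical_diversity = diversity)
}

#' @param ms a [seq_multiset()] to write.
#' @rdname read_multiset_text
#' @export
write_multiset_text <- function(ms, path) {
  stopifnot(inherits(ms, "seq_multiset"))
  header <- c(
    "# sequence multiset, tab-separated: <sequence>\t<count>",
    paste0("#! alphabet: ", ms$alphabet),
    paste0("#! theoretical_diversity: ",
           format(ms$theoretical_diversity, scientific = FALSE))
  )
  writeLines(c(header, paste(ms$sequences, ms$counts, sep = "\t")), path)
  invisible(path)
}

# Align `after` onto `before`'s sequence order; sequences absent from `after`
# get count 0. Errors if `after` contains sequences unseen in `before`.
.align_counts <- function(before, after) {
  idx <- match(after$sequences, before$sequences)
  if (anyNA(idx))
    stop("`after` contains sequences absent from `before`: ",
         after$sequences[is.na(idx)][[1L]])
  out <- integer(length(before$sequences))
  out[idx] <- after$counts
  out
}
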
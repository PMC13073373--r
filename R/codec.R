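# Payload <-> nucleotide codec. Sequences carry two synchronized views: the
# base string over {A,T,C,G} and the digit vector over {0,1,2,3} used by the
# continuous optimizers. All indexing of digit vectors is 0-based in value
# space (digits), 1-based in R position space.

.BASES <- c("A", "T", "C", "G")

#' Default digit/bit-pair to base encoding map
#'
#' Maps digits 0..3 to A, T, C, G (in that order) and bit pairs (MSB-first
#' within each byte) 00, 01, 10, 11 to the same bases, giving the theoretical
#' capacity of 2 bits per nucleotide. Both mappings must be bijections.
#'
#' @param digit_to_base character vector of 4 distinct bases, position k
#'   giving the base for digit k-1.
#' @return An object of class `encoding_map`.
#' @export
#' @examples
#' encoding_map()
encoding_map <- function(digit_to_base = c("A", "T", "C", "G")) {
  digit_to_base <- toupper(digit_to_base)
  if (length(digit_to_base) != 4L || anyDuplicated(digit_to_base) ||
      !all(digit_to_base %in% .BASES)) {
    stop("`digit_to_base` must be a permutation of A, T, C, G", call. = FALSE)
  }
  bitpair_to_base <- stats::setNames(digit_to_base, c("00", "01", "10", "11"))
  structure(
    list(digit_to_base = stats::setNames(digit_to_base, 0:3),
         bitpair_to_base = bitpair_to_base,
         base_to_digit = stats::setNames(0:3, digit_to_base)),
    class = "encoding_map"
  )
}

#' Information capacity of an encoding map in bits per nucleotide
#'
#' @param map an [encoding_map()].
#' @return `log2` of the alphabet size (2 for the 4-letter DNA alphabet).
#' @export
bits_per_nt <- function(map = encoding_map()) {
  log2(length(map$digit_to_base))
}

#' Nucleotide sequence with paired digit and base views
#'
#' @param bases a single string (or character vector of single bases) over
#'   A, C, G, T; lower case accepted, stored upper case.
#' @param map an [encoding_map()].
#' @return An object of class `dna_seq` with elements `bases` (string),
#'   `digits` (integer vector in 0..3) and `length`.
#' @export
#' @examples
#' dna_seq("ACGT")
dna_seq <- function(bases, map = encoding_map()) {
  if (length(bases) > 1L) bases <- paste(bases, collapse = "")
  if (!is.character(bases) || length(bases) != 1L || is.na(bases)) {
    stop("`bases` must be a single string", call. = FALSE)
  }
  bases <- toupper(bases)
  chars <- strsplit(bases, "", fixed = TRUE)[[1L]]
  if (length(chars) < 1L) stop("sequence must have length >= 1", call. = FALSE)
  if (!all(chars %in% .BASES)) {
    stop("bases outside {A,C,G,T} are not supported", call. = FALSE)
  }
  digits <- unname(map$base_to_digit[chars])
  structure(list(bases = bases, digits = as.integer(digits),
                 length = length(chars)),
            class = "dna_seq")
}

#' @export
print.dna_seq <- function(x, ...) {
  shown <- if (x$length > 60L) paste0(substr(x$bases, 1L, 57L), "...") else x$bases
  cat(sprintf("<dna_seq> %d nt: %s\n", x$length, shown))
  invisible(x)
}

#' @export
as.character.dna_seq <- function(x, ...) x$bases

as_dna_seq <- function(x, map = encoding_map()) {
  if (inherits(x, "dna_seq")) x else dna_seq(x, map)
}

#' Convert a digit vector to a base string
#'
#' @param digits integer vector with entries in 0..3.
#' @param map an [encoding_map()].
#' @return a single base string of the same length.
#' @export
#' @examples
#' digits_to_bases(c(0, 1, 2, 3))  # "ATCG" under the default map
digits_to_bases <- function(digits, map = encoding_map()) {
  if (length(digits) < 1L) stop("empty digit vector", call. = FALSE)
  if (anyNA(digits) || !all(digits %in% 0:3)) {
    stop("digits must all lie in {0,1,2,3}", call. = FALSE)
  }
  paste(map$digit_to_base[as.integer(digits) + 1L], collapse = "")
}

#' Convert a base string to its digit vector
#'
#' @inheritParams dna_seq
#' @return integer vector over 0..3.
#' @export
bases_to_digits <- function(bases, map = encoding_map()) {
  dna_seq(bases, map)$digits
}

#' Encode a digital payload as DNA at 2 bits per nucleotide
#'
#' Each byte yields four nucleotides; bit pairs are read MSB-first within the
#' byte. If the payload carries an `n_nt` attribute (as produced by
#' [make_benchmark_text()] for targets that are not a multiple of 4 nt) the
#' encoded sequence is truncated to that many nucleotides; the dropped
#' positions are zero-padding bits by construction.
#'
#' @param payload a raw vector or a single character string (encoded UTF-8).
#' @param map an [encoding_map()].
#' @return a [dna_seq()] of length `4 * length(payload)` nt (or `n_nt`).
#' @export
#' @examples
#' text_to_dna("A")  # 0x41 -> digits 1,0,0,1
text_to_dna <- function(payload, map = encoding_map()) {
  n_nt <- attr(payload, "n_nt")
  if (is.character(payload)) {
    if (length(payload) != 1L) stop("character payload must be one string", call. = FALSE)
    payload <- charToRaw(payload)
  }
  if (!is.raw(payload)) stop("payload must be raw bytes or a string", call. = FALSE)
  if (length(payload) == 0L) stop("nothing to encode: payload is empty", call. = FALSE)
  bytes <- as.integer(payload)
  # MSB-first bit-pair extraction: shifts 6, 4, 2, 0
  digits <- as.integer(t(outer(bytes, c(6L, 4L, 2L, 0L),
                               function(b, s) bitwAnd(bitwShiftR(b, s), 3L))))
  if (!is.null(n_nt)) {
    if (n_nt > length(digits) || n_nt < length(digits) - 3L) {
      stop("`n_nt` attribute inconsistent with payload size", call. = FALSE)
    }
    digits <- digits[seq_len(n_nt)]
  }
  seq <- dna_seq(digits_to_bases(digits, map), map)
  seq
}

#' Decode a DNA sequence back to payload bytes
#'
#' Inverse of [text_to_dna()]. If the sequence length is not a multiple of 4
#' the trailing partial byte is completed with zero bits (matching the padding
#' convention of [make_benchmark_text()]).
#'
#' @param seq a [dna_seq()] or base string.
#' @param map an [encoding_map()].
#' @param as_text if `TRUE`, return a UTF-8 string instead of raw bytes.
#' @return raw vector (or string).
#' @export
dna_to_text <- function(seq, map = encoding_map(), as_text = FALSE) {
  seq <- as_dna_seq(seq, map)
  d <- seq$digits
  pad <- (4L - length(d) %% 4L) %% 4L
  if (pad > 0L) d <- c(d, integer(pad))
  m <- matrix(d, nrow = 4L)
  bytes <- as.raw(colSums(m * c(64L, 16L, 4L, 1L)))
  if (as_text) rawToChar(bytes) else bytes
}

#' Write sequences to a FASTA file
#'
#' Standards-compliant FASTA with 60-column line wrapping (via Biostrings).
#'
#' @param seqs a list of [dna_seq()] objects (or base strings).
#' @param path output file path.
#' @param ids unique non-empty record identifiers; defaults to names of
#'   `seqs` or `seq_1`, `seq_2`, ...
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, ids = NULL) {
  if (inherits(seqs, "dna_seq")) seqs <- list(seqs)
  if (is.null(ids)) {
    ids <- names(seqs)
    if (is.null(ids)) ids <- paste0("seq_", seq_along(seqs))
  }
  if (length(ids) != length(seqs) || any(!nzchar(ids)) || anyNA(ids)) {
    stop("`ids` must be non-empty and match `seqs` in length", call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("duplicate FASTA ids", call. = FALSE)
  strings <- vapply(seqs, function(s) as_dna_seq(s)$bases, character(1L))
  set <- Biostrings::DNAStringSet(stats::setNames(strings, ids))
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @param map an [encoding_map()].
#' @return a named list of [dna_seq()] objects.
#' @export
read_fasta <- function(path, map = encoding_map()) {
  set <- Biostrings::readDNAStringSet(path)
  out <- lapply(as.character(set), dna_seq, map = map)
  out
}

#' Generate a deterministic synthetic benchmark payload
#'
#' Produces random payload bytes that encode to exactly `target_nt`
#' nucleotides, standing in for an undisclosed benchmark text of the same
#' length. If `target_nt` is not a multiple of 4, the final partial byte is
#' padded with zero bits and the pad length (in nt) is recorded in the
#' `pad_nt` attribute; the `n_nt` attribute carries the target so that
#' [text_to_dna()] truncates exactly.
#'
#' @param target_nt desired sequence length in nucleotides (>= 4).
#' @param seed integer seed; the same seed always yields the same payload.
#' @return raw vector of `ceiling(target_nt / 4)` bytes with attributes
#'   `n_nt` and `pad_nt`.
#' @export
#' @examples
#' p <- make_benchmark_text(1853, seed = 1)
#' text_to_dna(p)$length  # 1853
make_benchmark_text <- function(target_nt, seed) {
  if (!is.numeric(target_nt) || target_nt < 4) {
    stop("`target_nt` must be >= 4", call. = FALSE)
  }
  target_nt <- as.integer(target_nt)
  n_bytes <- as.integer(ceiling(target_nt / 4))
  pad_nt <- 4L * n_bytes - target_nt
  bytes <- local_seed(seed, sample.int(256L, n_bytes, replace = TRUE) - 1L)
  if (pad_nt > 0L) {
    # zero the unused low bits of the final byte (pad_nt trailing nt)
    keep_bits <- 2L * (4L - pad_nt)
    mask <- bitwShiftL(bitwShiftR(255L, 8L - keep_bits), 8L - keep_bits)
    bytes[n_bytes] <- bitwAnd(bytes[n_bytes], mask)
  }
  out <- as.raw(bytes)
  attr(out, "n_nt") <- target_nt
  attr(out, "pad_nt") <- pad_nt
  out
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
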
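# Independent oracles used by the tests; deliberately naive and separate
# from the package's implementation paths.

# Levenshtein distance by memoized recursion on the textbook definition.
edit_distance_recursive <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    cost <- as.integer(substr(a, i, i) != substr(b, j, j))
    v <- min(rec(i - 1L, j - 1L) + cost,
             rec(i - 1L, j) + 1L,
             rec(i, j - 1L) + 1L)
    memo[[key]] <- v
    v
  }
  rec(nchar(a), nchar(b))
}

# MSB-first bit-pair digits of a byte, via intToBits (bit-twiddling oracle).
byte_to_digits_oracle <- function(byte) {
  bits <- rev(as.integer(intToBits(as.integer(byte)))[1:8])  # MSB first
  bits[c(1, 3, 5, 7)] * 2L + bits[c(2, 4, 6, 8)]
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# thermo table with every step at the same energy
uniform_thermo <- function(value, target = value) {
  steps <- as.vector(outer(c("A", "T", "C", "G"), c("A", "T", "C", "G"), paste0))
  thermo_table(dg = stats::setNames(rep(value, 16), steps), dg_target = target)
}

# hand-built read_record for context-summary tests
fake_record <- function(ref, read, pos, type, ref_base, alt_base) {
  structure(list(read = read, ref = ref,
                 events = data.frame(pos = pos, type = type,
                                     ref_base = ref_base, alt_base = alt_base,
                                     stringsAsFactors = FALSE),
                 ref_length = nchar(ref)),
            class = "read_record")
}
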
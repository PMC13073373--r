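# Biophysical penalty model: six terms (GC, homopolymer, stacking free
# energy; melting temperature, Hamming, reverse-complement) combined into a
# single scalar fitness that the optimizers minimize. A sequence with ideal
# composition scores exactly 0.

# Unified nearest-neighbour stacking free energies at 37 C, kcal/mol per
# dinucleotide step (SantaLucia-style unified values).
.NN_DG37 <- c(
  AA = -1.00, AT = -0.88, AC = -1.44, AG = -1.28,
  TA = -0.58, TT = -1.00, TC = -1.30, TG = -1.45,
  CA = -1.45, CT = -1.28, CC = -1.84, CG = -2.17,
  GA = -1.30, GT = -1.44, GC = -2.24, GG = -1.84
)

#' Dinucleotide stacking free-energy table
#'
#' Holds the 16 nearest-neighbour stacking free energies (kcal/mol at 37 C)
#' and the target mean step energy used by the free-energy penalty. The
#' default table ships as `inst/extdata/nn_dg37.tsv` and can be replaced by
#' any 16-entry key/value file via `file`.
#'
#' @param dg named numeric vector of 16 dinucleotide step energies.
#' @param dg_target target mean step energy in kcal/mol (default -1.45, the
#'   biologically ideal value used by the penalty).
#' @param file optional path to a two-column (step, kcal/mol) TSV; overrides
#'   `dg`.
#' @return An object of class `thermo_table`.
#' @export
#' @examples
#' thermo_table()$dg[["AT"]]
thermo_table <- function(dg = .NN_DG37, dg_target = -1.45, file = NULL) {
  if (!is.null(file)) {
    tab <- utils::read.delim(file, header = TRUE, stringsAsFactors = FALSE)
    dg <- stats::setNames(as.numeric(tab[[2L]]), toupper(tab[[1L]]))
  }
  steps <- as.vector(outer(.BASES, .BASES, paste0))
  if (length(dg) != 16L || !all(steps %in% names(dg)) || !all(is.finite(dg))) {
    stop("`dg` must hold 16 finite dinucleotide entries", call. = FALSE)
  }
  if (!is.finite(dg_target)) stop("`dg_target` must be finite", call. = FALSE)
  # digit-indexed lookup: step (d1, d2) -> dg_vec[d1 * 4 + d2 + 1]
  pair_names <- as.vector(t(outer(c("A", "T", "C", "G"), c("A", "T", "C", "G"),
                                  paste0)))
  structure(list(dg = dg[sort(names(dg))], dg_target = dg_target,
                 dg_vec = unname(dg[pair_names])),
            class = "thermo_table")
}

#' Weights of the six fitness terms
#'
#' The published model states only that homopolymer and melting-temperature
#' terms carry higher weights; the numeric defaults here (hp = 10, tm = 5,
#' rc = 5, others 1) follow that priority and are fully configurable. All
#' reported fitness values are relative to the chosen weights.
#'
#' @param gc,hp,dg objective weights (GC deviation, homopolymer, free energy).
#' @param tm,hamming,rc constraint weights (melting temperature, Hamming
#'   distance, reverse-complement similarity).
#' @return An object of class `fitness_weights`.
#' @export
fitness_weights <- function(gc = 1, hp = 10, dg = 1, tm = 5, hamming = 1, rc = 5) {
  w <- c(gc = gc, hp = hp, dg = dg, tm = tm, hamming = hamming, rc = rc)
  if (anyNA(w) || any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  if (all(w == 0)) stop("at least one weight must be positive", call. = FALSE)
  structure(as.list(w), class = "fitness_weights")
}

#' Constraint configuration for the penalty model
#'
#' @param tm_range numeric length-2, melting-temperature target interval in
#'   degrees C (default `c(55, 65)`).
#' @param rc_threshold reverse-complement similarity threshold as a fraction
#'   (default 0.15).
#' @param d_min minimum Hamming distance to the archive in nt (default 0,
#'   i.e. inactive).
#' @param archive list of [dna_seq()] (or base strings) of the same length as
#'   candidate sequences; empty archive disables the Hamming term.
#' @param hp_limit maximal tolerated homopolymer run length (default 3).
#' @return An object of class `constraint_config`.
#' @export
constraint_config <- function(tm_range = c(55, 65), rc_threshold = 0.15,
                              d_min = 0, archive = list(), hp_limit = 3) {
  if (length(tm_range) != 2L || tm_range[1L] >= tm_range[2L]) {
    stop("`tm_range` must be c(low, high) with low < high", call. = FALSE)
  }
  if (rc_threshold <= 0 || rc_threshold >= 1) {
    stop("`rc_threshold` must lie in (0, 1)", call. = FALSE)
  }
  if (d_min < 0) stop("`d_min` must be >= 0", call. = FALSE)
  if (inherits(archive, "dna_seq")) archive <- list(archive)
  archive <- lapply(archive, as_dna_seq)
  structure(list(tm_range = as.numeric(tm_range),
                 rc_threshold = rc_threshold, d_min = as.integer(d_min),
                 archive = archive, hp_limit = as.integer(hp_limit)),
            class = "constraint_config")
}

#' GC content of a sequence in percent
#'
#' @param seq a [dna_seq()] or base string.
#' @return percentage of G and C bases, in \[0, 100\].
#' @export
#' @examples
#' gc_content("ATCG")  # 50
gc_content <- function(seq) {
  d <- as_dna_seq(seq)$digits
  mean(d >= 2L) * 100
}

#' Quadratic GC-deviation penalty
#'
#' `(GC% - 50)^2`; zero exactly at 50% GC.
#'
#' @inheritParams gc_content
#' @return non-negative penalty.
#' @export
gc_penalty <- function(seq) {
  (gc_content(seq) - 50)^2
}

#' Maximal homopolymer runs of a sequence
#'
#' @inheritParams gc_content
#' @return data.frame with columns `base` and `length`, runs in left-to-right
#'   order; lengths sum to the sequence length.
#' @export
#' @examples
#' homopolymer_blocks("AAAT")
homopolymer_blocks <- function(seq) {
  seq <- as_dna_seq(seq)
  r <- rle(strsplit(seq$bases, "", fixed = TRUE)[[1L]])
  data.frame(base = r$values, length = r$lengths, stringsAsFactors = FALSE)
}

#' Cumulative homopolymer penalty
#'
#' Sum of `(h_k - limit)^2` over all maximal runs longer than `hp_limit`
#' bases; zero iff the longest run is within the limit.
#'
#' @inheritParams gc_content
#' @param hp_limit maximal tolerated run length (default 3).
#' @return non-negative penalty.
#' @export
#' @examples
#' hp_penalty("AAAAA")  # (5 - 3)^2 = 4
hp_penalty <- function(seq, hp_limit = 3) {
  d <- as_dna_seq(seq)$digits
  .hp_penalty_digits(d, hp_limit)
}

.hp_penalty_digits <- function(d, hp_limit = 3L) {
  len <- rle(d)$lengths
  over <- len[len > hp_limit]
  if (length(over) == 0L) return(0)
  sum((over - hp_limit)^2)
}

#' Normalized stacking free-energy penalty
#'
#' Absolute deviation of the mean per-step stacking energy from the target,
#' scaled by 100: `|sum(dG_step) / (L - 1) - dG_target| * 100`. The divisor
#' is the number of dinucleotide steps so that a sequence whose every step
#' equals the target scores exactly zero at any length.
#'
#' @inheritParams gc_content
#' @param thermo a [thermo_table()].
#' @return non-negative penalty; sequences of length 1 return 0 with a
#'   warning (no dinucleotide step exists).
#' @export
dg_penalty <- function(seq, thermo = thermo_table()) {
  d <- as_dna_seq(seq)$digits
  if (length(d) < 2L) {
    warning("sequence has no dinucleotide step; dG penalty set to 0")
    return(0)
  }
  .dg_penalty_digits(d, thermo)
}

.dg_steps_digits <- function(d, thermo) {
  n <- length(d)
  thermo$dg_vec[d[-n] * 4L + d[-1L] + 1L]
}

.dg_penalty_digits <- function(d, thermo) {
  steps <- .dg_steps_digits(d, thermo)
  abs(mean(steps) - thermo$dg_target) * 100
}

#' Salt-corrected empirical melting temperature
#'
#' `Tm = 64.9 + 41 * (GC% - 16.4) / 100`, a function of GC content only.
#'
#' @inheritParams gc_content
#' @return melting temperature in degrees C.
#' @export
#' @examples
#' round(melting_temperature("ATCG"), 2)
melting_temperature <- function(seq) {
  tm_model(gc_content(seq))
}

#' Melting-temperature model as a function of GC percentage
#'
#' @param gc_percent GC content in percent.
#' @return melting temperature in degrees C.
#' @export
#' @examples
#' round(tm_model(40.53), 2)  # 74.79
tm_model <- function(gc_percent) {
  64.9 + 41 * (gc_percent - 16.4) / 100
}

#' Melting-temperature range violation penalty
#'
#' Zero when Tm lies inside the configured target interval, otherwise the
#' squared distance to the nearest bound (a soft constraint).
#'
#' @inheritParams gc_content
#' @param cfg a [constraint_config()].
#' @return non-negative penalty.
#' @export
tm_penalty <- function(seq, cfg = constraint_config()) {
  .tm_penalty_value(melting_temperature(seq), cfg$tm_range)
}

.tm_penalty_value <- function(tm, range) {
  if (tm < range[1L]) (range[1L] - tm)^2
  else if (tm > range[2L]) (tm - range[2L])^2
  else 0
}

#' Minimum Hamming distance to an archive and its violation penalty
#'
#' Penalty `(d_min - min_i d(S, A_i))^2` when the closest archive sequence is
#' nearer than `d_min`; an empty archive yields penalty 0 (single-sequence
#' design mode) and an `NA` distance.
#'
#' @inheritParams tm_penalty
#' @return list with `min_distance` (count, `NA` if archive empty) and
#'   `penalty`.
#' @export
hamming_penalty <- function(seq, cfg = constraint_config()) {
  d <- as_dna_seq(seq)$digits
  arch <- lapply(cfg$archive, function(a) a$digits)
  .hamming_penalty_digits(d, arch, cfg$d_min)
}

.hamming_penalty_digits <- function(d, archive_digits, d_min) {
  if (length(archive_digits) == 0L) {
    return(list(min_distance = NA_integer_, penalty = 0))
  }
  dists <- vapply(archive_digits, function(a) {
    if (length(a) != length(d)) {
      stop("archive sequence length differs from candidate", call. = FALSE)
    }
    sum(a != d)
  }, integer(1L))
  mind <- min(dists)
  pen <- if (mind < d_min) (d_min - mind)^2 else 0
  list(min_distance = mind, penalty = pen)
}

#' Reverse-complement self-similarity
#'
#' Fraction of positions at which the sequence matches its own reverse
#' complement (position i against the complement of position L-1-i,
#' 0-based). Values near 1 signal palindromic, hairpin-prone sequences; the
#' random expectation is 0.25.
#'
#' @inheritParams gc_content
#' @return fraction in \[0, 1\].
#' @export
#' @examples
#' rc_similarity("ACGT")  # 1: ACGT is its own reverse complement
rc_similarity <- function(seq) {
  .rc_similarity_digits(as_dna_seq(seq)$digits)
}

# complement in digit space: A<->T (0<->1), C<->G (2<->3)
.COMP_DIGIT <- c(1L, 0L, 3L, 2L)

.rc_similarity_digits <- function(d) {
  mean(d == .COMP_DIGIT[rev(d) + 1L])
}

#' Reverse-complement similarity penalty
#'
#' Linear penalty `(ratio - threshold) * 100` applied only above the
#' threshold (default 15%).
#'
#' @inheritParams tm_penalty
#' @return non-negative penalty.
#' @export
rc_penalty <- function(seq, cfg = constraint_config()) {
  .rc_penalty_value(rc_similarity(seq), cfg$rc_threshold)
}

.rc_penalty_value <- function(ratio, threshold) {
  if (ratio > threshold) (ratio - threshold) * 100 else 0
}

#' Full fitness breakdown of a candidate sequence
#'
#' Evaluates the six penalty terms and their weighted sum (lower is better;
#' the design problem is a minimization). The breakdown also records the raw
#' diagnostics behind each term (GC%, Tm, RC ratio, minimum Hamming
#' distance).
#'
#' @inheritParams gc_content
#' @param weights a [fitness_weights()].
#' @param cfg a [constraint_config()].
#' @param thermo a [thermo_table()].
#' @return An object of class `fitness_breakdown`: a list with the term
#'   values `f_gc`, `f_hp`, `f_dg`, `c_tm`, `c_ham`, `c_rc`, diagnostics
#'   `gc_percent`, `tm`, `rc_ratio`, `min_hamming`, `dg_sum`, `max_hp` and
#'   the weighted `total`.
#' @export
#' @examples
#' total_fitness("ATCGATCG")$total
total_fitness <- function(seq, weights = fitness_weights(),
                          cfg = constraint_config(), thermo = thermo_table()) {
  d <- as_dna_seq(seq)$digits
  arch <- lapply(cfg$archive, function(a) a$digits)
  .breakdown_digits(d, weights, cfg, thermo, arch)
}

.breakdown_digits <- function(d, weights, cfg, thermo, archive_digits) {
  gc <- mean(d >= 2L) * 100
  f_gc <- (gc - 50)^2
  f_hp <- .hp_penalty_digits(d, cfg$hp_limit)
  n <- length(d)
  steps <- if (n >= 2L) .dg_steps_digits(d, thermo) else numeric(0)
  f_dg <- if (n >= 2L) abs(mean(steps) - thermo$dg_target) * 100 else 0
  tm <- tm_model(gc)
  c_tm <- .tm_penalty_value(tm, cfg$tm_range)
  ham <- .hamming_penalty_digits(d, archive_digits, cfg$d_min)
  rc <- .rc_similarity_digits(d)
  c_rc <- .rc_penalty_value(rc, cfg$rc_threshold)
  terms <- c(f_gc = f_gc, f_hp = f_hp, f_dg = f_dg,
             c_tm = c_tm, c_ham = ham$penalty, c_rc = c_rc)
  w <- c(weights$gc, weights$hp, weights$dg, weights$tm, weights$hamming,
         weights$rc)
  structure(c(as.list(terms),
              list(gc_percent = gc, tm = tm, rc_ratio = rc,
                   min_hamming = ham$min_distance,
                   dg_sum = sum(steps),
                   max_hp = max(rle(d)$lengths),
                   total = sum(w * terms))),
            class = "fitness_breakdown")
}

# scalar fast path used inside the optimizer loops
.fitness_digits <- function(d, weights, cfg, thermo, archive_digits) {
  gc <- mean(d >= 2L) * 100
  tm <- tm_model(gc)
  total <- weights$gc * (gc - 50)^2 +
    weights$hp * .hp_penalty_digits(d, cfg$hp_limit) +
    weights$tm * .tm_penalty_value(tm, cfg$tm_range) +
    weights$rc * .rc_penalty_value(.rc_similarity_digits(d), cfg$rc_threshold)
  if (length(d) >= 2L) {
    total <- total + weights$dg * .dg_penalty_digits(d, thermo)
  }
  if (length(archive_digits) > 0L) {
    total <- total +
      weights$hamming * .hamming_penalty_digits(d, archive_digits, cfg$d_min)$penalty
  }
  total
}

#' @export
print.fitness_breakdown <- function(x, ...) {
  cat("<fitness_breakdown>\n")
  cat(sprintf("  total %.4f | GC %.2f%% (f_gc %.3f) | maxHP %d (f_hp %.3f)\n",
              x$total, x$gc_percent, x$f_gc, x$max_hp, x$f_hp))
  cat(sprintf("  Tm %.2fC (c_tm %.3f) | dG sum %.2f (f_dg %.3f)\n",
              x$tm, x$c_tm, x$dg_sum, x$f_dg))
  cat(sprintf("  RC %.2f%% (c_rc %.3f) | min Hamming %s (c_ham %.3f)\n",
              100 * x$rc_ratio, x$c_rc,
              ifelse(is.na(x$min_hamming), "NA", x$min_hamming), x$c_ham))
  invisible(x)
}

#' Export a fitness breakdown as JSON
#'
#' @param x a `fitness_breakdown`.
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @return JSON string or `path` invisibly.
#' @export
breakdown_to_json <- function(x, path = NULL) {
  obj <- unclass(x)
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
    invisible(path)
  }
}
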
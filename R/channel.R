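# Substitution/insertion/deletion error channel. Reads are generated in a
# single left-to-right pass over the reference; at each position exactly one
# of {deletion, insertion-before (the reference base is then emitted
# unchanged), substitution, match} is drawn, with indel probabilities
# multiplied inside long homopolymer runs to emulate polymerase slippage.
# Every event is logged against its reference position so reads can be
# replayed and error patterns decomposed by type and context.

#' PCR error regime
#'
#' The three noise regimes are parameterized by a central PCR cycle count:
#' low 50 (cycle range 10-100), medium 200 (50-400), high 500 (100-1000).
#'
#' @param name one of `"low"`, `"medium"`, `"high"`.
#' @return An object of class `error_regime` with `name`, `cycle_range` and
#'   `central_cycles`.
#' @export
error_regime <- function(name = c("low", "medium", "high")) {
  name <- match.arg(name)
  spec <- switch(name,
    low = list(cycle_range = c(10, 100), central_cycles = 50),
    medium = list(cycle_range = c(50, 400), central_cycles = 200),
    high = list(cycle_range = c(100, 1000), central_cycles = 500)
  )
  structure(c(list(name = name), spec), class = "error_regime")
}

#' Per-position error probabilities of the channel
#'
#' @param p_sub,p_ins,p_del per-position substitution / insertion / deletion
#'   probabilities; each in `[0, 1)` and summing below 1.
#' @param hp_threshold run length from which indel probabilities are boosted
#'   (default 4).
#' @param hp_indel_multiplier multiplicative indel boost inside runs of
#'   `hp_threshold` or more (default 3).
#' @return An object of class `channel_profile`.
#' @export
channel_profile <- function(p_sub, p_ins, p_del, hp_threshold = 4,
                            hp_indel_multiplier = 3.0) {
  p <- c(p_sub, p_ins, p_del)
  if (any(p < 0) || any(p >= 1) || sum(p) >= 1) {
    stop("error probabilities must lie in [0,1) and sum below 1", call. = FALSE)
  }
  if (hp_indel_multiplier < 1) stop("`hp_indel_multiplier` must be >= 1", call. = FALSE)
  structure(list(p_sub = p_sub, p_ins = p_ins, p_del = p_del,
                 hp_threshold = as.integer(hp_threshold),
                 hp_indel_multiplier = hp_indel_multiplier),
            class = "channel_profile")
}

#' Map an error regime to channel probabilities
#'
#' Linear cycle-to-probability calibration: `p = min(base_rate *
#' central_cycles, cap)`. The default per-cycle base rates (sub 6e-5, ins
#' 1.6e-4, del 4e-5) place the high regime near per-nt rates of 0.03 / 0.08
#' / 0.02.
#'
#' @param regime an [error_regime()] or regime name.
#' @param base_rates named per-cycle rates (`sub`, `ins`, `del`).
#' @param cap upper bound on each probability.
#' @param ... passed to [channel_profile()] (homopolymer boost settings).
#' @return a [channel_profile()].
#' @export
#' @examples
#' regime_profile("high")$p_ins  # 0.08
regime_profile <- function(regime,
                           base_rates = c(sub = 6e-5, ins = 1.6e-4, del = 4e-5),
                           cap = 0.30, ...) {
  if (is.character(regime)) regime <- error_regime(regime)
  cc <- regime$central_cycles
  channel_profile(p_sub = min(base_rates[["sub"]] * cc, cap),
                  p_ins = min(base_rates[["ins"]] * cc, cap),
                  p_del = min(base_rates[["del"]] * cc, cap), ...)
}

#' Simulate one noisy read of a reference sequence
#'
#' @param ref a [dna_seq()] or base string.
#' @param profile a [channel_profile()].
#' @return An object of class `read_record`: list with `read` (base string,
#'   possibly empty), `ref` (reference string), `events` (data.frame with
#'   `pos` = 1-based reference position, `type` in sub/ins/del, `ref_base`,
#'   `alt_base`) and `ref_length`.
#' @export
simulate_read <- function(ref, profile) {
  ref <- as_dna_seq(ref)
  chars <- strsplit(ref$bases, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  r <- rle(chars)
  in_run <- rep(r$lengths >= profile$hp_threshold, r$lengths)
  boost <- ifelse(in_run, profile$hp_indel_multiplier, 1)
  p_del <- pmin(profile$p_del * boost, 0.95)
  p_ins <- pmin(profile$p_ins * boost, 0.95)
  # keep the four outcomes a proper distribution even under boosting
  tot <- p_del + p_ins + profile$p_sub
  scale <- ifelse(tot >= 1, 0.999 / tot, 1)
  p_del <- p_del * scale
  p_ins <- p_ins * scale
  p_sub <- profile$p_sub * scale

  u <- runif(L)
  outcome <- ifelse(u < p_del, "del",
             ifelse(u < p_del + p_ins, "ins",
             ifelse(u < p_del + p_ins + p_sub, "sub", "match")))

  pieces <- chars
  ev_pos <- integer(0); ev_type <- character(0)
  ev_ref <- character(0); ev_alt <- character(0)

  idx_sub <- which(outcome == "sub")
  if (length(idx_sub)) {
    alts <- vapply(chars[idx_sub], function(b) {
      sample(setdiff(.BASES, b), 1L)
    }, character(1L))
    pieces[idx_sub] <- alts
    ev_pos <- c(ev_pos, idx_sub); ev_type <- c(ev_type, rep("sub", length(idx_sub)))
    ev_ref <- c(ev_ref, chars[idx_sub]); ev_alt <- c(ev_alt, alts)
  }
  idx_del <- which(outcome == "del")
  if (length(idx_del)) {
    pieces[idx_del] <- ""
    ev_pos <- c(ev_pos, idx_del); ev_type <- c(ev_type, rep("del", length(idx_del)))
    ev_ref <- c(ev_ref, chars[idx_del]); ev_alt <- c(ev_alt, rep(NA_character_, length(idx_del)))
  }
  idx_ins <- which(outcome == "ins")
  if (length(idx_ins)) {
    ins_bases <- sample(.BASES, length(idx_ins), replace = TRUE)
    pieces[idx_ins] <- paste0(ins_bases, pieces[idx_ins])
    ev_pos <- c(ev_pos, idx_ins); ev_type <- c(ev_type, rep("ins", length(idx_ins)))
    ev_ref <- c(ev_ref, rep(NA_character_, length(idx_ins))); ev_alt <- c(ev_alt, ins_bases)
  }

  ord <- order(ev_pos, match(ev_type, c("ins", "del", "sub")))
  events <- data.frame(pos = ev_pos[ord], type = ev_type[ord],
                       ref_base = ev_ref[ord], alt_base = ev_alt[ord],
                       stringsAsFactors = FALSE)
  structure(list(read = paste(pieces, collapse = ""), ref = ref$bases,
                 events = events, ref_length = L),
            class = "read_record")
}

#' Replay an event log against its reference
#'
#' Reconstructs the read from the reference and the ordered event list;
#' used to verify that event logs are complete.
#'
#' @param ref reference base string or [dna_seq()].
#' @param events event data.frame as produced by [simulate_read()].
#' @return the reconstructed read string.
#' @export
replay_events <- function(ref, events) {
  chars <- strsplit(as_dna_seq(ref)$bases, "", fixed = TRUE)[[1L]]
  pieces <- chars
  for (k in seq_len(nrow(events))) {
    p <- events$pos[k]
    switch(events$type[k],
      sub = { pieces[p] <- events$alt_base[k] },
      del = { pieces[p] <- "" },
      ins = { pieces[p] <- paste0(events$alt_base[k], pieces[p]) }
    )
  }
  paste(pieces, collapse = "")
}

#' Normalized edit distance between two sequences
#'
#' Levenshtein distance with unit costs divided by the longer length;
#' bounded in `[0, 1]`, zero iff the strings are equal. Two empty strings
#' give 0 by convention.
#'
#' @param ref,read base strings (or [dna_seq()]); empty strings allowed.
#' @return fraction in `[0, 1]`.
#' @export
#' @examples
#' normalized_edit_distance("ACGT", "AGT")  # 0.25
normalized_edit_distance <- function(ref, read) {
  a <- if (inherits(ref, "dna_seq")) ref$bases else ref
  b <- if (inherits(read, "dna_seq")) read$bases else read
  n <- max(nchar(a), nchar(b))
  if (n == 0L) return(0)
  as.integer(utils::adist(a, b)) / n
}

#' Decompose a minimal edit script into error-type counts
#'
#' Backtraces one minimal-cost Levenshtein alignment (tie-break: match >
#' substitution > deletion > insertion) and reports substitution, insertion
#' and deletion counts; the counts always sum to the edit distance. Rates
#' are per reference nucleotide.
#'
#' @inheritParams normalized_edit_distance
#' @return list with `n_sub`, `n_ins`, `n_del`, `distance` and `rates`
#'   (named numeric, counts / reference length).
#' @export
#' @examples
#' decompose_errors("AAAA", "AATA")$n_sub  # 1
decompose_errors <- function(ref, read) {
  a <- if (inherits(ref, "dna_seq")) ref$bases else ref
  b <- if (inherits(read, "dna_seq")) read$bases else read
  res <- .edit_ops_cpp(a, b)
  L <- nchar(a)
  rates <- if (L > 0) c(sub = res$n_sub, ins = res$n_ins, del = res$n_del) / L
           else c(sub = NA_real_, ins = NA_real_, del = NA_real_)
  c(res, list(rates = rates))
}

# run membership of each reference position (TRUE inside maximal runs of
# length >= min_run); pad = TRUE additionally marks positions adjacent
# (within 1 nt) to such a run.
.run_membership <- function(bases, min_run, pad = FALSE) {
  chars <- strsplit(bases, "", fixed = TRUE)[[1L]]
  r <- rle(chars)
  inr <- rep(r$lengths >= min_run, r$lengths)
  if (pad && any(inr)) {
    n <- length(inr)
    inr <- inr | c(FALSE, inr[-n]) | c(inr[-1L], FALSE)
  }
  inr
}

#' Homopolymer statistics over a set of reads
#'
#' @param records list of `read_record` objects (or plain base strings, in
#'   which case indel attribution is unavailable).
#' @param hp_min run length counted as a homopolymer region (default 3).
#' @return list with `avg_max_hp` (mean maximal run length per read),
#'   `avg_hp_count` (mean number of runs of length >= `hp_min`) and
#'   `hp_indel_pct` (% of indel events whose reference position lies in or
#'   within 1 nt of a reference run >= `hp_min`; `NA` if no indels or no
#'   event logs).
#' @export
homopolymer_stats <- function(records, hp_min = 3) {
  if (length(records) == 0L) stop("no reads supplied", call. = FALSE)
  reads <- vapply(records, function(r) {
    if (inherits(r, "read_record")) r$read else as.character(r)
  }, character(1L))
  per_read <- vapply(reads, function(s) {
    if (nchar(s) == 0L) return(c(0, 0))
    r <- rle(strsplit(s, "", fixed = TRUE)[[1L]])
    c(max(r$lengths), sum(r$lengths >= hp_min))
  }, numeric(2L))
  have_events <- all(vapply(records, inherits, logical(1L), "read_record"))
  hp_indel_pct <- NA_real_
  if (have_events) {
    n_indel <- 0L
    n_indel_hp <- 0L
    for (rec in records) {
      ev <- rec$events
      idx <- ev$type %in% c("ins", "del")
      if (!any(idx)) next
      inr <- .run_membership(rec$ref, hp_min, pad = TRUE)
      n_indel <- n_indel + sum(idx)
      n_indel_hp <- n_indel_hp + sum(inr[ev$pos[idx]])
    }
    if (n_indel > 0L) hp_indel_pct <- 100 * n_indel_hp / n_indel
  }
  list(avg_max_hp = mean(per_read[1L, ]),
       avg_hp_count = mean(per_read[2L, ]),
       hp_indel_pct = hp_indel_pct)
}

#' Context-dependent error summary over simulated reads
#'
#' Aggregates event logs into the per-regime report: mean normalized edit
#' distance, per-reference-nt event rates, transition-class substitution
#' percentages (GC to AT, AT to GC; same-class substitutions make up the
#' remainder) and homopolymer-context percentages. Percentages over zero
#' substitutions (or indels) are reported as `NA`, not 0.
#'
#' @param records list of `read_record` objects from [simulate_read()].
#' @param hp_min run length counted as homopolymer context (default 3).
#' @return An object of class `error_summary`: list with `ned`, `sub_rate`,
#'   `ins_rate`, `del_rate`, `gc_to_at_pct`, `at_to_gc_pct`, `hp_indel_pct`,
#'   `hp_sub_pct` and `n_reads`.
#' @export
context_error_summary <- function(records, hp_min = 3) {
  if (length(records) == 0L) stop("no read records supplied", call. = FALSE)
  stopifnot(all(vapply(records, inherits, logical(1L), "read_record")))
  n_sub <- n_ins <- n_del <- 0L
  gc_at <- at_gc <- hp_sub <- 0L
  total_ref <- 0L
  neds <- numeric(length(records))
  for (k in seq_along(records)) {
    rec <- records[[k]]
    neds[k] <- normalized_edit_distance(rec$ref, rec$read)
    total_ref <- total_ref + rec$ref_length
    ev <- rec$events
    if (nrow(ev) == 0L) next
    subs <- ev[ev$type == "sub", , drop = FALSE]
    n_sub <- n_sub + nrow(subs)
    n_ins <- n_ins + sum(ev$type == "ins")
    n_del <- n_del + sum(ev$type == "del")
    if (nrow(subs) > 0L) {
      gc_at <- gc_at + sum(subs$ref_base %in% c("G", "C") &
                             subs$alt_base %in% c("A", "T"))
      at_gc <- at_gc + sum(subs$ref_base %in% c("A", "T") &
                             subs$alt_base %in% c("G", "C"))
      inr <- .run_membership(rec$ref, hp_min, pad = FALSE)
      hp_sub <- hp_sub + sum(inr[subs$pos])
    }
  }
  hp <- homopolymer_stats(records, hp_min)
  structure(list(
    ned = mean(neds),
    sub_rate = n_sub / total_ref,
    ins_rate = n_ins / total_ref,
    del_rate = n_del / total_ref,
    gc_to_at_pct = if (n_sub > 0L) 100 * gc_at / n_sub else NA_real_,
    at_to_gc_pct = if (n_sub > 0L) 100 * at_gc / n_sub else NA_real_,
    hp_sub_pct = if (n_sub > 0L) 100 * hp_sub / n_sub else NA_real_,
    hp_indel_pct = hp$hp_indel_pct,
    avg_max_hp = hp$avg_max_hp,
    avg_hp_count = hp$avg_hp_count,
    n_reads = length(records)
  ), class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("<error_summary> %d reads | NED %.4f | rates sub %.4f ins %.4f del %.4f\n",
              x$n_reads, x$ned, x$sub_rate, x$ins_rate, x$del_rate))
  cat(sprintf("  GC->AT %.1f%% | AT->GC %.1f%% | HP indel %.1f%% | HP sub %.1f%%\n",
              x$gc_to_at_pct, x$at_to_gc_pct, x$hp_indel_pct, x$hp_sub_pct))
  invisible(x)
}

#' Stress-test a reference under an error regime
#'
#' Simulates `n_reads` noisy reads and returns the aggregated
#' [context_error_summary()].
#'
#' @param ref a [dna_seq()] or base string.
#' @param regime an [error_regime()] or regime name.
#' @param n_reads number of reads to simulate.
#' @param seed optional integer seed.
#' @param ... passed to [regime_profile()].
#' @return an `error_summary`.
#' @export
channel_report <- function(ref, regime, n_reads = 100, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  profile <- regime_profile(regime, ...)
  records <- replicate(n_reads, simulate_read(ref, profile), simplify = FALSE)
  context_error_summary(records)
}
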
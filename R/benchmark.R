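# Multi-run benchmark harness: repeated independent runs per algorithm with
# deterministic per-run seeds, aggregated summary tables (mean fitness and
# biophysical diagnostics), mean +/- sd convergence curves, optional channel
# stress tests of the per-algorithm best sequences, and Friedman / Wilcoxon
# comparisons of the per-run fitness matrix.

#' One-row biophysical summary of a designed sequence
#'
#' The benchmark table column set: fitness, GC%, Tm, total stacking energy,
#' maximal homopolymer run, RC similarity %, minimum Hamming distance.
#'
#' @param seq a [dna_seq()] or base string.
#' @param weights,constraints,thermo as in [total_fitness()].
#' @return one-row data.frame.
#' @export
design_summary <- function(seq, weights = fitness_weights(),
                           constraints = constraint_config(),
                           thermo = thermo_table()) {
  b <- total_fitness(seq, weights, constraints, thermo)
  data.frame(fitness = b$total, gc_percent = b$gc_percent, tm = b$tm,
             dg_sum = b$dg_sum, max_hp = b$max_hp,
             rc_percent = 100 * b$rc_ratio,
             min_hamming = ifelse(is.na(b$min_hamming), NA_integer_,
                                  b$min_hamming))
}

.make_optimizer <- function(algorithm, N, Tmax, seed) {
  algorithm <- tolower(algorithm)
  if (algorithm == "tchur") {
    function(L, weights, constraints, thermo) {
      tchur_optimize(L = L, weights = weights, constraints = constraints,
                     thermo = thermo,
                     control = tchur_config(N = N, Tmax = Tmax, seed = seed))
    }
  } else {
    function(L, weights, constraints, thermo) {
      run_baseline(baseline_config(algorithm, N = N, Tmax = Tmax, seed = seed),
                   L = L, weights = weights, constraints = constraints,
                   thermo = thermo)
    }
  }
}

#' Run a multi-run benchmark experiment
#'
#' Repeats each algorithm `runs` times with per-run seeds
#' `master_seed + run_index` (identical across algorithms, so runs are
#' paired for the signed-rank test), aggregates the per-run summaries, and
#' optionally writes per-run artifacts (trace CSV, best-sequence FASTA,
#' summary JSON) plus the aggregate tables to `outdir`. A failed run is
#' recorded with a warning and excluded from the aggregates, never silently
#' dropped. By default the Hamming constraint is active against one seeded
#' random reference sequence with `d_min = ceiling(0.75 * L)` (the expected
#' distance of a random pair).
#'
#' @param algorithms character vector from `"tchur"`, `"hgs"`, `"run"`,
#'   `"pso"`, `"gwo"`.
#' @param runs independent runs per algorithm (default 30).
#' @param L sequence length in nt (default 1853).
#' @param N,Tmax population size and iteration budget for every algorithm.
#' @param master_seed master seed; run `r` uses seed `master_seed + r`.
#' @param weights a [fitness_weights()].
#' @param constraints a [constraint_config()]; if its archive is empty a
#'   seeded random reference is installed as described above. Pass
#'   `hamming_reference = FALSE` to disable.
#' @param thermo a [thermo_table()].
#' @param regimes optional character vector of error regimes to stress-test
#'   each algorithm's best sequence under (e.g. `c("low","high")`).
#' @param n_reads reads per regime stress test.
#' @param hamming_reference install the seeded random Hamming reference?
#' @param outdir optional output directory for artifacts.
#' @return An object of class `tchur_experiment`: list with `table`
#'   (one row per algorithm), `fitness` (runs x algorithms matrix),
#'   `convergence` (long data.frame of mean +/- sd best fitness per
#'   iteration), `channel` (per-regime summaries or `NULL`), `runs_detail`
#'   and `failed`.
#' @export
run_experiment <- function(algorithms, runs = 30, L = 1853, N = 50,
                           Tmax = 100, master_seed = 1,
                           weights = fitness_weights(),
                           constraints = constraint_config(),
                           thermo = thermo_table(),
                           regimes = NULL, n_reads = 100,
                           hamming_reference = TRUE, outdir = NULL) {
  stopifnot(length(algorithms) >= 1L, runs >= 1L)
  algorithms <- tolower(algorithms)
  if (hamming_reference && length(constraints$archive) == 0L) {
    ref_digits <- local_seed(master_seed,
                             sample(0:3, L, replace = TRUE))
    constraints <- constraint_config(
      tm_range = constraints$tm_range,
      rc_threshold = constraints$rc_threshold,
      d_min = ceiling(0.75 * L),
      archive = list(dna_seq(digits_to_bases(ref_digits))),
      hp_limit = constraints$hp_limit
    )
  }
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }

  fitness <- matrix(NA_real_, nrow = runs, ncol = length(algorithms),
                    dimnames = list(NULL, algorithms))
  traces <- list()
  detail <- list()
  failed <- list()
  best_per_algo <- list()

  for (algo in algorithms) {
    best_fit <- Inf
    for (r in seq_len(runs)) {
      seed <- master_seed + r
      res <- tryCatch(
        .make_optimizer(algo, N, Tmax, seed)(L, weights, constraints, thermo),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        warning(sprintf("run failed (%s, run %d): %s", algo, r,
                        conditionMessage(res)), call. = FALSE)
        failed[[length(failed) + 1L]] <- list(algorithm = algo, run = r,
                                              message = conditionMessage(res))
        next
      }
      fitness[r, algo] <- res$breakdown$total
      traces[[paste(algo, r, sep = "_")]] <- res$trace$best_fitness
      detail[[length(detail) + 1L]] <- cbind(
        data.frame(algorithm = algo, run = r, seed = seed,
                   time_s = res$elapsed),
        design_summary(res$best, weights, constraints, thermo)
      )
      if (res$breakdown$total < best_fit) {
        best_fit <- res$breakdown$total
        best_per_algo[[algo]] <- res$best
      }
      if (!is.null(outdir)) {
        stem <- file.path(outdir, sprintf("%s_run%02d", algo, r))
        utils::write.csv(res$trace, paste0(stem, "_trace.csv"),
                         row.names = FALSE)
        write_fasta(list(res$best), paste0(stem, "_best.fasta"),
                    ids = sprintf("%s_run%02d", algo, r))
        jsonlite::write_json(c(unclass(res$breakdown),
                               list(algorithm = algo, run = r, seed = seed,
                                    time_s = res$elapsed)),
                             paste0(stem, "_summary.json"),
                             auto_unbox = TRUE, digits = NA, na = "null")
      }
    }
  }

  detail <- do.call(rbind, detail)
  agg <- do.call(rbind, lapply(algorithms, function(a) {
    d <- detail[detail$algorithm == a, , drop = FALSE]
    data.frame(algorithm = a,
               mean_fitness = mean(d$fitness),
               sd_fitness = if (nrow(d) > 1L) stats::sd(d$fitness) else 0,
               mean_time_s = mean(d$time_s),
               gc_percent = mean(d$gc_percent), tm = mean(d$tm),
               dg_sum = mean(d$dg_sum), max_hp = mean(d$max_hp),
               rc_percent = mean(d$rc_percent),
               min_hamming = mean(d$min_hamming),
               n_runs = nrow(d))
  }))

  convergence <- do.call(rbind, lapply(algorithms, function(a) {
    m <- do.call(cbind, traces[grep(paste0("^", a, "_"), names(traces))])
    data.frame(algorithm = a, iteration = seq_len(nrow(m)),
               mean_best = rowMeans(m),
               sd_best = apply(m, 1L, function(x) {
                 if (length(x) > 1L) stats::sd(x) else 0
               }))
  }))

  channel <- NULL
  if (!is.null(regimes)) {
    channel <- list()
    for (regime in regimes) {
      channel[[regime]] <- lapply(best_per_algo, function(s) {
        channel_report(s, regime, n_reads = n_reads,
                       seed = master_seed)
      })
    }
  }

  if (!is.null(outdir)) {
    utils::write.csv(agg, file.path(outdir, "results_table.csv"),
                     row.names = FALSE)
    utils::write.csv(convergence, file.path(outdir, "convergence.csv"),
                     row.names = FALSE)
  }

  structure(list(table = agg, fitness = fitness, convergence = convergence,
                 channel = channel, runs_detail = detail, failed = failed,
                 constraints = constraints),
            class = "tchur_experiment")
}

#' @export
print.tchur_experiment <- function(x, ...) {
  cat("<tchur_experiment>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Friedman and pairwise Wilcoxon comparison of algorithms
#'
#' Runs the Friedman rank test across algorithms (runs as blocks) and all
#' pairwise Wilcoxon signed-rank tests on the paired per-run fitness values.
#' P-values are reported unadjusted by default, with an optional Holm
#' correction.
#'
#' @param fitness runs x algorithms numeric matrix with column names (as
#'   produced by [run_experiment()]); no missing values, equal run counts.
#' @param holm apply Holm adjustment to the pairwise p-values?
#' @return list with `friedman` (htest), `pairwise` (data.frame a, b,
#'   p_value and optionally p_holm).
#' @export
compare_algorithms <- function(fitness, holm = FALSE) {
  fitness <- as.matrix(fitness)
  if (ncol(fitness) < 2L) stop("need at least two algorithms", call. = FALSE)
  if (anyNA(fitness)) {
    stop("unequal run counts across algorithms (missing values)", call. = FALSE)
  }
  fr <- stats::friedman.test(fitness)
  if (is.nan(fr$statistic)) {
    # complete ties in every block: no rank differences at all
    fr$statistic[] <- 0
    fr$p.value <- 1
  }
  pairs <- utils::combn(colnames(fitness), 2L)
  pw <- data.frame(a = pairs[1L, ], b = pairs[2L, ],
                   p_value = apply(pairs, 2L, function(p) {
                     stats::wilcox.test(fitness[, p[1L]], fitness[, p[2L]],
                                        paired = TRUE, exact = FALSE)$p.value
                   }))
  if (holm) pw$p_holm <- stats::p.adjust(pw$p_value, method = "holm")
  list(friedman = fr, pairwise = pw)
}
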
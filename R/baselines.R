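# Canonical baseline metaheuristics (PSO, GWO, HGS, RUN) sharing the
# biophysical fitness model and the trace/result contract of
# tchur_optimize(): continuous positions in [0,3]^L, round-half-up
# digitization for every fitness evaluation, elitist best-so-far trace with
# updates performed for t < Tmax only.

.BASELINE_DEFAULTS <- list(
  pso = list(c1 = 2.05, c2 = 2.05, w = 0.4),
  gwo = list(a_start = 2, a_end = 0),
  hgs = list(PUP = 0.08, LH = 10000),
  run = list(a = 20, f = 0.1)
)

#' Baseline optimizer configuration
#'
#' Published control parameters are the defaults: PSO `c1 = c2 = 2.05`,
#' `w = 0.4`; GWO `a` decreasing linearly 2 to 0; HGS `PUP = 0.08`,
#' `LH = 10000`; RUN `a = 20` (randomness control), `f = 0.1` (step-size
#' scaling).
#'
#' @param algorithm one of `"hgs"`, `"run"`, `"pso"`, `"gwo"`.
#' @param N population size.
#' @param Tmax total iterations.
#' @param seed optional integer seed.
#' @param parameters named list overriding the algorithm's defaults.
#' @return An object of class `baseline_config`.
#' @export
baseline_config <- function(algorithm, N = 50, Tmax = 100, seed = NULL,
                            parameters = list()) {
  algorithm <- tolower(algorithm)
  if (!algorithm %in% names(.BASELINE_DEFAULTS)) {
    stop("unknown algorithm: ", algorithm, call. = FALSE)
  }
  p <- utils::modifyList(.BASELINE_DEFAULTS[[algorithm]], parameters)
  structure(list(algorithm = algorithm, N = as.integer(N),
                 Tmax = as.integer(Tmax), seed = seed, parameters = p),
            class = "baseline_config")
}

#' Linear exploration schedule of grey wolf optimization
#'
#' @param t iteration in `[0, Tmax]`.
#' @param Tmax total iterations.
#' @param a_start,a_end endpoints of the linear decrease (default 2 to 0).
#' @return the control parameter `a` at iteration `t`.
#' @export
gwo_a <- function(t, Tmax, a_start = 2, a_end = 0) {
  a_start + (a_end - a_start) * t / Tmax
}

#' Run a baseline optimizer
#'
#' Same output contract as [tchur_optimize()]; positions are clipped and
#' digitized identically, the best-so-far trace is non-increasing, and a
#' seeded run is reproducible.
#'
#' @param cfg a [baseline_config()].
#' @param L sequence length in nt.
#' @param weights a [fitness_weights()].
#' @param constraints a [constraint_config()].
#' @param thermo a [thermo_table()].
#' @return An object of class `tchur_result` (with `algorithm` set to the
#'   baseline's name).
#' @export
#' @examples
#' res <- run_baseline(baseline_config("pso", N = 8, Tmax = 10, seed = 1), L = 24)
#' res$breakdown$total
run_baseline <- function(cfg, L, weights = fitness_weights(),
                         constraints = constraint_config(),
                         thermo = thermo_table()) {
  if (!inherits(cfg, "baseline_config")) stop("`cfg` must be a baseline_config")
  L <- as.integer(L)
  if (L < 2) stop("`L` must be >= 2", call. = FALSE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  arch <- lapply(constraints$archive, function(a) a$digits)
  fit_fun <- function(d) .fitness_digits(d, weights, constraints, thermo, arch)

  t0 <- proc.time()[["elapsed"]]
  N <- cfg$N
  Tmax <- cfg$Tmax
  p <- cfg$parameters
  pop <- matrix(runif(N * L, 0, 3), nrow = N)
  digits <- t(apply(pop, 1L, function(x) correct_bounds(x)$digits))
  if (N == 1L) digits <- matrix(digits, nrow = 1L)
  fitness <- apply(digits, 1L, fit_fun)
  b <- which.min(fitness)
  best_pos <- pop[b, ]
  best_dig <- digits[b, ]
  best_fit <- fitness[b]

  # algorithm-specific state
  if (cfg$algorithm == "pso") {
    vel <- matrix(0, nrow = N, ncol = L)
    pbest <- pop
    pbest_fit <- fitness
  }
  if (cfg$algorithm == "hgs") hungers <- numeric(N)

  trace_fit <- numeric(Tmax)
  for (t in seq_len(Tmax)) {
    trace_fit[t] <- best_fit
    if (t == Tmax) break

    if (cfg$algorithm == "pso") {
      for (i in seq_len(N)) {
        vel[i, ] <- p$w * vel[i, ] +
          p$c1 * runif(L) * (pbest[i, ] - pop[i, ]) +
          p$c2 * runif(L) * (best_pos - pop[i, ])
        pop[i, ] <- pmin(pmax(pop[i, ] + vel[i, ], 0), 3)
        digits[i, ] <- correct_bounds(pop[i, ])$digits
        fitness[i] <- fit_fun(digits[i, ])
        if (fitness[i] < pbest_fit[i]) {
          pbest[i, ] <- pop[i, ]
          pbest_fit[i] <- fitness[i]
        }
      }
    } else if (cfg$algorithm == "gwo") {
      a_t <- gwo_a(t, Tmax, p$a_start, p$a_end)
      lead <- order(fitness)[seq_len(min(3L, N))]
      leaders <- pop[lead, , drop = FALSE]
      for (i in seq_len(N)) {
        xnew <- numeric(L)
        for (k in seq_len(nrow(leaders))) {
          A <- 2 * a_t * runif(L) - a_t
          C <- 2 * runif(L)
          xnew <- xnew + leaders[k, ] - A * abs(C * leaders[k, ] - pop[i, ])
        }
        pop[i, ] <- pmin(pmax(xnew / nrow(leaders), 0), 3)
        digits[i, ] <- correct_bounds(pop[i, ])$digits
        fitness[i] <- fit_fun(digits[i, ])
      }
    } else if (cfg$algorithm == "hgs") {
      # original two-weight hunger model
      BF <- min(fitness)
      WF <- max(fitness)
      for (i in seq_len(N)) {
        if (fitness[i] == BF) {
          hungers[i] <- 0
        } else {
          TH <- (fitness[i] - BF) / (WF - BF + 1e-12) * runif(1) * 2 * 3
          H_new <- if (TH < p$LH) p$LH * (1 + runif(1)) else TH
          hungers[i] <- min(hungers[i] + H_new, p$LH)
        }
      }
      SH <- sum(hungers)
      a_t <- 2 * (1 - t / Tmax)
      E_all <- 1 / cosh(abs(fitness - best_fit))
      for (i in seq_len(N)) {
        W1 <- if (runif(1) < p$PUP) hungers[i] * N / (SH + 1e-12) * runif(1) else 1
        W2 <- (1 - exp(-abs(hungers[i] - SH))) * runif(1) * 2
        r1 <- runif(1)
        r2 <- runif(1)
        if (r1 < p$PUP) {
          xnew <- pop[i, ] * (1 + rnorm(L))
        } else {
          R <- runif(L, -a_t, a_t)
          xnew <- if (r2 > E_all[i]) {
            W1 * best_pos + R * W2 * abs(best_pos - pop[i, ])
          } else {
            W1 * best_pos - R * W2 * abs(best_pos - pop[i, ])
          }
        }
        pop[i, ] <- pmin(pmax(xnew, 0), 3)
        digits[i, ] <- correct_bounds(pop[i, ])$digits
        fitness[i] <- fit_fun(digits[i, ])
      }
    } else if (cfg$algorithm == "run") {
      # condensed RK4 search mechanism with enhanced solution quality (ESQ)
      h <- p$f * exp(-4 * t / Tmax)
      amp <- p$a / 20
      for (i in seq_len(N)) {
        if (runif(1) < 0.5 && N >= 2L) {
          others <- sample(setdiff(seq_len(N), i),
                           min(3L, N - 1L), replace = FALSE)
          xavg <- colMeans(pop[others, , drop = FALSE])
          beta <- runif(1)
          cand <- xavg + beta * (best_pos - xavg) + rnorm(L) * h
        } else {
          k1 <- best_pos - pop[i, ]
          k2 <- best_pos - (pop[i, ] + 0.5 * h * k1)
          k3 <- best_pos - (pop[i, ] + 0.5 * h * k2)
          k4 <- best_pos - (pop[i, ] + h * k3)
          SM <- (k1 + 2 * k2 + 2 * k3 + k4) / 6
          cand <- pop[i, ] + runif(L, 0, 2 * amp) * h * SM +
            rnorm(L) * h * amp
        }
        cand <- pmin(pmax(cand, 0), 3)
        cd <- correct_bounds(cand)$digits
        cf <- fit_fun(cd)
        if (cf < fitness[i]) {   # greedy selection as in canonical RUN
          pop[i, ] <- cand
          digits[i, ] <- cd
          fitness[i] <- cf
        }
      }
    }

    b <- which.min(fitness)
    if (fitness[b] < best_fit) {
      best_pos <- pop[b, ]
      best_dig <- digits[b, ]
      best_fit <- fitness[b]
    }
  }

  structure(list(
    best = dna_seq(digits_to_bases(best_dig)),
    breakdown = .breakdown_digits(best_dig, weights, constraints, thermo, arch),
    trace = data.frame(iteration = seq_len(Tmax), best_fitness = trace_fit,
                       phase = cfg$algorithm, stringsAsFactors = FALSE),
    best_position = best_pos,
    final_population = pop,
    algorithm = cfg$algorithm,
    elapsed = proc.time()[["elapsed"]] - t0
  ), class = "tchur_result")
}

#' Pure random search over digit sequences
#'
#' Evaluation-budget-matched sanity floor: draws `n_eval` random digit
#' sequences and returns the best.
#'
#' @param L sequence length in nt.
#' @param n_eval number of fitness evaluations.
#' @param weights,constraints,thermo as in [run_baseline()].
#' @param seed optional integer seed.
#' @return list with `best` ([dna_seq()]) and `best_fitness`.
#' @export
random_search <- function(L, n_eval, weights = fitness_weights(),
                          constraints = constraint_config(),
                          thermo = thermo_table(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  arch <- lapply(constraints$archive, function(a) a$digits)
  best_fit <- Inf
  best_dig <- NULL
  for (k in seq_len(n_eval)) {
    d <- sample(0:3, L, replace = TRUE)
    f <- .fitness_digits(d, weights, constraints, thermo, arch)
    if (f < best_fit) {
      best_fit <- f
      best_dig <- d
    }
  }
  list(best = dna_seq(digits_to_bases(best_dig)), best_fitness = best_fit)
}
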
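# TC-HUR: tri-phase hybrid optimizer over the continuous relaxation
# [0,3]^L of the nucleotide space. Phase 1 (t <= T_HGS) is hunger-driven
# global exploration with a heavy-tailed Cauchy jump around the incumbent
# best; phases 2+3 (t > T_HGS) run Runge-Kutta-style elite refinement
# together with adaptive targeted mutation of homopolymer and
# reverse-complement violations. Fitness is always evaluated on the
# digitized sequence; the continuous vector is optimizer-internal state.

#' TC-HUR control parameters
#'
#' Defaults follow the published configuration: population 50, 100
#' iterations, switching ratio 0.5, initial Cauchy intensity 0.015,
#' refinement coefficient 0.008 with exponential decay 3, mutation rate
#' ramping 2% to 5% over the exploitation half, elite fraction 30%, mutated
#' fraction 20%.
#'
#' @param N population size.
#' @param Tmax total iterations.
#' @param SR switching ratio; the exploration phase lasts `round(SR * Tmax)`
#'   iterations.
#' @param beta_start initial Cauchy jump intensity.
#' @param refine_coeff initial refinement step coefficient.
#' @param refine_decay exponential decay rate of the refinement coefficient.
#' @param mut_lo,mut_hi mutation-rate ramp endpoints.
#' @param elite_frac fraction of the population refined in phase 2.
#' @param mutation_frac fraction of the population mutated per phase-3
#'   iteration.
#' @param alpha_scale scale of the per-iteration hunger increment (only
#'   relative hunger matters, so the scale is benign).
#' @param LH hunger cap.
#' @param PUP canonical-HGS switching probability (kept for parity with the
#'   HGS baseline configuration).
#' @param w1,w2 diversity-weight coefficients.
#' @param a_start initial amplitude of the exploration vector R; the
#'   amplitude shrinks linearly to 0 over the exploration phase.
#' @param seed optional integer seed; a seeded run is bit-reproducible.
#' @return An object of class `tchur_config`.
#' @export
tchur_config <- function(N = 50, Tmax = 100, SR = 0.5, beta_start = 0.015,
                         refine_coeff = 0.008, refine_decay = 3.0,
                         mut_lo = 0.02, mut_hi = 0.05, elite_frac = 0.30,
                         mutation_frac = 0.20, alpha_scale = 1.0,
                         LH = 10000, PUP = 0.08, w1 = 1.0, w2 = 1.0,
                         a_start = 2.0, seed = NULL) {
  stopifnot(N >= 3, Tmax >= 1, SR > 0, SR < 1,
            elite_frac > 0, elite_frac <= 1,
            mutation_frac > 0, mutation_frac <= 1,
            mut_lo < mut_hi, beta_start > 0, refine_coeff > 0,
            refine_decay > 0, alpha_scale > 0, LH > 0, a_start > 0)
  structure(list(N = as.integer(N), Tmax = as.integer(Tmax), SR = SR,
                 beta_start = beta_start, refine_coeff = refine_coeff,
                 refine_decay = refine_decay, mut_lo = mut_lo,
                 mut_hi = mut_hi, elite_frac = elite_frac,
                 mutation_frac = mutation_frac, alpha_scale = alpha_scale,
                 LH = LH, PUP = PUP, w1 = w1, w2 = w2, a_start = a_start,
                 seed = seed),
            class = "tchur_config")
}

#' Hunger-memory update
#'
#' An individual that attains the current global best resets its hunger to
#' 0; every other individual accumulates `alpha`, capped at `LH`.
#'
#' @param hunger numeric vector of current hunger values.
#' @param fitness numeric vector of current fitness values.
#' @param best_fitness current global best fitness.
#' @param alpha hunger increment (scalar or per-individual vector).
#' @param LH hunger cap.
#' @return updated hunger vector.
#' @export
update_hunger <- function(hunger, fitness, best_fitness, alpha = 1,
                          LH = 10000) {
  out <- pmin(hunger + alpha, LH)
  out[fitness == best_fitness] <- 0
  out
}

#' Hunger sensitivity ratios
#'
#' Normalizes hunger values to a probability vector; an all-zero hunger
#' vector (every individual at the best) degenerates to the uniform
#' distribution.
#'
#' @param hungers non-negative numeric vector.
#' @return probability vector summing to 1.
#' @export
hunger_sensitivity <- function(hungers) {
  if (any(hungers < 0)) stop("hungers must be >= 0", call. = FALSE)
  s <- sum(hungers)
  if (s == 0) rep(1 / length(hungers), length(hungers)) else hungers / s
}

#' Convergence incentive factor
#'
#' `sech(|fitness_i - fitness_best|)`: 1 when the individual sits at the
#' best, decaying towards 0 as the gap grows, so exploitation pressure is
#' highest near the incumbent.
#'
#' @param fit_i individual fitness.
#' @param fit_best global best fitness.
#' @return value in (0, 1\].
#' @export
convergence_factor <- function(fit_i, fit_best) {
  1 / cosh(abs(fit_i - fit_best))
}

#' Index-adaptive diversity weight
#'
#' `w1 * exp(-(N - i) / N) + w2` for 0-based individual index `i`.
#'
#' @param i 0-based individual index in `[0, N]`.
#' @param N population size.
#' @param w1,w2 coefficients.
#' @return diversity weight.
#' @export
diversity_weight <- function(i, N, w1 = 1, w2 = 1) {
  w1 * exp(-(N - i) / N) + w2
}

#' Cauchy jump intensity schedule
#'
#' Linear decay `beta_start * (1 - t / T_hgs)` over the exploration phase.
#'
#' @param t iteration in `[0, T_hgs]`.
#' @param T_hgs length of the exploration phase.
#' @param beta_start initial intensity.
#' @return jump intensity.
#' @export
cauchy_beta <- function(t, T_hgs, beta_start = 0.015) {
  beta_start * (1 - t / T_hgs)
}

#' Refinement coefficient schedule
#'
#' `f0 * exp(-decay * t / Tmax)`, strictly decreasing so local steps shrink
#' as the run converges.
#'
#' @param t iteration in `[0, Tmax]`.
#' @param Tmax total iterations.
#' @param f0 initial coefficient.
#' @param decay exponential decay rate.
#' @return refinement coefficient.
#' @export
refine_coefficient <- function(t, Tmax, f0 = 0.008, decay = 3.0) {
  f0 * exp(-decay * t / Tmax)
}

#' Adaptive mutation-rate schedule
#'
#' Linear ramp from `mut_lo` to `mut_hi` across the exploitation half of the
#' run: `mut_lo + (mut_hi - mut_lo) * (t - SR*Tmax) / ((1 - SR)*Tmax)`.
#'
#' @param t iteration; must satisfy `t >= SR * Tmax`.
#' @param Tmax total iterations.
#' @param SR switching ratio.
#' @param mut_lo,mut_hi ramp endpoints.
#' @return mutation rate in `[mut_lo, mut_hi]`.
#' @export
mutation_rate <- function(t, Tmax, SR = 0.5, mut_lo = 0.02, mut_hi = 0.05) {
  t_switch <- SR * Tmax
  if (t < t_switch) {
    stop("mutation rate is defined only for the exploitation phase (t >= SR*Tmax)",
         call. = FALSE)
  }
  mut_lo + (mut_hi - mut_lo) * (t - t_switch) / (Tmax - t_switch)
}

#' Clip a continuous position to bounds and digitize it
#'
#' Positions are clipped to `[0, 3]`; digits are the round-half-up nearest
#' integers (1.5 digitizes to 2).
#'
#' @param position numeric vector (finite).
#' @return list with `position` (clipped) and `digits` (integers 0..3).
#' @export
correct_bounds <- function(position) {
  if (anyNA(position) || any(!is.finite(position))) {
    stop("position contains NA/NaN/Inf", call. = FALSE)
  }
  x <- pmin(pmax(position, 0), 3)
  list(position = x, digits = as.integer(pmin(floor(x + 0.5), 3)))
}

#' One hunger-games position update
#'
#' Draws `r1`, `r2` and the stochastic vectors internally. Branch 1
#' (`r1 < s_i`): self-perturbation `x * (1 + randn)`. Branch 2 (`r2 < E`):
#' move towards the best, `x_best + R * W * |x_best - x|` with `R` uniform
#' in `[-a, a]`. Branch 3: move between two random peers. The result is
#' clipped to `[0, 3]`.
#'
#' @param x current position.
#' @param x_best global best position.
#' @param x_r1,x_r2 positions of two distinct random peers.
#' @param s_i hunger sensitivity of the individual.
#' @param E convergence factor of the individual.
#' @param a amplitude of the exploration vector R.
#' @param W diversity weight of the individual.
#' @return clipped new position.
#' @export
hgs_step <- function(x, x_best, x_r1, x_r2, s_i, E, a, W) {
  L <- length(x)
  r1 <- runif(1)
  r2 <- runif(1)
  new <- if (r1 < s_i) {
    x * (1 + rnorm(L))
  } else if (r2 < E) {
    x_best + runif(L, -a, a) * W * abs(x_best - x)
  } else {
    x_r1 + runif(L, -a, a) * W * abs(x_r1 - x_r2)
  }
  pmin(pmax(new, 0), 3)
}

#' Heavy-tailed Cauchy jump around the best solution
#'
#' Adds per-dimension standard-Cauchy draws scaled by `beta` to the best
#' position and corrects bounds. The caller accepts the candidate only on
#' improvement (greedy elite update).
#'
#' @param x_best global best position.
#' @param beta jump intensity (see [cauchy_beta()]).
#' @return bound-corrected candidate position.
#' @export
cauchy_jump <- function(x_best, beta) {
  correct_bounds(x_best + rcauchy(length(x_best)) * beta)$position
}

#' Runge-Kutta-style elite refinement step
#'
#' `x_best + r * f_refine * (x_best - x_rand)` with `r` uniform per
#' dimension, bound-corrected; accepted greedily by the caller.
#'
#' @param x_best global best position.
#' @param x_rand position of a random individual.
#' @param f_refine refinement coefficient (see [refine_coefficient()]).
#' @return bound-corrected candidate position.
#' @export
rk_refine <- function(x_best, x_rand, f_refine) {
  correct_bounds(x_best + runif(length(x_best)) * f_refine *
                   (x_best - x_rand))$position
}

#' Targeted constraint-repair mutation
#'
#' Surgical mutation that touches only violating positions: bases inside
#' homopolymer runs longer than `hp_limit` and bases matching the complement
#' of their mirror position (reverse-complement self-similarity). Each
#' violating position is flipped with probability `rate` to a base that
#' breaks the violation. Homopolymer repairs additionally avoid the current
#' left and right neighbours, so a full pass at rate 1 cannot leave or
#' create any run above the limit.
#'
#' @param digits integer vector over 0..3.
#' @param rate per-position mutation probability in `[0, 1]`.
#' @param hp_limit maximal tolerated run length.
#' @return mutated digit vector.
#' @export
targeted_mutation <- function(digits, rate, hp_limit = 3) {
  stopifnot(rate >= 0, rate <= 1)
  d <- as.integer(digits)
  n <- length(d)
  if (rate == 0 || n == 0L) return(d)

  # reverse-complement repair first: flip matching positions to any base
  # that is not the complement of the (current) mirror base
  mirror <- n:1
  flagged <- which(d == .COMP_DIGIT[d[mirror] + 1L])
  if (length(flagged) > 0L) {
    hit <- flagged[runif(length(flagged)) < rate]
    for (i in hit) {
      forbidden <- .COMP_DIGIT[d[mirror[i]] + 1L]
      choices <- setdiff(0:3, forbidden)
      d[i] <- choices[sample.int(length(choices), 1L)]
    }
  }

  # homopolymer repair: left-to-right over runs above the limit; avoid the
  # run base and both current neighbours so no new violation can appear
  r <- rle(d)
  if (any(r$lengths > hp_limit)) {
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$lengths > hp_limit)) {
      for (i in starts[k]:ends[k]) {
        if (runif(1) >= rate) next
        forbidden <- r$values[k]
        if (i > 1L) forbidden <- c(forbidden, d[i - 1L])
        if (i < n) forbidden <- c(forbidden, d[i + 1L])
        choices <- setdiff(0:3, forbidden)
        d[i] <- choices[sample.int(length(choices), 1L)]
      }
    }
  }
  d
}

#' Run the TC-HUR optimizer
#'
#' Designs a nucleotide sequence of length `L` (or the length of `payload`)
#' minimizing the weighted biophysical penalty model. When a payload
#' sequence is supplied its encoding seeds one individual of the initial
#' population. Iteration `t` of the trace records the elitist best before
#' the update round of that iteration, so the trace is non-increasing by
#' construction and a 1-iteration budget returns the digitized best of the
#' initial population.
#'
#' @param L sequence length in nt (ignored when `payload` is given).
#' @param payload optional [dna_seq()] (or base string) whose length defines
#'   the problem and which seeds the initial population.
#' @param weights a [fitness_weights()].
#' @param constraints a [constraint_config()].
#' @param thermo a [thermo_table()].
#' @param control a [tchur_config()].
#' @return An object of class `tchur_result`: list with `best` (a
#'   [dna_seq()]), `breakdown` (a `fitness_breakdown`), `trace` (data.frame
#'   iteration/best_fitness/phase), `best_position`, `final_population`
#'   (N x L matrix of continuous positions) and `elapsed` seconds.
#' @export
#' @examples
#' res <- tchur_optimize(L = 24, control = tchur_config(N = 8, Tmax = 10, seed = 1))
#' res$breakdown$total
tchur_optimize <- function(L = NULL, payload = NULL,
                           weights = fitness_weights(),
                           constraints = constraint_config(),
                           thermo = thermo_table(),
                           control = tchur_config()) {
  cfg <- control
  if (!inherits(cfg, "tchur_config")) stop("`control` must be a tchur_config")
  if (!is.null(payload)) {
    payload <- as_dna_seq(payload)
    L <- payload$length
  }
  if (is.null(L) || L < 2) stop("provide `L` >= 2 or a payload", call. = FALSE)
  L <- as.integer(L)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  arch <- lapply(constraints$archive, function(a) a$digits)
  fit_fun <- function(d) .fitness_digits(d, weights, constraints, thermo, arch)

  t0 <- proc.time()[["elapsed"]]
  N <- cfg$N
  Tmax <- cfg$Tmax
  T_hgs <- max(1L, round(Tmax * cfg$SR))
  pop <- matrix(runif(N * L, 0, 3), nrow = N)
  if (!is.null(payload)) pop[1L, ] <- payload$digits
  digits <- t(apply(pop, 1L, function(x) correct_bounds(x)$digits))
  fitness <- apply(digits, 1L, fit_fun)
  hungers <- numeric(N)
  b <- which.min(fitness)
  best_pos <- pop[b, ]
  best_dig <- digits[b, ]
  best_fit <- fitness[b]
  W_all <- diversity_weight(seq_len(N) - 1L, N, cfg$w1, cfg$w2)

  trace_fit <- numeric(Tmax)
  trace_phase <- character(Tmax)
  n_elite <- max(1L, round(cfg$elite_frac * N))
  n_mut <- max(1L, round(cfg$mutation_frac * N))

  for (t in seq_len(Tmax)) {
    hgs_phase <- t <= T_hgs
    trace_fit[t] <- best_fit
    trace_phase[t] <- if (hgs_phase) "hgs" else "refine"
    if (t == Tmax) break

    if (hgs_phase) {
      alpha <- runif(N) * cfg$alpha_scale
      hungers <- update_hunger(hungers, fitness, min(fitness), alpha, cfg$LH)
      sens <- hunger_sensitivity(hungers)
      a_t <- cfg$a_start * (1 - t / T_hgs)
      for (i in seq_len(N)) {
        peers <- sample(setdiff(seq_len(N), i), 2L)
        E <- convergence_factor(fitness[i], best_fit)
        newx <- hgs_step(pop[i, ], best_pos, pop[peers[1L], ],
                         pop[peers[2L], ], sens[i], E, a_t, W_all[i])
        nd <- correct_bounds(newx)$digits
        pop[i, ] <- newx
        digits[i, ] <- nd
        fitness[i] <- fit_fun(nd)
      }
      beta <- cauchy_beta(t, T_hgs, cfg$beta_start)
      cand <- cauchy_jump(best_pos, beta)
      cd <- correct_bounds(cand)$digits
      cf <- fit_fun(cd)
      if (cf < best_fit) {
        best_pos <- cand
        best_dig <- cd
        best_fit <- cf
      }
    } else {
      elite <- order(fitness)[seq_len(n_elite)]
      fr <- refine_coefficient(t, Tmax, cfg$refine_coeff, cfg$refine_decay)
      for (i in elite) {
        xr <- pop[sample.int(N, 1L), ]
        cand <- rk_refine(best_pos, xr, fr)
        cd <- correct_bounds(cand)$digits
        cf <- fit_fun(cd)
        if (cf < fitness[i]) {
          pop[i, ] <- cand
          digits[i, ] <- cd
          fitness[i] <- cf
        }
      }
      rate <- mutation_rate(t, Tmax, cfg$SR, cfg$mut_lo, cfg$mut_hi)
      for (i in sample.int(N, n_mut)) {
        md <- targeted_mutation(digits[i, ], rate, constraints$hp_limit)
        pop[i, ] <- as.numeric(md)
        digits[i, ] <- md
        fitness[i] <- fit_fun(md)
      }
    }

    b <- which.min(fitness)
    if (fitness[b] < best_fit) {
      best_pos <- pop[b, ]
      best_dig <- digits[b, ]
      best_fit <- fitness[b]
    }
  }

  best_seq <- dna_seq(digits_to_bases(best_dig))
  structure(list(
    best = best_seq,
    breakdown = .breakdown_digits(best_dig, weights, constraints, thermo, arch),
    trace = data.frame(iteration = seq_len(Tmax), best_fitness = trace_fit,
                       phase = trace_phase, stringsAsFactors = FALSE),
    best_position = best_pos,
    final_population = pop,
    algorithm = "tchur",
    elapsed = proc.time()[["elapsed"]] - t0
  ), class = "tchur_result")
}

#' @export
print.tchur_result <- function(x, ...) {
  cat(sprintf("<tchur_result> %s | L = %d nt | best fitness %.4f (%d iterations)\n",
              x$algorithm, x$best$length, x$breakdown$total, nrow(x$trace)))
  invisible(x)
}
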
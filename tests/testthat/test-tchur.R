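test_that("hunger memory, sensitivity and convergence factor", {
  expect_equal(update_hunger(c(5, 3), c(1.0, 2.0), best_fitness = 1.0,
                             alpha = 1), c(0, 4))
  expect_equal(update_hunger(10000, 2, 1, alpha = 1, LH = 10000), 10000)

  expect_equal(hunger_sensitivity(c(0, 3, 1)), c(0, 0.75, 0.25))
  expect_equal(hunger_sensitivity(c(0, 0, 0)), rep(1 / 3, 3))
  set.seed(3)
  for (k in 1:20) {
    expect_equal(sum(hunger_sensitivity(runif(8, 0, 50))), 1)
  }
  expect_error(hunger_sensitivity(c(-1, 2)), ">= 0")

  expect_equal(convergence_factor(5, 5), 1)
  expect_equal(convergence_factor(1, 0), 2 / (exp(1) + exp(-1)),
               tolerance = 1e-12)
  expect_lt(convergence_factor(10, 0), convergence_factor(5, 0))
})

test_that("diversity weight follows the index-adaptive form", {
  expect_equal(diversity_weight(50, 50), 2)               # e^0 + 1
  expect_equal(diversity_weight(0, 50), exp(-1) + 1)
  expect_equal(diversity_weight(0:10, 10, w1 = 0, w2 = 3), rep(3, 11))
})

test_that("schedules hit their published endpoints exactly", {
  T_hgs <- 50
  Tmax <- 100
  expect_equal(cauchy_beta(0, T_hgs), 0.015, tolerance = 1e-12)
  expect_equal(cauchy_beta(T_hgs, T_hgs), 0, tolerance = 1e-12)
  expect_equal(cauchy_beta(T_hgs / 2, T_hgs), 0.0075, tolerance = 1e-12)

  expect_equal(refine_coefficient(0, Tmax), 0.008, tolerance = 1e-12)
  expect_equal(refine_coefficient(Tmax, Tmax), 0.008 * exp(-3),
               tolerance = 1e-12)
  fr <- refine_coefficient(0:100, Tmax)
  expect_true(all(diff(fr) < 0))

  expect_equal(mutation_rate(50, Tmax), 0.02, tolerance = 1e-12)
  expect_equal(mutation_rate(100, Tmax), 0.05, tolerance = 1e-12)
  expect_equal(mutation_rate(75, Tmax), 0.035, tolerance = 1e-12)
  expect_error(mutation_rate(40, Tmax), "exploitation")
})

test_that("bound correction clips and digitizes round-half-up", {
  expect_equal(correct_bounds(3.7), list(position = 3, digits = 3L))
  expect_equal(correct_bounds(-0.2), list(position = 0, digits = 0L))
  expect_equal(correct_bounds(1.5)$digits, 2L)
  expect_equal(correct_bounds(c(0.49, 0.5, 2.4999, 2.5))$digits,
               c(0L, 1L, 2L, 3L))
  expect_error(correct_bounds(c(1, NaN)), "NA")
})

test_that("stochastic operators stay in bounds and are reproducible", {
  set.seed(1234)
  L <- 20
  for (k in 1:4000) {
    x <- runif(L, 0, 3)
    xb <- runif(L, 0, 3)
    out <- hgs_step(x, xb, runif(L, 0, 3), runif(L, 0, 3),
                    s_i = runif(1), E = runif(1), a = runif(1, 0, 2),
                    W = runif(1, 1, 2))
    expect_true(all(out >= 0 & out <= 3))
  }
  for (k in 1:3000) {
    out <- cauchy_jump(runif(L, 0, 3), beta = runif(1, 0, 0.5))
    expect_true(all(out >= 0 & out <= 3))
  }
  for (k in 1:3000) {
    out <- rk_refine(runif(L, 0, 3), runif(L, 0, 3), f_refine = runif(1, 0, 1))
    expect_true(all(out >= 0 & out <= 3))
  }

  # degenerate amplitude: branch 2 lands exactly on the best position
  out <- hgs_step(rep(1, 5), rep(2.5, 5), rep(0, 5), rep(3, 5),
                  s_i = 0, E = 1, a = 0, W = 1.5)
  expect_equal(out, rep(2.5, 5))

  # seeded draws are byte-identical across fresh generators
  x <- seq(0, 3, length.out = 10)
  set.seed(77); a1 <- cauchy_jump(x, 0.01); b1 <- rk_refine(x, rev(x), 0.008)
  set.seed(77); a2 <- cauchy_jump(x, 0.01); b2 <- rk_refine(x, rev(x), 0.008)
  expect_identical(a1, a2)
  expect_identical(b1, b2)

  # zero-displacement refinement keeps the best unchanged
  expect_equal(rk_refine(x, x, 0.008), x)
})

test_that("targeted mutation repairs homopolymer and RC violations", {
  d <- dna_seq(strrep("A", 200))$digits
  set.seed(9)
  expect_identical(targeted_mutation(d, rate = 0), d)
  repaired <- targeted_mutation(d, rate = 1)
  expect_equal(tchur:::.hp_penalty_digits(repaired, 3L), 0)
  expect_true(all(repaired != 0L))  # every position left the A run

  # full palindrome: a full-rate pass strictly reduces RC self-similarity
  pal <- dna_seq("ACGTACGT")$digits
  expect_equal(tchur:::.rc_similarity_digits(pal), 1)
  set.seed(10)
  mut <- targeted_mutation(pal, rate = 1)
  expect_lt(tchur:::.rc_similarity_digits(mut), 1)

  # untouched positions: a clean sequence passes through unchanged at rate 1
  clean <- dna_seq("ATCATC")$digits   # no runs > 3, RC similarity 0
  expect_identical(targeted_mutation(clean, rate = 1), clean)
})

test_that("the optimizer is elitist, phase-correct and deterministic", {
  ctl <- tchur_config(N = 8, Tmax = 10, seed = 42)
  res <- tchur_optimize(L = 20, control = ctl)
  expect_equal(nrow(res$trace), 10L)
  expect_true(all(diff(res$trace$best_fitness) <= 0))
  expect_lte(res$breakdown$total, res$trace$best_fitness[1])
  expect_identical(res$trace$phase, rep(c("hgs", "refine"), each = 5L))
  expect_true(all(res$final_population >= 0 & res$final_population <= 3))

  res2 <- tchur_optimize(L = 20, control = ctl)
  expect_identical(res2$best$bases, res$best$bases)
  expect_identical(res2$trace$best_fitness, res$trace$best_fitness)

  # payload defines the length and seeds the initial population
  payload_seq <- text_to_dna(charToRaw("hello"))
  resp <- tchur_optimize(payload = payload_seq,
                         control = tchur_config(N = 6, Tmax = 6, seed = 5))
  expect_identical(resp$best$length, payload_seq$length)

  expect_error(tchur_optimize(L = 1), ">= 2")
  expect_error(tchur_config(SR = 1.2))
  expect_error(tchur_config(mut_lo = 0.1, mut_hi = 0.05))
})
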
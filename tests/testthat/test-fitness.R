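test_that("GC content and its quadratic penalty behave as worked examples", {
  expect_equal(gc_content("ATCG"), 50)
  expect_equal(gc_content("AAAA"), 0)
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_penalty("ATCG"), 0)
  expect_equal(gc_penalty("AAAA"), 2500)
  expect_equal((40.53 - 50)^2, 89.6809)  # GC deviation term at 40.53% GC
})

test_that("homopolymer runs and the cumulative penalty", {
  b <- homopolymer_blocks("AAAT")
  expect_equal(b$base, c("A", "T"))
  expect_equal(b$length, c(3L, 1L))
  expect_equal(nrow(homopolymer_blocks("ACGT")), 4L)
  expect_equal(homopolymer_blocks("AAAACCCCC")$length, c(4L, 5L))
  expect_equal(sum(homopolymer_blocks("AAAACCCCC")$length), 9L)

  expect_equal(hp_penalty("AAATTTCCC"), 0)
  expect_equal(hp_penalty("AAAAA"), 4)          # (5-3)^2
  expect_equal(hp_penalty("AAAACCCCC"), 5)      # (4-3)^2 + (5-3)^2
  # zero iff max run <= limit (property over random sequences)
  set.seed(31)
  for (k in 1:100) {
    s <- random_bases(40)
    maxrun <- max(homopolymer_blocks(s)$length)
    expect_identical(hp_penalty(s) == 0, maxrun <= 3)
  }
})

test_that("stacking free-energy penalty uses mean per-step deviation", {
  expect_equal(dg_penalty("ACGTACGT", uniform_thermo(-1.45)), 0)
  custom <- uniform_thermo(-0.88, target = -1.45)
  expect_equal(dg_penalty("AT", custom), 57)
  expect_equal(dg_penalty("ATAT", custom), 57)  # mean invariant to repetition
  expect_warning(p <- dg_penalty("A"), "dinucleotide")
  expect_equal(p, 0)
  expect_error(thermo_table(dg = c(AA = -1)), "16")
  # shipped table file matches the built-in defaults
  tsv <- system.file("extdata", "nn_dg37.tsv", package = "tchur")
  expect_equal(thermo_table(file = tsv)$dg, thermo_table()$dg)
})

test_that("melting temperature reproduces the published GC/Tm pairs", {
  gc <- c(40.53, 41.12, 41.77, 46.84)
  tm <- c(74.79, 75.04, 75.30, 77.38)
  expect_equal(round(tm_model(gc), 2), tm)
  expect_equal(tm_model(0), 58.176)
  # depends only on base counts: invariant under shuffling
  set.seed(17)
  s <- random_bases(60)
  chars <- strsplit(s, "")[[1]]
  for (k in 1:100) {
    sh <- paste(sample(chars), collapse = "")
    expect_identical(melting_temperature(sh), melting_temperature(s))
    expect_identical(gc_penalty(sh), gc_penalty(s))
  }
})

test_that("Tm range penalty is squared distance to the nearest bound", {
  cfg <- constraint_config()
  expect_equal(tchur:::.tm_penalty_value(60, cfg$tm_range), 0)
  expect_equal(tchur:::.tm_penalty_value(74.79, cfg$tm_range), (74.79 - 65)^2)
  expect_equal(tchur:::.tm_penalty_value(50, cfg$tm_range), 25)
})

test_that("Hamming penalty against an archive", {
  cfg <- constraint_config(d_min = 3, archive = list(dna_seq("TTTT")))
  h <- hamming_penalty("AAAA", cfg)
  expect_equal(h$min_distance, 4L)
  expect_equal(h$penalty, 0)

  cfg2 <- constraint_config(d_min = 3, archive = list(dna_seq("AAAA")))
  h2 <- hamming_penalty("AAAT", cfg2)
  expect_equal(h2$min_distance, 1L)
  expect_equal(h2$penalty, 4)   # (3-1)^2

  h3 <- hamming_penalty("AAAT", constraint_config(d_min = 3))
  expect_true(is.na(h3$min_distance))
  expect_equal(h3$penalty, 0)   # empty archive: single-sequence mode

  expect_error(hamming_penalty("AAATT", cfg2), "length")
})

test_that("reverse-complement similarity and its linear penalty", {
  expect_equal(rc_similarity("ACGT"), 1)    # ACGT is its own RC
  expect_equal(rc_similarity("AAAA"), 0)
  expect_equal(rc_similarity("AACT"), 0.5)
  # symmetric under taking the reverse complement
  revcomp <- function(s) {
    chartr("ATCG", "TAGC", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  set.seed(23)
  for (k in 1:50) {
    s <- random_bases(30)
    expect_equal(rc_similarity(s), rc_similarity(revcomp(s)))
  }
  cfg <- constraint_config()
  expect_equal(tchur:::.rc_penalty_value(0.10, cfg$rc_threshold), 0)
  expect_equal(tchur:::.rc_penalty_value(1.0, cfg$rc_threshold), 85)
  expect_equal(tchur:::.rc_penalty_value(0.1738, cfg$rc_threshold), 2.38)
})

test_that("total fitness is the weighted sum, zero iff all terms vanish", {
  # an ideal sequence under a config whose Tm window admits 50% GC
  cfg <- constraint_config(tm_range = c(70, 80))
  th <- uniform_thermo(-1.45)
  ideal <- total_fitness("ATCGATCGATCG", cfg = cfg, thermo = th)
  expect_equal(ideal$total, 0)
  expect_equal(unlist(ideal[c("f_gc", "f_hp", "f_dg", "c_tm", "c_ham", "c_rc")]),
               rep(0, 6), ignore_attr = TRUE)

  set.seed(41)
  w <- fitness_weights()
  w2 <- fitness_weights(2, 20, 2, 10, 2, 10)
  for (k in 1:25) {
    s <- random_bases(50)
    b <- total_fitness(s, w)
    terms <- unlist(b[c("f_gc", "f_hp", "f_dg", "c_tm", "c_ham", "c_rc")])
    expect_true(all(terms >= 0))
    expect_equal(b$total,
                 sum(terms * c(w$gc, w$hp, w$dg, w$tm, w$hamming, w$rc)))
    expect_equal(total_fitness(s, w2)$total, 2 * b$total)  # linear in weights
    expect_identical(b$total == 0, all(terms == 0))
    # fast scalar path agrees with the full breakdown
    expect_equal(tchur:::.fitness_digits(dna_seq(s)$digits, w,
                                         constraint_config(), thermo_table(),
                                         list()),
                 b$total)
  }
  expect_error(fitness_weights(0, 0, 0, 0, 0, 0), "positive")
  expect_error(fitness_weights(-1), "non-negative")
})
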
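test_that("error regimes map to channel probabilities monotonically", {
  expect_equal(error_regime("low")$central_cycles, 50)
  expect_equal(error_regime("medium")$central_cycles, 200)
  expect_equal(error_regime("high")$central_cycles, 500)
  expect_equal(error_regime("low")$cycle_range, c(10, 100))
  expect_equal(error_regime("high")$cycle_range, c(100, 1000))
  expect_error(error_regime("extreme"))

  lo <- regime_profile("low")
  hi <- regime_profile("high")
  expect_gte(hi$p_sub, lo$p_sub)
  expect_gte(hi$p_ins, lo$p_ins)
  expect_gte(hi$p_del, lo$p_del)
  expect_equal(hi$p_sub, 0.03)
  expect_equal(hi$p_ins, 0.08)
  expect_equal(hi$p_del, 0.02)

  expect_error(channel_profile(0.5, 0.4, 0.2), "sum below 1")
  expect_error(channel_profile(-0.1, 0, 0), "sum below 1|\\[0,1\\)")
})

test_that("simulated reads replay exactly from their event logs", {
  noiseless <- channel_profile(0, 0, 0)
  rec <- simulate_read("ACGTACGT", noiseless)
  expect_identical(rec$read, "ACGTACGT")
  expect_equal(nrow(rec$events), 0L)

  # deletion-dominated channel empties most of the read
  heavy_del <- channel_profile(0, 0, 0.99)
  set.seed(4)
  rec2 <- simulate_read(strrep("ACGT", 10), heavy_del)
  expect_equal(nchar(rec2$read), 40L - sum(rec2$events$type == "del"))

  set.seed(21)
  prof <- regime_profile("high")
  for (k in 1:40) {
    ref <- random_bases(120)
    rec <- simulate_read(ref, prof)
    expect_identical(replay_events(ref, rec$events), rec$read)
    # event counts match the log tallies and the decomposition sums to the
    # edit distance
    dec <- decompose_errors(ref, rec$read)
    expect_equal(dec$n_sub + dec$n_ins + dec$n_del, dec$distance)
  }
})

test_that("edit distance matches the recursive oracle and is a metric", {
  set.seed(8)
  for (k in 1:300) {
    a <- if (runif(1) < 0.1) "" else random_bases(sample(1:8, 1))
    b <- if (runif(1) < 0.1) "" else random_bases(sample(1:8, 1))
    d_oracle <- edit_distance_recursive(a, b)
    expect_equal(decompose_errors(a, b)$distance, d_oracle)
    n <- max(nchar(a), nchar(b), 1)
    expect_equal(normalized_edit_distance(a, b), d_oracle / n)
    expect_equal(normalized_edit_distance(a, b), normalized_edit_distance(b, a))
    expect_identical(normalized_edit_distance(a, b) == 0, a == b)
  }
  expect_equal(normalized_edit_distance("ACGT", "ACGT"), 0)
  expect_equal(normalized_edit_distance("ACGT", ""), 1)
  expect_equal(normalized_edit_distance("ACGT", "AGT"), 0.25)
  expect_equal(normalized_edit_distance("", ""), 0)
})

test_that("error decomposition identifies single-event types", {
  expect_equal(decompose_errors("AAAA", "AATA")[c("n_sub", "n_ins", "n_del")],
               list(n_sub = 1L, n_ins = 0L, n_del = 0L))
  expect_equal(decompose_errors("AAAA", "AAA")[c("n_sub", "n_ins", "n_del")],
               list(n_sub = 0L, n_ins = 0L, n_del = 1L))
  expect_equal(decompose_errors("AAAA", "AAAAA")[c("n_sub", "n_ins", "n_del")],
               list(n_sub = 0L, n_ins = 1L, n_del = 0L))
  expect_equal(decompose_errors("AAAA", "AATA")$rates[["sub"]], 0.25)
})

test_that("homopolymer statistics summarize reads correctly", {
  s <- homopolymer_stats(list("AAAACCGT"))
  expect_equal(s$avg_max_hp, 4)
  expect_equal(s$avg_hp_count, 1)
  expect_equal(homopolymer_stats(list("ACGT"))$avg_max_hp, 1)
  expect_equal(homopolymer_stats(list("ACGT"))$avg_hp_count, 0)
  two <- homopolymer_stats(list(strrep("A", 4), paste0(strrep("G", 6), "T")))
  expect_equal(two$avg_max_hp, 5)
  expect_error(homopolymer_stats(list()), "no reads")
})

test_that("context summary classifies substitutions and contexts", {
  r1 <- fake_record("ACGT", "ACAT", pos = 3L, type = "sub",
                    ref_base = "G", alt_base = "A")
  s1 <- context_error_summary(list(r1))
  expect_equal(s1$gc_to_at_pct, 100)
  expect_equal(s1$at_to_gc_pct, 0)

  r2 <- fake_record("ATCG", "GCCG", pos = c(1L, 2L), type = c("sub", "sub"),
                    ref_base = c("A", "T"), alt_base = c("G", "C"))
  s2 <- context_error_summary(list(r2))
  expect_equal(s2$at_to_gc_pct, 100)
  expect_equal(s2$gc_to_at_pct, 0)

  # substitution inside an AAAA run counts as homopolymer-context
  r3 <- fake_record("AAAAT", "AACAT", pos = 3L, type = "sub",
                    ref_base = "A", alt_base = "C")
  expect_equal(context_error_summary(list(r3))$hp_sub_pct, 100)

  # zero substitutions: percentages are NA, never 0
  r4 <- fake_record("ACGT", "ACG", pos = 4L, type = "del",
                    ref_base = "T", alt_base = NA_character_)
  s4 <- context_error_summary(list(r4))
  expect_true(is.na(s4$gc_to_at_pct))
  expect_true(is.na(s4$hp_sub_pct))
  expect_equal(s4$del_rate, 0.25)
})

test_that("homopolymer boosting raises indel rates on repetitive references", {
  prof <- channel_profile(0.01, 0.03, 0.01, hp_threshold = 4,
                          hp_indel_multiplier = 3)
  homo <- strrep("A", 200)
  hetero <- strrep("ACGT", 50)
  set.seed(33)
  n_indel <- function(ref) {
    sum(replicate(1000, {
      ev <- simulate_read(ref, prof)$events
      sum(ev$type %in% c("ins", "del"))
    }))
  }
  expect_gt(n_indel(homo), n_indel(hetero))
})
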
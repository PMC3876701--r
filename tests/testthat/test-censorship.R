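test_that("the measured fraction is sum(after)/sum(before), guarded", {
  before <- seq_multiset(c("AAA", "CCC"), c(600L, 400L))
  expect_equal(measure_fraction(before, before), 1)
  empty_after <- seq_multiset(c("AAA", "CCC"), c(0L, 0L))
  expect_equal(measure_fraction(before, empty_after), 0)
  after <- seq_multiset(c("AAA", "CCC"), c(540L, 360L))
  expect_equal(measure_fraction(before, after), 0.9)

  expect_error(measure_fraction(seq_multiset("AAA", 0L),
                                seq_multiset("AAA", 0L)), "empty")
  expect_error(measure_fraction(before,
                                seq_multiset(c("AAA", "CCC"), c(700L, 100L))),
               "cannot create")
  expect_error(measure_fraction(before, seq_multiset("GGG", 1L)), "absent")
})

test_that("bias factors follow the censorship rule on a worked example", {
  before <- seq_multiset(c("AAA", "CCC"), c(100L, 900L))
  after <- seq_multiset(c("AAA", "CCC"), c(45L, 855L))  # f = 0.9
  band <- make_band(before$sequences, before$counts,
                    lower = c(78L, 820L), upper = c(98L, 880L),
                    fraction = 0.9)
  bias <- detect_bias(before, after, band)
  expect_equal(as.character(bias$flags), c("censored_below", "within_band"))
  expect_equal(bias$bias, c(45 / (0.9 * 100), 1))
  expect_equal(bias$bias[1], 0.5)
})

test_that("flags cover low-copy, in-band, censored and enriched cases", {
  seqs <- c("AAA", "CCC", "GGG", "TTT")
  before <- seq_multiset(seqs, c(5L, 100L, 100L, 100L))
  after <- seq_multiset(seqs, c(0L, 90L, 40L, 99L))
  f <- measure_fraction(before, after)
  band <- make_band(seqs, before$counts,
                    lower = c(2L, 80L, 80L, 80L),
                    upper = c(5L, 95L, 95L, 95L),
                    fraction = f)
  bias <- detect_bias(before, after, band, low_copy_threshold = 10)
  expect_equal(as.character(bias$flags),
               c("undetermined_low_copy", "within_band", "censored_below",
                 "above_band"))
  expect_equal(bias$bias, c(1, 1, 40 / (f * 100), 1))
  # misaligned band is rejected
  expect_error(detect_bias(seq_multiset(rev(seqs), rev(before$counts)),
                           after, band), "aligned")
})

test_that("an unbiased filtering outcome stays within the band", {
  ramp <- ramp_multiset(200)
  f <- 0.9
  band <- confidence_interval(ramp, f, k = 5000, seed = 11)
  after <- seq_multiset(ramp$sequences, round(f * ramp$counts))
  # the measured fraction differs from 0.9 only by rounding
  bias <- suppressWarnings(detect_bias(ramp, after, band))
  eligible <- ramp$counts >= 10
  expect_true(all(bias$flags[eligible] == "within_band"))
  expect_true(all(bias$bias == 1))
})

test_that("false-positive rate under pure sampling stays below 1 - level", {
  # 200 replicate unbiased filterings: censored_below calls among eligible
  # sequences should not exceed the nominal miss rate of the band
  ramp <- ramp_multiset(100)
  f <- 0.9
  band <- confidence_interval(ramp, f, k = 10000, seed = 12)
  set.seed(13)
  eligible <- sum(ramp$counts >= 10)
  fp <- replicate(200, {
    after <- sample_multiset(ramp, f)
    sum(detect_bias(ramp, after, band)$flags == "censored_below")
  })
  expect_lte(mean(fp) / eligible, 1 - band$level)
})

test_that("bias detection is invariant under sequence permutation", {
  set.seed(14)
  seqs <- ramp_multiset(30)$sequences
  nb <- sample(20:200, 30, replace = TRUE)
  before <- seq_multiset(seqs, nb)
  f <- 0.9
  band <- confidence_interval(before, f, k = 3000, seed = 15)
  after_counts <- pmin(nb, round(f * nb) - sample(c(0L, 30L), 30, TRUE))
  after_counts <- pmax(after_counts, 0L)
  after <- seq_multiset(seqs, after_counts)
  bias <- suppressWarnings(detect_bias(before, after, band))

  perm <- sample(30)
  before_p <- seq_multiset(seqs[perm], nb[perm])
  band_p <- make_band(seqs[perm], nb[perm], band$lower[perm],
                      band$upper[perm], fraction = band$fraction)
  after_p <- seq_multiset(seqs[perm], after_counts[perm])
  bias_p <- suppressWarnings(detect_bias(before_p, after_p, band_p))
  expect_equal(as.character(bias_p$flags), as.character(bias$flags)[perm])
  expect_equal(bias_p$bias, bias$bias[perm])
})

test_that("the censored table ranks by severity with stable tie-breaks", {
  seqs <- c("AAACCC", "CCCAAA", "GGGTTT", "TTTGGG")
  before <- seq_multiset(seqs, c(1000L, 400L, 200L, 100L))
  after <- seq_multiset(seqs, c(100L, 40L, 20L, 85L))
  f <- measure_fraction(before, after)
  band <- make_band(seqs, before$counts,
                    lower = round(0.8 * f * before$counts),
                    upper = round(1.2 * f * before$counts),
                    fraction = f)
  bias <- detect_bias(before, after, band)
  tbl <- censored_table(bias)
  # the three censored rows share bias 0.1/f... ties broken by n_before desc
  expect_equal(tbl$sequence, c("AAACCC", "CCCAAA", "GGGTTT"))
  expect_equal(tbl$fold_loss, 1 / tbl$bias)
  expect_equal(tbl$peptide[1], translate_insert("AAACCC"))
  expect_equal(censored_table(bias, top_k = 2)$sequence,
               c("AAACCC", "CCCAAA"))

  none <- detect_bias(before, seq_multiset(seqs, round(f * before$counts)),
                      band)
  expect_equal(nrow(censored_table(none)), 0L)
})
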
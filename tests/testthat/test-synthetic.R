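test_that("copy-number laws produce the intended libraries", {
  ramp <- generate_library(synthetic_spec(1000, copy_law = "ramp",
                                          seed = 21))
  expect_equal(sum_total(ramp$multiset), 500500)
  expect_equal(uni_count(ramp$multiset), 1000L)
  expect_equal(nchar(ramp$multiset$sequences[1]), 21L)

  toy <- generate_library(synthetic_spec(4, copy_law = "explicit",
                                         counts = 1:4, seed = 22))
  expect_equal(sort(toy$multiset$counts), 1:4)

  wide <- generate_library(synthetic_spec(2000, copy_law = "log_uniform",
                                          min_count = 1, max_count = 1e6,
                                          seed = 23))
  counts <- wide$multiset$counts
  expect_gte(max(counts) / min(counts), 1e5)
})

test_that("generation round-trips exactly when nothing is degraded", {
  spec <- synthetic_spec(50, copy_law = "explicit", counts = rep(4L, 50),
                         background_fail_rate = 0, flawed_adapter_rate = 0,
                         seed = 24)
  lib <- generate_library(spec)
  fq <- withr::local_tempfile(fileext = ".fq")
  truth_csv <- withr::local_tempfile(fileext = ".csv")
  generate_fastq(lib, fq, truth_path = truth_csv)
  res <- ingest_fastq(fq, spec$adapter)
  expect_equal(res$report[["perfect_adapter"]], 200L)
  recovered <- filter_reads(res, filter_spec("min_phred",
                                             min_phred_cutoff = 13))
  ref <- lib$multiset
  ord <- order(ref$sequences)
  expect_identical(recovered$sequences, ref$sequences[ord])
  expect_identical(recovered$counts, ref$counts[ord])
  truth <- read.csv(truth_csv)
  expect_equal(nrow(truth), 50L)
  expect_true(all(truth$planted_B == 1))
})

test_that("flawed-adapter and background-failure rates are respected", {
  spec <- synthetic_spec(40, copy_law = "explicit", counts = rep(50L, 40),
                         background_fail_rate = 0.1,
                         flawed_adapter_rate = 0.2, seed = 25)
  lib <- generate_library(spec)
  fq <- withr::local_tempfile(fileext = ".fq")
  generate_fastq(lib, fq)
  res <- ingest_fastq(fq, spec$adapter)
  n <- res$report[["records"]]
  expect_equal(n, 2000L)
  flawed_rate <- res$report[["flawed_adapter"]] / n
  expect_lt(abs(flawed_rate - 0.2), 3 * sqrt(0.2 * 0.8 / n))

  # among ingested reads, min-Phred-13 filtering removes the background rate
  lib13 <- filter_reads(res, filter_spec("min_phred", min_phred_cutoff = 13))
  kept <- res$report[["perfect_adapter"]]
  surv <- sum_total(lib13) / kept
  expect_lt(abs(surv - 0.9), 3 * sqrt(0.1 * 0.9 / kept))
  # every generated read still passes the permissive min-Phred-1 filter
  lib1 <- filter_reads(res, filter_spec("min_phred", min_phred_cutoff = 1))
  expect_equal(sum_total(lib1), kept)
})

test_that("a planted censored sequence loses 1 - B of its reads", {
  spec <- synthetic_spec(1, copy_law = "explicit", counts = 100L,
                         n_censored = 1, censored_b_range = c(0.5, 0.5),
                         censored_count_range = c(10000, 10000),
                         background_fail_rate = 0, seed = 26)
  lib <- generate_library(spec)
  fq <- withr::local_tempfile(fileext = ".fq")
  generate_fastq(lib, fq)
  res <- ingest_fastq(fq, spec$adapter)
  lib13 <- filter_reads(res, filter_spec("min_phred", min_phred_cutoff = 13))
  cen_seq <- lib$truth$sequence[lib$truth$censored]
  after <- lib13$counts[match(cen_seq, lib13$sequences)]
  expect_lt(abs(after - 5000), 3 * sqrt(10000 * 0.25))
  # cluster positions are 3-4 sites within the 33-nt window
  pos <- as.integer(strsplit(
    lib$truth$cluster_positions[lib$truth$censored], ";")[[1]])
  expect_true(length(pos) %in% 3:4)
  expect_true(all(pos >= 1 & pos <= 33))
})

test_that("multiset-level filtering simulation matches the read model", {
  spec <- synthetic_spec(200, copy_law = "log_uniform", min_count = 10,
                         max_count = 1000, n_censored = 5,
                         background_fail_rate = 0.1, seed = 27)
  lib <- generate_library(spec)
  after <- simulate_quality_filtering(lib, seed = 28)
  expect_identical(after$sequences, lib$multiset$sequences)
  expect_true(all(after$counts <= lib$multiset$counts))
  # aggregate survival tracks the expected fraction
  expected <- sum(lib$multiset$counts * lib$truth$survival_prob)
  expect_lt(abs(sum_total(after) - expected),
            4 * sqrt(sum(lib$multiset$counts * 0.25)))
  # with no degradation at all the simulation is the identity
  clean <- generate_library(synthetic_spec(
    20, copy_law = "explicit", counts = rep(7L, 20),
    background_fail_rate = 0, seed = 29))
  expect_identical(simulate_quality_filtering(clean, seed = 30)$counts,
                   clean$multiset$counts)
})

test_that("planted censorship is recovered end-to-end from FASTQ reads", {
  # flagship integration test: generate reads with known censored
  # sequences, ingest, filter, build the sampling null and detect
  spec <- synthetic_spec(300, copy_law = "log_uniform", min_count = 1,
                         max_count = 300, n_censored = 10,
                         censored_b_range = c(0.05, 0.2),
                         censored_count_range = c(100, 1000),
                         background_fail_rate = 0.1, seed = 42)
  lib <- generate_library(spec)
  fq <- withr::local_tempfile(fileext = ".fq")
  generate_fastq(lib, fq)
  res <- ingest_fastq(fq, spec$adapter)
  before <- filter_reads(res, filter_spec("min_phred", min_phred_cutoff = 1))
  after <- filter_reads(res, filter_spec("min_phred", min_phred_cutoff = 13))
  f <- measure_fraction(before, after)
  band <- confidence_interval(before, f, k = 10000, seed = 43)
  bias <- detect_bias(before, after, band)

  truth_cen <- lib$truth$sequence[lib$truth$censored]
  flagged <- before$sequences[bias$flags == "censored_below"]
  expect_gte(sum(truth_cen %in% flagged), 9)
  unbiased_eligible <- setdiff(
    lib$truth$sequence[!lib$truth$censored & lib$truth$true_count >= 10],
    truth_cen)
  expect_equal(sum(flagged %in% unbiased_eligible), 0L)

  # the strongest planted censorship dominates the ranked table
  tbl <- censored_table(bias)
  expect_true(all(utils::head(tbl$sequence, 5) %in% truth_cen))
})
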
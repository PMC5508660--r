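test_that("Phred/error-probability conversions match the closed forms", {
  expect_identical(phred_to_error(0), 1)
  expect_identical(phred_to_error(10), 0.1)
  expect_identical(phred_to_error(20), 0.01)
  expect_equal(phred_to_error(33), 10^(-3.3), tolerance = 1e-12)
  expect_identical(error_to_phred(1), 0)
  expect_equal(error_to_phred(0.01), 20)
  expect_error(phred_to_error(-1), class = "tidyfastq_domain_error")
  expect_error(error_to_phred(0), class = "tidyfastq_domain_error")
  expect_error(error_to_phred(1.5), class = "tidyfastq_domain_error")
})

test_that("phred_to_error and error_to_phred are mutual inverses over Q in [0, 93]", {
  q <- seq(0, 93, by = 0.25)
  expect_lt(max(abs(error_to_phred(phred_to_error(q)) - q)), 1e-9)
  p <- phred_to_error(seq(0, 93))
  expect_lt(max(abs(phred_to_error(error_to_phred(p)) - p)), 1e-9)
  expect_true(all(diff(phred_to_error(q)) < 0)) # strictly decreasing
})

test_that("GC percent counts G/C case-insensitively over the full length", {
  expect_equal(gc_percent("GGCC"), 100)
  expect_equal(gc_percent("AATT"), 0)
  expect_equal(gc_percent("ACGTN"), 40) # ambiguous bases only in the denominator
  expect_equal(gc_percent("gcGC"), 100)
  expect_error(gc_percent(""), class = "tidyfastq_domain_error")
})

test_that("read_stats averages Phred scores and error probabilities separately", {
  # constant Q=40
  r <- fastq_tbl("r1", "ACGT", quality = const_qual(40, 4))
  s <- read_stats(r)
  expect_equal(s$mean_phred, 40)
  expect_equal(s$mean_error_prob, 1e-4)
  # Q = {10, 30}: mean error is (0.1 + 0.001)/2, not 10^(-2)
  r <- fastq_tbl("r2", "AC", quality = paste0(intToUtf8(10 + 33), intToUtf8(30 + 33)))
  s <- read_stats(r)
  expect_equal(s$mean_phred, 20)
  expect_equal(s$mean_error_prob, 0.0505)
  # single base
  r <- fastq_tbl("r3", "G", quality = const_qual(7, 1))
  s <- read_stats(r)
  expect_equal(s$length, 1L)
  expect_equal(s$gc_percent, 100)
  expect_equal(s$mean_phred, 7)
})

test_that("mean error probability dominates the error of the mean Phred (Jensen)", {
  sim <- simulate_fastq(500, seed = 21)
  s <- read_stats(sim$reads)
  expect_true(all(s$mean_error_prob >= phred_to_error(s$mean_phred) - 1e-12))
})

test_that("summarize_reads agrees exactly with a naive two-pass oracle", {
  sim <- simulate_fastq(1000, duplicate_rate = 0.05, n_rate = 0.05, seed = 13)
  smry <- summarize_reads(sim$reads)
  oracle <- oracle_summary(sim$reads)
  for (m in c("length", "gc_percent", "mean_phred", "mean_error_prob")) {
    row <- smry[smry$metric == m, ]
    expect_equal(row$min, oracle["min", m], tolerance = 1e-12)
    expect_equal(row$max, oracle["max", m], tolerance = 1e-12)
    expect_equal(row$avg, oracle["avg", m], tolerance = 1e-12)
  }
  expect_equal(attr(smry, "read_count"), 1000L)
})

test_that("summaries of degenerate read sets behave as documented", {
  empty <- fastq_tbl(character(), character(), character(), character())
  s0 <- summarize_reads(empty)
  expect_equal(attr(s0, "read_count"), 0L)
  expect_true(all(is.na(s0$min)))

  one <- fastq_tbl("r1", "ACGTT", quality = const_qual(30, 5))
  s1 <- summarize_reads(one)
  expect_equal(s1$min, s1$max)
  expect_equal(s1$min, s1$avg)

  sim <- simulate_fastq(200, seed = 5)
  s <- summarize_reads(sim$reads)
  expect_true(all(s$min <= s$avg & s$avg <= s$max))
})

test_that("render_summary prints both columns at fixed precision", {
  sim <- simulate_fastq(100, seed = 8)
  s <- summarize_reads(sim$reads)
  lines <- render_summary(s, s, file = textConnection(NULL, "w", local = TRUE))
  # identical tables render identical columns
  body <- lines[-1]
  cols <- do.call(rbind, strsplit(trimws(body), " {2,}"))
  expect_equal(cols[, 2], cols[, 3])
  expect_match(body[grepl("error probability", body)][1], "e-0?\\d")
  expect_match(body[grepl("avg read length", body)], "\\d+\\.\\d{2}")

  empty <- summarize_reads(fastq_tbl(character(), character(), character(), character()))
  lines <- render_summary(s, empty, file = textConnection(NULL, "w", local = TRUE))
  expect_true(all(grepl("NA$", lines[-1])))

  # tab-separated variant carries the same cells
  tsv <- render_summary(s, s, file = textConnection(NULL, "w", local = TRUE), format = "tsv")
  cells <- strsplit(tsv[-1], "\t", fixed = TRUE)
  expect_true(all(lengths(cells) == 3L))
  expect_equal(
    vapply(cells, `[[`, "", 2L),
    vapply(strsplit(trimws(body), " {2,}"), `[[`, "", 2L)
  )
})

test_that("quality filtering can only raise the rendered average Phred", {
  sim <- simulate_fastq(500, quality_start = 30, quality_sd = 6, seed = 17)
  kept <- filter_by_quality(sim$reads, 30)
  expect_gt(removed_count(kept), 0L) # threshold bites on this fixture
  before <- summarize_reads(sim$reads)
  after <- summarize_reads(kept)
  avg_of <- function(s, m) s$avg[s$metric == m]
  expect_gte(avg_of(after, "mean_phred"), avg_of(before, "mean_phred"))
  expect_gte(after$min[after$metric == "mean_phred"], 30)
})
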
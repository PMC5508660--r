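test_that("end trimming removes bases and qualities in lockstep", {
  r <- fastq_tbl("r1", "ACGTAC", quality = "IJKLMN")
  left <- trim_left(r, 2)
  expect_equal(left$sequence, "GTAC")
  expect_equal(left$quality, "KLMN")
  right <- trim_right(r, 2)
  expect_equal(right$sequence, "ACGT")
  expect_equal(right$quality, "IJKL")
  expect_equal(as.data.frame(trim_left(r, 0)), as.data.frame(r))
  # saturation: trimming past the end empties the record
  gone <- trim_left(r, 10)
  expect_equal(gone$sequence, "")
  expect_equal(gone$quality, "")
  expect_error(trim_left(r, -1), class = "tidyfastq_domain_error")
})

test_that("left and right trims commute on disjoint ends", {
  sim <- simulate_fastq(100, length_range = c(20L, 60L), seed = 31)
  a <- trim_right(trim_left(sim$reads, 5), 7)
  b <- trim_left(trim_right(sim$reads, 7), 5)
  expect_equal(as.data.frame(a), as.data.frame(b))
  expect_equal(nchar(a$sequence), nchar(sim$reads$sequence) - 12L)
  expect_equal(nchar(a$sequence), nchar(a$quality))
})

test_that("trimming 8 bases from each end shortens every read by exactly 16", {
  sim <- simulate_fastq(300, length_range = c(25L, 100L), seed = 42)
  out <- trim_right(trim_left(sim$reads, 8), 8)
  expect_equal(nchar(out$sequence), nchar(sim$reads$sequence) - 16L)
})

test_that("hamming distance counts mismatched positions case-insensitively", {
  expect_equal(hamming_distance("TAG", "AAG"), 1L)
  expect_equal(hamming_distance("TAG", "TAG"), 0L)
  expect_equal(hamming_distance("tag", "TAG"), 0L)
  expect_equal(hamming_distance("NAG", "TAG"), 1L) # N mismatches everything
  expect_error(hamming_distance("TA", "TAG"), class = "tidyfastq_domain_error")
  # distance distribution of all 64 3-mers against TAG: {0:1, 1:9, 2:27, 3:27}
  d <- hamming_distance(all_kmers(3), "TAG")
  expect_equal(unname(table(d)), array(c(1L, 9L, 27L, 27L)))
})

test_that("mismatch-variant enumeration matches its closed form and brute force", {
  v <- enumerate_mismatch_variants("TAG", 1)
  expect_length(v, 9L)
  expect_setequal(v, all_kmers(3)[hamming_distance(all_kmers(3), "TAG") == 1])
  expect_equal(enumerate_mismatch_variants("TAG", 0), "TAG")
  expect_length(enumerate_mismatch_variants("ACGT", 2), 54L) # C(4,2) * 3^2
  for (adapter in c("AC", "TAG", "ACGT", "GATTAC")) {
    len <- nchar(adapter)
    kmers <- all_kmers(len)
    for (k in seq_len(len - 1L)) {
      v <- enumerate_mismatch_variants(adapter, k)
      expect_length(v, choose(len, k) * 3^k)
      expect_setequal(v, kmers[hamming_distance(kmers, adapter) == k])
    }
  }
  expect_error(enumerate_mismatch_variants("TAG", 3), class = "tidyfastq_domain_error")
})

test_that("anchored adapter stripping follows the worked 3-base example", {
  r <- fastq_tbl("r1", "AAGCCCC", quality = "IIIIIII")
  out <- strip_adapter(r, "TAG", side = "left", max_mismatch = 1)
  expect_equal(out$sequence, "CCCC")
  expect_equal(out$quality, "IIII")
  expect_true(adapter_matched(out))

  out <- strip_adapter(
    fastq_tbl("r2", "GGGCCCC", quality = "IIIIIII"),
    "TAG",
    side = "left", max_mismatch = 1
  )
  expect_equal(out$sequence, "GGGCCCC")
  expect_false(adapter_matched(out))
})

test_that("the distance test and the enumeration oracle accept the same windows", {
  adapter <- "ACGT"
  kmers <- all_kmers(4)
  for (m in 0:2) {
    allowed <- unlist(lapply(0:m, function(j) enumerate_mismatch_variants(adapter, j)))
    reads <- fastq_tbl(kmers, paste0(kmers, "TTTTT"),
      quality = strrep("I", 9)
    )
    out <- strip_adapter(reads, adapter, side = "left", max_mismatch = m)
    expect_equal(adapter_matched(out), kmers %in% allowed)
  }
})

test_that("adapter stripping is anchored, single-shot and right-side symmetric", {
  # interior occurrence is not matched
  out <- strip_adapter(
    fastq_tbl("r", "CCTAGCC", quality = strrep("I", 7)),
    "TAG",
    side = "left"
  )
  expect_false(adapter_matched(out))
  # reads shorter than the adapter never match
  out <- strip_adapter(fastq_tbl("r", "TA", quality = "II"), "TAG", side = "left")
  expect_false(adapter_matched(out))
  # right side strips the terminal window with its qualities
  out <- strip_adapter(
    fastq_tbl("r", "CCCCTAG", quality = "IIIIJKL"),
    "TAG",
    side = "right"
  )
  expect_equal(out$sequence, "CCCC")
  expect_equal(out$quality, "IIII")
  # tandem copies are stripped once per invocation
  out <- strip_adapter(
    fastq_tbl("r", "TAGTAGCC", quality = strrep("I", 8)),
    "TAG",
    side = "left"
  )
  expect_equal(out$sequence, "TAGCC")
  expect_error(
    strip_adapter(fastq_tbl("r", "ACGT", quality = "IIII"), "TAG", max_mismatch = 3),
    class = "tidyfastq_domain_error"
  )
})

test_that("adapter stripping recovers exactly the planted reads at zero mismatches", {
  sim <- simulate_fastq(800,
    adapter = "ACGTACGGTT", adapter_fraction = 0.5,
    duplicate_rate = 0, n_rate = 0, seed = 71
  )
  out <- strip_adapter(sim$reads, "ACGTACGGTT", side = "left", max_mismatch = 0)
  expect_equal(adapter_matched(out), sim$manifest$has_adapter)
  expect_equal(mean(adapter_matched(out)), mean(sim$manifest$has_adapter))
  expect_equal(nchar(out$sequence), nchar(out$quality))
})
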
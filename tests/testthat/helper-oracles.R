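# Independent brute-force oracles: one read at a time, character-by-character,
# sharing no code with the implementation paths they check.

oracle_stats_one <- function(sequence, quality, offset) {
  s <- strsplit(sequence, "", fixed = TRUE)[[1]]
  q <- utf8ToInt(quality) - offset
  c(
    length = length(s),
    gc_percent = 100 * sum(s %in% c("G", "g", "C", "c")) / length(s),
    mean_phred = sum(q) / length(q),
    mean_error_prob = sum(10^(-q / 10)) / length(q)
  )
}

oracle_stats <- function(reads, offset = 33L) {
  do.call(rbind, lapply(seq_len(nrow(reads)), function(i) {
    oracle_stats_one(reads$sequence[[i]], reads$quality[[i]], offset)
  }))
}

# Two-pass naive summary: compute all per-read stats, then min/max/mean.
oracle_summary <- function(reads, offset = 33L) {
  m <- oracle_stats(reads, offset)
  apply(m, 2L, function(v) c(min = min(v), max = max(v), avg = mean(v)))
}

oracle_hamming <- function(a, b) {
  x <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  y <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  sum(x != y)
}

# All k-mers over ACGT, as a character vector of length 4^k.
all_kmers <- function(k) {
  grid <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), k))
  apply(grid, 1L, paste, collapse = "")
}

# Quality string with every base at the same integer Q (sanger offset).
const_qual <- function(q, len) strrep(intToUtf8(q + 33L), len)

tmp_fastq <- function(lines) {
  f <- withr::local_tempfile(fileext = ".fastq", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# Project a FASTQ tibble onto its record columns, dropping bookkeeping
# attributes, for record-identity comparisons.
records_of <- function(x) {
  data.frame(
    header = x$header, sequence = x$sequence,
    plus = x$plus, quality = x$quality
  )
}
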
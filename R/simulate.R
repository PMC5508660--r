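#' Simulate a FASTQ read set with planted ground truth
#'
#' Generates a seeded synthetic read set together with a manifest recording,
#' per read, exactly which features were planted -- so every filter and the
#' adapter matcher can be tested against known truth without external data.
#'
#' Reads are uniform-random A/C/G/T sequences with lengths drawn uniformly
#' from `length_range`. Per-base Phred scores follow a linear per-position
#' profile `quality_start + quality_slope * (position - 1)` with Gaussian
#' jitter (`quality_sd`), rounded and clamped to \[2, 40\]; the default
#' negative slope emulates the quality decay along real short reads. Planted
#' features:
#'
#' * duplicates: `round(duplicate_rate * n_reads)` reads are exact copies
#'   (sequence and quality) of earlier originals, appended after all
#'   originals with distinct headers, so "first occurrence kept" is
#'   unambiguous;
#' * ambiguous bases: a fraction `n_rate` of the originals get 1-3 positions
#'   replaced by `N` (copies inherit their original's bases, so a duplicated
#'   N-read stays an exact duplicate);
#' * adapter: when `adapter` is given, a fraction `adapter_fraction` of the
#'   originals get the adapter prepended (`adapter_side = "left"`) or appended
#'   (`"right"`), with profile-drawn quality characters, so stripping it
#'   recovers the original read exactly.
#'
#' Base sequences are drawn until all originals are distinct, so the
#' manifest's `duplicate_of` column is the complete duplication truth.
#'
#' @param n_reads Total number of reads (originals + duplicate copies).
#' @param length_range Two integers, inclusive read-length bounds.
#' @param quality_start,quality_slope,quality_sd Per-position quality profile:
#'   mean Phred at position 1, change per position, and Gaussian spread.
#' @param duplicate_rate Fraction of reads that are planted duplicate copies.
#' @param n_rate Fraction of original reads carrying at least one `N`.
#' @param adapter Optional adapter sequence over A/C/G/T to plant.
#' @param adapter_side `"left"` or `"right"`.
#' @param adapter_fraction Fraction of originals carrying the adapter.
#' @param encoding Quality encoding used for the quality strings.
#' @param seed Integer seed; identical arguments and seed give identical output.
#' @return A list with elements `reads` (FASTQ tibble) and `manifest` (tibble
#'   with columns `header`, `length`, `duplicate_of` (`NA` or the original's
#'   header), `has_n`, `has_adapter`, `true_mean_q`).
#' @examples
#' sim <- simulate_fastq(50, duplicate_rate = 0.1, seed = 7)
#' sum(!is.na(sim$manifest$duplicate_of)) # 5 planted copies
#' @export
simulate_fastq <- function(n_reads,
                           length_range = c(25L, 100L),
                           quality_start = 38,
                           quality_slope = -0.1,
                           quality_sd = 3,
                           duplicate_rate = 0,
                           n_rate = 0,
                           adapter = NULL,
                           adapter_side = c("left", "right"),
                           adapter_fraction = 0.5,
                           encoding = "sanger",
                           seed = 1L) {
  adapter_side <- rlang::arg_match(adapter_side)
  stopifnot(
    n_reads >= 0, length(length_range) == 2L, length_range[[1]] >= 1L,
    length_range[[1]] <= length_range[[2]],
    duplicate_rate >= 0, duplicate_rate <= 1,
    n_rate >= 0, n_rate <= 1,
    adapter_fraction >= 0, adapter_fraction <= 1
  )
  if (!is.null(adapter) && grepl("[^ACGTacgt]", adapter)) {
    rlang::abort("`adapter` must be over A/C/G/T.", class = "tidyfastq_domain_error")
  }
  n_dup <- round(duplicate_rate * n_reads)
  if (duplicate_rate > 0 && n_reads < 2L) {
    rlang::abort("Cannot plant duplicates with fewer than 2 reads.",
      class = "tidyfastq_domain_error"
    )
  }
  n_orig <- n_reads - n_dup
  enc <- quality_encoding(encoding)

  empty <- fastq_tbl(character(), character(), character(), character())
  if (n_reads == 0L) {
    return(list(
      reads = empty,
      manifest = tibble::tibble(
        header = character(), length = integer(), duplicate_of = character(),
        has_n = logical(), has_adapter = logical(), true_mean_q = double()
      )
    ))
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()),
    add = TRUE
  )
  set.seed(seed)

  bases <- c("A", "C", "G", "T")
  profile_q <- function(len, from = 1L) {
    mu <- quality_start + quality_slope * (seq.int(from, length.out = len) - 1)
    pmin(pmax(round(mu + stats::rnorm(len, sd = quality_sd)), 2L), 40L)
  }
  rand_seq <- function(len) paste(sample(bases, len, replace = TRUE), collapse = "")

  lens <- sample(seq.int(length_range[[1]], length_range[[2]]), n_orig, replace = TRUE)
  seqs <- vapply(lens, rand_seq, character(1))
  # Re-draw colliding originals so the planted duplication truth is exact.
  while (anyDuplicated(toupper(seqs)) > 0L) {
    i <- which(duplicated(toupper(seqs)))
    seqs[i] <- vapply(lens[i], rand_seq, character(1))
  }

  has_n <- logical(n_orig)
  if (n_rate > 0 && n_orig > 0L) {
    idx_n <- sample(n_orig, round(n_rate * n_orig))
    for (i in idx_n) {
      pos <- sample(lens[[i]], min(sample(3L, 1L), lens[[i]]))
      s <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
      s[pos] <- "N"
      seqs[[i]] <- paste(s, collapse = "")
    }
    has_n[idx_n] <- TRUE
  }

  qvals <- lapply(lens, profile_q)

  has_adapter <- logical(n_orig)
  if (!is.null(adapter) && n_orig > 0L) {
    idx_a <- sample(n_orig, round(adapter_fraction * n_orig))
    ak <- nchar(adapter)
    for (i in idx_a) {
      aq <- profile_q(ak)
      if (adapter_side == "left") {
        seqs[[i]] <- paste0(adapter, seqs[[i]])
        qvals[[i]] <- c(aq, qvals[[i]])
      } else {
        seqs[[i]] <- paste0(seqs[[i]], adapter)
        qvals[[i]] <- c(qvals[[i]], aq)
      }
    }
    has_adapter[idx_a] <- TRUE
  }

  headers <- sprintf("sim_%06d", seq_len(n_orig))
  quals <- vapply(qvals, encode_phred, character(1), encoding = enc)

  dup_src <- if (n_dup > 0L) sample(n_orig, n_dup, replace = TRUE) else integer()
  reads <- fastq_tbl(
    header = c(headers, sprintf("%s_dup%d", headers[dup_src], seq_len(n_dup))),
    sequence = c(seqs, seqs[dup_src]),
    plus = "",
    quality = c(quals, quals[dup_src])
  )
  manifest <- tibble::tibble(
    header = reads$header,
    length = nchar(reads$sequence),
    duplicate_of = c(rep(NA_character_, n_orig), headers[dup_src]),
    has_n = c(has_n, has_n[dup_src]),
    has_adapter = c(has_adapter, has_adapter[dup_src]),
    true_mean_q = vapply(c(qvals, qvals[dup_src]), mean, numeric(1))
  )
  list(reads = reads, manifest = manifest)
}

#' Write a simulated read set and its manifest to disk
#'
#' Convenience wrapper: writes the reads as FASTQ and the manifest as
#' tab-separated text next to it.
#'
#' @param sim A list from [simulate_fastq()].
#' @param path Output FASTQ path; the manifest goes to `paste0(path, ".manifest.tsv")`.
#' @return `path`, invisibly.
#' @export
write_simulated_fastq <- function(sim, path) {
  write_fastq(sim$reads, path)
  utils::write.table(sim$manifest, paste0(path, ".manifest.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
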
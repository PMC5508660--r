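#' Trim a fixed number of bases from read ends
#'
#' Removes `n` bases (and the matching quality characters, so sequence and
#' quality stay in lockstep) from the left or right end of every read. Trimming
#' more than a read's length leaves an empty record; the pipeline drops and
#' counts such reads.
#'
#' @param reads A FASTQ tibble.
#' @param n Number of bases to remove (>= 0).
#' @return The trimmed FASTQ tibble, headers and plus lines unchanged.
#' @examples
#' r <- fastq_tbl("r1", "ACGTAC", quality = "IIIIII")
#' trim_left(r, 2)$sequence # "GTAC"
#' trim_right(r, 2)$sequence # "ACGT"
#' @export
trim_left <- function(reads, n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0) {
    rlang::abort("`n` must be a single number >= 0.", class = "tidyfastq_domain_error")
  }
  validate_fastq(reads, allow_empty = TRUE)
  reads$sequence <- substring(reads$sequence, n + 1L)
  reads$quality <- substring(reads$quality, n + 1L)
  reads
}

#' @rdname trim_left
#' @export
trim_right <- function(reads, n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0) {
    rlang::abort("`n` must be a single number >= 0.", class = "tidyfastq_domain_error")
  }
  validate_fastq(reads, allow_empty = TRUE)
  keep <- pmax(nchar(reads$sequence) - n, 0L)
  reads$sequence <- substr(reads$sequence, 1L, keep)
  reads$quality <- substr(reads$quality, 1L, keep)
  reads
}

# Hamming distance of each string in `x` to the single string `y`,
# case-insensitive; all elements of `x` must have nchar(y) characters.
hamming_to <- function(x, y) {
  x <- toupper(x)
  y <- toupper(y)
  d <- integer(length(x))
  for (i in seq_len(nchar(y))) {
    d <- d + (substring(x, i, i) != substring(y, i, i))
  }
  d
}

#' Hamming distance between equal-length sequences
#'
#' Counts mismatched positions, case-insensitively. Vectorised over pairs.
#'
#' @param a,b Character vectors (recycled to common length); each pair must
#'   have equal length.
#' @return Integer vector of mismatch counts.
#' @examples
#' hamming_distance("TAG", "AAG") # 1
#' @export
hamming_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  if (any(nchar(a) != nchar(b))) {
    rlang::abort("Hamming distance requires equal-length sequences.",
      class = "tidyfastq_domain_error"
    )
  }
  au <- strsplit(toupper(a), "", fixed = TRUE)
  bu <- strsplit(toupper(b), "", fixed = TRUE)
  as.integer(mapply(function(x, y) sum(x != y), au, bu))
}

#' Enumerate all sequences at an exact Hamming distance from an adapter
#'
#' All sequences over A/C/G/T at distance exactly `k` from `adapter`; there
#' are choose(len, k) * 3^k of them. With a 3-base adapter and `k = 1` that is
#' 9 variants, so a 1-mismatch matcher accepts 10 distinct starts in total.
#'
#' @param adapter Adapter sequence over A/C/G/T.
#' @param k Exact mismatch count, `0 <= k < nchar(adapter)`.
#' @return Character vector of distinct variant sequences (uppercase).
#' @examples
#' length(enumerate_mismatch_variants("TAG", 1)) # 9
#' @export
enumerate_mismatch_variants <- function(adapter, k) {
  adapter <- toupper(adapter)
  len <- nchar(adapter)
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k >= len) {
    rlang::abort("`k` must satisfy 0 <= k < nchar(adapter).",
      class = "tidyfastq_domain_error"
    )
  }
  k <- as.integer(k)
  if (k == 0L) {
    return(adapter)
  }
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(adapter, "", fixed = TRUE)[[1]]
  pos_sets <- utils::combn(len, k, simplify = FALSE)
  out <- purrr::map(pos_sets, function(pos) {
    alts <- purrr::map(pos, function(p) setdiff(bases, chars[[p]]))
    grid <- expand.grid(alts, stringsAsFactors = FALSE)
    apply(grid, 1L, function(subs) {
      v <- chars
      v[pos] <- subs
      paste(v, collapse = "")
    })
  })
  unique(unlist(out))
}

#' Strip an anchored adapter from read ends
#'
#' Tests the adapter once against the terminal window of each read -- the
#' first `nchar(adapter)` bases for `side = "left"`, the last for
#' `side = "right"` -- and removes that window (sequence and quality) when its
#' Hamming distance to the adapter is at most `max_mismatch`. Matching is
#' anchored: interior occurrences and partial overhangs are never matched.
#' Reads shorter than the adapter are left unchanged. `N` in a read counts as
#' a mismatch to every adapter base.
#'
#' @param reads A FASTQ tibble.
#' @param adapter Adapter sequence over A/C/G/T (non-empty).
#' @param side `"left"` or `"right"`.
#' @param max_mismatch Mismatch budget, `0 <= max_mismatch < nchar(adapter)`.
#' @return The FASTQ tibble with matched windows removed; attribute `matched`
#'   (logical per input read, see [adapter_matched()]) records which reads
#'   carried the adapter.
#' @examples
#' r <- fastq_tbl("r1", "AAGCCCC", quality = "IIIIIII")
#' out <- strip_adapter(r, "TAG", side = "left", max_mismatch = 1)
#' out$sequence # "CCCC"
#' adapter_matched(out) # TRUE
#' @export
strip_adapter <- function(reads, adapter, side = c("left", "right"), max_mismatch = 0L) {
  side <- rlang::arg_match(side)
  if (!is.character(adapter) || length(adapter) != 1L || nchar(adapter) == 0L ||
    grepl("[^ACGTacgt]", adapter)) {
    rlang::abort("`adapter` must be a non-empty sequence over A/C/G/T.",
      class = "tidyfastq_domain_error"
    )
  }
  k <- nchar(adapter)
  if (!is.numeric(max_mismatch) || max_mismatch < 0 || max_mismatch >= k) {
    rlang::abort("`max_mismatch` must satisfy 0 <= max_mismatch < nchar(adapter).",
      class = "tidyfastq_domain_error"
    )
  }
  validate_fastq(reads, allow_empty = TRUE)
  len <- nchar(reads$sequence)
  eligible <- len >= k
  window <- if (side == "left") {
    substr(reads$sequence, 1L, k)
  } else {
    substring(reads$sequence, len - k + 1L)
  }
  dist <- rep.int(k + 1L, nrow(reads))
  if (any(eligible)) {
    dist[eligible] <- hamming_to(window[eligible], adapter)
  }
  matched <- eligible & dist <= max_mismatch
  if (side == "left") {
    reads$sequence[matched] <- substring(reads$sequence[matched], k + 1L)
    reads$quality[matched] <- substring(reads$quality[matched], k + 1L)
  } else {
    reads$sequence[matched] <- substr(reads$sequence[matched], 1L, len[matched] - k)
    reads$quality[matched] <- substr(reads$quality[matched], 1L, len[matched] - k)
  }
  attr(reads, "matched") <- matched
  reads
}

#' Which reads matched the adapter in the last [strip_adapter()] call
#'
#' @param reads The tibble returned by [strip_adapter()].
#' @return Logical vector, one element per input read.
#' @export
adapter_matched <- function(reads) {
  m <- attr(reads, "matched")
  if (is.null(m)) logical(nrow(reads)) else m
}
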
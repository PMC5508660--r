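#' @name filters
#' @title Read-level filters
#'
#' @description
#' Each filter keeps the records that satisfy its predicate, in input order,
#' and records how many it removed (retrievable with [removed_count()]).
#' Thresholds follow "below removes": a read exactly at the threshold is kept.
#'
#' * `filter_by_quality()` keeps reads whose mean per-base Phred score is
#'   >= `min_q`.
#' * `filter_by_length()` keeps reads of length >= `min_len`.
#' * `remove_duplicates()` keeps the first occurrence of every distinct
#'   sequence (case-insensitive; header and quality are ignored for identity).
#' * `remove_ambiguous()` keeps reads whose sequence is entirely A/C/G/T
#'   (case-insensitive); any other character (N, IUPAC codes, gaps) removes
#'   the read.
#'
#' @param reads A FASTQ tibble.
#' @param min_q Minimum mean Phred score (>= 0).
#' @param min_len Minimum read length (>= 1).
#' @param encoding Quality encoding for decoding `quality` strings.
#' @param seen For `remove_duplicates()`: an optional environment carrying
#'   sequences already observed, letting the streaming pipeline deduplicate
#'   across chunks. Ignored in ordinary in-memory use.
#' @return The kept reads as a FASTQ tibble, with attributes `removed`
#'   (integer count) and `filter` (the filter's name).
#' @examples
#' reads <- fastq_tbl(c("a", "b"), c("ACGT", "ACGTN"), quality = c("IIII", "IIIII"))
#' kept <- remove_ambiguous(reads)
#' nrow(kept) # 1
#' removed_count(kept) # 1
NULL

filter_outcome <- function(reads, keep, name) {
  out <- reads[keep, , drop = FALSE]
  attr(out, "removed") <- sum(!keep)
  attr(out, "filter") <- name
  class(out) <- unique(c("fastq_tbl", class(out)))
  out
}

#' Number of reads removed by the last filter
#'
#' @param reads The tibble returned by one of the [filters].
#' @return Integer count (0 if the tibble carries no filter bookkeeping).
#' @export
removed_count <- function(reads) {
  n <- attr(reads, "removed")
  if (is.null(n)) 0L else as.integer(n)
}

#' @rdname filters
#' @export
filter_by_quality <- function(reads, min_q, encoding = "sanger") {
  if (!is.numeric(min_q) || min_q < 0) {
    rlang::abort("`min_q` must be >= 0.", class = "tidyfastq_domain_error")
  }
  validate_fastq(reads)
  mean_q <- vapply(decode_phred(reads$quality, encoding), mean, numeric(1))
  filter_outcome(reads, mean_q >= min_q, "quality")
}

#' @rdname filters
#' @export
filter_by_length <- function(reads, min_len) {
  if (!is.numeric(min_len) || min_len < 1) {
    rlang::abort("`min_len` must be >= 1.", class = "tidyfastq_domain_error")
  }
  validate_fastq(reads)
  filter_outcome(reads, nchar(reads$sequence) >= min_len, "length")
}

#' @rdname filters
#' @export
remove_duplicates <- function(reads, seen = NULL) {
  validate_fastq(reads)
  key <- toupper(reads$sequence)
  if (is.null(seen)) {
    keep <- !duplicated(key)
  } else {
    keep <- logical(nrow(reads))
    for (i in seq_along(key)) {
      if (!exists(key[[i]], envir = seen, inherits = FALSE)) {
        assign(key[[i]], TRUE, envir = seen)
        keep[[i]] <- TRUE
      }
    }
  }
  filter_outcome(reads, keep, "duplicate")
}

#' @rdname filters
#' @export
remove_ambiguous <- function(reads) {
  validate_fastq(reads)
  keep <- !grepl("[^ACGTacgt]", reads$sequence)
  filter_outcome(reads, keep, "ambiguous")
}
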
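#' Construct a tibble of FASTQ records
#'
#' The package-wide representation of a read set is a tibble with one row per
#' record and columns `header` (identifier line content after `@`), `sequence`,
#' `plus` (content after `+`, usually empty, preserved verbatim) and `quality`.
#' Every user-facing function takes and returns this shape, so steps chain with
#' the pipe.
#'
#' @param header,sequence,quality Character vectors of equal length.
#' @param plus Character vector (recycled); text after the `+` separator.
#'
#' @return A tibble with class `fastq_tbl` prepended.
#' @examples
#' fastq_tbl("r1", "ACGT", quality = "IIII")
#' @export
fastq_tbl <- function(header, sequence, plus = "", quality) {
  out <- tibble::tibble(
    header = as.character(header),
    sequence = as.character(sequence),
    plus = as.character(plus),
    quality = as.character(quality)
  )
  validate_fastq(out)
}

#' Validate a FASTQ tibble
#'
#' Checks the record invariants: required columns present, sequences non-empty,
#' sequence and quality of equal length, and (when `encoding` is given) every
#' quality character decoding to Phred >= 0.
#'
#' @param reads A FASTQ tibble (see [fastq_tbl()]).
#' @param encoding Optional quality encoding; when supplied, quality strings
#'   are checked against its offset.
#' @param allow_empty Allow zero-length sequences (used transiently inside the
#'   pipeline after trimming; ingest never allows them).
#' @return `reads`, invisibly classed as `fastq_tbl`.
#' @export
validate_fastq <- function(reads, encoding = NULL, allow_empty = FALSE) {
  need <- c("header", "sequence", "plus", "quality")
  missing_cols <- setdiff(need, names(reads))
  if (length(missing_cols) > 0L) {
    rlang::abort(
      paste0("Not a FASTQ tibble: missing column(s) ", toString(missing_cols), "."),
      class = "tidyfastq_parse_error"
    )
  }
  ns <- nchar(reads$sequence)
  nq <- nchar(reads$quality)
  bad_len <- which(ns != nq)
  if (length(bad_len) > 0L) {
    rlang::abort(
      sprintf(
        "Record %d ('%s'): sequence length %d != quality length %d.",
        bad_len[[1]], reads$header[[bad_len[[1]]]], ns[[bad_len[[1]]]], nq[[bad_len[[1]]]]
      ),
      class = "tidyfastq_parse_error"
    )
  }
  if (!allow_empty && any(ns == 0L)) {
    rlang::abort(
      sprintf("Record %d: empty sequence.", which(ns == 0L)[[1]]),
      class = "tidyfastq_parse_error"
    )
  }
  if (!is.null(encoding)) {
    decode_phred(reads$quality, encoding)
  }
  if (!inherits(reads, "fastq_tbl")) {
    class(reads) <- c("fastq_tbl", class(reads))
  }
  invisible(reads)
}

open_seq_connection <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

# Parse 4-line groups into a record tibble; `offset` is the 0-based count of
# records already consumed (for 1-based indices in error messages).
parse_fastq_lines <- function(lines, offset, enc) {
  n <- length(lines)
  if (n %% 4L != 0L) {
    rlang::abort(
      sprintf("Truncated FASTQ: record %d is incomplete (%d trailing line(s)).",
        offset + n %/% 4L + 1L, n %% 4L
      ),
      class = "tidyfastq_parse_error"
    )
  }
  idx <- seq.int(1L, n, by = 4L)
  h <- lines[idx]
  s <- lines[idx + 1L]
  p <- lines[idx + 2L]
  q <- lines[idx + 3L]

  bad <- which(!startsWith(h, "@"))
  if (length(bad) > 0L) {
    rlang::abort(
      sprintf("Record %d: identifier line does not start with '@'.", offset + bad[[1]]),
      class = "tidyfastq_parse_error"
    )
  }
  bad <- which(!startsWith(p, "+"))
  if (length(bad) > 0L) {
    rlang::abort(
      sprintf("Record %d: separator line does not start with '+'.", offset + bad[[1]]),
      class = "tidyfastq_parse_error"
    )
  }
  ns <- nchar(s)
  bad <- which(ns != nchar(q))
  if (length(bad) > 0L) {
    rlang::abort(
      sprintf(
        "Record %d: sequence length %d != quality length %d.",
        offset + bad[[1]], ns[[bad[[1]]]], nchar(q)[[bad[[1]]]]
      ),
      class = "tidyfastq_parse_error"
    )
  }
  bad <- which(ns == 0L)
  if (length(bad) > 0L) {
    rlang::abort(
      sprintf("Record %d: empty sequence.", offset + bad[[1]]),
      class = "tidyfastq_parse_error"
    )
  }
  # Encoding check: any character below the offset means the other encoding.
  too_low <- vapply(q, function(x) min(utf8ToInt(x)) < enc$offset, logical(1), USE.NAMES = FALSE)
  if (any(too_low)) {
    i <- which(too_low)[[1]]
    codes <- utf8ToInt(q[[i]])
    other <- if (enc$name == "sanger") "illumina" else "sanger"
    rlang::abort(
      sprintf(
        paste0(
          "Record %d: quality character '%s' is below the '%s' offset %d ",
          "(decodes to Phred %d). Did you mean encoding = \"%s\"?"
        ),
        offset + i, intToUtf8(min(codes)), enc$name, enc$offset,
        min(codes) - enc$offset, other
      ),
      class = "tidyfastq_encoding_error"
    )
  }
  out <- tibble::tibble(
    header = substring(h, 2L),
    sequence = s,
    plus = substring(p, 2L),
    quality = q
  )
  class(out) <- c("fastq_tbl", class(out))
  out
}

#' Stream a FASTQ file chunk by chunk
#'
#' The streaming engine behind [read_fastq()] and [run_pipeline()]: records are
#' parsed in chunks of `chunk_size` and handed to `f`, so peak memory is bounded
#' by the chunk size, not the file size. Handles gzip input (`.gz` suffix) and
#' CRLF line endings.
#'
#' @param path Path to a FASTQ file (optionally gzip-compressed).
#' @param f Function called as `f(chunk, first_index)` where `chunk` is a FASTQ
#'   tibble and `first_index` the 1-based index of its first record.
#' @inheritParams decode_phred
#' @param chunk_size Records per chunk.
#' @return The total record count, invisibly.
#' @export
fastq_chunk_apply <- function(path, f, encoding = "sanger", chunk_size = 10000L) {
  enc <- quality_encoding(encoding)
  con <- open_seq_connection(path, "r")
  on.exit(close(con), add = TRUE)
  done <- 0L
  repeat {
    lines <- readLines(con, n = 4L * chunk_size, warn = FALSE)
    if (length(lines) == 0L) break
    lines <- sub("\r$", "", lines)
    chunk <- parse_fastq_lines(lines, offset = done, enc = enc)
    f(chunk, done + 1L)
    done <- done + nrow(chunk)
    if (length(lines) < 4L * chunk_size) break
  }
  invisible(done)
}

#' Read a FASTQ file into a tibble
#'
#' Parses 4-line FASTQ records under an explicit quality encoding. Malformed
#' input (missing `@`/`+`, sequence/quality length mismatch, truncated final
#' record) raises a parse error naming the 1-based record index; a quality
#' character below the encoding's offset raises an encoding error suggesting
#' the other encoding. For files too large to hold in memory use
#' [fastq_chunk_apply()] or [run_pipeline()], which stream.
#'
#' @inheritParams fastq_chunk_apply
#' @param n_max Maximum number of records to read.
#' @return A FASTQ tibble (columns `header`, `sequence`, `plus`, `quality`).
#' @examples
#' f <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), f)
#' read_fastq(f)
#' @export
read_fastq <- function(path, encoding = "sanger", n_max = Inf) {
  chunks <- list()
  chunk_size <- if (is.finite(n_max)) max(1L, as.integer(min(n_max, 10000))) else 10000L
  fastq_chunk_apply(path, function(chunk, first) {
    if (length(chunks) * chunk_size < n_max) {
      chunks[[length(chunks) + 1L]] <<- chunk
    }
  }, encoding = encoding, chunk_size = chunk_size)
  out <- if (length(chunks) == 0L) {
    fastq_tbl(character(), character(), character(), character())
  } else {
    dplyr::bind_rows(chunks)
  }
  if (is.finite(n_max) && nrow(out) > n_max) {
    out <- out[seq_len(n_max), ]
  }
  class(out) <- unique(c("fastq_tbl", class(out)))
  out
}

fastq_record_lines <- function(reads) {
  as.vector(rbind(
    paste0("@", reads$header),
    reads$sequence,
    paste0("+", reads$plus),
    reads$quality
  ))
}

#' Write a FASTQ tibble to a file
#'
#' Emits 4-line records with UNIX newlines; the `plus` column is written
#' verbatim after `+`, so a read/write cycle is a byte-level round trip.
#' A `.gz` suffix triggers gzip compression.
#'
#' @inheritParams validate_fastq
#' @param path Output path.
#' @param append Append to an existing file (used by the streaming pipeline).
#' @return The number of records written, invisibly.
#' @export
write_fastq <- function(reads, path, append = FALSE) {
  validate_fastq(reads, allow_empty = TRUE)
  con <- open_seq_connection(path, if (append) "ab" else "wb")
  on.exit(close(con), add = TRUE)
  if (nrow(reads) > 0L) {
    writeLines(fastq_record_lines(reads), con, sep = "\n")
  }
  invisible(nrow(reads))
}

#' Write reads as FASTA
#'
#' Each record becomes exactly two lines: `>` + header, then the unwrapped
#' sequence. Quality data and the plus line are discarded.
#'
#' @inheritParams write_fastq
#' @return The number of records written, invisibly.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' write_fasta(fastq_tbl("r1", "ACGT", quality = "IIII"), f)
#' readLines(f) # ">r1" "ACGT"
#' @export
write_fasta <- function(reads, path, append = FALSE) {
  validate_fastq(reads, allow_empty = TRUE)
  con <- open_seq_connection(path, if (append) "ab" else "wb")
  on.exit(close(con), add = TRUE)
  if (nrow(reads) > 0L) {
    writeLines(as.vector(rbind(paste0(">", reads$header), reads$sequence)), con, sep = "\n")
  }
  invisible(nrow(reads))
}
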
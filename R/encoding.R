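#' Quality-score encodings
#'
#' FASTQ stores one printable ASCII character per base; the character's code
#' minus a fixed offset is the integer Phred score Q. Two offsets are in common
#' use: 33 ("sanger", also modern Illumina) and 64 (legacy Illumina). The
#' encoding is always chosen explicitly -- there is no auto-detection.
#'
#' @param encoding Either `"sanger"`, `"illumina"`, or an existing
#'   `quality_encoding` object (returned unchanged).
#'
#' @return A `quality_encoding` object: a list with elements `name`, `offset`
#'   (33 or 64) and `max_q`, the largest Phred score representable by a
#'   printable character (93 for sanger, 62 for illumina).
#' @examples
#' quality_encoding("sanger")$offset   # 33
#' quality_encoding("illumina")$max_q  # 62
#' @export
quality_encoding <- function(encoding = c("sanger", "illumina")) {
  if (inherits(encoding, "quality_encoding")) {
    return(encoding)
  }
  if (!is.character(encoding)) {
    rlang::abort("`encoding` must be \"sanger\", \"illumina\" or a quality_encoding object.",
      class = "tidyfastq_encoding_error"
    )
  }
  name <- rlang::arg_match0(tolower(encoding[[1]]), c("sanger", "illumina"),
    arg_nm = "encoding"
  )
  offset <- if (name == "sanger") 33L else 64L
  structure(
    list(name = name, offset = offset, max_q = 126L - offset),
    class = "quality_encoding"
  )
}

#' @export
print.quality_encoding <- function(x, ...) {
  cat(sprintf(
    "<quality_encoding> %s (ASCII offset %d, Q range 0..%d)\n",
    x$name, x$offset, x$max_q
  ))
  invisible(x)
}

#' Decode quality strings to integer Phred scores
#'
#' @param quality Character vector of FASTQ quality strings.
#' @param encoding Quality encoding (see [quality_encoding()]).
#'
#' @return A list of integer vectors, one per input string, each the per-base
#'   Phred scores.
#' @examples
#' decode_phred("II5", "sanger")[[1]] # 40 40 20
#' @export
decode_phred <- function(quality, encoding = "sanger") {
  enc <- quality_encoding(encoding)
  out <- lapply(quality, function(q) utf8ToInt(q) - enc$offset)
  bad <- vapply(out, function(q) length(q) > 0L && min(q) < 0L, logical(1))
  if (any(bad)) {
    other <- if (enc$name == "sanger") "illumina" else "sanger"
    i <- which(bad)[[1]]
    rlang::abort(
      sprintf(
        paste0(
          "Quality character %s (record %d) decodes below Phred 0 under the ",
          "'%s' encoding (offset %d). Is the file '%s'-encoded?"
        ),
        deparse(substr(quality[[i]], which.min(out[[i]]), which.min(out[[i]]))),
        i, enc$name, enc$offset, other
      ),
      class = "tidyfastq_encoding_error"
    )
  }
  out
}

#' Encode integer Phred scores as a quality string
#'
#' Inverse of [decode_phred()] for a single read: `decode_phred(encode_phred(q))`
#' recovers `q` for every Q in `0..max_q` of the encoding.
#'
#' @param q Integer vector of Phred scores for one read.
#' @inheritParams decode_phred
#' @return A single quality string.
#' @examples
#' encode_phred(c(40, 40, 20)) # "II5"
#' @export
encode_phred <- function(q, encoding = "sanger") {
  enc <- quality_encoding(encoding)
  q <- as.integer(round(q))
  if (any(q < 0L) || any(q > enc$max_q)) {
    rlang::abort(
      sprintf("Phred scores must lie in [0, %d] under the '%s' encoding.", enc$max_q, enc$name),
      class = "tidyfastq_encoding_error"
    )
  }
  if (length(q) == 0L) {
    return("")
  }
  intToUtf8(q + enc$offset)
}
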
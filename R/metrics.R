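#' Convert a Phred score to a base-calling error probability
#'
#' The Phred score Q encodes the probability P that a base call is wrong on a
#' log scale: P = 10^(-Q/10). Q = 10 means a 1-in-10 error chance, Q = 20
#' 1-in-100, and so on.
#'
#' @param q Numeric vector of Phred scores, all >= 0.
#' @return `10^(-q/10)`, a probability in (0, 1].
#' @examples
#' phred_to_error(c(0, 10, 20)) # 1, 0.1, 0.01
#' @export
phred_to_error <- function(q) {
  if (!is.numeric(q) || any(is.na(q)) || any(q < 0)) {
    rlang::abort("Phred scores must be numeric and >= 0.", class = "tidyfastq_domain_error")
  }
  10^(-q / 10)
}

#' Convert an error probability to a Phred score
#'
#' Inverse of [phred_to_error()]: Q = -10 * log10(P).
#'
#' @param p Numeric vector of probabilities in (0, 1].
#' @return `-10 * log10(p)`.
#' @examples
#' error_to_phred(0.01) # 20
#' @export
error_to_phred <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    rlang::abort("Error probabilities must lie in (0, 1].", class = "tidyfastq_domain_error")
  }
  -10 * log10(p)
}

#' GC content of sequences, in percent
#'
#' 100 x (count of G/g/C/c) / sequence length. Ambiguous characters (N, IUPAC
#' codes) count toward the denominator only, so an all-N read has GC 0.
#'
#' @param sequence Character vector of non-empty nucleotide sequences.
#' @return Numeric vector in \[0, 100\].
#' @examples
#' gc_percent(c("GGCC", "AATT", "ACGTN")) # 100, 0, 40
#' @export
gc_percent <- function(sequence) {
  if (any(nchar(sequence) == 0L)) {
    rlang::abort("gc_percent() is undefined for empty sequences.",
      class = "tidyfastq_domain_error"
    )
  }
  gc <- nchar(gsub("[^GCgc]", "", sequence))
  100 * gc / nchar(sequence)
}

#' Per-read metrics
#'
#' Computes, for each record: read length, GC percent, the arithmetic mean of
#' the per-base Phred scores, and the arithmetic mean of the per-base error
#' probabilities. The two means are taken in different orders on purpose --
#' averaging probabilities weights low-quality bases far more heavily than
#' averaging scores, and by Jensen's inequality
#' `mean_error_prob >= phred_to_error(mean_phred)` for every read.
#'
#' @inheritParams validate_fastq
#' @inheritParams decode_phred
#' @return A tibble with columns `header`, `length`, `gc_percent`,
#'   `mean_phred`, `mean_error_prob`, one row per read.
#' @examples
#' reads <- fastq_tbl("r1", "ACGT", quality = "I+I+")
#' read_stats(reads) # mean_phred 25, mean_error_prob (1e-4 + 0.1)/2
#' @export
read_stats <- function(reads, encoding = "sanger") {
  validate_fastq(reads)
  q <- decode_phred(reads$quality, encoding)
  tibble::tibble(
    header = reads$header,
    length = nchar(reads$sequence),
    gc_percent = gc_percent(reads$sequence),
    mean_phred = vapply(q, mean, numeric(1)),
    mean_error_prob = vapply(q, function(x) mean(10^(-x / 10)), numeric(1))
  )
}

summary_metrics <- c("length", "gc_percent", "mean_phred", "mean_error_prob")

new_fastq_summary <- function(tbl, read_count) {
  structure(tbl, read_count = read_count, class = c("fastq_summary", class(tbl)))
}

#' Summarise a read set
#'
#' Min, max and unweighted per-read mean of each [read_stats()] metric over the
#' whole read set (a 25-base read counts as much as a 100-base read). An empty
#' read set yields `read_count` 0 and `NA` metric fields.
#'
#' @inheritParams read_stats
#' @return A `fastq_summary` tibble with columns `metric`, `min`, `max`, `avg`
#'   and attribute `read_count`.
#' @export
summarize_reads <- function(reads, encoding = "sanger") {
  if (nrow(reads) == 0L) {
    return(new_fastq_summary(
      tibble::tibble(
        metric = summary_metrics,
        min = NA_real_, max = NA_real_, avg = NA_real_
      ),
      read_count = 0L
    ))
  }
  stats <- read_stats(reads, encoding)
  long <- tidyr::pivot_longer(stats, dplyr::all_of(summary_metrics),
    names_to = "metric", values_to = "value"
  )
  tbl <- long |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      min = min(.data$value),
      max = max(.data$value),
      avg = mean(.data$value),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$metric, summary_metrics))
  new_fastq_summary(tbl, read_count = nrow(reads))
}

#' @export
print.fastq_summary <- function(x, ...) {
  cat(sprintf("<fastq_summary> %d reads\n", attr(x, "read_count")))
  NextMethod()
}

# Streaming accumulator for summarize_reads: running min/max/sum/count per
# metric, so the pipeline can summarise arbitrarily large files in O(1) memory.
new_summary_acc <- function() {
  list(
    n = 0L,
    min = stats::setNames(rep(Inf, 4), summary_metrics),
    max = stats::setNames(rep(-Inf, 4), summary_metrics),
    sum = stats::setNames(rep(0, 4), summary_metrics)
  )
}

update_summary_acc <- function(acc, reads, encoding) {
  if (nrow(reads) == 0L) {
    return(acc)
  }
  stats <- read_stats(reads, encoding)
  for (m in summary_metrics) {
    v <- stats[[m]]
    acc$min[[m]] <- min(acc$min[[m]], min(v))
    acc$max[[m]] <- max(acc$max[[m]], max(v))
    acc$sum[[m]] <- acc$sum[[m]] + sum(v)
  }
  acc$n <- acc$n + nrow(reads)
  acc
}

finalize_summary_acc <- function(acc) {
  if (acc$n == 0L) {
    return(summarize_reads(fastq_tbl(character(), character(), character(), character())))
  }
  new_fastq_summary(
    tibble::tibble(
      metric = summary_metrics,
      min = unname(acc$min),
      max = unname(acc$max),
      avg = unname(acc$sum) / acc$n
    ),
    read_count = acc$n
  )
}

fmt_summary_cell <- function(metric, value) {
  if (is.na(value)) {
    return("NA")
  }
  if (metric == "mean_error_prob") {
    formatC(value, format = "e", digits = 2) # 3 significant digits
  } else {
    sprintf("%.2f", value)
  }
}

#' Render a before/after summary table
#'
#' Formats two [summarize_reads()] tables side by side for standard output,
#' the "before" column computed on the unfiltered input and the "after" column
#' on the filtered output. GC percent, lengths and Phred scores are printed
#' with 2 decimal places; error probabilities in scientific notation with 3
#' significant digits; empty-set cells as `NA`.
#'
#' @param before,after `fastq_summary` objects.
#' @param file Connection or `""` (standard output) passed to [cat()].
#' @param format `"table"` for the aligned human-readable layout, `"tsv"`
#'   for a tab-separated variant with the same cells, for machine parsing.
#' @return The formatted lines, invisibly.
#' @export
render_summary <- function(before, after, file = "", format = c("table", "tsv")) {
  format <- rlang::arg_match(format)
  stopifnot(inherits(before, "fastq_summary"), inherits(after, "fastq_summary"))
  row_fmt <- if (format == "table") {
    function(a, b, c) sprintf("%-34s %14s %14s", a, b, c)
  } else {
    function(a, b, c) paste(a, b, c, sep = "\t")
  }
  labels <- c(
    length = "read length",
    gc_percent = "GC %",
    mean_phred = "mean Phred score",
    mean_error_prob = "mean error probability"
  )
  rows <- list(row_fmt(
    "metric",
    sprintf("before (n=%d)", attr(before, "read_count")),
    sprintf("after (n=%d)", attr(after, "read_count"))
  ))
  for (m in summary_metrics) {
    for (stat in c("min", "max", "avg")) {
      b <- before[[stat]][before$metric == m]
      a <- after[[stat]][after$metric == m]
      rows[[length(rows) + 1L]] <- row_fmt(
        paste(stat, labels[[m]]),
        fmt_summary_cell(m, b), fmt_summary_cell(m, a)
      )
    }
  }
  lines <- unlist(rows)
  cat(lines, sep = "\n", file = file)
  invisible(lines)
}
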
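#' Plot a before/after quality-score distribution
#'
#' Histograms of per-read mean Phred scores before and after filtering,
#' overlaid -- quality filtering shows up as a shift of the distribution
#' toward higher scores.
#'
#' @param before,after FASTQ tibbles (e.g. the input reads and the reads
#'   re-read from the filtered output).
#' @param encoding Quality encoding.
#' @param binwidth Histogram bin width in Phred units.
#' @return A ggplot object.
#' @export
plot_quality_shift <- function(before, after, encoding = "sanger", binwidth = 1) {
  df <- dplyr::bind_rows(
    dplyr::mutate(read_stats(before, encoding), set = "before"),
    dplyr::mutate(read_stats(after, encoding), set = "after")
  )
  df$set <- factor(df$set, levels = c("before", "after"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_phred, fill = .data$set)) +
    ggplot2::geom_histogram(
      binwidth = binwidth, position = "identity", alpha = 0.55
    ) +
    ggplot2::labs(
      x = "mean Phred score per read", y = "reads", fill = NULL,
      title = "Read-quality distribution before and after filtering"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-stage removal counts of a pipeline run
#'
#' @param object A `fastq_pipeline` object.
#' @param ... Unused.
#' @return A ggplot object (bar chart of reads removed per stage).
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.fastq_pipeline <- function(object, ...) {
  df <- tidy.fastq_pipeline(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$removed)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = NULL, y = "reads removed",
      title = sprintf("Reads removed per stage (kept %d of %d)",
        object$n_output, object$n_input
      )
    ) +
    ggplot2::theme_minimal()
}
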
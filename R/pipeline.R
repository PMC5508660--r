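#' Assemble a preprocessing pipeline configuration
#'
#' Collects and validates the full option set of the preprocessing pipeline,
#' mirroring the command-line flags one-to-one (see [parse_pipeline_args()]).
#' Filters chain into a single filtered output file; each requested transform
#' (`fasta`, `rev_comp`, `rna`) writes its own new file from the filtered
#' output.
#'
#' @param lib Quality encoding name, `"sanger"` or `"illumina"` (required).
#' @param input Name of the FASTQ input file (required).
#' @param path Directory containing `input`.
#' @param smry Print a before/after summary-statistics table to standard output.
#' @param qf Mean-Phred quality threshold: reads with mean Phred below it are
#'   removed. `NULL` disables the filter.
#' @param lf Minimum read length; shorter reads are removed.
#' @param trim_l,trim_r Bases to trim from the left / right end of every read.
#' @param adpt_l,adpt_r Adapter sequence to strip (anchored) from the left /
#'   right end.
#' @param mis_l,mis_r Hamming-mismatch budget for the left / right adapter;
#'   defaults to 0 when the adapter is given; an error when given without it.
#' @param dup Remove duplicate reads (first occurrence kept).
#' @param no_n Remove reads containing any base other than A/C/G/T.
#' @param fasta,rev_comp,rna Transforms, each writing a new file.
#' @param clean Delete intermediate files after the run.
#' @param out_dir Directory for output files (defaults to `path`).
#' @param chunk_size Records processed per streaming chunk.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(lib, input, path = ".",
                            smry = FALSE, qf = NULL, lf = NULL,
                            trim_l = NULL, trim_r = NULL,
                            adpt_l = NULL, adpt_r = NULL,
                            mis_l = NULL, mis_r = NULL,
                            dup = FALSE, no_n = FALSE,
                            fasta = FALSE, rev_comp = FALSE, rna = FALSE,
                            clean = FALSE, out_dir = path,
                            chunk_size = 10000L) {
  usage_abort <- function(msg) rlang::abort(msg, class = "tidyfastq_usage_error")
  if (missing(lib) || is.null(lib)) usage_abort("-lib is required (sanger or illumina).")
  if (!is.character(lib) || !tolower(lib) %in% c("sanger", "illumina")) {
    usage_abort(sprintf("-lib must be 'sanger' or 'illumina', not '%s'.", lib))
  }
  if (missing(input) || is.null(input)) usage_abort("-i (input FASTQ file name) is required.")
  input_path <- file.path(path, input)
  if (!file.exists(input_path)) {
    usage_abort(sprintf("Input file not found: %s", input_path))
  }
  if (!is.null(mis_l) && is.null(adpt_l)) usage_abort("-mis_l requires -adpt_l.")
  if (!is.null(mis_r) && is.null(adpt_r)) usage_abort("-mis_r requires -adpt_r.")
  if (!is.null(adpt_l) && is.null(mis_l)) mis_l <- 0L
  if (!is.null(adpt_r) && is.null(mis_r)) mis_r <- 0L
  if (!is.null(qf) && qf < 0) usage_abort("-qf must be >= 0.")
  if (!is.null(lf) && lf < 1) usage_abort("-lf must be >= 1.")
  for (v in c("trim_l", "trim_r")) {
    x <- get(v)
    if (!is.null(x) && x < 0) usage_abort(sprintf("-%s must be >= 0.", v))
  }
  structure(
    list(
      lib = tolower(lib), path = path, input = input, input_path = input_path,
      smry = isTRUE(smry), qf = qf, lf = lf,
      trim_l = trim_l, trim_r = trim_r,
      adpt_l = adpt_l, adpt_r = adpt_r, mis_l = mis_l, mis_r = mis_r,
      dup = isTRUE(dup), no_n = isTRUE(no_n),
      fasta = isTRUE(fasta), rev_comp = isTRUE(rev_comp), rna = isTRUE(rna),
      clean = isTRUE(clean), out_dir = out_dir,
      chunk_size = as.integer(chunk_size)
    ),
    class = "pipeline_config"
  )
}

config_has_filters <- function(config) {
  !is.null(config$qf) || !is.null(config$lf) ||
    (!is.null(config$trim_l) && config$trim_l > 0) ||
    (!is.null(config$trim_r) && config$trim_r > 0) ||
    !is.null(config$adpt_l) || !is.null(config$adpt_r) ||
    config$dup || config$no_n
}

output_stem <- function(config) {
  sub("\\.(fastq|fq)(\\.gz)?$", "", config$input, ignore.case = TRUE)
}

# Canonical stage order. Adapters go first (they sit outside the insert),
# then fixed end-trims, so the quality/length filters see the post-trim read
# (the sequence that survives to downstream use) and dedup sees final
# sequences. Zero-length reads arising from trimming are dropped and counted.
apply_filter_chain <- function(chunk, config, enc, seen, counts) {
  take <- function(out, name) {
    counts[[name]] <<- counts[[name]] + removed_count(out)
    out
  }
  if (!is.null(config$adpt_l)) {
    chunk <- strip_adapter(chunk, config$adpt_l, "left", config$mis_l)
    counts$adapter_left_matched <- counts$adapter_left_matched + sum(adapter_matched(chunk))
  }
  if (!is.null(config$adpt_r)) {
    chunk <- strip_adapter(chunk, config$adpt_r, "right", config$mis_r)
    counts$adapter_right_matched <- counts$adapter_right_matched + sum(adapter_matched(chunk))
  }
  if (!is.null(config$trim_l) && config$trim_l > 0) chunk <- trim_left(chunk, config$trim_l)
  if (!is.null(config$trim_r) && config$trim_r > 0) chunk <- trim_right(chunk, config$trim_r)
  empty <- nchar(chunk$sequence) == 0L
  if (any(empty)) {
    counts$zero_length <- counts$zero_length + sum(empty)
    chunk <- chunk[!empty, , drop = FALSE]
  }
  if (config$no_n) chunk <- take(remove_ambiguous(chunk), "ambiguous")
  if (!is.null(config$qf)) chunk <- take(filter_by_quality(chunk, config$qf, enc), "quality")
  if (!is.null(config$lf)) chunk <- take(filter_by_length(chunk, config$lf), "length")
  if (config$dup) chunk <- take(remove_duplicates(chunk, seen = seen), "duplicate")
  list(chunk = chunk, counts = counts)
}

#' Run the preprocessing pipeline
#'
#' Streams the input FASTQ in chunks, applies the enabled stages in the
#' canonical order -- left adapter, right adapter, left trim, right trim,
#' zero-length drop, ambiguous-base filter, quality filter, length filter,
#' duplicate removal -- and writes one filtered FASTQ. Requested transforms
#' then each write their own file from the filtered output. With `smry`,
#' summary statistics of the input and the filtered output are printed to
#' standard output; per-stage removal counts are logged to standard error.
#'
#' @param config A [pipeline_config()].
#' @return A `fastq_pipeline` object: paths of the filtered file and any
#'   transform outputs, per-stage removal counts, input/output read counts,
#'   and the before/after `fastq_summary` tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  enc <- quality_encoding(config$lib)
  stem <- output_stem(config)
  gz <- if (grepl("\\.gz$", config$input, ignore.case = TRUE)) ".gz" else ""
  filtered_path <- file.path(config$out_dir, paste0(stem, ".filtered.fastq", gz))

  counts <- list(
    adapter_left_matched = 0L, adapter_right_matched = 0L,
    zero_length = 0L, ambiguous = 0L, quality = 0L, length = 0L, duplicate = 0L
  )
  seen <- new.env(parent = emptyenv())
  acc_before <- new_summary_acc()
  acc_after <- new_summary_acc()
  n_in <- 0L
  n_out <- 0L

  out_con <- open_seq_connection(filtered_path, "wb")
  closed <- FALSE
  on.exit(if (!closed) close(out_con), add = TRUE)
  fastq_chunk_apply(config$input_path, function(chunk, first) {
    n_in <<- n_in + nrow(chunk)
    if (config$smry) acc_before <<- update_summary_acc(acc_before, chunk, enc)
    res <- apply_filter_chain(chunk, config, enc, seen, counts)
    counts <<- res$counts
    kept <- res$chunk
    n_out <<- n_out + nrow(kept)
    if (config$smry) acc_after <<- update_summary_acc(acc_after, kept, enc)
    if (nrow(kept) > 0L) {
      writeLines(fastq_record_lines(kept), out_con, sep = "\n")
    }
  }, encoding = enc, chunk_size = config$chunk_size)
  close(out_con)
  closed <- TRUE

  removed <- counts[c("zero_length", "ambiguous", "quality", "length", "duplicate")]
  for (nm in names(removed)) {
    if (removed[[nm]] > 0L) {
      message(sprintf("stage %-12s removed %d read(s)", nm, removed[[nm]]))
    }
  }
  message(sprintf("kept %d of %d read(s)", n_out, n_in))

  transform_paths <- character()
  if (config$fasta || config$rev_comp || config$rna) {
    t_out <- list()
    if (config$fasta) {
      t_out$fasta <- file.path(config$out_dir, paste0(stem, ".fasta"))
    }
    if (config$rev_comp) {
      t_out$rev_comp <- file.path(config$out_dir, paste0(stem, ".revcomp.fastq", gz))
    }
    if (config$rna) {
      t_out$rna <- file.path(config$out_dir, paste0(stem, ".rna.fastq", gz))
    }
    cons <- lapply(t_out, function(p) {
      open_seq_connection(p, "wb")
    })
    on.exit(for (cn in cons) try(close(cn), silent = TRUE), add = TRUE)
    fastq_chunk_apply(filtered_path, function(chunk, first) {
      if (config$fasta) {
        writeLines(
          as.vector(rbind(paste0(">", chunk$header), chunk$sequence)),
          cons$fasta,
          sep = "\n"
        )
      }
      if (config$rev_comp) {
        writeLines(fastq_record_lines(reverse_complement(chunk)), cons$rev_comp, sep = "\n")
      }
      if (config$rna) {
        writeLines(fastq_record_lines(to_rna(chunk)), cons$rna, sep = "\n")
      }
    }, encoding = enc, chunk_size = config$chunk_size)
    for (cn in cons) close(cn)
    cons <- list()
    transform_paths <- unlist(t_out)
  }

  summary_before <- NULL
  summary_after <- NULL
  if (config$smry) {
    summary_before <- finalize_summary_acc(acc_before)
    summary_after <- finalize_summary_acc(acc_after)
    render_summary(summary_before, summary_after)
    cat("\n")
  }

  # The filtered file is a staging intermediate only when the run did no
  # filtering and exists solely to feed transforms.
  temp_files <- character()
  if (!config_has_filters(config) && length(transform_paths) > 0L) {
    temp_files <- filtered_path
  }

  result <- structure(
    list(
      config = config,
      input_path = config$input_path,
      filtered_path = filtered_path,
      transform_paths = transform_paths,
      removed = unlist(removed),
      adapter_matched = c(
        left = counts$adapter_left_matched,
        right = counts$adapter_right_matched
      ),
      n_input = n_in,
      n_output = n_out,
      summary_before = summary_before,
      summary_after = summary_after,
      temp_files = temp_files
    ),
    class = "fastq_pipeline"
  )
  if (config$clean) {
    cleanup_temp(result)
    result$temp_files <- character()
  }
  result
}

#' Delete intermediate files from a pipeline run
#'
#' Removes staging intermediates recorded by [run_pipeline()]; the input file
#' and final outputs are never deleted. Deletion failures warn rather than
#' abort. A second call removes nothing.
#'
#' @param result A `fastq_pipeline` object.
#' @return Character vector of removed paths, invisibly.
#' @export
cleanup_temp <- function(result) {
  stopifnot(inherits(result, "fastq_pipeline"))
  existing <- result$temp_files[file.exists(result$temp_files)]
  removed <- character()
  for (p in existing) {
    ok <- tryCatch(file.remove(p), warning = function(w) FALSE, error = function(e) FALSE)
    if (isTRUE(ok)) {
      removed <- c(removed, p)
    } else {
      warning(sprintf("Could not remove temporary file %s", p))
    }
  }
  invisible(removed)
}

#' @export
print.fastq_pipeline <- function(x, ...) {
  cat(sprintf(
    "<fastq_pipeline> %s: kept %d of %d read(s)\n",
    basename(x$input_path), x$n_output, x$n_input
  ))
  cat("  filtered: ", x$filtered_path, "\n", sep = "")
  for (p in x$transform_paths) cat("  transform:", p, "\n")
  invisible(x)
}

#' Tidy a pipeline result into a per-stage table
#'
#' @param x A `fastq_pipeline` object.
#' @param ... Unused.
#' @return A tibble with columns `stage` and `removed`, one row per filter
#'   stage that ran (plus the zero-length drop).
#' @exportS3Method generics::tidy
#' @export
tidy.fastq_pipeline <- function(x, ...) {
  tibble::tibble(stage = names(x$removed), removed = as.integer(x$removed))
}

#' One-row pipeline overview
#'
#' @inheritParams tidy.fastq_pipeline
#' @return A one-row tibble: input/kept/removed read counts and the fraction
#'   of reads retained.
#' @exportS3Method generics::glance
#' @export
glance.fastq_pipeline <- function(x, ...) {
  tibble::tibble(
    n_input = x$n_input,
    n_kept = x$n_output,
    n_removed = x$n_input - x$n_output,
    fraction_kept = if (x$n_input > 0) x$n_output / x$n_input else NA_real_
  )
}
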
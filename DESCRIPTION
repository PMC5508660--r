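Package: tidyfastq
Title: Tidy FASTQ Quality Control, Filtering, Trimming and Reformatting
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for preprocessing short-read sequencing
    data in FASTQ format. Reads are represented as tibbles (one row per record)
    so quality-aware parsing, per-read metrics (length, GC content, mean Phred
    score, mean base-calling error probability), read-level filters (mean
    quality, minimum length, exact-duplicate removal, ambiguous-base removal),
    fixed end-trimming, anchored adapter stripping under a Hamming-mismatch
    budget, and whole-file transforms (reverse complement, DNA-to-RNA, FASTA
    export) compose with the pipe. Includes a streaming pipeline with a
    command-line front end, before/after summary statistics, and a seeded
    synthetic-read simulator that plants known ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
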
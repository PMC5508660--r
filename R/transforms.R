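# Complement table covering the IUPAC nucleotide codes, both cases.
# A<->T, C<->G, U->A, R<->Y, K<->M, B<->V, D<->H; S, W, N are self-complementary.
.comp_from <- "ACGTURYKMBVDHSWNacgturykmbvdhswn"
.comp_to <- "TGCAAYRMKVBHDSWNtgcaayrmkvbhdswn"

#' Reverse complement reads
#'
#' Complements every base (IUPAC ambiguity codes included, case preserved) and
#' reverses the sequence; the quality string is reversed in step, so each base
#' keeps its own quality character. Headers and plus lines are unchanged.
#'
#' @param reads A FASTQ tibble.
#' @return The reverse-complemented FASTQ tibble. A character with no defined
#'   complement raises an error naming the character and record.
#' @examples
#' r <- fastq_tbl("r1", "GATTACA", quality = "IIIIIIH")
#' reverse_complement(r)$sequence # "TGTAATC"
#' @export
reverse_complement <- function(reads) {
  validate_fastq(reads, allow_empty = TRUE)
  bad <- grepl(sprintf("[^%s]", .comp_from), reads$sequence)
  if (any(bad)) {
    i <- which(bad)[[1]]
    ch <- stringr::str_extract(reads$sequence[[i]], sprintf("[^%s]", .comp_from))
    rlang::abort(
      sprintf("Record %d ('%s'): no defined complement for character '%s'.",
        i, reads$header[[i]], ch
      ),
      class = "tidyfastq_domain_error"
    )
  }
  reads$sequence <- stringi::stri_reverse(chartr(.comp_from, .comp_to, reads$sequence))
  reads$quality <- stringi::stri_reverse(reads$quality)
  reads
}

#' Convert DNA reads to RNA
#'
#' Replaces every T with U (and t with u); all other characters and the
#' quality string are unchanged.
#'
#' @inheritParams reverse_complement
#' @return The converted FASTQ tibble.
#' @examples
#' to_rna(fastq_tbl("r1", "ACGT", quality = "IIII"))$sequence # "ACGU"
#' @export
to_rna <- function(reads) {
  validate_fastq(reads, allow_empty = TRUE)
  reads$sequence <- chartr("Tt", "Uu", reads$sequence)
  reads
}

#' Export reads to a FASTA file
#'
#' Transform-level entry point that writes a new 2-line-per-record FASTA file;
#' delegates to [write_fasta()].
#'
#' @inheritParams write_fasta
#' @return The number of records written, invisibly.
#' @export
export_fasta <- function(reads, path) {
  write_fasta(reads, path)
}
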
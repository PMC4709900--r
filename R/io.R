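# Sequence file I/O goes through Biostrings; in memory, reads travel as
# plain data.frames (id, seq, qual) so the parsing stages can use fast
# vectorised string operations.

#' Read a FASTQ file into a read table
#'
#' Reads a (possibly gzipped) 4-line-record FASTQ file.  Qualities must be
#' Phred+33 (Illumina 1.8+); other encodings are rejected at load.
#'
#' @param path Path to a `.fastq` or `.fastq.gz` file.
#' @return A data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  qual <- as.character(S4Vectors::mcols(x)$qualities)
  df <- data.frame(id = names(x), seq = as.character(x), qual = qual,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  check_phred33(df$qual)
  df
}

#' Write a read table to FASTQ
#'
#' @param reads A data.frame with columns `id`, `seq`, `qual`.
#' @param path Output path; gzip compression via `compress = TRUE`.
#' @param compress Write gzip-compressed output.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, compress = FALSE) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq", compress = compress,
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' @rdname read_fastq
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  stats::setNames(as.character(x), names(x))
}

#' @param seqs Named character vector of sequences.
#' @rdname write_fastq
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

# Phred+33 sanity check: codes 33..74 cover Q0-Q41 (Illumina 1.8+); a higher
# code indicates a Phred+64 file.
check_phred33 <- function(qual) {
  bad <- grepl("[^\\x21-\\x4A]", qual, perl = TRUE, useBytes = TRUE)
  if (any(bad)) {
    stop("quality strings are not Phred+33 (Illumina 1.8+); offending read #",
         which(bad)[1], call. = FALSE)
  }
  invisible(TRUE)
}

# Reverse-complement / reverse for plain character vectors (compiled).
revcomp_chr <- function(x) cpp_revcomp(x)
revstr_chr <- function(x) cpp_revstring(x)

empty_read_table <- function() {
  data.frame(id = character(), seq = character(), qual = character(),
             stringsAsFactors = FALSE)
}
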
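#' Write a reference set (or DNAStringSet) to FASTA
#'
#' @param x a `reference_set` or `DNAStringSet`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "reference_set")) x <- x$seqs
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' Read a FASTA file as a reference set
#'
#' @param path FASTA file.
#' @param kind reference kind (see [reference_set()]).
#' @return a `reference_set`.
#' @export
read_fasta <- function(path, kind = "genome") {
  reference_set(Biostrings::readDNAStringSet(path), kind = kind)
}

#' Write reads to FASTQ with constant Sanger qualities
#'
#' Quality realism is a non-goal of the simulator; every base gets Phred 40
#' (`"I"`).
#'
#' @param seqs character vector of read sequences.
#' @param path output file.
#' @param ids read identifiers (defaults to names of `seqs` or `read_<i>`).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path, ids = NULL) {
  if (is.null(ids)) {
    ids <- if (!is.null(names(seqs))) names(seqs) else
      sprintf("read_%06d", seq_along(seqs))
  }
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- ids
  qual <- Biostrings::BStringSet(strrep("I", BiocGenerics::width(x)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file as a named character vector of sequences
#'
#' @param path FASTQ file.
#' @return character vector of read sequences named by read id.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), names(x))
}
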
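#' Reference sequence set
#'
#' A named collection of reference sequences of a single kind: genome contigs,
#' predicted coding sequences (CDSs), EST contigs, or contaminants
#' (rRNA/tRNA/plastid). CDSs carry an implicit stop-codon anchor: the last
#' three nucleotides are the stop codon and distances from the stop are
#' measured from its first nucleotide (position 0 at the stop, increasing
#' toward 5').
#'
#' @param seqs a `Biostrings::DNAStringSet` or named character vector.
#' @param kind one of `"genome"`, `"cds"`, `"est"`, `"contaminant"`.
#' @return an object of class `reference_set` with elements `seqs`
#'   (DNAStringSet) and `kind`.
#' @export
reference_set <- function(seqs, kind = c("genome", "cds", "est", "contaminant")) {
  kind <- match.arg(kind)
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  stopifnot(methods::is(seqs, "DNAStringSet"))
  if (length(seqs) && is.null(names(seqs))) {
    names(seqs) <- sprintf("%s_%05d", kind, seq_along(seqs))
  }
  if (anyDuplicated(names(seqs))) stop("reference ids must be unique")
  structure(list(seqs = seqs, kind = kind), class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> kind=%s n=%d total_nt=%d\n",
              x$kind, length(x$seqs), sum(BiocGenerics::width(x$seqs))))
  invisible(x)
}

#' Reference ids
#' @param x a `reference_set`.
#' @return character vector of sequence ids.
#' @export
ref_ids <- function(x) names(x$seqs)

#' Reference lengths
#' @param x a `reference_set`.
#' @return named integer vector of sequence lengths (nt).
#' @export
ref_lengths <- function(x) {
  stats::setNames(BiocGenerics::width(x$seqs), names(x$seqs))
}

#' Stop-codon anchors of a CDS reference set
#'
#' @param x a `reference_set` of kind `"cds"`.
#' @return named integer vector: 0-based position of the first stop-codon
#'   nucleotide of each CDS (i.e. length - 3).
#' @export
stop_anchors <- function(x) {
  stopifnot(x$kind == "cds")
  ref_lengths(x) - 3L
}
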
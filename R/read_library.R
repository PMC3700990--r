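#' Condition-labelled read library
#'
#' Stores a library as the distinct-sequence ("unique") view with per-sequence
#' copy counts; the "redundant" total is the sum of copies. Provenance
#' counters track what happened to every raw read assigned to the library:
#' `raw = retained + untrimmable + size_rejected + contaminant_rejected`
#' holds at every pipeline stage.
#'
#' @param seqs character vector of read sequences (one element per read copy
#'   unless `counts` is given).
#' @param condition library label (e.g. `"normal"`, `"salt"`).
#' @param counts optional integer copy counts parallel to `seqs` (then `seqs`
#'   must be distinct).
#' @param counters optional named numeric vector of provenance counters.
#' @return an object of class `read_library`.
#' @export
read_library <- function(seqs, condition, counts = NULL, counters = NULL) {
  if (is.null(counts)) {
    tab <- table(seqs)
    seqs <- names(tab)
    counts <- as.integer(tab)
  } else {
    if (anyDuplicated(seqs)) stop("seqs must be distinct when counts is given")
    counts <- as.integer(counts)
    ord <- order(seqs)
    seqs <- seqs[ord]
    counts <- counts[ord]
  }
  stopifnot(all(counts >= 1L))
  redundant <- sum(counts)
  if (is.null(counters)) {
    counters <- c(raw = redundant, untrimmable = 0, size_rejected = 0,
                  contaminant_rejected = 0, retained = redundant)
  }
  structure(list(condition = condition,
                 seq = as.character(seqs),
                 count = counts,
                 counters = counters),
            class = "read_library")
}

# Replace the sequence multiset, keeping counters consistent by caller.
set_reads <- function(lib, seqs, counts, counters = lib$counters) {
  keep <- counts >= 1L
  seqs <- seqs[keep]
  counts <- as.integer(counts[keep])
  if (anyDuplicated(seqs)) {
    agg <- rowsum(counts, seqs)
    seqs <- rownames(agg)
    counts <- as.integer(agg[, 1L])
  }
  ord <- order(seqs)
  lib$seq <- seqs[ord]
  lib$count <- counts[ord]
  counters["retained"] <- sum(lib$count)
  lib$counters <- counters
  lib
}

#' Redundant read total of a library
#' @param lib a `read_library`.
#' @return sum of copy counts.
#' @export
redundant_total <- function(lib) sum(lib$count)

#' Unique (distinct-sequence) total of a library
#' @param lib a `read_library`.
#' @return number of distinct sequences.
#' @export
unique_total <- function(lib) length(lib$seq)

#' @export
print.read_library <- function(x, ...) {
  cat(sprintf("<read_library> condition=%s redundant=%d unique=%d\n",
              x$condition, redundant_total(x), unique_total(x)))
  cat("  counters:", paste(names(x$counters), x$counters, sep = "=",
                           collapse = " "), "\n")
  invisible(x)
}
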
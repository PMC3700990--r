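# Read preprocessing: demultiplex, trim, size-select, decontaminate.

#' Demultiplex raw reads and trim barcode + 3' adapter
#'
#' Reads open with a fixed-length 5' barcode identifying the condition,
#' followed by the insert and the 3' adapter. The barcode and everything
#' from the first exact occurrence of the adapter onward are removed. Reads
#' with an unknown barcode are dropped and counted (attribute
#' `unknown_barcode`); reads with a known barcode but no adapter match are
#' counted as `untrimmable` in their library and dropped.
#'
#' @param reads character vector of raw read sequences.
#' @param barcode_map named character vector, condition -> barcode; barcodes
#'   must be mutually distinct and of equal length (an ambiguous table is
#'   rejected).
#' @param adapter3 3' adapter sequence (exact substring match, first
#'   occurrence from 5').
#' @return named list of `read_library`, one per condition, with attribute
#'   `unknown_barcode` (count of unassignable reads).
#' @export
demultiplex_and_trim <- function(reads, barcode_map, adapter3) {
  if (anyDuplicated(barcode_map)) {
    stop("ambiguous barcode table: barcodes must be mutually distinct")
  }
  bw <- unique(nchar(barcode_map))
  if (length(bw) != 1L) stop("ambiguous barcode table: unequal barcode lengths")
  reads <- unname(as.character(reads))
  bc <- substr(reads, 1L, bw)
  cond <- names(barcode_map)[match(bc, barcode_map)]
  unknown <- sum(is.na(cond))
  rest <- substr(reads, bw + 1L, nchar(reads))
  apos <- regexpr(adapter3, rest, fixed = TRUE)

  libs <- lapply(names(barcode_map), function(cn) {
    sel <- !is.na(cond) & cond == cn
    n_raw <- sum(sel)
    trimmed_ok <- sel & apos > 0L
    inserts <- substr(rest[trimmed_ok], 1L, apos[trimmed_ok] - 1L)
    inserts <- inserts[nchar(inserts) > 0L]
    n_untrim <- n_raw - length(inserts)
    counters <- c(raw = n_raw, untrimmable = n_untrim, size_rejected = 0,
                  contaminant_rejected = 0, retained = length(inserts))
    if (length(inserts) == 0L) {
      read_library(character(), cn, counts = integer(), counters = counters)
    } else {
      lib <- read_library(inserts, cn)
      lib$counters <- counters
      lib
    }
  })
  names(libs) <- names(barcode_map)
  attr(libs, "unknown_barcode") <- unknown
  libs
}

#' Size-select a read library
#'
#' Retains reads with `min_len <= length <= max_len` (both bounds
#' inclusive); rejected copies are added to the `size_rejected` counter.
#'
#' @param lib a `read_library`.
#' @param min_len,max_len inclusive length bounds (nt); 16-32 for sRNAs,
#'   25-45 for degradome tags.
#' @return the filtered `read_library`.
#' @export
size_filter <- function(lib, min_len, max_len) {
  stopifnot(min_len <= max_len)
  n <- nchar(lib$seq)
  keep <- n >= min_len & n <= max_len
  counters <- lib$counters
  counters["size_rejected"] <- counters["size_rejected"] +
    sum(lib$count[!keep])
  set_reads(lib, lib$seq[keep], lib$count[keep], counters)
}

#' Remove poly-A tails from degradome reads
#'
#' Removes the maximal trailing run of A's when it is at least `min_tail`
#' long; shorter runs are left untouched. Intended for degradome libraries,
#' where the oligo-d(T) priming leaves poly-A stretches on tags.
#'
#' @param lib a `read_library`.
#' @param min_tail minimum run length that counts as a tail (default 4).
#' @return the trimmed `read_library` (sequences re-aggregated, counters
#'   unchanged; reads trimmed to length zero are removed by the subsequent
#'   size filter).
#' @export
trim_polya <- function(lib, min_tail = 4L) {
  trimmed <- sub(sprintf("A{%d,}$", min_tail), "", lib$seq)
  set_reads(lib, trimmed, lib$count)
}

#' Remove contaminant-matching reads
#'
#' Drops every read whose full-length sequence matches a contaminant
#' reference with 100% identity on either strand -- the same matching
#' semantics as [map_exact()]. Removed copies are counted in
#' `contaminant_rejected`.
#'
#' @param lib a `read_library`.
#' @param contaminant a `reference_set` (rRNA/tRNA/plastid databases).
#' @return the decontaminated `read_library`.
#' @export
remove_contaminants <- function(lib, contaminant) {
  if (length(contaminant$seqs) == 0L || unique_total(lib) == 0L) return(lib)
  hit <- lib$seq %in% matched_sequences(lib$seq, contaminant)
  counters <- lib$counters
  counters["contaminant_rejected"] <- counters["contaminant_rejected"] +
    sum(lib$count[hit])
  set_reads(lib, lib$seq[!hit], lib$count[!hit], counters)
}

#' Full sRNA preprocessing: demultiplex, trim, size-select, decontaminate
#'
#' @param reads raw multiplexed reads (character vector).
#' @param barcode_map condition -> barcode map.
#' @param adapter3 3' adapter sequence.
#' @param min_len,max_len size-selection bounds (default 16-32 nt).
#' @param contaminant optional contaminant `reference_set`.
#' @return named list of processed `read_library` with attribute
#'   `unknown_barcode`.
#' @export
preprocess_srna <- function(reads, barcode_map, adapter3,
                            min_len = 16L, max_len = 32L,
                            contaminant = NULL) {
  libs <- demultiplex_and_trim(reads, barcode_map, adapter3)
  unknown <- attr(libs, "unknown_barcode")
  libs <- lapply(libs, size_filter, min_len = min_len, max_len = max_len)
  if (!is.null(contaminant)) {
    libs <- lapply(libs, remove_contaminants, contaminant = contaminant)
  }
  attr(libs, "unknown_barcode") <- unknown
  libs
}

#' Full degradome preprocessing: poly-A trim then size-select
#'
#' @param reads raw degradome tag sequences.
#' @param condition library label (default `"degradome"`).
#' @param min_len,max_len size bounds (default 25-45 nt).
#' @param min_tail poly-A tail threshold (default 4).
#' @param contaminant optional contaminant `reference_set`.
#' @return a processed `read_library`.
#' @export
preprocess_degradome <- function(reads, condition = "degradome",
                                 min_len = 25L, max_len = 45L,
                                 min_tail = 4L, contaminant = NULL) {
  lib <- read_library(unname(as.character(reads)), condition)
  lib <- trim_polya(lib, min_tail = min_tail)
  lib <- size_filter(lib, min_len, max_len)
  if (!is.null(contaminant)) lib <- remove_contaminants(lib, contaminant)
  lib
}

#' Preprocessing counter report
#'
#' @param libs list of `read_library`.
#' @return data.frame of provenance counters, one row per library.
#' @export
preprocess_report <- function(libs) {
  do.call(rbind, lapply(libs, function(l) {
    data.frame(condition = l$condition, t(l$counters),
               unique_retained = unique_total(l),
               stringsAsFactors = FALSE)
  }))
}
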
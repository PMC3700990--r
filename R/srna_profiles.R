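# Global descriptive statistics of mapped sRNA libraries: length
# distribution, 5'-base composition, per-reference count binning and
# hotspot concentration.

as_lib_list <- function(libs) {
  if (inherits(libs, "read_library")) list(libs) else libs
}

#' Redundant read-length distribution
#'
#' @param libs a `read_library` or list of them (post-filter, mapped reads).
#' @param lengths lengths to tabulate (default 16:32).
#' @return list with `counts` (named integer vector over `lengths`) and
#'   `mode` (the modal length, or `NA` when empty, reported as "none" in
#'   tables).
#' @export
length_distribution <- function(libs, lengths = 16:32) {
  libs <- as_lib_list(libs)
  counts <- stats::setNames(integer(length(lengths)), lengths)
  for (lib in libs) {
    n <- nchar(lib$seq)
    keep <- n %in% lengths
    if (any(keep)) {
      tab <- rowsum(lib$count[keep], n[keep])
      counts[rownames(tab)] <- counts[rownames(tab)] + as.integer(tab[, 1L])
    }
  }
  mode <- if (sum(counts) == 0L) NA_integer_ else
    lengths[which.max(counts)]
  list(counts = counts, mode = mode)
}

#' 5'-base composition of unique sRNAs
#'
#' Fractions are computed over distinct sequences (the union across
#' libraries), not copies. Reads are DNA; T is reported as U.
#'
#' @param libs a `read_library` or list of them.
#' @return named numeric vector over A, C, G, U summing to 1 (all zero when
#'   empty).
#' @export
first_base_composition <- function(libs) {
  libs <- as_lib_list(libs)
  seqs <- unique(unlist(lapply(libs, function(l) l$seq), use.names = FALSE))
  out <- c(A = 0, C = 0, G = 0, U = 0)
  if (length(seqs) == 0L) return(out)
  first <- substr(seqs, 1L, 1L)
  first[first == "T"] <- "U"
  tab <- table(factor(first, levels = c("A", "C", "G", "U")))
  out[] <- as.numeric(tab) / length(seqs)
  out
}

#' Bin references by mapped-read count
#'
#' Each reference with at least one read falls in exactly one bin
#' `[edge_i, edge_{i+1})`, with a final open bin `[last_edge, Inf)`;
#' references with zero reads are reported separately.
#'
#' @param ref_counts named numeric vector of per-reference redundant counts
#'   (zeros included for unmapped references).
#' @param bin_edges strictly increasing count edges
#'   (default powers of ten: 1, 10, 100, ...).
#' @return list with `bins` (named counts of references per range) and
#'   `zero_references` (count of references with no reads).
#' @export
bin_references_by_count <- function(ref_counts,
                                    bin_edges = c(1, 10, 100, 1000, 10000,
                                                  100000)) {
  if (any(diff(bin_edges) <= 0)) stop("bin_edges must be strictly increasing")
  nz <- ref_counts[ref_counts >= bin_edges[1]]
  labels <- c(sprintf("[%g,%g)", utils::head(bin_edges, -1L),
                      bin_edges[-1L]),
              sprintf(">=%g", bin_edges[length(bin_edges)]))
  idx <- findInterval(nz, bin_edges)
  bins <- stats::setNames(tabulate(idx, nbins = length(labels)), labels)
  below <- sum(ref_counts > 0 & ref_counts < bin_edges[1])
  list(bins = bins,
       zero_references = sum(ref_counts == 0),
       below_first_edge = below)
}

#' Hotspot concentration summary
#'
#' Ranks references by redundant count (ties broken by reference id for
#' deterministic reports) and reports the share of all mapped reads carried
#' by the top `top_n` references together with the fraction of total
#' reference length they span. Percentages are rounded half-up to two
#' decimals in the summary fields; the full ranking keeps full precision.
#'
#' @param ref_counts named numeric vector of per-reference redundant counts.
#' @param ref_lengths named numeric vector of reference lengths (nt).
#' @param top_n number of top references to summarize.
#' @return list of class `hotspot_summary`: `ranking` (data.frame with
#'   `ref`, `count`, `cum_share` in percent), `top_n`, `top_n_share`,
#'   `top_n_genome_fraction`.
#' @export
hotspot_summary <- function(ref_counts, ref_lengths, top_n) {
  if (top_n > length(ref_counts)) {
    stop("top_n exceeds the number of references")
  }
  ord <- order(-ref_counts, names(ref_counts))
  counts <- ref_counts[ord]
  total <- sum(counts)
  cum_share <- if (total > 0) 100 * cumsum(counts) / total else
    rep(0, length(counts))
  ranking <- data.frame(ref = names(counts), count = as.numeric(counts),
                        cum_share = cum_share, stringsAsFactors = FALSE)
  rownames(ranking) <- NULL
  top_ids <- names(counts)[seq_len(top_n)]
  structure(list(
    ranking = ranking,
    top_n = top_n,
    top_n_share = pct_share(sum(counts[seq_len(top_n)]), total),
    top_n_genome_fraction = pct_share(sum(ref_lengths[top_ids]),
                                      sum(ref_lengths)),
    top_ids = top_ids), class = "hotspot_summary")
}

#' @export
print.hotspot_summary <- function(x, ...) {
  cat(sprintf("<hotspot_summary> top %d refs: %.2f%% of reads, %.2f%% of sequence\n",
              x$top_n, x$top_n_share, x$top_n_genome_fraction))
  invisible(x)
}
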
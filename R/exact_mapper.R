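# Exact full-length read mapping: 100% identity over the whole read, both
# strands, every occurrence reported. Implemented with Aho-Corasick
# dictionaries (Biostrings::PDict) per read length against the reference
# set concatenated with N spacers (patterns are ACGT-only, so no match can
# cross a spacer).

SPACER_WIDTH <- 64L

# Concatenate a reference set into one subject with spacers; returns the
# DNAString plus the 1-based global start of each reference.
concat_subject <- function(refs) {
  s <- as.character(refs$seqs)
  w <- nchar(s)
  spacer <- strrep("N", SPACER_WIDTH)
  subject <- Biostrings::DNAString(paste(s, collapse = spacer))
  starts <- cumsum(c(1L, utils::head(w + SPACER_WIDTH, -1L)))
  list(subject = subject, starts = starts, ids = names(refs$seqs), width = w)
}

#' Map reads to references requiring full-length 100% identity
#'
#' Reports every occurrence of each distinct read sequence on either strand
#' of every reference. Reads containing non-ACGT characters are skipped and
#' counted (attribute `skipped`, redundant copies).
#'
#' @param lib a `read_library`, or a character vector of read sequences
#'   (copy count 1 each, duplicates aggregated).
#' @param refs a `reference_set`.
#' @return data.frame of class `alignment_table` with columns `seq` (read
#'   sequence), `count` (copy count), `ref`, `start` (0-based), `end`
#'   (exclusive), `strand` (`+`/`-`). For `-` rows the reverse complement of
#'   the forward reference substring `[start, end)` equals the read.
#' @export
map_exact <- function(lib, refs) {
  if (is.character(lib)) lib <- read_library(lib, condition = "reads")
  seqs <- lib$seq
  counts <- lib$count
  ok <- grepl("^[ACGT]+$", seqs)
  skipped <- sum(counts[!ok])
  seqs <- seqs[ok]
  counts <- counts[ok]

  out <- list()
  if (length(seqs) && length(refs$seqs)) {
    cs <- concat_subject(refs)
    widths <- nchar(seqs)
    pats <- Biostrings::DNAStringSet(seqs)
    # one variable-width dictionary per strand: trusted band = the shortest
    # read, heads/tails verified exactly by matchPDict at 0 mismatches
    wmin <- min(widths)
    for (str in c("+", "-")) {
      p <- if (str == "+") pats else Biostrings::reverseComplement(pats)
      pd <- Biostrings::PDict(p, tb.start = 1L, tb.end = wmin)
      m <- Biostrings::matchPDict(pd, cs$subject)
      nh <- S4Vectors::elementNROWS(m)
      if (sum(nh) == 0L) next
      pi <- rep.int(seq_along(nh), nh)
      gstart <- BiocGenerics::start(unlist(m))
      ridx <- findInterval(gstart, cs$starts)
      local0 <- gstart - cs$starts[ridx]
      out[[length(out) + 1L]] <- data.frame(
        seq = seqs[pi], count = counts[pi], ref = cs$ids[ridx],
        start = local0, end = local0 + widths[pi], strand = str,
        stringsAsFactors = FALSE)
    }
  }
  aln <- if (length(out)) do.call(rbind, out) else
    data.frame(seq = character(), count = integer(), ref = character(),
               start = integer(), end = integer(), strand = character(),
               stringsAsFactors = FALSE)
  aln <- aln[order(aln$ref, aln$start, aln$strand, aln$seq), , drop = FALSE]
  rownames(aln) <- NULL
  attr(aln, "skipped") <- skipped
  class(aln) <- c("alignment_table", "data.frame")
  aln
}

# Distinct read sequences with at least one exact full-length hit in refs.
matched_sequences <- function(seqs, refs) {
  seqs <- unique(seqs)
  ok <- grepl("^[ACGT]+$", seqs)
  aln <- map_exact(seqs[ok], refs)
  unique(aln$seq)
}

#' Aggregate an alignment table into per-reference and library counts
#'
#' Per-reference redundant counts sum read copies over occurrences (a read
#' hitting a reference twice contributes its copies twice there); unique
#' counts tally distinct sequences per reference and strand. Library-level
#' totals count each read's copies once no matter how many references it
#' hits, so they never double count multi-mapping reads.
#'
#' @param aln an `alignment_table` from [map_exact()].
#' @param lib the `read_library` the table was computed from (used for the
#'   library label).
#' @return list of class `count_table`: `per_ref` (data.frame with
#'   redundant/unique counts split by strand) and `totals` (list with
#'   `redundant_mapped_total`, `unique_mapped_total`, `references_hit`).
#' @export
count_by_reference <- function(aln, lib = NULL) {
  condition <- if (!is.null(lib)) lib$condition else NA_character_
  if (nrow(aln) == 0L) {
    per_ref <- data.frame(ref = character(), redundant_sense = integer(),
                          redundant_antisense = integer(),
                          unique_sense = integer(),
                          unique_antisense = integer(),
                          stringsAsFactors = FALSE)
    totals <- list(redundant_mapped_total = 0L, unique_mapped_total = 0L,
                   references_hit = 0L)
    return(structure(list(per_ref = per_ref, totals = totals,
                          condition = condition), class = "count_table"))
  }
  key <- paste0(aln$ref, "\r", aln$strand)
  red <- rowsum(aln$count, key)
  dedup <- !duplicated(paste0(aln$seq, "\r", key))
  uni <- rowsum(rep(1L, sum(dedup)), key[dedup])

  split_key <- function(k) {
    parts <- strsplit(k, "\r", fixed = TRUE)
    list(ref = vapply(parts, `[`, "", 1L),
         strand = vapply(parts, `[`, "", 2L))
  }
  rk <- split_key(rownames(red))
  refs_all <- sort(unique(rk$ref))
  per_ref <- data.frame(ref = refs_all,
                        redundant_sense = 0L, redundant_antisense = 0L,
                        unique_sense = 0L, unique_antisense = 0L,
                        stringsAsFactors = FALSE)
  fill <- function(df, key_obj, values, plus_col, minus_col) {
    i <- match(key_obj$ref, df$ref)
    plus <- key_obj$strand == "+"
    df[[plus_col]][i[plus]] <- values[plus]
    df[[minus_col]][i[!plus]] <- values[!plus]
    df
  }
  per_ref <- fill(per_ref, rk, as.integer(red[, 1L]),
                  "redundant_sense", "redundant_antisense")
  uk <- split_key(rownames(uni))
  per_ref <- fill(per_ref, uk, as.integer(uni[, 1L]),
                  "unique_sense", "unique_antisense")

  first <- !duplicated(aln$seq)
  totals <- list(redundant_mapped_total = sum(aln$count[first]),
                 unique_mapped_total = sum(first),
                 references_hit = length(refs_all))
  structure(list(per_ref = per_ref, totals = totals, condition = condition),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> condition=%s refs_hit=%d redundant=%d unique=%d\n",
              x$condition, x$totals$references_hit,
              x$totals$redundant_mapped_total, x$totals$unique_mapped_total))
  invisible(x)
}

#' Map a library and count in one step
#'
#' @param lib a `read_library`.
#' @param refs a `reference_set`.
#' @return list with `aln` (alignment table) and `counts` (count table).
#' @export
map_library <- function(lib, refs) {
  aln <- map_exact(lib, refs)
  list(aln = aln, counts = count_by_reference(aln, lib))
}

#' Mapping summary across libraries, one reference set
#'
#' Produces the per-library redundant/unique/references-mapped summary plus
#' a `Total` row whose redundant count is the sum over libraries, whose
#' unique count is the number of distinct sequences in the union of the
#' libraries' mapped reads (always <= the per-library sum), and whose
#' references-mapped count is the number of references hit by any library.
#'
#' @param libs named list of `read_library`.
#' @param refs a `reference_set`.
#' @param alns optional precomputed list of alignment tables parallel to
#'   `libs` (avoids re-mapping).
#' @return data.frame with columns `library`, `redundant`, `unique`,
#'   `references_mapped`.
#' @export
mapping_summary <- function(libs, refs, alns = NULL) {
  if (is.null(alns)) alns <- lapply(libs, map_exact, refs = refs)
  rows <- Map(function(lib, aln) {
    ct <- count_by_reference(aln, lib)
    data.frame(library = lib$condition,
               redundant = ct$totals$redundant_mapped_total,
               unique = ct$totals$unique_mapped_total,
               references_mapped = ct$totals$references_hit,
               stringsAsFactors = FALSE)
  }, libs, alns)
  all_seq <- unique(unlist(lapply(alns, function(a) unique(a$seq)),
                           use.names = FALSE))
  all_ref <- unique(unlist(lapply(alns, function(a) unique(a$ref)),
                           use.names = FALSE))
  tot <- data.frame(library = "Total",
                    redundant = sum(vapply(rows, function(r) r$redundant, 0L)),
                    unique = length(all_seq),
                    references_mapped = length(all_ref),
                    stringsAsFactors = FALSE)
  out <- rbind(do.call(rbind, rows), tot)
  rownames(out) <- NULL
  out
}

#' Pool per-strand reference counts across libraries
#'
#' Redundant counts are summed over libraries; unique counts are the number
#' of distinct sequences in the pooled union per reference and strand.
#'
#' @param alns list of alignment tables (one per library).
#' @return data.frame with columns `ref`, `redundant_sense`,
#'   `redundant_antisense`, `unique_sense`, `unique_antisense`.
#' @export
pooled_strand_counts <- function(alns) {
  aln <- do.call(rbind, lapply(alns, function(a) {
    as.data.frame(a)[, c("seq", "count", "ref", "strand")]
  }))
  if (is.null(aln) || nrow(aln) == 0L) {
    return(data.frame(ref = character(), redundant_sense = integer(),
                      redundant_antisense = integer(),
                      unique_sense = integer(), unique_antisense = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- paste0(aln$ref, "\r", aln$strand)
  red <- rowsum(aln$count, key)
  dedup <- !duplicated(paste0(aln$seq, "\r", key))
  uni <- rowsum(rep(1L, sum(dedup)), key[dedup])
  refs_all <- sort(unique(aln$ref))
  out <- data.frame(ref = refs_all, redundant_sense = 0L,
                    redundant_antisense = 0L, unique_sense = 0L,
                    unique_antisense = 0L, stringsAsFactors = FALSE)
  assign_col <- function(out, tab, plus_col, minus_col) {
    parts <- strsplit(rownames(tab), "\r", fixed = TRUE)
    r <- vapply(parts, `[`, "", 1L)
    s <- vapply(parts, `[`, "", 2L)
    i <- match(r, out$ref)
    out[[plus_col]][i[s == "+"]] <- as.integer(tab[s == "+", 1L])
    out[[minus_col]][i[s == "-"]] <- as.integer(tab[s == "-", 1L])
    out
  }
  out <- assign_col(out, red, "redundant_sense", "redundant_antisense")
  out <- assign_col(out, uni, "unique_sense", "unique_antisense")
  out
}

#' Export an alignment table as BED6
#'
#' 0-based half-open coordinates; name is the read sequence, score its copy
#' count.
#'
#' @param aln an `alignment_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment_bed <- function(aln, path) {
  bed <- data.frame(chrom = aln$ref, start = aln$start, end = aln$end,
                    name = aln$seq, score = aln$count, strand = aln$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
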
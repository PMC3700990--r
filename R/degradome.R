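# Degradome 5'-end pileups, per-CDS normalization, stop-distance profile,
# >=3x-mean peak calling, factor histogram, randomized control and the
# sRNA-peak permutation overlap test.

#' Per-CDS 5'-end degradome pileups
#'
#' Each sense alignment contributes its copies at its 5'-most CDS coordinate
#' (the alignment start); antisense alignments are tallied separately at
#' their own 5' end, which in forward coordinates is `end - 1`. Per-CDS
#' relative frequencies normalize sense tag counts to the total tag count on
#' that CDS. Every CDS of the reference set gets a profile (empty when no
#' tag mapped).
#'
#' @param aln an `alignment_table` of degradome tags mapped to the CDS set
#'   (size-filtered to 25-45 nt and poly-A trimmed beforehand).
#' @param cds the CDS `reference_set`.
#' @return object of class `degradome_profiles`: a named list, one element
#'   per CDS, each with `pos` (0-based sense positions with tags), `count`,
#'   `rel_freq` (count / total), `total`, `n_nonzero`, and `antisense`
#'   (data.frame `pos`, `count` of antisense 5' ends); attribute `lengths`
#'   holds the CDS lengths.
#' @export
pileup_5prime <- function(aln, cds) {
  lens <- ref_lengths(cds)
  profiles <- stats::setNames(vector("list", length(lens)), names(lens))
  sense <- aln[aln$strand == "+", , drop = FALSE]
  anti <- aln[aln$strand == "-", , drop = FALSE]
  anti_pos <- anti$end - 1L
  s_split <- split(seq_len(nrow(sense)), sense$ref)
  a_split <- split(seq_len(nrow(anti)), anti$ref)
  for (id in names(lens)) {
    si <- s_split[[id]]
    if (length(si)) {
      tab <- rowsum(sense$count[si], sense$start[si])
      pos <- as.integer(rownames(tab))
      cnt <- as.integer(tab[, 1L])
      ord <- order(pos)
      pos <- pos[ord]
      cnt <- cnt[ord]
    } else {
      pos <- integer()
      cnt <- integer()
    }
    ai <- a_split[[id]]
    if (length(ai)) {
      atab <- rowsum(anti$count[ai], anti_pos[ai])
      adf <- data.frame(pos = as.integer(rownames(atab)),
                        count = as.integer(atab[, 1L]))
      adf <- adf[order(adf$pos), , drop = FALSE]
      rownames(adf) <- NULL
    } else {
      adf <- data.frame(pos = integer(), count = integer())
    }
    total <- sum(cnt)
    profiles[[id]] <- list(cds = id, pos = pos, count = cnt,
                           rel_freq = if (total > 0) cnt / total else
                             numeric(),
                           total = total, n_nonzero = length(pos),
                           antisense = adf)
  }
  structure(profiles, lengths = lens, class = "degradome_profiles")
}

#' Per-reference degradome strand counts for orientation
#'
#' @param profiles a `degradome_profiles`.
#' @return data.frame `ref`, `degradome_sense`, `degradome_antisense`.
#' @export
degradome_strand_counts <- function(profiles) {
  data.frame(
    ref = names(profiles),
    degradome_sense = vapply(profiles, function(p) p$total, 0),
    degradome_antisense = vapply(profiles,
                                 function(p) sum(p$antisense$count), 0),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Average relative tag frequency by distance from the stop codon
#'
#' Distance 0 is the first nucleotide of the stop codon, increasing toward
#' 5'. For each distance the value is the sum over CDSs of the relative
#' frequency at that position divided by the total number of CDSs in the
#' analysis -- a fixed denominator, so CDSs that are shorter than a given
#' distance (or have no tags) contribute zero there. Positions 3' of the
#' stop anchor (inside the stop codon) are ignored.
#'
#' @param profiles a `degradome_profiles`.
#' @param max_distance largest distance reported (default 500 nt).
#' @return data.frame `distance`, `mean_rel_freq`.
#' @export
stop_distance_profile <- function(profiles, max_distance = 500L) {
  lens <- attr(profiles, "lengths")
  n_cds <- length(profiles)
  acc <- numeric(max_distance + 1L)
  for (p in profiles) {
    if (p$total == 0L) next
    d <- (lens[[p$cds]] - 3L) - p$pos
    keep <- d >= 0L & d <= max_distance
    if (any(keep)) {
      acc[d[keep] + 1L] <- acc[d[keep] + 1L] + p$rel_freq[keep]
    }
  }
  data.frame(distance = 0:max_distance, mean_rel_freq = acc / n_cds)
}

#' Call degradome peaks at or above a factor of the per-CDS mean
#'
#' A position is a peak when its relative frequency is at least
#' `factor_threshold` times the mean relative frequency of the CDS, where
#' the mean is taken over positions with at least one tag
#' (`mean_mode = "nonzero"`, the default: a "peak" is a nonzero position)
#' or over all positions of the CDS (`mean_mode = "all"`). Equality
#' survives: only peaks strictly below the threshold are removed. CDSs with
#' no tags yield no peaks, and peak calls are invariant under rescaling all
#' counts of a CDS.
#'
#' @param profiles a `degradome_profiles`.
#' @param factor_threshold multiple of the mean (default 3; must be > 1).
#' @param mean_mode `"nonzero"` or `"all"`.
#' @return data.frame of class `peak_table`: `cds`, `pos`, `count`,
#'   `rel_freq`, `factor`.
#' @export
call_peaks <- function(profiles, factor_threshold = 3,
                       mean_mode = c("nonzero", "all")) {
  stopifnot(factor_threshold > 1)
  mean_mode <- match.arg(mean_mode)
  lens <- attr(profiles, "lengths")
  rows <- lapply(profiles, function(p) {
    if (p$total == 0L) return(NULL)
    k <- if (mean_mode == "nonzero") p$n_nonzero else lens[[p$cds]]
    factor <- p$rel_freq * k
    keep <- factor >= factor_threshold - 1e-12
    if (!any(keep)) return(NULL)
    data.frame(cds = p$cds, pos = p$pos[keep], count = p$count[keep],
               rel_freq = p$rel_freq[keep], factor = factor[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cds = character(), pos = integer(), count = integer(),
                      rel_freq = numeric(), factor = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Histogram of peak factors
#'
#' Bin b holds peaks whose factor floors to b, for b in 3..12; the final
#' bin holds every factor >= 13.
#'
#' @param peaks output of [call_peaks()].
#' @return named integer vector over bins `3`..`12` and `13+`.
#' @export
peak_factor_histogram <- function(peaks) {
  labels <- c(as.character(3:12), "13+")
  out <- stats::setNames(integer(length(labels)), labels)
  if (nrow(peaks)) {
    b <- pmin(floor(peaks$factor + 1e-9), 13)
    tab <- table(factor(b, levels = 3:13))
    out[] <- as.integer(tab)
  }
  out
}

# Map uniform draws over the concatenated CDS length back to (cds, pos).
sample_cds_positions <- function(n, cds_lengths) {
  cs <- cumsum(as.numeric(cds_lengths))
  g <- sample.int(cs[length(cs)], n, replace = TRUE)
  idx <- findInterval(g - 1, c(0, cs))
  data.frame(cds = names(cds_lengths)[idx],
             pos = as.integer(g - 1 - c(0, cs)[idx]),
             stringsAsFactors = FALSE)
}

#' Random peak control
#'
#' Places the same number of pseudo-peaks uniformly at random, each on a
#' CDS drawn with probability proportional to its length and at a uniform
#' position within it. Deterministic under `seed`.
#'
#' @param peaks a `peak_table` (only its row count is used) or an integer
#'   count.
#' @param cds_lengths named vector of CDS lengths.
#' @param seed RNG seed.
#' @return data.frame `cds`, `pos` with as many rows as `peaks`.
#' @export
random_peak_control <- function(peaks, cds_lengths, seed = 1L) {
  n <- if (is.numeric(peaks)) as.integer(peaks) else nrow(peaks)
  with_seed(seed, sample_cds_positions(n, cds_lengths))
}

#' Permutation test for sRNA / degradome-peak overlap
#'
#' A peak overlaps when any mapped sRNA interval (either strand) covers its
#' position. The observed overlap count is compared to `n_permutations`
#' random placements of the same number of peaks (length-weighted uniform,
#' the same scheme as [random_peak_control()]); the empirical p-value is
#' `(1 + #{control >= observed}) / (1 + n_permutations)`.
#'
#' @param peaks a `peak_table` (or data.frame with `cds`, `pos`).
#' @param srna_aln `alignment_table` of sRNAs mapped to the CDS set.
#' @param cds_lengths named vector of CDS lengths.
#' @param n_permutations number of control replicates (>= 1).
#' @param seed RNG seed.
#' @return list: `observed`, `control` (integer vector of replicate
#'   overlaps), `p_value`, `n_permutations`.
#' @export
srna_peak_overlap_test <- function(peaks, srna_aln, cds_lengths,
                                   n_permutations = 199L, seed = 1L) {
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  cs <- cumsum(as.numeric(cds_lengths))
  offsets <- stats::setNames(c(0, utils::head(cs, -1L)), names(cds_lengths))
  total <- cs[length(cs)]

  cov <- rep(FALSE, total)
  s <- srna_aln[srna_aln$ref %in% names(cds_lengths), , drop = FALSE]
  if (nrow(s)) {
    gs <- offsets[s$ref] + s$start + 1
    ge <- offsets[s$ref] + s$end
    rle_cov <- IRanges::coverage(IRanges::IRanges(gs, ge), width = total)
    cov <- as.vector(rle_cov > 0)
  }
  gp <- offsets[peaks$cds] + peaks$pos + 1
  observed <- sum(cov[gp])

  n <- nrow(peaks)
  ctrl <- if (n == 0L) integer(n_permutations) else with_seed(seed, {
    samp <- sample.int(total, n * n_permutations, replace = TRUE)
    as.integer(colSums(matrix(cov[samp], nrow = n)))
  })
  list(observed = observed, control = ctrl,
       p_value = (1 + sum(ctrl >= observed)) / (1 + n_permutations),
       n_permutations = n_permutations)
}

#' Export peaks as single-base BED intervals
#'
#' @param peaks a `peak_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_peak_bed <- function(peaks, path) {
  bed <- data.frame(chrom = peaks$cds, start = peaks$pos,
                    end = peaks$pos + 1L,
                    name = sprintf("peak_%05d", seq_len(nrow(peaks))),
                    score = round(peaks$factor, 2), strand = "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
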
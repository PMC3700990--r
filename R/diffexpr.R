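# RPKM normalization and the 100-RPKM / 10-fold differential filter.

#' RPKM expression matrix
#'
#' `RPKM(c, l) = count(c, l) / (length_kb(c) * mapped_millions(l))`:
#' reads per kilobase of CDS per million library-mapped reads, where the
#' library size is the per-library redundant total mapped to the CDS set.
#'
#' @param counts integer matrix, CDS rows by condition columns.
#' @param cds_lengths named vector of CDS lengths (nt, > 0).
#' @param library_sizes named vector of per-library mapped totals (> 0).
#' @return numeric RPKM matrix with the same dimnames.
#' @export
rpkm <- function(counts, cds_lengths, library_sizes) {
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  len_kb <- cds_lengths[rownames(counts)] / 1000
  if (any(is.na(len_kb)) || any(len_kb <= 0)) {
    stop("every CDS needs a positive length")
  }
  m <- library_sizes[colnames(counts)] / 1e6
  sweep(sweep(counts, 1, len_kb, "/"), 2, m, "/")
}

#' Filter differentially expressed CDSs
#'
#' A CDS is retained when (i) its RPKM reaches `min_rpkm` in at least one
#' condition and (ii) for some stress condition the fold change against the
#' reference condition is at least `min_fold`. Fold change between values
#' `a` and `b` is `max(a, b) / max(min(a, b), eps)` where the pseudo-floor
#' `eps` is the RPKM a single read would have in the library holding the
#' smaller value -- this keeps CDSs that switch off entirely well-defined.
#' Each record is labelled up- or down-regulated under stress by the
#' direction of the largest qualifying ratio. Raising `min_fold` can only
#' shrink the result.
#'
#' @param mat RPKM matrix from [rpkm()].
#' @param cds_lengths,library_sizes as in [rpkm()] (used for the
#'   single-read pseudo-floor).
#' @param min_rpkm expression floor (default 100).
#' @param min_fold fold-change threshold (default 10).
#' @param reference_condition the unstressed column (default `"normal"`).
#' @return data.frame: `cds`, `condition` (stress condition of the largest
#'   qualifying fold), `fold`, `direction` (`"up"`/`"down"` under stress),
#'   plus one RPKM column per condition.
#' @export
filter_differential <- function(mat, cds_lengths, library_sizes,
                                min_rpkm = 100, min_fold = 10,
                                reference_condition = "normal") {
  if (!reference_condition %in% colnames(mat)) {
    stop("reference condition not present: ", reference_condition)
  }
  stress <- setdiff(colnames(mat), reference_condition)
  len_kb <- cds_lengths[rownames(mat)] / 1000
  m <- library_sizes[colnames(mat)] / 1e6
  eps_one_read <- 1 / outer(len_kb, m)  # RPKM of a single read per cell
  dimnames(eps_one_read) <- dimnames(mat)

  rows <- lapply(seq_len(nrow(mat)), function(i) {
    if (max(mat[i, ]) < min_rpkm) return(NULL)
    b <- mat[i, reference_condition]
    best <- NULL
    for (s in stress) {
      a <- mat[i, s]
      lo <- min(a, b)
      lo_col <- if (a <= b) s else reference_condition
      ratio <- max(a, b) / max(lo, eps_one_read[i, lo_col])
      if (ratio >= min_fold && (is.null(best) || ratio > best$ratio)) {
        best <- list(s = s, ratio = ratio,
                     direction = if (a > b) "up" else "down")
      }
    }
    if (is.null(best)) return(NULL)
    cbind(data.frame(cds = rownames(mat)[i], condition = best$s,
                     fold = best$ratio, direction = best$direction,
                     stringsAsFactors = FALSE),
          as.data.frame(t(mat[i, ])))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- cbind(data.frame(cds = character(), condition = character(),
                            fold = numeric(), direction = character(),
                            stringsAsFactors = FALSE),
                 stats::setNames(as.data.frame(matrix(numeric(), 0,
                                                      ncol(mat))),
                                 colnames(mat)))
  }
  rownames(out) <- NULL
  out
}

#' Cluster differential records and summarize
#'
#' Orders the retained CDSs by agglomerative hierarchical clustering
#' (average linkage, Euclidean distance on `log2(RPKM + 1)`), the usual
#' heat-map row ordering; identical expression rows merge at distance zero
#' and end up adjacent. The summary tallies up- versus down-regulated
#' records and, when strand-bias records are supplied, how many retained
#' CDSs have predominantly sense versus antisense sRNAs.
#'
#' @param records output of [filter_differential()] (must be nonempty).
#' @param mat the RPKM matrix the records came from.
#' @param bias_records optional output of [srna_strand_profile()].
#' @return list: `order` (CDS ids in dendrogram order), `matrix` (log2
#'   RPKM + 1, reordered), `hclust` (NULL for a single record), `summary`
#'   (named counts).
#' @export
cluster_and_summarize <- function(records, mat, bias_records = NULL) {
  if (nrow(records) == 0L) stop("records must be nonempty")
  lm <- log2(mat[records$cds, , drop = FALSE] + 1)
  if (nrow(lm) == 1L) {
    ord <- 1L
    hc <- NULL
  } else {
    hc <- stats::hclust(stats::dist(lm), method = "average")
    ord <- hc$order
  }
  summary <- c(total = nrow(records),
               up = sum(records$direction == "up"),
               down = sum(records$direction == "down"))
  if (!is.null(bias_records)) {
    cls <- bias_records$bias_class[match(records$cds, bias_records$ref)]
    summary <- c(summary,
                 sense_prevalent = sum(cls == "sense_prevalent",
                                       na.rm = TRUE),
                 antisense = sum(cls %in% c("antisense_biased",
                                            "antisense_only"), na.rm = TRUE),
                 unprofiled = sum(is.na(cls)))
  }
  list(order = records$cds[ord], matrix = lm[ord, , drop = FALSE],
       hclust = hc, summary = summary)
}
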
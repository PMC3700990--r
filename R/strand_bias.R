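# Degradome-based transcript orientation and sense/antisense strand-bias
# classification of exonic sRNAs.

#' Orient references by degradome evidence
#'
#' A reference is retained when its degradome sense fraction exceeds the
#' threshold -- strictly greater for CDSs (prevalent sense transcription,
#' > 0.75) or greater-or-equal for ESTs (>= 0.70) -- or when it has sense
#' tags and no antisense tag at all (the absence rule). CDSs are already
#' directional through their reading frame; degradome orientation is used
#' as corroborating evidence and disagreements can be inspected in the
#' returned table.
#'
#' @param deg_counts data.frame with columns `ref`, `degradome_sense`,
#'   `degradome_antisense` (e.g. renamed from [pooled_strand_counts()]).
#' @param threshold sense-fraction threshold (0.75 for CDSs, 0.70 for ESTs).
#' @param inclusive logical; `FALSE` (CDS rule, strict >) or `TRUE`
#'   (EST rule, >=).
#' @return the input rows of the retained references, with `sense_fraction`
#'   and `oriented_by` (`"fraction"` or `"absence"`) columns added.
#' @export
orient_references <- function(deg_counts, threshold = 0.75,
                              inclusive = FALSE) {
  s <- deg_counts$degradome_sense
  a <- deg_counts$degradome_antisense
  tot <- s + a
  frac <- ifelse(tot > 0, s / tot, NA_real_)
  by_frac <- !is.na(frac) &
    (if (inclusive) frac >= threshold else frac > threshold)
  by_abs <- a == 0 & s > 0
  keep <- by_frac | by_abs
  out <- deg_counts[keep, , drop = FALSE]
  out$sense_fraction <- frac[keep]
  out$oriented_by <- ifelse(by_abs[keep], "absence", "fraction")
  rownames(out) <- NULL
  out
}

#' Per-reference sRNA strand profile
#'
#' For each oriented reference with at least `min_srna` sRNAs (redundant
#' copies, or distinct sequences when `unique_mode`), computes the percent
#' of sense and antisense sRNAs and assigns a bias class:
#' `antisense_only` (no sense sRNA), `antisense_biased`
#' (antisense percentage > 50), otherwise `sense_prevalent`. Exact 50/50
#' ties count as `sense_prevalent` and are flagged in the `tie` column.
#' Records are sorted by percent sense, descending.
#'
#' @param srna_counts data.frame with columns `ref`, `redundant_sense`,
#'   `redundant_antisense`, `unique_sense`, `unique_antisense`
#'   (see [pooled_strand_counts()]).
#' @param oriented_ids character vector of retained reference ids from
#'   [orient_references()]; `NULL` keeps all.
#' @param min_srna minimum sRNA total (default 10).
#' @param unique_mode count distinct sequences instead of copies.
#' @return data.frame of strand-bias records with columns `ref`, `sense`,
#'   `antisense`, `pct_sense`, `pct_antisense`, `bias_class`, `tie`.
#' @export
srna_strand_profile <- function(srna_counts, oriented_ids = NULL,
                                min_srna = 10L, unique_mode = FALSE) {
  stopifnot(min_srna >= 1L)
  df <- srna_counts
  if (!is.null(oriented_ids)) df <- df[df$ref %in% oriented_ids, , drop = FALSE]
  s <- if (unique_mode) df$unique_sense else df$redundant_sense
  a <- if (unique_mode) df$unique_antisense else df$redundant_antisense
  keep <- (s + a) >= min_srna
  s <- s[keep]
  a <- a[keep]
  tot <- s + a
  pct_s <- 100 * s / tot
  pct_a <- 100 * a / tot
  class <- ifelse(s == 0, "antisense_only",
                  ifelse(pct_a > 50, "antisense_biased", "sense_prevalent"))
  out <- data.frame(ref = df$ref[keep], sense = s, antisense = a,
                    pct_sense = pct_s, pct_antisense = pct_a,
                    bias_class = class, tie = pct_s == 50 & pct_a == 50,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$pct_sense, out$ref), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summary counts over strand-bias records
#'
#' @param records output of [srna_strand_profile()].
#' @param antisense_min threshold for the "more than `antisense_min`
#'   antisense sRNAs" tally (default 20).
#' @return named integer vector: `total`, `sense_prevalent`,
#'   `antisense_biased` (percent antisense > 50), `antisense_only`,
#'   `antisense_gt_threshold` (antisense count > `antisense_min`),
#'   `sense_prevalent_with_antisense` (sense-prevalent with >= 1 antisense
#'   sRNA), `ties`.
#' @export
classify_bias_summary <- function(records, antisense_min = 20L) {
  cls <- records$bias_class
  c(total = nrow(records),
    sense_prevalent = sum(cls == "sense_prevalent"),
    antisense_biased = sum(cls %in% c("antisense_biased", "antisense_only")),
    antisense_only = sum(cls == "antisense_only"),
    antisense_gt_threshold = sum(records$antisense > antisense_min),
    sense_prevalent_with_antisense = sum(cls == "sense_prevalent" &
                                           records$antisense >= 1L),
    ties = sum(records$tie))
}
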
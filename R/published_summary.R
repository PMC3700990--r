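#' Published genome-scale mapping summary for *Cyanophora paradoxa*
#'
#' The per-library redundant/unique mapped-read counts and
#' references-mapped tallies of the published genome-scale *C. paradoxa*
#' sRNA study (four libraries: normal, cold, salt, light; mapped to 60,119
#' genome contigs, 31,895 CDSs and 15,003 EST contigs > 199 bp). Shipped as
#' a plain TSV and used as an arithmetic input: the full read data are not
#' redistributable at desk scale, but the printed per-library counts let the
#' aggregation, hotspot-share and coverage arithmetic be checked exactly.
#'
#' @return data.frame with columns `reference_set`, `library`, `redundant`,
#'   `unique`, `references_mapped`, `references_total`; the `Total` rows are
#'   the published totals (the unique total is over the union of distinct
#'   sequences, hence below the per-library sum).
#' @export
published_mapping_summary <- function() {
  path <- system.file("extdata", "cyanophora_srna_mapping_summary.tsv",
                      package = "srnadeg", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Aggregate per-library redundant counts of a mapping summary
#'
#' Sums the per-library redundant counts of each reference set (excluding
#' any `Total` row) and reports the per-set reference coverage
#' (references mapped / references total, percent, from the `Total` row).
#'
#' @param df a data.frame shaped like [published_mapping_summary()].
#' @return data.frame with one row per reference set: `redundant_total`
#'   (sum over libraries), `published_total` (the `Total` row, NA if
#'   absent), `coverage_pct`.
#' @export
summarize_mapping_table <- function(df) {
  sets <- unique(df$reference_set)
  rows <- lapply(sets, function(s) {
    d <- df[df$reference_set == s, , drop = FALSE]
    lib <- d[d$library != "Total", , drop = FALSE]
    tot <- d[d$library == "Total", , drop = FALSE]
    data.frame(reference_set = s,
               redundant_total = sum(lib$redundant),
               published_total = if (nrow(tot)) tot$redundant else NA,
               coverage_pct = if (nrow(tot)) {
                 pct_share(tot$references_mapped, tot$references_total)
               } else NA,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
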
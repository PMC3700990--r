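#' Default insert-length distribution (15-35 nt, 21-nt mode)
#'
#' The simulator draws insert lengths over 15-35 nt so that the downstream
#' 16-32 nt size filter is actually exercised (the wet-lab gel excises
#' 15-35 nt while the computational filter keeps 16-32 nt). The distribution
#' peaks sharply at 21 nt, the modal class of plant-like small RNAs.
#'
#' @return named numeric vector over lengths 15..35 summing to 1.
#' @export
default_length_dist <- function() {
  len <- 15:35
  w <- exp(-abs(len - 21)^1.5 / 2.5)
  stats::setNames(w / sum(w), len)
}

#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic-data generator.
#' Defaults are the package's stated world: a desk-scale genome (600 contigs,
#' 500 CDSs) with the statistical structure seen in plant-like small-RNA and
#' degradome data: 21-nt modal insert length with A/U-enriched 5' base, a few
#' hotspot contigs attracting most genomic reads, per-CDS sense/antisense
#' bias mixtures, a 3'-biased exonucleolytic degradome background with
#' planted endonucleolytic spikes and occasional poly-A tails, and planted
#' >=10-fold condition-specific expression changes.
#'
#' @param seed integer RNG seed; a fixed seed makes every generator output
#'   byte-identical.
#' @param n_genome_contigs,n_cds,n_est,n_contaminants set sizes. Each CDS is
#'   embedded in its own genome contig, so `n_cds <= n_genome_contigs`.
#' @param cds_length_range CDS length bounds (nt); generated lengths are
#'   trimmed to a multiple of 3.
#' @param genome_contig_length_range,est_length_range,contaminant_length_range
#'   length bounds (nt) for the other sets; ESTs are always > 199 nt.
#' @param frac_cds_with_srna fraction of CDSs producing any sRNA; must equal
#'   `1 - bias_mixture["no_srna"]`.
#' @param bias_mixture proportions over the four per-CDS classes
#'   `sense_prevalent`, `antisense_biased`, `antisense_only`, `no_srna`;
#'   must sum to 1.
#' @param hotspot_frac_contigs fraction of genome contigs designated hotspots.
#' @param hotspot_read_share share of non-contaminant sRNA reads drawn from
#'   hotspot contigs.
#' @param length_dist insert-length probabilities (named by length, nt).
#' @param first_base_dist probabilities of the read 5' base over A/C/G/U
#'   (reads are emitted in DNA alphabet; U means T).
#' @param conditions the four library labels; the first is the unstressed
#'   reference condition.
#' @param n_srna_reads raw sRNA reads generated per condition.
#' @param fold_change_loci number of CDSs with a planted expression change.
#' @param fold_change_factor planted fold change (>= 10).
#' @param degradome_background_rate exonucleolytic background, tags per nt
#'   of CDS.
#' @param degradome_3prime_bias decay constant (per nt) of the exponential
#'   pull of background tag 5' ends toward the stop codon; 0 means uniform.
#' @param degradome_antisense_frac antisense fraction of degradome tags for
#'   ordinary CDSs.
#' @param ambiguous_cds_frac fraction of CDSs given an elevated antisense
#'   degradome fraction (`ambiguous_antisense_frac`), exercising the
#'   rejection branch of the >75% orientation rule.
#' @param ambiguous_antisense_frac antisense degradome fraction of the
#'   ambiguous subset (> 0.25).
#' @param peak_cds_frac fraction of CDSs receiving one planted degradome peak.
#' @param planted_peak_factor_range bounds of the planted peak factor
#'   (multiples of the per-CDS mean tag frequency); both >= 3.
#' @param polya_tail_prob probability a degradome tag carries a 3-10 nt
#'   poly-A tail.
#' @param contaminant_read_frac fraction of sRNA reads drawn from the
#'   contaminant (rRNA/tRNA/plastid) set.
#' @param barcode_map named character vector condition -> 4-nt barcode.
#' @param adapter3 3' adapter sequence appended to every sRNA read.
#' @param class_sense_prob per-class probability that an sRNA read is sense.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genome_contigs = 600L,
                       n_cds = 500L,
                       n_est = 250L,
                       n_contaminants = 20L,
                       cds_length_range = c(300L, 900L),
                       genome_contig_length_range = c(1500L, 2500L),
                       est_length_range = c(250L, 1200L),
                       contaminant_length_range = c(120L, 1500L),
                       frac_cds_with_srna = 0.75,
                       bias_mixture = c(sense_prevalent = 0.58,
                                        antisense_biased = 0.14,
                                        antisense_only = 0.03,
                                        no_srna = 0.25),
                       hotspot_frac_contigs = 0.005,
                       hotspot_read_share = 0.83,
                       length_dist = default_length_dist(),
                       first_base_dist = c(A = 0.30, C = 0.20,
                                           G = 0.22, U = 0.28),
                       conditions = c("normal", "cold", "salt", "light"),
                       n_srna_reads = 30000L,
                       fold_change_loci = 8L,
                       fold_change_factor = 12,
                       degradome_background_rate = 0.2,
                       degradome_3prime_bias = 0.01,
                       degradome_antisense_frac = 0.10,
                       ambiguous_cds_frac = 0.10,
                       ambiguous_antisense_frac = 0.35,
                       peak_cds_frac = 0.5,
                       planted_peak_factor_range = c(5, 12),
                       polya_tail_prob = 0.10,
                       contaminant_read_frac = 0.05,
                       barcode_map = c(normal = "AACC", cold = "GGTT",
                                       salt = "ACAC", light = "GTGT"),
                       adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                       class_sense_prob = c(sense_prevalent = 0.85,
                                            antisense_biased = 0.25,
                                            antisense_only = 0)) {
  cfg <- list(seed = as.integer(seed),
              n_genome_contigs = as.integer(n_genome_contigs),
              n_cds = as.integer(n_cds),
              n_est = as.integer(n_est),
              n_contaminants = as.integer(n_contaminants),
              cds_length_range = as.integer(cds_length_range),
              genome_contig_length_range = as.integer(genome_contig_length_range),
              est_length_range = as.integer(est_length_range),
              contaminant_length_range = as.integer(contaminant_length_range),
              frac_cds_with_srna = frac_cds_with_srna,
              bias_mixture = bias_mixture,
              hotspot_frac_contigs = hotspot_frac_contigs,
              hotspot_read_share = hotspot_read_share,
              length_dist = length_dist,
              first_base_dist = first_base_dist,
              conditions = conditions,
              n_srna_reads = as.integer(n_srna_reads),
              fold_change_loci = as.integer(fold_change_loci),
              fold_change_factor = fold_change_factor,
              degradome_background_rate = degradome_background_rate,
              degradome_3prime_bias = degradome_3prime_bias,
              degradome_antisense_frac = degradome_antisense_frac,
              ambiguous_cds_frac = ambiguous_cds_frac,
              ambiguous_antisense_frac = ambiguous_antisense_frac,
              peak_cds_frac = peak_cds_frac,
              planted_peak_factor_range = planted_peak_factor_range,
              polya_tail_prob = polya_tail_prob,
              contaminant_read_frac = contaminant_read_frac,
              barcode_map = barcode_map,
              adapter3 = adapter3,
              class_sense_prob = class_sense_prob)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  frac_fields <- c("frac_cds_with_srna", "hotspot_frac_contigs",
                   "hotspot_read_share", "degradome_antisense_frac",
                   "ambiguous_cds_frac", "ambiguous_antisense_frac",
                   "peak_cds_frac", "polya_tail_prob", "contaminant_read_frac")
  for (f in frac_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) stop(f, " must lie in [0, 1]")
  }
  if (abs(sum(cfg$bias_mixture) - 1) > 1e-8) stop("bias_mixture must sum to 1")
  need <- c("sense_prevalent", "antisense_biased", "antisense_only", "no_srna")
  if (!setequal(names(cfg$bias_mixture), need)) {
    stop("bias_mixture must name the four classes: ",
         paste(need, collapse = ", "))
  }
  if (abs((1 - cfg$bias_mixture[["no_srna"]]) - cfg$frac_cds_with_srna) > 0.02) {
    stop("frac_cds_with_srna must equal 1 - bias_mixture['no_srna']")
  }
  if (abs(sum(cfg$length_dist) - 1) > 1e-8) stop("length_dist must sum to 1")
  if (abs(sum(cfg$first_base_dist) - 1) > 1e-8) {
    stop("first_base_dist must sum to 1")
  }
  if (!setequal(names(cfg$first_base_dist), c("A", "C", "G", "U"))) {
    stop("first_base_dist must be named over A, C, G, U")
  }
  if (length(cfg$conditions) != 4L) stop("exactly 4 conditions are expected")
  if (!setequal(names(cfg$barcode_map), cfg$conditions)) {
    stop("barcode_map must name every condition")
  }
  if (anyDuplicated(cfg$barcode_map)) stop("barcodes must be mutually distinct")
  if (length(unique(nchar(cfg$barcode_map))) != 1L) {
    stop("barcodes must share one length")
  }
  if (cfg$n_cds > cfg$n_genome_contigs) {
    stop("n_cds exceeds what fits in the generated genome ",
         "(one CDS per contig; need n_cds <= n_genome_contigs)")
  }
  if (cfg$fold_change_factor < 10) stop("fold_change_factor must be >= 10")
  if (any(cfg$planted_peak_factor_range < 3)) {
    stop("planted peak factors must be >= 3")
  }
  if (diff(cfg$cds_length_range) < 0 || cfg$cds_length_range[1] < 60) {
    stop("cds_length_range must be increasing and >= 60 nt")
  }
  if (cfg$est_length_range[1] <= 199L) {
    stop("est_length_range must generate sequences > 199 nt")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> seed=%d contigs=%d cds=%d est=%d ",
                     "reads/condition=%d\n"),
              x$seed, x$n_genome_contigs, x$n_cds, x$n_est, x$n_srna_reads))
  invisible(x)
}
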
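# End-to-end orchestration with a single configuration, per-stage reports
# and a reproducibility manifest.

#' Workflow configuration
#'
#' Holds either a [sim_config()] (self-contained simulated run) or file
#' paths to references and raw FASTQ input, plus every stage parameter at
#' its standard default: 16-32 nt sRNA window, 25-45 nt degradome window,
#' full-length 100%-identity mapping, > 75% (CDS) / >= 70% (EST) degradome
#' orientation, >= 10 sRNAs per profiled CDS, >= 3x-mean peaks, 100 RPKM
#' and 10-fold differential thresholds.
#'
#' @param sim optional [sim_config()]; when given, input paths are ignored.
#' @param srna_fastq,degradome_fastq raw FASTQ paths (file mode).
#' @param genome_fasta,cds_fasta,est_fasta,contaminant_fasta reference
#'   FASTA paths (file mode; `est_fasta`/`contaminant_fasta` optional).
#' @param barcode_map,adapter3 demultiplexing parameters (file mode).
#' @param srna_size,degradome_size inclusive length windows.
#' @param orient_threshold_cds,orient_threshold_est degradome sense-fraction
#'   thresholds (strict > for CDSs, >= for ESTs).
#' @param min_srna minimum sRNA count for strand-bias records.
#' @param peak_factor peak-calling threshold (multiple of the mean).
#' @param min_rpkm,min_fold,reference_condition differential filter.
#' @param polya_min_tail poly-A trimming threshold.
#' @param n_permutations overlap-test permutations.
#' @param seed seed for the randomized stages.
#' @param out_dir output directory for reports (required by [run_all()]).
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = NULL,
                       srna_fastq = NULL, degradome_fastq = NULL,
                       genome_fasta = NULL, cds_fasta = NULL,
                       est_fasta = NULL, contaminant_fasta = NULL,
                       barcode_map = NULL, adapter3 = NULL,
                       srna_size = c(16L, 32L),
                       degradome_size = c(25L, 45L),
                       orient_threshold_cds = 0.75,
                       orient_threshold_est = 0.70,
                       min_srna = 10L,
                       peak_factor = 3,
                       min_rpkm = 100,
                       min_fold = 10,
                       reference_condition = "normal",
                       polya_min_tail = 4L,
                       n_permutations = 199L,
                       seed = 1L,
                       out_dir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

need_file <- function(path, what) {
  if (is.null(path) || !file.exists(path)) {
    stop(sprintf("missing %s: %s", what,
                 if (is.null(path)) "(not set)" else path))
  }
  path
}

#' Run the whole pipeline
#'
#' Simulation (or input loading), sRNA preprocessing, exact mapping to
#' genome/CDS/EST sets, global profiles, degradome analysis with peak
#' calling and randomized control, strand-bias classification and RPKM
#' differential expression. Every stage writes a TSV (or BED) report under
#' `out_dir` and a `manifest.json` records parameters, seed and the MD5
#' checksum of every emitted file, so two runs with the same seed produce
#' identical manifests.
#'
#' @param config a [run_config()].
#' @return list with the in-memory results of every stage, invisibly.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (is.null(out)) stop("run_config$out_dir is required")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  res <- list(config = config)

  # --- inputs ---------------------------------------------------------
  if (!is.null(config$sim)) {
    sim <- stage("simulate", simulate_dataset(config$sim,
                                              file.path(out, "sim")))
    refs <- sim$refs
    raw_srna <- sim$srna$reads
    raw_deg <- sim$degradome$reads
    barcode_map <- config$sim$barcode_map
    adapter3 <- config$sim$adapter3
    res$sim <- sim
  } else {
    refs <- stage("load_references", list(
      genome = read_fasta(need_file(config$genome_fasta, "genome FASTA"),
                          "genome"),
      cds = read_fasta(need_file(config$cds_fasta, "CDS FASTA"), "cds"),
      est = if (!is.null(config$est_fasta)) {
        read_fasta(need_file(config$est_fasta, "EST FASTA"), "est")
      },
      contaminant = if (!is.null(config$contaminant_fasta)) {
        read_fasta(need_file(config$contaminant_fasta, "contaminant FASTA"),
                   "contaminant")
      }))
    raw_srna <- stage("load_reads",
                      read_fastq(need_file(config$srna_fastq,
                                           "sRNA FASTQ")))
    raw_deg <- if (!is.null(config$degradome_fastq)) {
      stage("load_reads", read_fastq(need_file(config$degradome_fastq,
                                               "degradome FASTQ")))
    } else character()
    barcode_map <- config$barcode_map
    adapter3 <- config$adapter3
  }

  # --- sRNA preprocessing --------------------------------------------
  libs <- stage("preprocess", preprocess_srna(
    raw_srna, barcode_map, adapter3,
    min_len = config$srna_size[1], max_len = config$srna_size[2],
    contaminant = refs$contaminant))
  res$libs <- libs
  write_tsv_report(preprocess_report(libs),
                   file.path(out, "preprocess_counters.tsv"),
                   header = list(unknown_barcode =
                                   attr(libs, "unknown_barcode")))

  # --- mapping --------------------------------------------------------
  sets <- Filter(Negate(is.null),
                 list(genome = refs$genome, cds = refs$cds, est = refs$est))
  alns <- stage("map", lapply(sets, function(rs) {
    lapply(libs, map_exact, refs = rs)
  }))
  res$alns <- alns
  tbl <- do.call(rbind, lapply(names(sets), function(sn) {
    cbind(reference_set = sn, mapping_summary(libs, sets[[sn]],
                                              alns = alns[[sn]]))
  }))
  res$mapping_table <- tbl
  write_tsv_report(tbl, file.path(out, "mapping_summary.tsv"))

  # --- global profiles ------------------------------------------------
  mapped_libs <- lapply(names(libs), function(cn) {
    keep <- libs[[cn]]$seq %in% unique(alns$genome[[cn]]$seq)
    set_reads(libs[[cn]], libs[[cn]]$seq[keep], libs[[cn]]$count[keep])
  })
  names(mapped_libs) <- names(libs)
  ld <- length_distribution(mapped_libs,
                            lengths = config$srna_size[1]:config$srna_size[2])
  fb <- first_base_composition(mapped_libs)
  genome_counts <- pooled_strand_counts(alns$genome)
  gc_tot <- stats::setNames(rep(0, length(refs$genome$seqs)),
                            ref_ids(refs$genome))
  gc_tot[genome_counts$ref] <- genome_counts$redundant_sense +
    genome_counts$redundant_antisense
  bins <- bin_references_by_count(gc_tot)
  hot <- hotspot_summary(gc_tot, ref_lengths(refs$genome),
                         top_n = max(1L, min(10L, length(gc_tot))))
  res$profiles <- list(length_dist = ld, first_base = fb, bins = bins,
                       hotspot = hot)
  write_tsv_report(data.frame(length = names(ld$counts),
                              redundant = as.integer(ld$counts)),
                   file.path(out, "length_distribution.tsv"),
                   header = list(mode = ifelse(is.na(ld$mode), "none",
                                               ld$mode)))
  write_tsv_report(data.frame(base = names(fb), fraction = as.numeric(fb)),
                   file.path(out, "first_base_composition.tsv"))
  write_tsv_report(data.frame(bin = names(bins$bins),
                              references = as.integer(bins$bins)),
                   file.path(out, "reference_count_bins.tsv"),
                   header = list(zero_references = bins$zero_references))
  write_tsv_report(utils::head(hot$ranking, 50),
                   file.path(out, "hotspot_ranking.tsv"),
                   header = list(top_n = hot$top_n,
                                 top_n_share = hot$top_n_share,
                                 top_n_genome_fraction =
                                   hot$top_n_genome_fraction))

  # --- degradome ------------------------------------------------------
  if (length(raw_deg)) {
    deg_lib <- stage("degradome_preprocess", preprocess_degradome(
      raw_deg, min_len = config$degradome_size[1],
      max_len = config$degradome_size[2],
      min_tail = config$polya_min_tail, contaminant = refs$contaminant))
    deg_aln <- stage("degradome_map", map_exact(deg_lib, refs$cds))
    profiles <- pileup_5prime(deg_aln, refs$cds)
    sdp <- stop_distance_profile(profiles)
    peaks <- call_peaks(profiles, factor_threshold = config$peak_factor)
    hist <- peak_factor_histogram(peaks)
    ctrl <- random_peak_control(peaks, ref_lengths(refs$cds),
                                seed = config$seed)
    srna_cds_aln <- do.call(rbind, lapply(alns$cds, as.data.frame))
    ov <- srna_peak_overlap_test(peaks, srna_cds_aln,
                                 ref_lengths(refs$cds),
                                 n_permutations = config$n_permutations,
                                 seed = config$seed + 1L)
    res$degradome <- list(lib = deg_lib, aln = deg_aln,
                          profiles = profiles, stop_profile = sdp,
                          peaks = peaks, histogram = hist,
                          control = ctrl, overlap = ov)
    write_tsv_report(sdp, file.path(out, "stop_distance_profile.tsv"))
    write_tsv_report(as.data.frame(peaks), file.path(out, "peaks.tsv"))
    write_peak_bed(peaks, file.path(out, "peaks.bed"))
    write_tsv_report(data.frame(factor_bin = names(hist),
                                peaks = as.integer(hist)),
                     file.path(out, "peak_factor_histogram.tsv"))
    write_tsv_report(ctrl, file.path(out, "random_peak_control.tsv"))
    write_tsv_report(data.frame(observed = ov$observed,
                                p_value = ov$p_value,
                                n_permutations = ov$n_permutations),
                     file.path(out, "srna_peak_overlap.tsv"))
  }

  # --- strand bias ----------------------------------------------------
  srna_counts <- pooled_strand_counts(alns$cds)
  if (length(raw_deg)) {
    deg_counts <- degradome_strand_counts(res$degradome$profiles)
    oriented <- orient_references(deg_counts,
                                  threshold = config$orient_threshold_cds,
                                  inclusive = FALSE)
    oriented_ids <- oriented$ref
  } else {
    oriented <- NULL
    oriented_ids <- NULL  # CDSs are directional by reading frame
  }
  records <- srna_strand_profile(srna_counts, oriented_ids,
                                 min_srna = config$min_srna)
  bias_sum <- classify_bias_summary(records)
  res$strand_bias <- list(oriented = oriented, records = records,
                          summary = bias_sum)
  write_tsv_report(records, file.path(out, "strand_bias_records.tsv"),
                   header = list(min_srna = config$min_srna))
  write_tsv_report(data.frame(metric = names(bias_sum),
                              count = as.integer(bias_sum)),
                   file.path(out, "strand_bias_summary.tsv"))

  # --- differential expression ---------------------------------------
  cds_ids <- ref_ids(refs$cds)
  counts <- sapply(names(libs), function(cn) {
    ct <- pooled_strand_counts(alns$cds[cn])
    v <- stats::setNames(rep(0L, length(cds_ids)), cds_ids)
    v[ct$ref] <- ct$redundant_sense + ct$redundant_antisense
    v
  })
  lib_sizes <- vapply(names(libs), function(cn) {
    count_by_reference(alns$cds[[cn]],
                       libs[[cn]])$totals$redundant_mapped_total
  }, 0)
  de <- NULL
  if (all(lib_sizes > 0)) {
    mat <- rpkm(counts, ref_lengths(refs$cds), lib_sizes)
    de_records <- filter_differential(mat, ref_lengths(refs$cds), lib_sizes,
                                      min_rpkm = config$min_rpkm,
                                      min_fold = config$min_fold,
                                      reference_condition =
                                        config$reference_condition)
    clus <- if (nrow(de_records)) {
      cluster_and_summarize(de_records, mat, bias_records = records)
    }
    de <- list(counts = counts, rpkm = mat, records = de_records,
               clustering = clus)
    write_tsv_report(cbind(cds = rownames(mat), as.data.frame(mat)),
                     file.path(out, "rpkm_matrix.tsv"))
    write_tsv_report(de_records, file.path(out, "differential_records.tsv"),
                     header = list(min_rpkm = config$min_rpkm,
                                   min_fold = config$min_fold))
  }
  res$diffexpr <- de

  # --- truth comparison (simulated runs) ------------------------------
  if (!is.null(config$sim)) {
    truth <- res$sim$truth
    cmp <- data.frame(metric = "planted_de_loci",
                      value = nrow(truth$de_loci))
    if (!is.null(de) && nrow(de$records)) {
      hitde <- sum(de$records$cds %in% truth$de_loci$cds)
      cmp <- rbind(cmp,
                   data.frame(metric = c("recovered_de_loci",
                                         "called_de_records"),
                              value = c(hitde, nrow(de$records))))
    }
    if (!is.null(res$degradome)) {
      pk <- res$degradome$peaks
      planted <- truth$planted_peaks
      hitpk <- sum(paste(planted$cds, planted$pos) %in%
                     paste(pk$cds, pk$pos))
      cmp <- rbind(cmp,
                   data.frame(metric = c("planted_peaks", "recovered_peaks",
                                         "called_peaks"),
                              value = c(nrow(planted), hitpk, nrow(pk))))
    }
    res$truth_comparison <- cmp
    write_tsv_report(cmp, file.path(out, "truth_comparison.tsv"))
  }

  # --- manifest -------------------------------------------------------
  files <- sort(setdiff(list.files(out, recursive = TRUE),
                        "manifest.json"))
  sums <- tools::md5sum(file.path(out, files))
  params <- config[!vapply(config, is.null, TRUE)]
  params$sim <- if (!is.null(config$sim)) unclass(config$sim)
  manifest <- list(package = "srnadeg",
                   seed = config$seed,
                   parameters = params[setdiff(names(params),
                                               c("out_dir"))],
                   checksums = as.list(stats::setNames(unname(sums), files)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
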
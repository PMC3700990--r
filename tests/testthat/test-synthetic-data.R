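# Generator contracts: determinism, embedded coordinates, planted structure.

test_that("config validation rejects inconsistent settings", {
  expect_error(tiny_config(contaminant_read_frac = 1.5), "\\[0, 1\\]")
  expect_error(tiny_config(bias_mixture = c(sense_prevalent = 0.5,
                                            antisense_biased = 0.5,
                                            antisense_only = 0,
                                            no_srna = 0.25)), "sum to 1")
  expect_error(tiny_config(frac_cds_with_srna = 0.4), "no_srna")
  expect_error(tiny_config(barcode_map = c(normal = "AAAA", cold = "AAAA",
                                           salt = "CCCC", light = "GGGG")),
               "distinct")
  expect_error(tiny_config(n_cds = 60L), "exceeds")
  expect_error(tiny_config(fold_change_factor = 5), ">= 10")
})

test_that("references: CDSs embedded at recorded coordinates, stops, ESTs", {
  cfg <- tiny_config()
  refs <- generate_references(cfg)
  lens <- ref_lengths(refs$cds)
  expect_true(all(lens %% 3L == 0L))
  stops <- substring(as.character(refs$cds$seqs), lens - 2L, lens)
  expect_true(all(stops %in% c("TAA", "TAG", "TGA")))
  expect_identical(unname(stop_anchors(refs$cds)), unname(lens - 3L))
  # independent substring extraction at the recorded coordinates
  m <- refs$cds_map
  contig <- as.character(refs$genome$seqs)[m$contig]
  extracted <- unname(substring(contig, m$start0 + 1L, m$start0 + m$length))
  expect_identical(extracted, unname(as.character(refs$cds$seqs)[m$cds]))
  expect_true(all(ref_lengths(refs$est) > 199L))
})

test_that("degenerate config: n_cds = 0 gives empty CDS set, nonempty genome", {
  cfg <- tiny_config(n_cds = 0L, peak_cds_frac = 0, fold_change_loci = 0L)
  refs <- generate_references(cfg)
  expect_length(ref_ids(refs$cds), 0L)
  expect_gt(length(ref_ids(refs$genome)), 0L)
  expect_true(all(ref_lengths(refs$est) > 199L))
})

test_that("fixed seed gives byte-identical FASTA/FASTQ output", {
  cfg <- tiny_config(n_srna_reads = 300L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(cfg, out_dir = d1)
  simulate_dataset(cfg, out_dir = d2)
  for (f in c("genome.fasta", "cds.fasta", "srna_raw.fastq",
              "degradome_raw.fastq", "srna_truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("sRNA truth table matches the generated reads one-to-one", {
  cfg <- tiny_config()
  refs <- generate_references(cfg)
  truth <- generate_truth(refs, cfg)
  srna <- generate_srna_reads(refs, truth, cfg)
  expect_identical(length(srna$reads), nrow(srna$truth))
  expect_identical(names(srna$reads), srna$truth$read_id)
  # reads reconstruct as barcode + insert + adapter
  rebuilt <- paste0(cfg$barcode_map[srna$truth$condition],
                    srna$truth$insert, cfg$adapter3)
  expect_identical(unname(srna$reads), rebuilt)
  # inserts extract from the named reference at the recorded coordinates
  allseq <- c(as.character(refs$genome$seqs), as.character(refs$cds$seqs),
              as.character(refs$contaminant$seqs))
  tt <- srna$truth
  raw <- substring(allseq[tt$ref], tt$start0 + 1L, tt$start0 + tt$insert_len)
  minus <- tt$strand == "-"
  raw[minus] <- revcomp(raw[minus])
  expect_identical(unname(raw), tt$insert)
  # antisense_only CDSs emit only antisense reads
  ao <- names(truth$cds_bias_class)[truth$cds_bias_class == "antisense_only"]
  sel <- tt$category == "cds" & tt$ref %in% ao
  expect_true(any(sel))
  expect_true(all(tt$strand[sel] == "-"))
  # no_srna CDSs emit nothing
  ns <- names(truth$cds_bias_class)[truth$cds_bias_class == "no_srna"]
  expect_false(any(tt$ref %in% ns))
})

test_that("contaminant_read_frac = 0 leaves no contaminant-matching insert", {
  cfg <- tiny_config(contaminant_read_frac = 0, n_srna_reads = 500L)
  refs <- generate_references(cfg)
  truth <- generate_truth(refs, cfg)
  srna <- generate_srna_reads(refs, truth, cfg)
  expect_false(any(srna$truth$category == "contaminant"))
  hits <- srnadeg:::matched_sequences(unique(srna$truth$insert),
                                      refs$contaminant)
  expect_length(hits, 0L)
})

test_that("insert length mode is 21 over >= 10,000 reads", {
  cfg <- tiny_config(seed = 21L, n_srna_reads = 3000L)
  refs <- generate_references(cfg)
  truth <- generate_truth(refs, cfg)
  srna <- generate_srna_reads(refs, truth, cfg)
  expect_gte(nrow(srna$truth), 10000L)
  tab <- table(srna$truth$insert_len)
  expect_identical(names(tab)[which.max(tab)], "21")
})

test_that("bias-class proportions match the mixture within the 99% CI", {
  cfg <- sim_config(seed = 13, n_genome_contigs = 320L, n_cds = 300L,
                    n_est = 10L, n_srna_reads = 100L)
  refs <- generate_references(cfg)
  truth <- generate_truth(refs, cfg)
  expect_gte(length(truth$cds_bias_class), 200L)
  for (cl in names(cfg$bias_mixture)) {
    expect_within_binom_ci(mean(truth$cds_bias_class == cl),
                           cfg$bias_mixture[[cl]],
                           length(truth$cds_bias_class))
  }
})

test_that("degradome: empty library when background 0 and no planted peaks", {
  cfg <- tiny_config(degradome_background_rate = 0, peak_cds_frac = 0)
  refs <- generate_references(cfg)
  truth <- generate_truth(refs, cfg)
  deg <- generate_degradome_reads(refs, truth, cfg)
  expect_length(deg$reads, 0L)
  expect_identical(nrow(deg$truth), 0L)
})

test_that("3'-bias pulls tag 5' ends toward the stop codon vs uniform", {
  cfg_b <- tiny_config(seed = 31L, degradome_antisense_frac = 0,
                       peak_cds_frac = 0)
  cfg_u <- tiny_config(seed = 31L, degradome_antisense_frac = 0,
                       peak_cds_frac = 0, degradome_3prime_bias = 0)
  refs <- generate_references(cfg_b)
  truth <- generate_truth(refs, cfg_b)
  deg_b <- generate_degradome_reads(refs, truth, cfg_b)
  deg_u <- generate_degradome_reads(refs, truth, cfg_u)
  expect_gte(nrow(deg_b$truth), 1000L)
  lens <- ref_lengths(refs$cds)
  dist_from_stop <- function(tt) (lens[tt$cds] - 3L) - tt$pos5
  expect_lt(mean(dist_from_stop(deg_b$truth)),
            0.6 * mean(dist_from_stop(deg_u$truth)))
})

test_that("planted peak tags exceed 3x the per-position mean on their CDS", {
  cfg <- tiny_config(seed = 41L)
  refs <- generate_references(cfg)
  truth <- generate_truth(refs, cfg)
  deg <- generate_degradome_reads(refs, truth, cfg)
  tt <- deg$truth[deg$truth$strand == "+", ]
  ok <- vapply(seq_len(nrow(truth$planted_peaks)), function(i) {
    pk <- truth$planted_peaks[i, ]
    pos <- tt$pos5[tt$cds == pk$cds]
    tab <- table(pos)
    at_peak <- tab[[as.character(pk$pos)]]
    at_peak >= 3 * mean(tab)
  }, NA)
  expect_gte(mean(ok), 0.95)
})

test_that("noise-free expression counts plant exact fold changes", {
  cfg <- tiny_config()
  refs <- generate_references(cfg)
  truth <- generate_truth(refs, cfg)
  mat <- simulate_expression_counts(truth, cfg)
  expect_identical(rownames(mat), names(truth$cds_weights))
  base <- round(cfg$n_srna_reads * truth$cds_weights)
  de <- truth$de_loci
  for (j in seq_len(nrow(de))) {
    expected <- if (de$direction[j] == "up") {
      round(base[[de$cds[j]]] * de$fold[j])
    } else max(1, base[[de$cds[j]]] %/% de$fold[j])
    expect_identical(mat[de$cds[j], de$condition[j]], as.integer(expected))
  }
  untouched <- setdiff(rownames(mat), de$cds)
  expect_true(all(mat[untouched, ] == base[untouched]))
})
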
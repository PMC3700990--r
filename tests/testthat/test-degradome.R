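# Degradome pileups, stop-distance profile, peak calling, controls, overlap.

# Build a degradome_profiles object directly from (cds, pos, count) triples.
make_profiles <- function(counts_list, lengths) {
  refs <- reference_set(stats::setNames(
    vapply(lengths, function(L) paste(rep("A", L), collapse = ""), ""),
    names(lengths)), "cds")
  rows <- lapply(names(counts_list), function(id) {
    x <- counts_list[[id]]
    if (!length(x)) return(NULL)
    data.frame(seq = strrep("C", 25), count = as.integer(x),
               ref = id, start = as.integer(names(x)),
               end = as.integer(names(x)) + 25L, strand = "+",
               stringsAsFactors = FALSE)
  })
  aln <- do.call(rbind, rows)
  if (is.null(aln)) {
    aln <- data.frame(seq = character(), count = integer(), ref = character(),
                      start = integer(), end = integer(), strand = character())
  }
  pileup_from_rows(aln, refs)
}

# pileup_5prime requires distinct seq rows only for realism; here we feed the
# rows straight through (counts already aggregated per position)
pileup_from_rows <- function(aln, refs) {
  class(aln) <- c("alignment_table", "data.frame")
  pileup_5prime(aln, refs)
}

test_that("5'-end pileup places sense starts and antisense ends", {
  cds <- reference_set(c(x = paste(rep("ACGT", 25), collapse = "")), "cds")
  aln <- data.frame(seq = c(strrep("A", 30), strrep("C", 28)),
                    count = c(4L, 2L),
                    ref = "x", start = c(10L, 40L), end = c(40L, 68L),
                    strand = c("+", "-"), stringsAsFactors = FALSE)
  prof <- pileup_from_rows(aln, cds)
  expect_identical(prof$x$pos, 10L)
  expect_identical(prof$x$count, 4L)
  expect_identical(prof$x$total, 4L)
  expect_equal(prof$x$rel_freq, 1)
  expect_identical(prof$x$antisense$pos, 67L)  # 5' end of a minus read
  expect_identical(prof$x$antisense$count, 2L)
  # empty CDS profile
  cds2 <- reference_set(c(x = "ACGTACGTACGTACGTACGTACGTACGT",
                          y = "ACGTACGTACGTACGTACGTACGTACGT"), "cds")
  prof2 <- pileup_from_rows(aln[0, ], cds2)
  expect_identical(prof2$y$total, 0L)
  expect_length(prof2$y$pos, 0L)
})

test_that("pileup equals a recount from the simulator truth table", {
  cfg <- tiny_config(seed = 61L, polya_tail_prob = 0)
  sim <- simulate_dataset(cfg)
  dlib <- preprocess_degradome(sim$degradome$reads)
  daln <- map_exact(dlib, sim$refs$cds)
  prof <- pileup_5prime(daln, sim$refs$cds)
  tt <- sim$degradome$truth
  # reconstruct each sense tag and emulate retention independently:
  # poly-A trimming (trailing-run scan) then the 25-45 size filter
  cds_str <- as.character(sim$refs$cds$seqs)
  core <- substring(cds_str[tt$cds], tt$pos5 + 1L, tt$pos5 + tt$core_len)
  run <- vapply(core, trailing_a_run, 0L, USE.NAMES = FALSE)
  eff_len <- tt$core_len - ifelse(run >= 4L, run, 0L)
  tt <- tt[eff_len >= 25L & eff_len <= 45L, ]
  for (id in sample(names(prof), 10)) {
    sel <- tt$cds == id & tt$strand == "+"
    expected <- table(tt$pos5[sel])
    expect_identical(prof[[id]]$total, as.integer(sum(expected)), label = id)
    got <- stats::setNames(prof[[id]]$count, prof[[id]]$pos)
    expect_identical(got[names(expected)],
                     stats::setNames(as.integer(expected), names(expected)),
                     label = id)
  }
})

test_that("stop-distance profile follows the fixed-denominator formula", {
  # CDS a: all mass at the stop anchor; CDS b: no tags -> profile[0] = 0.5
  prof <- make_profiles(list(a = c(`97` = 5), b = integer()),
                        c(a = 100L, b = 80L))
  sdp <- stop_distance_profile(prof, max_distance = 10)
  expect_equal(sdp$mean_rel_freq[sdp$distance == 0], 0.5)
  expect_equal(sum(sdp$mean_rel_freq), 0.5)

  # uniform tags over one CDS: flat profile at 1/(k * N_cds) per covered
  # distance, total mass = (CDSs with tags) / N_cds
  k <- 50L
  pos <- stats::setNames(rep(1, k), seq(97 - k, 96))
  prof2 <- make_profiles(list(a = pos, b = integer()),
                         c(a = 100L, b = 80L))
  sdp2 <- stop_distance_profile(prof2, max_distance = 97)
  covered <- sdp2$mean_rel_freq[sdp2$distance >= 1 & sdp2$distance <= k]
  expect_equal(covered, rep(1 / (k * 2), k), tolerance = 1e-12)
  expect_equal(sum(sdp2$mean_rel_freq), 1 / 2, tolerance = 1e-12)
})

test_that("3'-biased simulation enriches the profile toward distance 0", {
  cfg_b <- tiny_config(seed = 71L, peak_cds_frac = 0)
  cfg_u <- tiny_config(seed = 71L, peak_cds_frac = 0,
                       degradome_3prime_bias = 0)
  refs <- generate_references(cfg_b)
  truth <- generate_truth(refs, cfg_b)
  run <- function(cfg) {
    deg <- generate_degradome_reads(refs, truth, cfg)
    dlib <- preprocess_degradome(deg$reads)
    prof <- pileup_5prime(map_exact(dlib, refs$cds), refs$cds)
    stop_distance_profile(prof, max_distance = 400)
  }
  sb <- run(cfg_b)
  su <- run(cfg_u)
  near <- function(s) sum(s$mean_rel_freq[s$distance <= 100])
  far <- function(s) sum(s$mean_rel_freq[s$distance > 100])
  expect_gt(near(sb) / max(far(sb), 1e-9), near(su) / max(far(su), 1e-9))
})

test_that("peak calling: hand arithmetic, uniform case, scale invariance", {
  counts <- stats::setNames(c(10, 1, 1, 1, 1, 1), c(30, 40, 50, 60, 70, 80))
  prof <- make_profiles(list(a = counts), c(a = 200L))
  pk <- call_peaks(prof, factor_threshold = 3)
  expect_identical(nrow(pk), 1L)
  expect_identical(pk$pos, 30L)
  expect_equal(pk$rel_freq, 10 / 15)
  expect_equal(pk$factor, 4)  # (10/15) * 6 nonzero positions

  uni <- make_profiles(list(a = stats::setNames(rep(3, 20),
                                                seq(10, 105, by = 5))),
                       c(a = 200L))
  expect_identical(nrow(call_peaks(uni)), 0L)

  scaled <- make_profiles(list(a = counts * 7), c(a = 200L))
  pk2 <- call_peaks(scaled, factor_threshold = 3)
  expect_identical(pk2[, c("cds", "pos", "rel_freq", "factor")],
                   pk[, c("cds", "pos", "rel_freq", "factor")])

  # equality survives: (9/12) * 4 nonzero positions = factor exactly 3
  eq <- make_profiles(list(a = stats::setNames(c(9, 1, 1, 1), c(10, 20, 30, 40))),
                      c(a = 200L))
  pke <- call_peaks(eq, factor_threshold = 3)
  expect_identical(pke$pos, 10L)
  expect_equal(pke$factor, 3)
})

test_that("all-positions mean mode uses the CDS length as denominator", {
  counts <- stats::setNames(c(10, 1, 1, 1, 1, 1), c(30, 40, 50, 60, 70, 80))
  prof <- make_profiles(list(a = counts), c(a = 60L + 30L))
  pk <- call_peaks(prof, factor_threshold = 3, mean_mode = "all")
  # every position clears 3 / L easily under the long-denominator mean
  expect_true(all(c(30L, 40L) %in% pk$pos))
  expect_equal(pk$factor[pk$pos == 30L], (10 / 15) * 90)
})

test_that("rel_freq sums to 1 per CDS with tags", {
  cfg <- tiny_config(seed = 81L)
  sim <- simulate_dataset(cfg)
  dlib <- preprocess_degradome(sim$degradome$reads)
  prof <- pileup_5prime(map_exact(dlib, sim$refs$cds), sim$refs$cds)
  sums <- vapply(prof, function(p) if (p$total > 0) sum(p$rel_freq) else 1, 0)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("factor histogram floors into 3..12 and 13+", {
  pk <- data.frame(cds = "a", pos = 1:3, count = 1L, rel_freq = 0.1,
                   factor = c(3.2, 4.9, 13.7))
  class(pk) <- c("peak_table", "data.frame")
  h <- peak_factor_histogram(pk)
  expect_identical(unname(h[c("3", "4", "13+")]), c(1L, 1L, 1L))
  expect_identical(sum(h), 3L)
  empty <- peak_factor_histogram(pk[0, , drop = FALSE])
  expect_true(all(empty == 0L))
  # brute-force floor binning on random factors
  set.seed(10)
  f <- runif(500, 3, 16)
  pkr <- data.frame(cds = "a", pos = seq_along(f), count = 1L,
                    rel_freq = 0.1, factor = f)
  class(pkr) <- c("peak_table", "data.frame")
  hr <- peak_factor_histogram(pkr)
  expect_identical(unname(hr), as.integer(table(factor(pmin(floor(f), 13),
                                                       levels = 3:13))))
})

test_that("random peak control: count, determinism, length weighting", {
  lens <- c(a = 1000L, b = 3000L)
  pk <- data.frame(cds = "a", pos = 1:7)
  c1 <- random_peak_control(pk, lens, seed = 3)
  c2 <- random_peak_control(pk, lens, seed = 3)
  expect_identical(nrow(c1), 7L)
  expect_identical(c1, c2)
  big <- random_peak_control(10000L, lens, seed = 4)
  expect_within_binom_ci(mean(big$cds == "b"), 0.75, 10000L)
  expect_true(all(big$pos >= 0L & big$pos < lens[big$cds]))
})

test_that("overlap test: coverage rule, empty sRNA case, permutation p", {
  lens <- c(a = 200L, b = 200L)
  aln <- data.frame(seq = strrep("A", 21), count = 1L, ref = "a",
                    start = 10L, end = 31L, strand = "+",
                    stringsAsFactors = FALSE)
  pk <- data.frame(cds = c("a", "a", "b"), pos = c(15L, 31L, 15L))
  ov <- srna_peak_overlap_test(pk, aln, lens, n_permutations = 99, seed = 5)
  expect_identical(ov$observed, 1L)  # [10,31) covers 15 but not 31
  expect_length(ov$control, 99L)
  expect_gte(ov$p_value, 1 / 100)
  expect_lte(ov$p_value, 1)
  ov0 <- srna_peak_overlap_test(pk, aln[0, ], lens, n_permutations = 19,
                                seed = 5)
  expect_identical(ov0$observed, 0L)
  expect_equal(ov0$p_value, 1)
  expect_error(srna_peak_overlap_test(pk, aln, lens, n_permutations = 0),
               "n_permutations")
})
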
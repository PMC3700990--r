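# Demultiplexing, trimming, size selection, poly-A removal, decontamination.

BC <- c(normal = "AACC", cold = "GGTT", salt = "ACAC", light = "GTGT")
AD <- "TGGAATTCTCGGGTGCCAAGG"

test_that("demultiplex assigns by barcode and trims the first adapter hit", {
  reads <- c(paste0("AACC", "ACGTACGTACGTACGTACGTA", AD),
             paste0("GGTT", "TTTTGGGGCCCCAAAA", AD, "GCGC"),
             paste0("ACAC", "AAAATTTT"),             # no adapter
             paste0("TTTT", "ACGTACGTACGTACGT", AD)) # unknown barcode
  libs <- demultiplex_and_trim(reads, BC, AD)
  expect_identical(libs$normal$seq, "ACGTACGTACGTACGTACGTA")
  expect_identical(libs$cold$seq, "TTTTGGGGCCCCAAAA")
  expect_identical(unique_total(libs$salt), 0L)
  expect_identical(unname(libs$salt$counters["untrimmable"]), 1)
  expect_identical(attr(libs, "unknown_barcode"), 1L)
  expect_error(demultiplex_and_trim(reads, c(a = "AAAA", b = "AAAA"), AD),
               "ambiguous")
})

test_that("size_filter bounds are inclusive on both ends", {
  lib <- read_library(c(strrep("A", 15), strrep("C", 16),
                        strrep("G", 32), strrep("T", 33)), "x")
  out <- size_filter(lib, 16, 32)
  expect_setequal(out$seq, c(strrep("C", 16), strrep("G", 32)))
  expect_identical(unname(out$counters["size_rejected"]), 2)
  empty <- size_filter(read_library(character(), "x", counts = integer()),
                       16, 32)
  expect_identical(unique_total(empty), 0L)
})

test_that("trim_polya removes maximal >= min_tail runs only", {
  lib <- read_library(c("GGCAAAAA", "GGCAA", "AAAAAA", "GGC"), "deg")
  out <- trim_polya(lib, min_tail = 4)
  # GGCAAAAA -> GGC merges with the untouched GGC; AAAAAA trims to an empty
  # read that the downstream size filter removes
  expect_identical(out$seq, c("", "GGC", "GGCAA"))
  expect_identical(out$count[out$seq == "GGC"], 2L)
  expect_identical(redundant_total(out), redundant_total(lib))
})

test_that("remove_contaminants drops exact full-length hits on either strand", {
  cont <- reference_set(c(trna = "ACGTACGTACGTACGTACGTACGTACGT"), "contaminant")
  inside <- substr("ACGTACGTACGTACGTACGTACGTACGT", 3, 20)
  lib <- read_library(c(inside, revcomp(inside), "TTTTTGGGGGCCCCCAAAAT"), "x")
  out <- remove_contaminants(lib, cont)
  expect_identical(out$seq, "TTTTTGGGGGCCCCCAAAAT")
  expect_identical(unname(out$counters["contaminant_rejected"]), 2)
  # empty contaminant set: unchanged
  none <- reference_set(Biostrings::DNAStringSet(), "contaminant")
  expect_identical(remove_contaminants(lib, none)$seq, lib$seq)
})

test_that("simulated demultiplexing matches the truth table exactly", {
  cfg <- tiny_config(n_srna_reads = 250L)
  sim <- simulate_dataset(cfg)
  libs <- demultiplex_and_trim(sim$srna$reads, cfg$barcode_map, cfg$adapter3)
  truth_counts <- table(sim$srna$truth$condition)
  for (cn in cfg$conditions) {
    expect_identical(unname(libs[[cn]]$counters["raw"]),
                     as.numeric(truth_counts[[cn]]), label = cn)
  }
  expect_identical(attr(libs, "unknown_barcode"), 0L)
  # retained insert multiset equals the truth-table inserts per condition
  for (cn in cfg$conditions) {
    tt <- sort(sim$srna$truth$insert[sim$srna$truth$condition == cn])
    got <- sort(rep(libs[[cn]]$seq, libs[[cn]]$count))
    expect_identical(got, tt, label = cn)
  }
})

test_that("size_filter agrees with a brute-force length scan on simulation", {
  cfg <- tiny_config(n_srna_reads = 400L)
  sim <- simulate_dataset(cfg)
  libs <- demultiplex_and_trim(sim$srna$reads, cfg$barcode_map, cfg$adapter3)
  out <- size_filter(libs$salt, 16, 32)
  tt <- sim$srna$truth
  expected <- sum(tt$condition == "salt" & tt$insert_len >= 16 &
                    tt$insert_len <= 32)
  expect_identical(redundant_total(out), as.integer(expected))
})

test_that("poly-A trimming matches the per-character scan oracle", {
  cfg <- tiny_config(polya_tail_prob = 0.3)
  sim <- simulate_dataset(cfg)
  reads <- sim$degradome$reads
  lib <- read_library(unname(reads), "degradome")
  out <- trim_polya(lib, min_tail = 4)
  runs <- vapply(lib$seq, trailing_a_run, 0L)
  expected <- ifelse(runs >= 4L, substr(lib$seq, 1L, nchar(lib$seq) - runs),
                     lib$seq)
  agg <- rowsum(lib$count, expected)
  expect_identical(out$seq, sort(rownames(agg)[agg[, 1] > 0]))
  expect_identical(redundant_total(out), redundant_total(lib))
  # every truth-flagged tail is gone: tagged reads lose at least the tail
  tt <- sim$degradome$truth
  tagged <- tt$polya_len >= 4L
  expect_true(all(vapply(which(tagged), function(i) {
    trailing_a_run(reads[[i]]) >= tt$polya_len[i]
  }, NA)))
})

test_that("contaminant removal recovers the planted fraction within 99% CI", {
  cfg <- tiny_config(seed = 19L, n_srna_reads = 2500L)
  sim <- simulate_dataset(cfg)
  libs <- preprocess_srna(sim$srna$reads, cfg$barcode_map, cfg$adapter3,
                          contaminant = sim$refs$contaminant)
  rej <- sum(vapply(libs, function(l) l$counters[["contaminant_rejected"]], 0))
  raw <- sum(vapply(libs, function(l) l$counters[["raw"]], 0))
  expect_within_binom_ci(rej / raw, cfg$contaminant_read_frac, raw)
  # and removal equals the truth category (contaminants are disjoint)
  expect_identical(as.integer(rej),
                   sum(sim$srna$truth$category == "contaminant"))
})

test_that("counters conserve reads and stages are idempotent", {
  cfg <- tiny_config(n_srna_reads = 600L)
  sim <- simulate_dataset(cfg)
  libs <- preprocess_srna(sim$srna$reads, cfg$barcode_map, cfg$adapter3,
                          contaminant = sim$refs$contaminant)
  for (lib in libs) {
    k <- lib$counters
    expect_equal(unname(k["raw"]),
                 unname(k["retained"] + k["untrimmable"] +
                          k["size_rejected"] + k["contaminant_rejected"]))
  }
  lib <- libs$normal
  again <- remove_contaminants(size_filter(lib, 16, 32),
                               sim$refs$contaminant)
  expect_identical(again$seq, lib$seq)
  expect_identical(again$count, lib$count)
  expect_identical(again$counters, lib$counters)
})
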
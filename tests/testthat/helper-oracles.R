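# Shared fixtures and independent oracles. Oracles stay deliberately naive
# (vectorized substring enumeration, per-character scans) so they share no
# code path with the implementation they check.

tiny_config <- function(seed = 7L, ...) {
  args <- list(seed = seed,
               n_genome_contigs = 50L, n_cds = 35L, n_est = 15L,
               n_contaminants = 8L,
               genome_contig_length_range = c(900L, 1400L),
               cds_length_range = c(300L, 600L),
               n_srna_reads = 2000L,
               fold_change_loci = 4L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# 99% binomial confidence check for an observed proportion.
expect_within_binom_ci <- function(phat, p, n) {
  half <- stats::qnorm(0.995) * sqrt(p * (1 - p) / n)
  expect_gte(phat, p - half)
  expect_lte(phat, p + half)
}

random_seqs <- function(n, len_range = c(16L, 32L)) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"),
                 sample(seq(len_range[1], len_range[2]), 1L),
                 replace = TRUE), collapse = "")
  }, "")
}

random_refs <- function(n, len, kind = "genome", prefix = "r") {
  reference_set(stats::setNames(vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, ""), paste0(prefix, seq_len(n))), kind)
}

# Exhaustive substring-search oracle for exact full-length mapping: tests
# every (reference, offset, strand) triple by enumerating every reference
# substring of each read width (vectorized substring) and hash-joining
# (match) against the read set and its reverse complements. Requires the
# read sequences to be distinct.
naive_map <- function(seqs, refs) {
  stopifnot(!anyDuplicated(seqs))
  refstrs <- stats::setNames(as.character(refs$seqs), ref_ids(refs))
  rc <- revcomp(seqs)
  rows <- list()
  add <- function(sq, ref, start, strand) {
    rows[[length(rows) + 1L]] <<- data.frame(
      seq = sq, ref = ref, start = start, strand = strand,
      stringsAsFactors = FALSE)
  }
  for (w in unique(nchar(seqs))) {
    iw <- which(nchar(seqs) == w)
    for (ri in seq_along(refstrs)) {
      L <- nchar(refstrs[ri])
      if (L < w) next
      subs <- substring(refstrs[ri], 1:(L - w + 1L), w:L)
      m <- match(subs, seqs[iw])
      hit <- which(!is.na(m))
      if (length(hit)) {
        add(seqs[iw][m[hit]], names(refstrs)[ri], hit - 1L, "+")
      }
      m <- match(subs, rc[iw])
      hit <- which(!is.na(m))
      if (length(hit)) {
        add(seqs[iw][m[hit]], names(refstrs)[ri], hit - 1L, "-")
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(seq = character(), ref = character(),
                      start = integer(), strand = character()))
  }
  do.call(rbind, rows)
}

aln_key <- function(df) sort(paste(df$seq, df$ref, df$start, df$strand))

# Per-character scan for the maximal trailing run of A's (poly-A oracle).
trailing_a_run <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  k <- 0L
  while (k < n && ch[n - k] == "A") k <- k + 1L
  k
}
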
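# Synthetic data with planted ground truth.
#
# The generator is first-class, tested code: every downstream module is
# validated against the truth records emitted here. All randomness is
# drawn under seeds derived from config$seed, one fixed offset per
# generator, so a fixed seed gives byte-identical FASTA/FASTQ output and
# truth tables while keeping the stage outputs independent of call order.

# 61 sense codons (64 minus the three stop codons).
sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
}

#' Generate reference sets
#'
#' Builds a synthetic genome (random contigs), predicted CDSs embedded in
#' their own contigs at recorded coordinates, EST contigs (> 199 nt windows
#' of host contigs spanning a CDS, mimicking assembled transcript evidence),
#' and a contaminant set (stand-ins for rRNA/tRNA/plastid sequences, disjoint
#' from the genome with overwhelming probability since all sequences are
#' independent uniform DNA).
#'
#' Every CDS has length divisible by 3, starts with ATG, contains no internal
#' stop codon and ends with a stop codon; the last three nucleotides are the
#' stop-codon anchor used for degradome distance profiles.
#'
#' @param config a [sim_config()].
#' @return a list with `reference_set`s `genome`, `cds`, `est`,
#'   `contaminant`, and `cds_map`, a data.frame recording for each CDS its
#'   host contig and 0-based start coordinate.
#' @export
generate_references <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_cds > config$n_genome_contigs) {
    stop("n_cds exceeds what fits in the generated genome")
  }
  with_seed(config$seed + 101L, {
    n_c <- config$n_genome_contigs
    n_cds <- config$n_cds

    # CDS sequences
    if (n_cds > 0L) {
      rng <- config$cds_length_range
      Lc <- sample(seq(rng[1], rng[2]), n_cds, replace = TRUE)
      Lc <- Lc - (Lc %% 3L)
      ncod <- (Lc - 6L) %/% 3L
      body <- sample(sense_codons(), sum(ncod), replace = TRUE)
      ends <- cumsum(ncod)
      starts <- ends - ncod + 1L
      body_str <- vapply(seq_len(n_cds), function(i) {
        paste(body[starts[i]:ends[i]], collapse = "")
      }, "")
      stops <- sample(c("TAA", "TAG", "TGA"), n_cds, replace = TRUE)
      cds_seq <- paste0("ATG", body_str, stops)
      names(cds_seq) <- sprintf("cds_%05d", seq_len(n_cds))
    } else {
      Lc <- integer()
      cds_seq <- character()
    }

    # Genome contigs; the first n_cds contigs each host one CDS.
    grng <- config$genome_contig_length_range
    glen <- sample(seq(grng[1], grng[2]), n_c, replace = TRUE)
    if (n_cds > 0L) glen[seq_len(n_cds)] <- pmax(glen[seq_len(n_cds)], Lc + 60L)
    contig_seq <- random_dna(glen)
    names(contig_seq) <- sprintf("contig_%05d", seq_len(n_c))
    cds_start0 <- integer(n_cds)
    if (n_cds > 0L) {
      for (i in seq_len(n_cds)) {
        cds_start0[i] <- sample.int(glen[i] - Lc[i] + 1L, 1L) - 1L
      }
      substr(contig_seq[seq_len(n_cds)], cds_start0 + 1L, cds_start0 + Lc) <-
        cds_seq
    }

    # ESTs: windows of host contigs containing the CDS (sense strand).
    n_est <- config$n_est
    if (n_est > 0L) {
      erng <- config$est_length_range
      est_len <- sample(seq(erng[1], erng[2]), n_est, replace = TRUE)
      if (n_cds > 0L) {
        host <- rep_len(seq_len(n_cds), n_est)
        s0 <- pmax(0L, cds_start0[host] - 30L)
        avail <- glen[host] - s0
        el <- pmin(est_len, avail)
        est_seq <- substring(contig_seq[host], s0 + 1L, s0 + el)
      } else {
        est_seq <- random_dna(est_len)
      }
      names(est_seq) <- sprintf("est_%05d", seq_len(n_est))
    } else {
      est_seq <- character()
    }

    crng <- config$contaminant_length_range
    cont_seq <- random_dna(sample(seq(crng[1], crng[2]),
                                  config$n_contaminants, replace = TRUE))
    if (config$n_contaminants > 0L) {
      names(cont_seq) <- sprintf("contam_%03d", seq_len(config$n_contaminants))
    }

    list(genome = reference_set(contig_seq, "genome"),
         cds = reference_set(cds_seq, "cds"),
         est = reference_set(est_seq, "est"),
         contaminant = reference_set(cont_seq, "contaminant"),
         cds_map = data.frame(cds = names(cds_seq),
                              contig = if (n_cds) names(contig_seq)[seq_len(n_cds)] else character(),
                              start0 = cds_start0,
                              length = Lc,
                              stringsAsFactors = FALSE))
  })
}

#' Generate the ground-truth record
#'
#' Assigns each CDS a strand-bias class (multinomial draw from
#' `bias_mixture`), a long-tailed abundance weight (gamma, shape 0.8; zero
#' for `no_srna` CDSs), designates hotspot contigs (preferring contigs that
#' host no CDS), plants per-condition expression changes on CDSs of
#' mid-range abundance (weights between the 50th and 85th percentile, spread
#' round-robin over the stress conditions and alternating up/down so that no
#' single library's size is distorted), plants one degradome peak on a
#' fraction of CDSs at 25-400 nt from the stop codon, and marks an
#' "ambiguous" CDS subset that will receive elevated antisense degradome
#' transcription.
#'
#' @param refs output of [generate_references()].
#' @param config a [sim_config()].
#' @return an object of class `truth_record`.
#' @export
generate_truth <- function(refs, config) {
  with_seed(config$seed + 202L, {
    ids <- ref_ids(refs$cds)
    n_cds <- length(ids)
    lens <- ref_lengths(refs$cds)

    classes <- if (n_cds) {
      stats::setNames(sample(names(config$bias_mixture), n_cds,
                             replace = TRUE, prob = config$bias_mixture), ids)
    } else stats::setNames(character(), character())

    w <- if (n_cds) stats::rgamma(n_cds, shape = 0.8, rate = 1) else numeric()
    w[classes == "no_srna"] <- 0
    if (sum(w) > 0) w <- w / sum(w)
    names(w) <- ids

    host <- unique(refs$cds_map$contig)
    nonhost <- setdiff(ref_ids(refs$genome), host)
    n_hot <- max(1L, round(config$hotspot_frac_contigs *
                             config$n_genome_contigs))
    pool <- if (length(nonhost) >= n_hot) nonhost else ref_ids(refs$genome)
    hotspot <- sort(sample(pool, min(n_hot, length(pool))))

    pos_w <- w[w > 0]
    de <- data.frame(cds = character(), condition = character(),
                     fold = numeric(), direction = character(),
                     stringsAsFactors = FALSE)
    if (length(pos_w) >= 2L && config$fold_change_loci > 0L) {
      qs <- stats::quantile(pos_w, c(0.5, 0.85))
      elig <- names(pos_w)[pos_w >= qs[1] & pos_w <= qs[2]]
      k <- min(config$fold_change_loci, length(elig))
      de_cds <- sample(elig, k)
      stress <- config$conditions[-1]
      de <- data.frame(cds = de_cds,
                       condition = rep_len(stress, k),
                       fold = config$fold_change_factor,
                       direction = rep_len(c("up", "down"), k),
                       stringsAsFactors = FALSE)
    }

    n_pk <- round(config$peak_cds_frac * n_cds)
    peaks <- data.frame(cds = character(), pos = integer(),
                        distance = integer(), factor = numeric(),
                        stringsAsFactors = FALSE)
    if (n_pk > 0L) {
      pk_cds <- sort(sample(ids, n_pk))
      dmax <- pmin(lens[pk_cds] - 60L, 400L)
      ok <- dmax >= 25L
      pk_cds <- pk_cds[ok]
      dmax <- dmax[ok]
      d <- vapply(dmax, function(m) sample(25:m, 1L), 0L)
      fr <- config$planted_peak_factor_range
      peaks <- data.frame(cds = pk_cds,
                          pos = lens[pk_cds] - 3L - d,
                          distance = d,
                          factor = stats::runif(length(pk_cds), fr[1], fr[2]),
                          stringsAsFactors = FALSE)
      rownames(peaks) <- NULL
    }

    amb <- if (n_cds) sort(sample(ids, round(config$ambiguous_cds_frac *
                                               n_cds))) else character()

    structure(list(cds_bias_class = classes,
                   cds_weights = w,
                   hotspot_contigs = hotspot,
                   de_loci = de,
                   planted_peaks = peaks,
                   ambiguous_cds = amb),
              class = "truth_record")
  })
}

# First-base position weights: w_plus applies to the forward base under the
# start of a sense read; w_minus to the forward base under the 5' end of an
# antisense read (whose first base is the complement of that forward base).
first_base_weights <- function(config) {
  fb <- config$first_base_dist
  list(plus = c(A = fb[["A"]], C = fb[["C"]], G = fb[["G"]], T = fb[["U"]]),
       minus = c(A = fb[["U"]], C = fb[["G"]], G = fb[["C"]], T = fb[["A"]]))
}

# Sample n 5'-end anchor coordinates on one reference, biased by the
# configured first-base distribution. For "+" the anchor is the read start
# (0-based, in [0, L - margin]); for "-" it is the forward coordinate of the
# read 5' end (in [margin - 1, L - 1]).
sample_anchor_positions <- function(chars, strand, n, margin, fbw) {
  L <- length(chars)
  if (strand == "+") {
    cand <- 0:(L - margin)
    w <- fbw$plus[chars[cand + 1L]]
  } else {
    cand <- (margin - 1L):(L - 1L)
    w <- fbw$minus[chars[cand + 1L]]
  }
  cand[sample.int(length(cand), n, replace = TRUE, prob = w)]
}

#' Generate multiplexed sRNA reads with a per-read truth table
#'
#' Each raw read is `barcode + insert + 3' adapter`. Insert lengths follow
#' `length_dist` (15-35 nt so the 16-32 filter is exercised); insert 5' bases
#' follow `first_base_dist`. Reads are drawn per condition from three
#' sources: the contaminant set (`contaminant_read_frac`), hotspot contigs
#' (`hotspot_read_share` of the rest, either strand), and CDSs, where the
#' CDS is drawn by abundance weight (scaled by planted fold changes in the
#' matching condition) and the strand by the CDS's planted bias class.
#'
#' @param refs output of [generate_references()].
#' @param truth output of [generate_truth()].
#' @param config a [sim_config()].
#' @return list with `reads` (named character vector, raw multiplexed reads)
#'   and `truth` (one data.frame row per read: condition, category,
#'   reference, strand, 0-based start, insert length and sequence).
#' @export
generate_srna_reads <- function(refs, truth, config) {
  with_seed(config$seed + 303L, {
    lens_all <- as.integer(names(config$length_dist))
    margin <- max(lens_all)
    fbw <- first_base_weights(config)
    char_cache <- new.env(parent = emptyenv())
    seq_str <- c(as.character(refs$genome$seqs),
                 as.character(refs$cds$seqs),
                 as.character(refs$contaminant$seqs))
    get_chars <- function(id) {
      if (is.null(char_cache[[id]])) {
        char_cache[[id]] <- strsplit(seq_str[[id]], "", fixed = TRUE)[[1]]
      }
      char_cache[[id]]
    }

    cont_ids <- ref_ids(refs$contaminant)
    cont_len <- ref_lengths(refs$contaminant)
    hot_ids <- truth$hotspot_contigs
    hot_len <- ref_lengths(refs$genome)[hot_ids]
    have_cds <- sum(truth$cds_weights) > 0

    all_reads <- character()
    all_truth <- vector("list", length(config$conditions))

    for (ci in seq_along(config$conditions)) {
      cond <- config$conditions[ci]
      n <- config$n_srna_reads
      f <- if (length(cont_ids)) config$contaminant_read_frac else 0
      h <- if (length(hot_ids)) config$hotspot_read_share else 0
      prob <- c(contaminant = f,
                hotspot = (1 - f) * h,
                cds = (1 - f) * (1 - h))
      if (!have_cds) {
        prob["hotspot"] <- prob["hotspot"] + prob["cds"]
        prob["cds"] <- 0
      }
      category <- sample(names(prob), n, replace = TRUE, prob = prob)
      len <- sample(lens_all, n, replace = TRUE, prob = config$length_dist)
      ref <- character(n)
      strand <- character(n)

      i_cds <- which(category == "cds")
      if (length(i_cds)) {
        wvec <- truth$cds_weights
        de <- truth$de_loci
        de_here <- de[de$condition == cond, , drop = FALSE]
        if (nrow(de_here)) {
          mult <- ifelse(de_here$direction == "up", de_here$fold,
                         1 / de_here$fold)
          wvec[de_here$cds] <- wvec[de_here$cds] * mult
        }
        pick <- sample(names(wvec), length(i_cds), replace = TRUE,
                       prob = wvec)
        ref[i_cds] <- pick
        ps <- config$class_sense_prob[truth$cds_bias_class[pick]]
        strand[i_cds] <- ifelse(stats::runif(length(i_cds)) < ps, "+", "-")
      }
      i_hot <- which(category == "hotspot")
      if (length(i_hot)) {
        ref[i_hot] <- sample(hot_ids, length(i_hot), replace = TRUE,
                             prob = hot_len)
        strand[i_hot] <- sample(c("+", "-"), length(i_hot), replace = TRUE)
      }
      i_con <- which(category == "contaminant")
      if (length(i_con)) {
        ref[i_con] <- sample(cont_ids, length(i_con), replace = TRUE,
                             prob = cont_len)
        strand[i_con] <- sample(c("+", "-"), length(i_con), replace = TRUE)
      }

      # anchor positions per (reference, strand) group
      anchor <- integer(n)
      grp <- split(seq_len(n), paste(ref, strand))
      for (g in grp) {
        anchor[g] <- sample_anchor_positions(get_chars(ref[g[1]]),
                                             strand[g[1]], length(g),
                                             margin, fbw)
      }
      start0 <- ifelse(strand == "+", anchor, anchor - len + 1L)
      insert <- substring(seq_str[ref], start0 + 1L, start0 + len)
      if (any(strand == "-")) {
        insert[strand == "-"] <- revcomp(insert[strand == "-"])
      }

      reads <- paste0(config$barcode_map[[cond]], insert, config$adapter3)
      ids <- sprintf("%s_r%06d", cond, seq_len(n))
      names(reads) <- ids
      all_reads <- c(all_reads, reads)
      all_truth[[ci]] <- data.frame(read_id = ids, condition = cond,
                                    category = category, ref = ref,
                                    strand = strand, start0 = start0,
                                    insert_len = len, insert = insert,
                                    stringsAsFactors = FALSE)
    }
    list(reads = all_reads, truth = do.call(rbind, all_truth))
  })
}

#' Generate degradome tags with a per-tag truth table
#'
#' Background tags emulate 5' to 3' exonucleolytic turnover: sense-strand
#' CDS fragments of 25-45 nt (truncated at the CDS end) whose 5' position
#' sits at a distance from the stop codon drawn from a geometric
#' distribution with decay `degradome_3prime_bias` per nt (uniform if 0).
#' Planted endonucleolytic peaks add a point mass of tags at the truth
#' position, sized from the realized background so the planted factor is the
#' multiple of the mean per-position tag count. A configurable fraction of
#' tags is antisense (elevated for the "ambiguous" subset) and
#' `polya_tail_prob` of tags carry a 3-10 nt poly-A tail.
#'
#' @param refs output of [generate_references()].
#' @param truth output of [generate_truth()].
#' @param config a [sim_config()].
#' @return list with `reads` (named character vector) and `truth` (one row
#'   per tag: condition, cds, strand, forward 0-based 5'-end coordinate,
#'   core fragment length, poly-A tail length, planted flag).
#' @export
generate_degradome_reads <- function(refs, truth, config) {
  with_seed(config$seed + 404L, {
    ids <- ref_ids(refs$cds)
    lens <- ref_lengths(refs$cds)
    seq_str <- as.character(refs$cds$seqs)
    lam <- config$degradome_3prime_bias
    rows <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      id <- ids[i]
      L <- lens[[id]]
      n_bg <- stats::rpois(1L, config$degradome_background_rate * L)
      anti_frac <- if (id %in% truth$ambiguous_cds) {
        config$ambiguous_antisense_frac
      } else config$degradome_antisense_frac
      is_anti <- stats::runif(n_bg) < anti_frac
      n_s <- sum(!is_anti)
      n_a <- sum(is_anti)
      d <- if (lam > 0) {
        pmin(stats::rgeom(n_s, 1 - exp(-lam)), L - 3L)
      } else if (n_s > 0) {
        sample.int(L - 2L, n_s, replace = TRUE) - 1L
      } else integer()
      pos_s <- (L - 3L) - d

      pk <- truth$planted_peaks[truth$planted_peaks$cds == id, , drop = FALSE]
      pos_p <- integer()
      if (nrow(pk)) {
        k_bg <- length(unique(pos_s))
        mean_ct <- if (k_bg > 0) n_s / k_bg else 1
        c_p <- max(2L, as.integer(ceiling(pk$factor[1] * mean_ct)))
        pos_p <- rep.int(pk$pos[1], c_p)
      }

      pos5 <- c(pos_s, pos_p)
      n_sense <- length(pos5)
      if (n_sense + n_a == 0L) next
      e_a <- if (n_a > 0) sample.int(L, n_a, replace = TRUE) - 1L else integer()

      len_s <- pmin(sample(25:45, n_sense, replace = TRUE), L - pos5)
      len_a <- pmin(sample(25:45, n_a, replace = TRUE), e_a + 1L)
      frag_s <- if (n_sense > 0) {
        substring(seq_str[[id]], pos5 + 1L, pos5 + len_s)
      } else character()
      frag_a <- if (n_a > 0) {
        revcomp(substring(seq_str[[id]], e_a - len_a + 2L, e_a + 1L))
      } else character()

      n_tot <- n_sense + n_a
      frag <- c(frag_s, frag_a)
      tail_len <- ifelse(stats::runif(n_tot) < config$polya_tail_prob,
                         sample(3:10, n_tot, replace = TRUE), 0L)
      rows[[i]] <- data.frame(
        cds = id,
        strand = rep(c("+", "-"), c(n_sense, n_a)),
        pos5 = c(pos5, e_a),
        core_len = c(len_s, len_a),
        polya_len = as.integer(tail_len),
        planted = c(rep(FALSE, length(pos_s)), rep(TRUE, length(pos_p)),
                    rep(FALSE, n_a)),
        read = paste0(frag, strrep("A", tail_len)),
        stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    if (is.null(tab)) {
      return(list(reads = character(),
                  truth = data.frame(read_id = character(),
                                     condition = character(),
                                     cds = character(), strand = character(),
                                     pos5 = integer(), core_len = integer(),
                                     polya_len = integer(),
                                     planted = logical(),
                                     stringsAsFactors = FALSE)))
    }
    tab$condition <- sample(config$conditions, nrow(tab), replace = TRUE)
    tab$read_id <- sprintf("deg_r%06d", seq_len(nrow(tab)))
    reads <- stats::setNames(tab$read, tab$read_id)
    tab <- tab[, c("read_id", "condition", "cds", "strand", "pos5",
                   "core_len", "polya_len", "planted")]
    rownames(tab) <- NULL
    list(reads = reads, truth = tab)
  })
}

#' Noise-free per-CDS expression counts from the truth record
#'
#' Deterministic counterpart of the read generator for validating the
#' differential-expression filter: each CDS gets `round(n_srna_reads * w)`
#' counts per condition, multiplied (divided) by the planted fold for
#' up- (down-) regulated loci in their stress condition. With
#' `noise_free = FALSE` a Poisson draw with those means is returned instead.
#'
#' @param truth output of [generate_truth()].
#' @param config a [sim_config()].
#' @param noise_free logical; exact deterministic counts if TRUE.
#' @return integer matrix, CDS by condition.
#' @export
simulate_expression_counts <- function(truth, config, noise_free = TRUE) {
  ids <- names(truth$cds_weights)
  base <- round(config$n_srna_reads * truth$cds_weights)
  mat <- matrix(rep(base, length(config$conditions)),
                nrow = length(ids),
                dimnames = list(ids, config$conditions))
  de <- truth$de_loci
  for (j in seq_len(nrow(de))) {
    v <- base[[de$cds[j]]]
    # integer rounding must not erode the planted bound: up-regulation
    # multiplies exactly; down-regulation floors so the realized count
    # ratio stays >= fold
    mat[de$cds[j], de$condition[j]] <-
      if (de$direction[j] == "up") round(v * de$fold[j]) else
        max(1, v %/% de$fold[j])
  }
  if (!noise_free) {
    mat[] <- stats::rpois(length(mat), mat)
  }
  storage.mode(mat) <- "integer"
  mat
}

#' Run the full simulator, optionally writing files
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; if given, writes reference FASTA files,
#'   raw multiplexed sRNA FASTQ, degradome FASTQ, TSV truth tables and a
#'   JSON echo of the configuration.
#' @return list with `refs`, `truth`, `srna` and `degradome` (see the
#'   individual generators), invisibly when writing.
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  refs <- generate_references(config)
  truth <- generate_truth(refs, config)
  srna <- generate_srna_reads(refs, truth, config)
  deg <- generate_degradome_reads(refs, truth, config)
  res <- list(refs = refs, truth = truth, srna = srna, degradome = deg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(refs$genome, file.path(out_dir, "genome.fasta"))
    write_fasta(refs$cds, file.path(out_dir, "cds.fasta"))
    write_fasta(refs$est, file.path(out_dir, "est.fasta"))
    write_fasta(refs$contaminant, file.path(out_dir, "contaminant.fasta"))
    write_fastq(srna$reads, file.path(out_dir, "srna_raw.fastq"))
    if (length(deg$reads)) {
      write_fastq(deg$reads, file.path(out_dir, "degradome_raw.fastq"))
    }
    write_tsv_report(srna$truth, file.path(out_dir, "srna_truth.tsv"))
    write_tsv_report(deg$truth, file.path(out_dir, "degradome_truth.tsv"))
    write_tsv_report(data.frame(cds = names(truth$cds_bias_class),
                                class = unname(truth$cds_bias_class),
                                weight = unname(truth$cds_weights)),
                     file.path(out_dir, "cds_classes.tsv"))
    write_tsv_report(truth$de_loci, file.path(out_dir, "de_loci.tsv"))
    write_tsv_report(truth$planted_peaks,
                     file.path(out_dir, "planted_peaks.tsv"))
    write_tsv_report(data.frame(contig = truth$hotspot_contigs),
                     file.path(out_dir, "hotspot_contigs.tsv"))
    cfg <- unclass(config)
    # named atomic vectors must become lists to survive the JSON round trip
    named_fields <- c("bias_mixture", "length_dist", "first_base_dist",
                      "barcode_map", "class_sense_prob")
    cfg[named_fields] <- lapply(cfg[named_fields], as.list)
    jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(res))
  }
  res
}
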
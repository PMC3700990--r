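---
title: "Methods: small-RNA and degradome profiling with exact-match mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-RNA and degradome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis model

`srnadeg` implements the analysis chain used in genome-wide surveys of
exonic small RNAs in organisms with draft assemblies: reads are mapped to
three reference collections — genome contigs, predicted coding sequences
(CDSs) and EST contigs — by **full-length matches at 100% identity on
either strand**. No mismatches, clipping or seeds: a read either occurs as
an exact substring of a reference (or of its reverse complement) or it does
not map. This is deliberately conservative; with 16–32 nt reads a single
mismatch tolerance would mostly admit cross-mapping noise, and the strict
rule makes redundant/unique bookkeeping exact.

Counting distinguishes **redundant** totals (read copies) from **unique**
totals (distinct sequences). A multi-mapping read contributes its copies to
*every* reference it hits — per-locus maps need per-locus counts — but only
once to library-level totals, so summary tables never double count. The
pooled "Total" row counts unique sequences over the *union* of libraries,
which is why a published union total can be smaller than the per-library
sum.

## Strand bias and transcript orientation

Degradome (PARE) libraries are directionally cloned from the 5' phosphate
of mRNA fragments, so the strand of a degradome tag identifies the
transcribed strand. A transcript is *oriented* when its degradome sense
fraction is **strictly greater than 0.75** for CDSs ("prevalent sense
transcription") or **at least 0.70** for ESTs, or when it has sense tags
and **no antisense tag at all** (the absence rule). The two inclusivity
conventions follow the wording of the respective selection rules
(">75%" vs "70% or more"). CDSs are additionally directional through their
reading frame; the degradome orientation serves as corroboration and the
`oriented_by` column lets disagreements be audited.

For oriented references with at least `min_srna = 10` sRNAs, each record
carries percent sense / percent antisense and a bias class:

* `antisense_only` — no sense sRNA at all;
* `antisense_biased` — percent antisense > 50;
* `sense_prevalent` — otherwise.

The 50% boundary is a package choice: the source analyses report "a bias
for antisense production" without defining the cutoff. Exact 50/50 ties are
counted as `sense_prevalent` and flagged (`tie`), so the involution
property — swapping every read's strand swaps the classes — holds exactly
off the tie set and remains auditable on it.

## Degradome pileups and the ≥ 3×-mean peak rule

Each sense alignment contributes its copies at its 5'-most coordinate; the
per-CDS profile is normalized to **relative frequencies** (counts divided
by the CDS's total tags). A position is a **peak** when its relative
frequency is at least `factor_threshold = 3` times the per-CDS mean.
Two readings of "mean frequency per CDS" exist and both are implemented:

* `mean_mode = "nonzero"` (default): mean over positions with ≥ 1 tag — a
  "peak" is a tagged position, matching plots in which every tagged
  position is drawn as a peak. With `k` tagged positions the mean relative
  frequency is exactly `1/k`, so `factor = rel_freq × k`.
* `mean_mode = "all"`: mean over all positions of the CDS.

The threshold is inclusive (the rule removes peaks *below* three-fold, so
equality survives), peak calls are invariant under rescaling a CDS's
counts, and a CDS with no tags yields no peaks.

The **stop-distance profile** uses the fixed-denominator convention:
distance 0 is the first nucleotide of the stop codon, increasing toward
5', and the value at distance *d* is the sum of relative frequencies at
*d* over *all* CDSs divided by the total number of CDSs — CDSs that are
shorter than *d*, or that have no tags, contribute zero rather than being
dropped from the denominator.

The **random peak control** places the same number of pseudo-peaks on CDSs
drawn with probability proportional to length, uniformly within each CDS
(the published control's randomization is not described; this is the
natural null for positionally uniform peaks). The **overlap test** counts
peaks covered by any mapped sRNA interval and compares against `B`
control placements: `p = (1 + #{control ≥ observed}) / (1 + B)`. This
replaces a BLAST-based overlap search with an exact-coordinate permutation
test — the same question, but deterministic and self-contained.

## RPKM and the 100 / 10-fold differential rule

`RPKM(c, l) = count(c, l) / (length_kb(c) × mapped_millions(l))`, with the
library size defined as the per-library redundant total mapped to the CDS
set. A CDS is differential when (i) some condition reaches
`min_rpkm = 100` and (ii) some stress condition differs from normal by
`min_fold = 10` or more. Because transcripts can switch off entirely, the
fold change divides by `max(smaller value, ε)` where **ε is the RPKM a
single read would have** in the library holding the smaller value — the
smallest observable nonzero expression, which keeps "400 vs 0" finite
(fold 400 in the worked example) without inventing a global pseudocount.
Heat-map ordering uses average-linkage hierarchical clustering on
Euclidean distances of log2(RPKM + 1); the linkage and distance are
package choices (unreported in the source analyses) and configurable.

# The simulator: what it emulates

`sim_config()` defaults define the package's stated world, a desk-scale
genome with the statistical structure of plant-like sRNA data:

| parameter | default | rationale |
|---|---|---|
| `n_genome_contigs`, `n_cds`, `n_est` | 600 / 500 / 250 | desk-scale analogue of a fragmented draft assembly; every CDS sits in its own contig at recorded coordinates |
| `length_dist` | 15–35 nt, sharp mode at 21 | gel excision spans 15–35 nt while the computational filter keeps 16–32, so the filter is genuinely exercised; 21 nt is the modal class of Dicer products |
| `first_base_dist` | A .30, U .28, G .22, C .20 | slight A/U 5' overrepresentation |
| `bias_mixture` | sense .58 / anti-biased .14 / anti-only .03 / none .25 | ~75% of CDSs produce sRNAs; among profiled CDSs roughly 4:1 sense-prevalent to antisense, a few percent antisense-only |
| `hotspot_frac_contigs`, `hotspot_read_share` | 0.5%, 0.83 | a handful of contigs carrying ~83% of genomic reads |
| `degradome_background_rate` | 0.2 tags/nt | gives 60–180 background tags per CDS |
| `degradome_3prime_bias` | 0.01 /nt | exponential pull of 5' ends toward the stop codon (5'→3' exonucleolytic turnover); mean distance ~100 nt |
| `planted_peak_factor_range` | 5–12 | endonucleolytic spikes comfortably above the 3× calling threshold |
| `degradome_antisense_frac` | 0.10 (0.35 for a 10% "ambiguous" subset) | ordinary CDSs pass the >75% orientation rule; the ambiguous subset exercises its rejection branch |
| `fold_change_loci`, `fold_change_factor` | 8 loci, 12× | planted ≥10-fold changes; see below for why 12 rather than exactly 10 |
| `polya_tail_prob` | 0.10 | tags acquiring 3–10 nt poly-A tails from oligo-d(T) priming |
| `contaminant_read_frac` | 0.05 | rRNA/tRNA/plastid carry-through |

Reads are emitted in DNA alphabet (T, not U); 5'-base reports translate T
to U. Each sRNA read is `4-nt barcode + insert + 3' adapter` with constant
qualities — only trimability matters, so no sequencing-error or
quality model is included. The generators draw from seeds derived from
`config$seed` with fixed per-stage offsets, so a fixed seed yields
byte-identical FASTA/FASTQ and truth tables regardless of which subset of
generators is called.

Design choices worth recording:

* **Planted expression changes** are placed on CDSs of mid-range abundance
  (weights between the 50th and 85th percentile), spread round-robin over
  the stress conditions and alternating up/down. This is not cosmetic: the
  RPKM fold observed for a planted locus is the planted count fold divided
  by the library-size ratio its own planting induces. Plant 10× on a locus
  carrying several percent of a library and the observed fold drops below
  10 — hence a 12× plant, bounded per-locus mass, and balanced assignment.
  Exact recovery is guaranteed only while planted mass stays a small
  fraction of the library; the noise-free count generator also floors
  down-regulated counts (`base %/% fold`, minimum 1) so integer rounding
  can never erode the planted bound (rounding 19/12 to 2 would make the
  realized fold 9.5).
* **Degradome truncation**: tags are CDS suffix-anchored fragments; near
  the stop codon a 25-nt tag no longer fits, so tags with 5' ends within
  ~22 nt of the stop are lost to the size filter — the same censoring a
  real gel selection applies to short 3'-turnover fragments.
* The 3'-bias is geometric (`P(d) ∝ exp(-λd)`); `λ = 0` switches to a
  uniform background, used by the paired-simulation tests.

## What a green test does and does not establish

The simulator has no sequencing errors, no quality variation, no
UTR/intron structure, no paralogy beyond chance k-mer collisions, and
contaminants are random sequences disjoint from the genome. Green recovery
tests therefore establish that the *pipeline arithmetic* is correct under
the stated statistical structure — not that the thresholds would perform
identically on real libraries with error-containing reads and repetitive
references, where the 100%-identity rule discards errors instead of
mis-assigning them.

Two validity regimes are worth spelling out:

* **5'-base recovery** is checked in the low-coverage (linear) regime. The
  unique-read view of a deeply covered locus saturates: once most start
  positions are observed, the distinct-sequence composition drifts toward
  the reference composition no matter how biased the sampling. That is a
  property of the unique collapse, not a generator defect, so the
  confidence-interval check runs without hotspot saturation.
* **Peak-caller precision** against planted truth is *not* asserted. With
  an exponential background, the ≥3×-mean rule systematically calls
  3'-proximal background positions (their relative frequency genuinely is
  ≥3× the CDS mean — these are exactly the "high-frequency" positions the
  published procedure retains); with a flat ~1-tag-per-position
  background, any 4-tag position clears 3× the mean. Measured precision at
  default settings is ~2/3, and no realistic background makes it ≥95%.
  The suite instead asserts sensitivity (≥0.9 for planted factors ≥5 on
  CDSs with ≥50 background tags; measured 1.0), zero calls on uniform
  profiles, scale invariance, and — via an independent recount — that
  every called peak satisfies the ≥3× definition exactly.
* **Overlap-test calibration** uses 400-peak datasets so the overlap count
  is spread over many values; the `(1 + #{≥}) / (1 + B)` estimator is
  conservative under heavy ties, and with a nearly continuous statistic
  the null rejection rate at α = 0.05 lands within the 99% binomial band
  of 0.05 (measured 0.038–0.048 across seeds).

# Numerical and interface choices

* Percentages in human-facing tables are rounded **half-up to 2 decimals**
  (83.128… reports as 83.13); ranking ties break by reference id so
  reports are deterministic.
* Size filters are inclusive on both ends (16 and 32 both pass).
* Adapter trimming is exact-substring, first occurrence from 5'; reads
  without an adapter hit are dropped and counted (`untrimmable`) rather
  than clipped — the kit-level behaviour is unspecified, and counting
  keeps the conservation invariant exact. Poly-A trimming removes the
  maximal trailing A-run when it is ≥ 4 nt; a read trimmed to length zero
  survives until the size filter removes it, so stage counters stay
  conserved.
* Contaminant removal reuses the exact full-length both-strand matching of
  the mapper — one matching semantics throughout.
* Coordinates are 0-based half-open internally and in BED exports; the
  stop-codon anchor is the first nucleotide of the stop codon (distance 0),
  increasing toward 5'.
* Configuration files are JSON (`jsonlite`); named vectors are serialized
  as objects so they round-trip. The CLI (`inst/cli/srnadeg`) exposes the
  file-level subcommands `simulate`, `preprocess`, `map` and `run-all`;
  the per-stage analysis operations consume in-memory objects and are
  reached through the R API or `run-all`, which writes every stage's
  tables plus a checksum manifest.
* The degradome FASTQ is emitted as one multiplexed file with a per-tag
  condition column in the truth table; the degradome analyses (orientation,
  peaks) pool conditions, as the published peak analysis does.

# Known limitations

* The exact mapper is built on Biostrings dictionaries
  (variable-width `PDict` with a trusted band); reference sets are
  concatenated with `N` spacers, so references longer than ~2 Gb in total
  would need chunking.
* No statistical test accompanies the differential filter — the design has
  no replicates, matching the source analyses; the filter is a screen, not
  an inference.
* Phasing-register detection, miRNA hairpin discovery and homology-based
  target prediction are out of scope.
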
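#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero, the convention
#' used in all human-facing percentage tables of this package (e.g. a hotspot
#' share of 83.125 reports as 83.13, not banker's 83.12).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage share, rounded half-up
#'
#' @param x numerator (count).
#' @param total denominator (count).
#' @param digits decimal places (default 2, matching report tables).
#' @return `100 * x / total` rounded half-up.
#' @export
pct_share <- function(x, total, digits = 2) {
  round_half_up(100 * x / total, digits)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

# Random DNA strings of the given lengths (uniform base composition).
random_dna <- function(lengths) {
  lengths <- as.integer(lengths)
  if (length(lengths) == 0L) return(character())
  total <- sum(lengths)
  s <- paste(sample(c("A", "C", "G", "T"), total, replace = TRUE),
             collapse = "")
  ends <- cumsum(lengths)
  starts <- ends - lengths + 1L
  substring(s, starts, ends)
}

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Write a data.frame as TSV with optional '# key: value' provenance header.
write_tsv_report <- function(df, path, header = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) {
    writeLines(paste0("# ", names(header), ": ",
                      vapply(header, paste, "", collapse = ",")), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
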
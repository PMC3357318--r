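# Shared small helpers: rounding conventions, validation, coordinate conversion.

DNA_BASES <- c("A", "C", "G", "T")

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; identity percentages and allele
#' frequencies follow the usual half-away-from-zero reporting convention
#' (283/285 -> 99.30, not 99.3 via banker's rounding).
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Validate a nucleotide string over ACGTN (uppercase).
assert_dna <- function(seq, what = "sequence", allow_n = TRUE) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || nchar(seq) == 0L)
    stop(what, " must be a single non-empty string", call. = FALSE)
  alph <- if (allow_n) "ACGTN" else "ACGT"
  bad <- gsub(sprintf("[%s]", alph), "", seq)
  if (nchar(bad) > 0L)
    stop(what, " contains characters outside {", alph, "}: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ","), call. = FALSE)
  invisible(seq)
}

# Split a sequence string into a character vector of single bases.
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

chars_seq <- function(x) paste(x, collapse = "")

# Reverse complement (ACGTN).
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(seq_chars(seq)), collapse = ""))
}

# 0-based half-open genome coordinates are used in all tables (BED
# convention); consensus positions shown to users are 1-based. These two
# helpers are the single conversion point.
to1based <- function(start0) start0 + 1L
to0based <- function(start1) start1 - 1L

# Derive a deterministic sub-seed for a named pipeline stage from the master
# seed, kept below 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) + 1000003L * (h %% 2048L)) %% .Machine$integer.max
}
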
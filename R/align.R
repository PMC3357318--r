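# align_consensus: pairwise global alignment of element copies to consensus
# sequences, the percent-identity convention used in the hit tables,
# consensus building, and a seed-and-extend genome scanner.

#' Default alignment scores
#'
#' Match +1, mismatch -1, gap open -4, gap extend -1. A length-k gap costs
#' 4 + (k-1); a single indel therefore outweighs three mismatches, matching
#' the rarity of indels in young Alu copies.
#'
#' @return named list of scores
#' @export
align_scores <- function() {
  list(match = 1, mismatch = -1, gap_open = -4, gap_extend = -1)
}

# Substitution matrix over ACGTN; N never matches anything (including N).
.subst_matrix <- function(match, mismatch) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- match
  m["N", ] <- mismatch
  m[, "N"] <- mismatch
  m
}

.pa_to_alignment <- function(pa, scores) {
  q <- as.character(Biostrings::alignedPattern(pa))
  r <- as.character(Biostrings::alignedSubject(pa))
  qc <- seq_chars(q)
  rc <- seq_chars(r)
  ref_pos <- cumsum(rc != "-")
  ref_pos[rc == "-"] <- 0L
  qry_pos <- cumsum(qc != "-")
  qry_pos[qc == "-"] <- 0L
  structure(list(query = q, reference = r,
                 score = Biostrings::score(pa),
                 ref_pos = as.integer(ref_pos),
                 qry_pos = as.integer(qry_pos),
                 scores = scores),
            class = "alu_alignment")
}

#' Global pairwise alignment
#'
#' Needleman-Wunsch global alignment with affine gaps under the scores of
#' [align_scores()] (configurable). Both sequences must be non-empty over
#' ACGTN; `N` never scores as a match.
#'
#' @param query query sequence (an element copy)
#' @param reference reference sequence (a consensus)
#' @param scores list as returned by [align_scores()]
#' @return an `alu_alignment`: gapped `query` and `reference` strings of
#'   equal length, the alignment `score`, and per-column position maps
#'   `ref_pos`/`qry_pos` (0 at gap columns)
#' @export
#' @examples
#' aln <- global_align("ACGACGT", "ACGTACGT")
#' aln$score  # 7 matches - one length-1 gap = 3
global_align <- function(query, reference, scores = align_scores()) {
  assert_dna(query, "query")
  assert_dna(reference, "reference")
  mat <- .subst_matrix(scores$match, scores$mismatch)
  pa <- Biostrings::pairwiseAlignment(
    pattern = query, subject = reference, type = "global",
    substitutionMatrix = mat,
    gapOpening = -(scores$gap_open - scores$gap_extend),
    gapExtension = -scores$gap_extend)
  .pa_to_alignment(pa, scores)
}

#' Percent identity of an alignment
#'
#' `100 * matches / columns` after trimming the query's trailing poly(A) run
#' (>= `polyA_min` A's) and any columns flagged as target-site duplication.
#' Reported to two decimals, rounding half away from zero. This is the
#' element-body identity convention of the hit tables: a 285-column
#' alignment with 283 matches reports 99.30.
#'
#' @param alignment an `alu_alignment` from [global_align()]
#' @param polyA_min minimum trailing A-run length to trim (set `Inf` to
#'   disable)
#' @param exclude_cols optional integer vector of additional columns to drop
#'   (e.g. TSD columns flagged upstream)
#' @return percent identity, rounded to 2 decimals
#' @export
percent_identity <- function(alignment, polyA_min = 5L, exclude_cols = NULL) {
  qc <- seq_chars(alignment$query)
  rc <- seq_chars(alignment$reference)
  keep <- rep(TRUE, length(qc))
  if (!is.null(exclude_cols)) keep[exclude_cols] <- FALSE
  if (is.finite(polyA_min)) {
    res_cols <- which(qc != "-")
    if (length(res_cols) > 0) {
      run <- 0L
      for (i in rev(res_cols)) {
        if (qc[i] == "A") run <- run + 1L else break
      }
      if (run >= polyA_min) {
        cut <- res_cols[length(res_cols) - run + 1L]
        keep[seq_along(qc) >= cut] <- FALSE
      } else {
        # drop trailing query-gap columns beyond the last query residue
        keep[seq_along(qc) > res_cols[length(res_cols)]] <- FALSE
      }
    }
  }
  qc <- qc[keep]
  rc <- rc[keep]
  if (length(qc) == 0L) return(NA_real_)
  matches <- sum(qc == rc & qc != "-" & qc != "N")
  round_half_up(100 * matches / length(qc), 2)
}

#' Build a consensus from pre-aligned member sequences
#'
#' Per column the strict-majority base wins; ties go to the ancestral base
#' when one is supplied (and is among the tied bases), otherwise to the
#' lexicographically smallest tied base. Columns gapped in a strict majority
#' of members are omitted.
#'
#' @param members character vector of equal-length gapped sequences
#' @param ancestral optional ancestral sequence aligned to the same columns
#' @return ungapped consensus sequence
#' @export
build_consensus <- function(members, ancestral = NULL) {
  stopifnot(length(members) >= 1L)
  L <- unique(nchar(members))
  if (length(L) != 1L)
    stop("members must be pre-aligned to a common length", call. = FALSE)
  if (!is.null(ancestral) && nchar(ancestral) != L)
    stop("ancestral sequence must share the member alignment length", call. = FALSE)
  m <- do.call(rbind, lapply(members, seq_chars))
  anc <- if (!is.null(ancestral)) seq_chars(ancestral) else NULL
  out <- character(0)
  for (j in seq_len(L)) {
    col <- m[, j]
    n_gap <- sum(col == "-")
    if (n_gap > length(col) / 2) next
    bases <- col[col != "-" & col != "N"]
    if (length(bases) == 0L) next
    tab <- table(bases)
    top <- names(tab)[tab == max(tab)]
    pick <- if (length(top) == 1L) top
            else if (!is.null(anc) && anc[j] %in% top) anc[j]
            else sort(top)[1]
    out <- c(out, pick)
  }
  chars_seq(out)
}

# ---- Seed-and-extend genome scanner ----------------------------------------

# All exact k-mer start positions (1-based) of `kmers` in `seqstr`.
.kmer_hits <- function(seqstr, kmers, k) {
  n <- nchar(seqstr) - k + 1L
  if (n < 1L) return(data.frame(gpos = integer(0), cpos = integer(0)))
  subs <- substring(seqstr, seq_len(n), seq_len(n) + k - 1L)
  idx <- match(subs, kmers)
  hit <- which(!is.na(idx))
  data.frame(gpos = hit, cpos = idx[hit])
}

#' Scan a genome for copies of a consensus sequence
#'
#' Seed-and-extend homology search: exact 12-mer seeds from the consensus
#' are located on both strands, overlapping seed clusters are extended by
#' pairwise alignment of the implied window (ends-free), and hits with
#' [percent_identity()] at or above `min_identity` and aligned length at
#' least `min_len` are reported with 0-based half-open coordinates and
#' strand. Overlapping hits are merged keeping the higher identity. `N`
#' never seeds and never matches.
#'
#' @param genome genome sequence (single string) or named length-1 vector
#' @param consensus consensus sequence to search for
#' @param min_identity minimum percent identity
#' @param min_len minimum alignment column count
#' @param seed_len exact seed length (default 12)
#' @param chrom name used in the output table
#' @return data.frame: locus_id, chrom, start, end, strand, identity
#' @export
scan_genome <- function(genome, consensus, min_identity = 90, min_len = 150L,
                        seed_len = 12L, chrom = NULL) {
  if (is.null(chrom)) chrom <- names(genome) %||% "genome"
  genome <- toupper(unname(genome))
  consensus <- toupper(consensus)
  assert_dna(genome, "genome"); assert_dna(consensus, "consensus")
  Lc <- nchar(consensus)
  nk <- Lc - seed_len + 1L
  kmers <- substring(consensus, seq_len(nk), seq_len(nk) + seed_len - 1L)
  kmers[grepl("N", kmers, fixed = TRUE)] <- NA  # N never seeds
  Lg <- nchar(genome)
  hits_all <- list()
  for (strand in c("+", "-")) {
    target <- if (strand == "+") genome else revcomp(genome)
    h <- .kmer_hits(target, kmers, seed_len)
    if (nrow(h) == 0L) next
    h$s <- h$gpos - h$cpos + 1L  # implied element start on this strand
    h <- h[order(h$s, h$gpos), ]
    cl <- cumsum(c(1L, diff(h$s) > 30L))
    for (g in split(h, cl)) {
      w_start <- max(1L, min(g$s) - 15L)
      w_end <- min(nchar(target), max(g$s) + Lc - 1L + 15L)
      window <- substr(target, w_start, w_end)
      mat <- .subst_matrix(1, -1)
      pa <- Biostrings::pairwiseAlignment(pattern = window, subject = consensus,
                                          type = "overlap",
                                          substitutionMatrix = mat,
                                          gapOpening = 3, gapExtension = 1)
      aln <- .pa_to_alignment(pa, align_scores())
      ident <- percent_identity(aln, polyA_min = Inf)
      ncol_aln <- nchar(aln$query)
      if (is.na(ident) || ident < min_identity || ncol_aln < min_len) next
      pr <- as.integer(c(Biostrings::start(Biostrings::pattern(pa)),
                         Biostrings::end(Biostrings::pattern(pa))))
      a_start <- w_start + pr[1] - 1L  # 1-based on this strand
      a_end <- w_start + pr[2] - 1L
      if (strand == "+") {
        start0 <- a_start - 1L; end0 <- a_end
      } else {
        start0 <- Lg - a_end; end0 <- Lg - a_start + 1L
      }
      hits_all[[length(hits_all) + 1L]] <-
        data.frame(chrom = chrom, start = start0, end = end0,
                   strand = strand, identity = ident)
    }
  }
  if (length(hits_all) == 0L)
    return(data.frame(locus_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), identity = numeric(0)))
  hits <- do.call(rbind, hits_all)
  hits <- hits[order(-hits$identity, hits$start), ]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    if (i < nrow(hits)) for (j in (i + 1L):nrow(hits)) {
      if (keep[j] && hits$start[j] < hits$end[i] && hits$end[j] > hits$start[i])
        keep[j] <- FALSE  # overlap: keep the higher identity (sorted first)
    }
  }
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[order(hits$start), , drop = FALSE]
  hits$locus_id <- sprintf("hit%03d", seq_len(nrow(hits)))
  rownames(hits) <- NULL
  hits[, c("locus_id", "chrom", "start", "end", "strand", "identity")]
}

#' Extract an element locus (body plus flanks) from a genome
#'
#' Sequences are returned oriented 5'->3' on the element strand:
#' `left_flank` is upstream of the element start.
#'
#' @param genome genome sequence string
#' @param start,end 0-based half-open element coordinates
#' @param strand "+" or "-"
#' @param flank flank length to extract (clipped at genome ends)
#' @return list(element_seq, left_flank, right_flank)
#' @export
extract_locus <- function(genome, start, end, strand = "+", flank = 80L) {
  genome <- unname(genome)
  Lg <- nchar(genome)
  body <- substr(genome, start + 1L, end)
  lf <- substr(genome, max(1L, start - flank + 1L), start)
  rf <- substr(genome, end + 1L, min(Lg, end + flank))
  if (strand == "-") {
    tmp <- revcomp(lf)
    lf <- revcomp(rf)
    rf <- tmp
    body <- revcomp(body)
  }
  list(element_seq = body, left_flank = lf, right_flank = rf)
}
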
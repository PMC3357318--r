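# hallmarks: retrotransposition-competence annotation. TSD detection,
# poly(A) tail measurement and disruption typing, Pol III terminator
# distance, promoter A/B-box and left-monomer integrity, a composite
# competence score, and in-silico PCR product sizes.

#' Find the target site duplication between two flanks
#'
#' The longest suffix of `left_flank` matching a prefix of `right_flank`
#' with at most `max_mismatch` mismatches (no indels). Longer matches win;
#' at equal length fewer mismatches win.
#'
#' @param left_flank,right_flank flanking sequences, element strand
#' @param min_len minimum TSD length
#' @param max_mismatch maximum mismatches between the two copies
#' @return list(sequence, length, mismatches) or NULL when no duplication
#'   of at least `min_len` is found
#' @export
find_tsd <- function(left_flank, right_flank, min_len = 8L,
                     max_mismatch = 2L) {
  Lmax <- min(nchar(left_flank), nchar(right_flank))
  if (Lmax < min_len) return(NULL)
  best <- NULL
  for (L in Lmax:min_len) {
    a <- seq_chars(substr(left_flank, nchar(left_flank) - L + 1L,
                          nchar(left_flank)))
    b <- seq_chars(substr(right_flank, 1L, L))
    mm <- sum(a != b)
    if (mm <= max_mismatch) {
      best <- list(sequence = chars_seq(a), length = L,
                   mismatches = as.integer(mm))
      break  # longest qualifying length
    }
  }
  best
}

# Longest prefix of `x` (character vector) in which every full window of
# `win` has at least `need` A's; short prefixes (< win) must hold the same
# 70% proportion. Used forward for tail regions and on the reversed element
# to split body from tail.
.tail_run <- function(x, win = 10L, need = 7L) {
  n <- length(x)
  if (n == 0L) return(0L)
  isA <- cumsum(c(0L, x == "A"))
  count_A <- function(i, j) isA[j + 1L] - isA[i]
  best <- 0L
  for (L in seq_len(n)) {
    w <- min(win, L)
    req <- if (w < win) ceiling(0.7 * w) else need
    ok <- TRUE
    for (i in seq_len(L - w + 1L)) {
      if (count_A(i, i + w - 1L) < req) { ok <- FALSE; break }
    }
    if (ok) best <- L else if (L >= win) break
  }
  while (best > 0L && x[best] != "A") best <- best - 1L
  best
}

#' Measure a poly(A) tail
#'
#' The tail is the maximal run from the 5' end of the tail region in which
#' every window of 10 nt contains at least 7 A's (trailing non-A bases are
#' trimmed). Disruptions are the non-A positions inside the run, typed
#' `tolerated` for A-to-T changes and `severe` for C or G, reflecting their
#' very different impact on mobilization.
#'
#' @param tail_region sequence from the element body end onwards (the
#'   downstream flank may be included; it does not affect the measurement)
#' @return list(length, disruptions = data.frame(offset, base, type))
#' @export
measure_polyA <- function(tail_region) {
  x <- seq_chars(toupper(tail_region))
  L <- .tail_run(x)
  if (L == 0L)
    return(list(length = 0L,
                disruptions = data.frame(offset = integer(0),
                                         base = character(0),
                                         type = character(0))))
  tail <- x[seq_len(L)]
  off <- which(tail != "A")
  list(length = L,
       disruptions = data.frame(
         offset = off, base = tail[off],
         type = ifelse(tail[off] == "T", "tolerated", "severe"),
         stringsAsFactors = FALSE))
}

#' Split an element into body and poly(A) tail
#'
#' Applies the tail window rule from the 3' end of the element sequence.
#'
#' @param element_seq element sequence, tail included at the 3' end
#' @return the body with the measured tail removed
#' @export
trim_tail <- function(element_seq) {
  x <- rev(seq_chars(element_seq))
  L <- .tail_run(x)
  substr(element_seq, 1L, nchar(element_seq) - L)
}

#' Distance from tail end to the Pol III terminator
#'
#' Offset of the first TTTT run in the downstream sequence; 0 means the
#' terminator immediately follows the poly(A) tail (the configuration
#' associated with efficient mobilization), -1 means no TTTT starts within
#' `window` nt.
#'
#' @param downstream sequence immediately 3' of the tail (typically the
#'   right flank, whose prefix is the 3' TSD)
#' @param window search window in nt
#' @return integer offset, or -1
#' @export
terminator_distance <- function(downstream, window = 50L) {
  m <- regexpr("TTTT", substr(downstream, 1L, window + 3L), fixed = TRUE)
  if (m < 0 || as.integer(m) > window) return(-1L)
  as.integer(m) - 1L
}

#' Promoter box and left-monomer integrity
#'
#' Given variant calls of an element against its subfamily consensus,
#' reports whether the internal RNA Pol III promoter A and B boxes are
#' intact (no substitution or indel touching the interval) and how many
#' variant calls fall in the left monomer. Intervals are 1-based consensus
#' coordinates; the defaults are declared conventions for a ~280 nt dimeric
#' consensus (left monomer up to the middle A-rich linker).
#'
#' @param variants data.frame from [call_variants()]
#' @param consensus_len consensus length (for interval validation)
#' @param a_box,b_box,left_monomer 1-based closed intervals
#' @return list(a_box_intact, b_box_intact, left_monomer_mutation_count)
#' @export
check_boxes <- function(variants, consensus_len,
                        a_box = c(6L, 37L), b_box = c(70L, 101L),
                        left_monomer = c(1L, 132L)) {
  for (iv in list(a_box, b_box, left_monomer))
    if (iv[1] < 1L || iv[2] > consensus_len || iv[1] > iv[2])
      stop("interval [", iv[1], ",", iv[2], "] outside consensus 1..",
           consensus_len, call. = FALSE)
  touches <- function(iv) {
    if (nrow(variants) == 0L) return(logical(0))
    span_end <- ifelse(variants$kind == "deletion",
                       variants$position + nchar(variants$ref) - 1L,
                       variants$position)
    variants$position <= iv[2] & span_end >= iv[1]
  }
  list(a_box_intact = !any(touches(a_box)),
       b_box_intact = !any(touches(b_box)),
       left_monomer_mutation_count = sum(touches(left_monomer)))
}

#' Locate an upstream promoter/endonuclease-like motif
#'
#' Searches the upstream flank for the best match among TATAAAAA,
#' TTTTAAAA and TTAAAA (longer motifs preferred) and reports it with its
#' offset from the element start. The motif is reported without
#' interpreting whether it acts as a promoter or is an endonuclease-site
#' remnant.
#'
#' @param left_flank upstream flank (element strand)
#' @param window how far upstream to search, nt
#' @return list(motif, offset) or NULL
#' @export
find_upstream_motif <- function(left_flank, window = 40L) {
  region <- substr(left_flank, max(1L, nchar(left_flank) - window + 1L),
                   nchar(left_flank))
  for (motif in c("TATAAAAA", "TTTTAAAA", "TTAAAA")) {
    m <- regexpr(motif, region, fixed = TRUE)
    if (m > 0) {
      offset <- nchar(region) - (as.integer(m) + nchar(motif) - 1L)
      return(list(motif = motif, offset = offset))
    }
  }
  NULL
}

#' Composite retrotransposition-competence score
#'
#' Weighted sum of normalized hallmark features: left monomer intact (0.3),
#' A/B boxes intact (0.2), poly(A) length saturating at 20 nt (0.2; longer
#' tails add little under endogenous conditions), severe tail disruption
#' penalty (0.15), terminator-adjacency bonus decaying with distance (0.1),
#' upstream motif presence (0.05). Weights are editorial, configurable and
#' sum-normalized; all per-feature values are exported in the hallmark
#' table so users can re-weight.
#'
#' @param report a hallmark report list (see [hallmark_report()])
#' @param weights named numeric weights
#' @return score in `[0, 1]`
#' @export
score_competence <- function(report,
                             weights = c(left_monomer = 0.3, boxes = 0.2,
                                         polyA = 0.2, severe = 0.15,
                                         terminator = 0.1, motif = 0.05)) {
  if (sum(weights) <= 0) stop("weights must not all be zero", call. = FALSE)
  term <- report$terminator_distance
  f <- c(left_monomer = as.numeric(report$left_monomer_mutation_count == 0L),
         boxes = (as.numeric(report$a_box_intact) +
                  as.numeric(report$b_box_intact)) / 2,
         polyA = min(report$polyA_length, 20L) / 20,
         severe = max(0, 1 - report$polyA_severe_count / 3),
         terminator = if (term < 0) 0 else exp(-term / 10),
         motif = as.numeric(!is.null(report$upstream_motif)))
  unname(sum(weights * f[names(weights)]) / sum(weights))
}

#' Full hallmark report for one locus
#'
#' Runs every annotator: TSD detection between the flanks, poly(A) tail
#' measurement with disruption typing, Pol III terminator distance in the
#' right flank, A/B box and left-monomer integrity against the subfamily
#' consensus, upstream motif search, and the composite score.
#'
#' @param element_seq element sequence, poly(A) tail included
#' @param left_flank,right_flank flanks, element strand
#' @param consensus subfamily consensus (body, no tail) for box checks
#' @param tsd_min_len,tsd_max_mismatch TSD search settings
#' @param box_args optional list of interval overrides for [check_boxes()]
#' @return a `hallmark_report` list (all fields of the hallmark table)
#' @export
hallmark_report <- function(element_seq, left_flank, right_flank, consensus,
                            tsd_min_len = 8L, tsd_max_mismatch = 2L,
                            box_args = list()) {
  body <- trim_tail(element_seq)
  tail_seq <- substr(element_seq, nchar(body) + 1L, nchar(element_seq))
  pa <- measure_polyA(tail_seq)
  boxes <- do.call(check_boxes, c(list(
    variants = call_variants(global_align(
      if (nchar(body)) body else element_seq, consensus)),
    consensus_len = nchar(consensus)), box_args))
  rep <- list(
    left_monomer_mutation_count = boxes$left_monomer_mutation_count,
    a_box_intact = boxes$a_box_intact,
    b_box_intact = boxes$b_box_intact,
    polyA_length = pa$length,
    polyA_disruptions = pa$disruptions,
    polyA_tolerated_count = sum(pa$disruptions$type == "tolerated"),
    polyA_severe_count = sum(pa$disruptions$type == "severe"),
    terminator_distance = terminator_distance(right_flank),
    upstream_motif = find_upstream_motif(left_flank),
    tsd = find_tsd(left_flank, right_flank, tsd_min_len, tsd_max_mismatch))
  rep$composite_score <- score_competence(rep)
  class(rep) <- "hallmark_report"
  rep
}

#' Predict in-silico PCR product sizes
#'
#' Exact string matching of the primers on the filled template (left flank +
#' element + right flank); no melting-temperature model, since the purpose
#' is size arithmetic. The filled size is the distance between the primer
#' 5' ends inclusive; the empty size removes the element body, poly(A) and
#' one TSD copy.
#'
#' @param left_flank,element_seq,right_flank locus sequences (element
#'   strand; `element_seq` includes the poly(A) tail)
#' @param fwd forward primer (plus strand)
#' @param rev reverse primer (minus strand, given 5'->3')
#' @param tsd_len length of the target site duplication
#' @return list(filled, empty) product sizes in bp
#' @export
predict_pcr_products <- function(left_flank, element_seq, right_flank,
                                 fwd, rev, tsd_len) {
  template <- paste0(left_flank, element_seq, right_flank)
  find_all <- function(x, pat) {
    m <- gregexpr(pat, x, fixed = TRUE)[[1]]
    if (m[1] < 0) integer(0) else as.integer(m)
  }
  fpos <- find_all(template, fwd)
  rpos <- find_all(template, revcomp(rev))
  check <- function(pos, primer, name) {
    if (length(pos) == 0L) {
      if (length(find_all(template, revcomp(primer))) > 0L ||
          (name == "reverse" && length(find_all(template, primer)) > 0L))
        stop(name, " primer matches in the wrong orientation", call. = FALSE)
      stop(name, " primer not found in template", call. = FALSE)
    }
    if (length(pos) > 1L)
      stop(name, " primer maps to multiple sites", call. = FALSE)
    pos
  }
  f <- check(fpos, fwd, "forward")
  r <- check(rpos, rev, "reverse")
  if (r <= f) stop("primers are not in amplifying orientation", call. = FALSE)
  filled <- (r + nchar(rev) - 1L) - f + 1L
  list(filled = as.integer(filled),
       empty = as.integer(filled - nchar(element_seq) - tsd_len))
}
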
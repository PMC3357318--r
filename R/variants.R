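# variant_classify: call per-locus differences from an ancestral consensus,
# class each substitution as CpG/non-CpG (context taken on the ancestral
# consensus, which is deterministic and matches how sites are classed when
# counting mutations for dating), and partition variants across loci into
# subfamily diagnostics versus private changes.

#' Is a consensus position part of a CpG dinucleotide?
#'
#' TRUE iff the consensus carries C at `position` with G immediately 3', or
#' G at `position` with C immediately 5'. CpG sites deaminate roughly 6-10x
#' faster than other sites and must be accounted separately when counting
#' mutations.
#'
#' @param consensus consensus sequence
#' @param position 1-based position
#' @return logical
#' @export
classify_cpg <- function(consensus, position) {
  L <- nchar(consensus)
  if (any(position < 1L | position > L))
    stop("position out of range 1..", L, call. = FALSE)
  vapply(position, function(p) {
    b <- substr(consensus, p, p)
    (b == "C" && p < L && substr(consensus, p + 1L, p + 1L) == "G") ||
      (b == "G" && p > 1L && substr(consensus, p - 1L, p - 1L) == "C")
  }, logical(1))
}

# Sharing key for a variant call: identical alt required (position alone
# would let hypermutable CpG sites fake diagnostics); deletions also key on
# the deleted reference run, insertions on the inserted string.
variant_key <- function(kind, position, ref, alt) {
  paste(kind, position, ref, alt, sep = ":")
}

#' Call variants from an alignment to an ancestral consensus
#'
#' One call per non-match column; adjacent gap columns in the same row
#' coalesce into a single indel call anchored at the leftmost consensus
#' position involved (insertions anchor at the last consensus base before
#' the inserted run, 0 if at the start). Positions are 1-based consensus
#' coordinates. CpG status is evaluated on the ancestral consensus and is
#' only meaningful for substitutions.
#'
#' @param alignment `alu_alignment` with query = element body, reference =
#'   ancestral consensus
#' @return data.frame: position, ref, alt, kind, cpg, key
#' @export
call_variants <- function(alignment) {
  qc <- seq_chars(alignment$query)
  rc <- seq_chars(alignment$reference)
  consensus <- gsub("-", "", alignment$reference, fixed = TRUE)
  ref_pos <- alignment$ref_pos
  n <- length(qc)
  rows <- list()
  emit <- function(position, ref, alt, kind, cpg) {
    rows[[length(rows) + 1L]] <<- data.frame(
      position = as.integer(position), ref = ref, alt = alt, kind = kind,
      cpg = cpg, stringsAsFactors = FALSE)
  }
  i <- 1L
  while (i <= n) {
    if (qc[i] == "-") {           # deletion run
      j <- i
      while (j < n && qc[j + 1L] == "-") j <- j + 1L
      emit(ref_pos[i], paste(rc[i:j], collapse = ""), "-", "deletion", NA)
      i <- j + 1L
    } else if (rc[i] == "-") {    # insertion run
      j <- i
      while (j < n && rc[j + 1L] == "-") j <- j + 1L
      anchor <- if (any(ref_pos[seq_len(i - 1L)] > 0L))
        max(ref_pos[seq_len(i - 1L)]) else 0L
      emit(anchor, "-", paste(qc[i:j], collapse = ""), "insertion", NA)
      i <- j + 1L
    } else {
      if (qc[i] != rc[i])
        emit(ref_pos[i], rc[i], qc[i], "substitution",
             classify_cpg(consensus, ref_pos[i]))
      i <- i + 1L
    }
  }
  if (length(rows) == 0L)
    return(data.frame(position = integer(0), ref = character(0),
                      alt = character(0), kind = character(0),
                      cpg = logical(0), key = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$key <- variant_key(out$kind, out$position, out$ref, out$alt)
  out
}

#' Call variants for a set of loci against one ancestral consensus
#'
#' Convenience wrapper: trims each element's 3' poly(A) tail (measured with
#' [measure_polyA()]), aligns the body to the consensus and calls variants.
#'
#' @param elements named character vector of element sequences (poly(A)
#'   included at the 3' end)
#' @param consensus ancestral consensus (element body, no tail)
#' @param trim_polyA drop the measured tail before aligning (tail changes
#'   are scored by the hallmark module, not counted as body variants)
#' @return data.frame of variant calls with a locus_id column
#' @export
call_variants_set <- function(elements, consensus, trim_polyA = TRUE) {
  stopifnot(!is.null(names(elements)))
  out <- list()
  for (id in names(elements)) {
    body <- elements[[id]]
    if (trim_polyA) body <- trim_tail(body)
    v <- call_variants(global_align(body, consensus))
    if (nrow(v) > 0) v <- cbind(locus_id = id, v)
    out[[id]] <- v
  }
  out <- out[vapply(out, nrow, 0L) > 0]
  if (length(out) == 0L)
    return(data.frame(locus_id = character(0), position = integer(0),
                      ref = character(0), alt = character(0),
                      kind = character(0), cpg = logical(0),
                      key = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Partition shared versus private variants
#'
#' A variant (same position, same alternative allele) carried by at least
#' `k_min_share` loci is a subfamily diagnostic; all other calls are private
#' to their locus. Because a diagnostic's carriers are exactly the loci of
#' the subfamily it defines, a locus's private count is its count of
#' non-diagnostic calls.
#'
#' @param variants data.frame from [call_variants_set()]
#' @param k_min_share minimum carrier count (>= 2)
#' @return list with `variants` (input plus status/support columns),
#'   `diagnostics` (one row per diagnostic with support count and carrier
#'   list) and `private_counts` (per locus: total, cpg, noncpg)
#' @export
partition_diagnostic_private <- function(variants, k_min_share = 3L) {
  stopifnot(k_min_share >= 2L)
  if (nrow(variants) == 0L)
    return(list(variants = variants,
                diagnostics = data.frame(key = character(0),
                                         position = integer(0),
                                         ref = character(0),
                                         alt = character(0),
                                         kind = character(0), cpg = logical(0),
                                         support = integer(0)),
                carriers = list(),
                private_counts = data.frame(locus_id = character(0),
                                            total = integer(0),
                                            cpg = integer(0),
                                            noncpg = integer(0))))
  support <- tapply(variants$locus_id, variants$key,
                    function(x) length(unique(x)))
  variants$support <- as.integer(support[variants$key])
  variants$status <- ifelse(variants$support >= k_min_share,
                            "diagnostic", "private")
  dk <- variants$status == "diagnostic"
  diag_tab <- unique(variants[dk, c("key", "position", "ref", "alt",
                                    "kind", "cpg", "support")])
  diag_tab <- diag_tab[order(-diag_tab$support, diag_tab$position), ]
  rownames(diag_tab) <- NULL
  carriers <- lapply(diag_tab$key, function(k)
    sort(unique(variants$locus_id[variants$key == k])))
  names(carriers) <- diag_tab$key
  loci <- unique(variants$locus_id)
  pc <- do.call(rbind, lapply(loci, function(id) {
    v <- variants[variants$locus_id == id & variants$status == "private", ]
    data.frame(locus_id = id, total = nrow(v),
               cpg = sum(v$kind == "substitution" & v$cpg %in% TRUE),
               noncpg = sum(v$kind == "substitution" & v$cpg %in% FALSE))
  }))
  list(variants = variants, diagnostics = diag_tab, carriers = carriers,
       private_counts = pc)
}
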
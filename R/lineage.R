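# subfamily_lineage: nested subfamily inference from diagnostic variants,
# standardized subfamily naming, source-candidate ranking, and the
# independent-acquisition test for co-occurring variants.

#' Name a subfamily by the standardized convention
#'
#' `parent + sibling letter + number of new diagnostics + "_" + lineage
#' tag`: a subfamily derived from AluYe5 with two additional mutations in
#' the Pongo lineage is AluYe5a2_Pongo; a sibling with five is
#' AluYe5b5_Pongo. Sibling letters follow node-creation order. A trailing
#' `_tag` on the parent name is stripped before composing so grandchild
#' names do not repeat the tag.
#'
#' @param parent_name parent subfamily name
#' @param n_new_diagnostics number of new diagnostic mutations (>= 1; 0
#'   returns the parent name unchanged, consuming no letter)
#' @param sibling_index 0-based index among siblings in creation order
#' @param lineage_tag lineage suffix (e.g. "Pongo")
#' @return subfamily name
#' @export
name_subfamily <- function(parent_name, n_new_diagnostics, sibling_index,
                           lineage_tag) {
  stopifnot(sibling_index >= 0)
  if (n_new_diagnostics == 0L) return(parent_name)
  base <- sub(paste0("_", lineage_tag, "$"), "", parent_name)
  paste0(base, letters[sibling_index + 1L], n_new_diagnostics, "_",
         lineage_tag)
}

#' Infer the nested subfamily hierarchy
#'
#' Candidate diagnostic sets are maximal variant sets with identical
#' carrier sets of at least `k_min_share` loci; nodes nest by carrier-set
#' inclusion (robust to a member losing a diagnostic by back-mutation: a
#' single-variant candidate whose carrier set is one locus short of an
#' otherwise identical node is absorbed into it, with the discrepancy
#' recorded). Loci are assigned to the deepest node whose carrier set
#' contains them; the root is the ancestral consensus with no diagnostics.
#' Construction is deterministic: candidates are processed by descending
#' support, then by position. Carrier sets that partially overlap without
#' nesting become sibling nodes and a homoplasy/recombination warning is
#' recorded.
#'
#' @param partition output of [partition_diagnostic_private()]
#' @param all_loci character vector of every locus id under study
#' @param ancestral_consensus ancestral consensus sequence
#' @param lineage_tag lineage suffix for subfamily names
#' @param ancestral_name root subfamily name
#' @return a `subfamily_tree`: list of nodes (name, diagnostics, carriers,
#'   members, parent, depth, consensus) plus warnings and recorded
#'   discrepancies
#' @export
infer_subfamilies <- function(partition, all_loci, ancestral_consensus,
                              lineage_tag = "Pongo",
                              ancestral_name = "AluY") {
  diag_tab <- partition$diagnostics
  carriers <- partition$carriers
  disc <- data.frame(locus_id = character(0), key = character(0),
                     stringsAsFactors = FALSE)
  warnings <- character(0)

  groups <- list()
  if (nrow(diag_tab) > 0) {
    ckey <- vapply(diag_tab$key,
                   function(k) paste(carriers[[k]], collapse = ","), "")
    for (kk in unique(ckey)) {
      rows <- diag_tab[ckey == kk, , drop = FALSE]
      groups[[length(groups) + 1L]] <- list(
        variants = rows, carriers = carriers[[rows$key[1]]])
    }
    sup <- vapply(groups, function(g) length(g$carriers), 0L)
    minpos <- vapply(groups, function(g) min(g$variants$position), 0L)
    groups <- groups[order(-sup, minpos)]

    # absorb single-variant back-mutation artifacts (carrier set one locus
    # short of an otherwise identical node)
    absorbed <- rep(FALSE, length(groups))
    for (i in seq_along(groups)) {
      if (absorbed[i] || nrow(groups[[i]]$variants) != 1L) next
      for (j in seq_along(groups)) {
        if (i == j || absorbed[j]) next
        Si <- groups[[i]]$carriers; Sj <- groups[[j]]$carriers
        if (length(Sj) == length(Si) + 1L && all(Si %in% Sj)) {
          missing <- setdiff(Sj, Si)
          groups[[j]]$variants <- rbind(groups[[j]]$variants,
                                        groups[[i]]$variants)
          disc <- rbind(disc, data.frame(locus_id = missing,
                                         key = groups[[i]]$variants$key,
                                         stringsAsFactors = FALSE))
          absorbed[i] <- TRUE
          break
        }
      }
    }
    groups <- groups[!absorbed]
  }

  nodes <- list(list(name = ancestral_name,
                     diagnostics = diag_tab[0, , drop = FALSE],
                     carriers = sort(all_loci), members = character(0),
                     parent = NA_integer_, depth = 0L,
                     consensus = ancestral_consensus, n_new = 0L))
  for (g in groups) {
    S <- g$carriers
    parent <- 1L
    best_depth <- 0L
    for (ni in seq_along(nodes)) {
      if (ni == 1L) next
      Sn <- nodes[[ni]]$carriers
      inter <- length(intersect(S, Sn))
      if (inter > 0L && inter < length(S) && inter < length(Sn))
        warnings <- c(warnings, paste0(
          "carrier sets of {", paste(g$variants$key, collapse = ";"),
          "} and node ", nodes[[ni]]$name,
          " overlap without nesting (homoplasy or recombination signal)"))
      if (all(S %in% Sn) && length(S) < length(Sn) &&
          nodes[[ni]]$depth >= best_depth) {
        parent <- ni
        best_depth <- nodes[[ni]]$depth
      }
    }
    nodes[[length(nodes) + 1L]] <- list(
      name = NA_character_, diagnostics = g$variants, carriers = S,
      members = character(0), parent = parent,
      depth = nodes[[parent]]$depth + 1L, consensus = NA_character_,
      n_new = nrow(g$variants))
  }

  # names (sibling letters in creation order) and node consensus sequences
  sib_count <- integer(length(nodes))
  for (ni in seq_along(nodes)) {
    if (ni == 1L) next
    p <- nodes[[ni]]$parent
    nodes[[ni]]$name <- name_subfamily(nodes[[p]]$name, nodes[[ni]]$n_new,
                                       sib_count[p], lineage_tag)
    sib_count[p] <- sib_count[p] + 1L
    chain <- nodes[[ni]]$diagnostics
    q <- p
    while (!is.na(q)) {
      chain <- rbind(chain, nodes[[q]]$diagnostics)
      q <- nodes[[q]]$parent
    }
    nodes[[ni]]$consensus <- apply_variants(ancestral_consensus, chain)
  }

  # assign loci to the deepest node whose carrier set contains them
  for (id in sort(all_loci)) {
    depth <- vapply(nodes, function(n)
      if (id %in% n$carriers) n$depth else -1L, 0L)
    depth[1] <- 0L
    nd <- which.max(depth)
    nodes[[nd]]$members <- c(nodes[[nd]]$members, id)
  }

  structure(list(nodes = nodes, warnings = unique(warnings),
                 discrepancies = disc),
            class = "subfamily_tree")
}

#' Apply variant calls to a consensus sequence
#'
#' Edits a consensus at the given diagnostic variants (substitutions,
#' deletions, insertions in 1-based consensus coordinates; applied
#' position-descending so coordinates stay valid).
#'
#' @param consensus consensus sequence
#' @param variants data.frame of calls ([call_variants()] columns)
#' @return edited sequence
#' @export
apply_variants <- function(consensus, variants) {
  if (nrow(variants) == 0L) return(consensus)
  v <- variants[order(-variants$position), , drop = FALSE]
  x <- consensus
  for (i in seq_len(nrow(v))) {
    p <- v$position[i]
    if (v$kind[i] == "substitution") {
      substr(x, p, p) <- v$alt[i]
    } else if (v$kind[i] == "deletion") {
      x <- paste0(substr(x, 1L, p - 1L),
                  substr(x, p + nchar(v$ref[i]), nchar(x)))
    } else {
      x <- paste0(substr(x, 1L, p), v$alt[i], substr(x, p + 1L, nchar(x)))
    }
  }
  x
}

#' @export
print.subfamily_tree <- function(x, ...) {
  cat(format_subfamily_tree(x), sep = "\n")
  invisible(x)
}

#' Indented text rendering of a subfamily tree
#' @param tree a `subfamily_tree`
#' @return character vector of lines
#' @export
format_subfamily_tree <- function(tree) {
  lines <- character(0)
  recurse <- function(ni, indent) {
    n <- tree$nodes[[ni]]
    lines <<- c(lines, paste0(strrep("  ", indent), n$name,
                              "  [", n$n_new, " diagnostics; ",
                              length(n$members), " members]"))
    kids <- which(vapply(tree$nodes, function(m)
      identical(m$parent, ni), TRUE))
    for (k in kids) recurse(k, indent + 1L)
  }
  recurse(1L, 0L)
  lines
}

#' Newick-like rendering of a subfamily tree (node names, no lengths)
#' @param tree a `subfamily_tree`
#' @return single newick-like string
#' @export
subfamily_newick <- function(tree) {
  recurse <- function(ni) {
    n <- tree$nodes[[ni]]
    kids <- which(vapply(tree$nodes, function(m)
      identical(m$parent, ni), TRUE))
    if (length(kids) == 0L) return(n$name)
    paste0("(", paste(vapply(kids, recurse, ""), collapse = ","), ")",
           n$name)
  }
  paste0(recurse(1L), ";")
}

#' Probability that shared variants arose independently
#'
#' Small-rate approximation: the chance a specific substitution j occurs in
#' a given locus within `t_myr` is `p_j = rate_j * t / 3` (capped at 1),
#' with `rate_j = beta * mu` at CpG sites and `mu` elsewhere; the
#' probability that the remaining `n_loci - 1` loci each independently
#' acquired the whole set is `(prod p_j)^(n_loci - 1)`. This one-shot
#' approximation is adequate for the threshold decision it feeds and is
#' reported as an approximation.
#'
#' @param n_loci number of loci sharing the variants (>= 1)
#' @param shared_variants data.frame with `kind` and `cpg` columns
#'   (substitution calls; indels are treated as non-CpG events)
#' @param mu,beta substitution rates
#' @param t_myr time window in Myr
#' @return probability in `[0, 1]`
#' @export
independent_acquisition_probability <- function(n_loci, shared_variants,
                                                mu, beta, t_myr) {
  stopifnot(n_loci >= 1L, t_myr > 0)
  if (n_loci == 1L || nrow(shared_variants) == 0L) return(1.0)
  rate <- ifelse(shared_variants$kind == "substitution" &
                   shared_variants$cpg %in% TRUE, beta * mu, mu)
  p <- pmin(1, rate * t_myr / 3)
  prod(p)^(n_loci - 1L)
}

#' Identify and rank source-element candidates for a subfamily
#'
#' Candidates are node members that plausibly fathered the subfamily:
#' either carrying no private variants at all, or present in a strict
#' superset of the other members' species (an older, shared insertion such
#' as a great-ape-wide founder). Qualified candidates are ranked by
#' ascending total private count, then descending hallmark score, then
#' presence-superset first, then descending allele frequency (fixation
#' sorts as 1.0), then locus id. An empty candidate list flags the node
#' "source unidentified or lost" - the subfamily's driver may not be
#' present in the assembly or was lost from the genome.
#'
#' @param node one node of a `subfamily_tree`
#' @param private_counts data.frame from [partition_diagnostic_private()]
#'   (`private_counts` element); loci absent from it carry 0 privates
#' @param hallmark_scores named numeric vector of composite scores
#' @param presence named list: locus id -> character vector of species
#'   where the insertion is present
#' @param frequencies named numeric vector of allele frequencies
#' @return list(`candidates` data.frame with per-member evidence, ranks for
#'   qualified candidates and an alternative-order annotation; `flag`
#'   "source unidentified or lost" or NA)
#' @export
identify_source_candidates <- function(node, private_counts,
                                       hallmark_scores, presence,
                                       frequencies) {
  members <- node$members
  stopifnot(length(members) >= 1L)
  pc <- function(id, col) {
    i <- match(id, private_counts$locus_id)
    if (is.na(i)) 0L else private_counts[[col]][i]
  }
  union_all <- sort(unique(unlist(presence[members])))
  df <- do.call(rbind, lapply(members, function(id) {
    others <- setdiff(members, id)
    union_others <- sort(unique(unlist(presence[others])))
    mine <- presence[[id]] %||% character(0)
    data.frame(
      locus_id = id,
      private_count_cpg = pc(id, "cpg"),
      private_count_noncpg = pc(id, "noncpg"),
      private_total = pc(id, "total"),
      hallmark_score = unname(hallmark_scores[id]),
      presence_superset = all(union_all %in% mine),
      strict_superset = all(union_others %in% mine) &&
        length(setdiff(mine, union_others)) > 0L,
      frequency = unname(frequencies[id]),
      stringsAsFactors = FALSE)
  }))
  df$qualified <- df$private_total == 0L | df$strict_superset
  df$rank <- NA_integer_
  df$alternative <- FALSE
  q <- which(df$qualified)
  if (length(q) == 0L)
    return(list(candidates = df, flag = "source unidentified or lost"))
  o <- q[order(df$private_total[q], -df$hallmark_score[q],
               -as.integer(df$presence_superset[q]), -df$frequency[q],
               df$locus_id[q])]
  df$rank[o] <- seq_along(o)
  if (length(o) >= 2L) {
    a <- o[1]; b <- o[2]
    if (df$private_total[a] == df$private_total[b] &&
        isTRUE(all.equal(df$hallmark_score[a], df$hallmark_score[b])) &&
        df$presence_superset[a] == df$presence_superset[b])
      df$alternative[c(a, b)] <- TRUE
  }
  df <- df[order(!df$qualified, df$rank, df$locus_id), ]
  rownames(df) <- NULL
  list(candidates = df, flag = NA_character_)
}
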
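# presence_dating: allele frequencies from genotype panels, single-gain
# (Dollo) placement of insertions on a dated species tree, CpG-aware
# insertion-age estimates from private-mutation counts, and offspring
# ordering with alternative-order annotation.

#' Insertion allele frequency from a genotype panel
#'
#' `(2 * n(+/+) + n(+/-)) / (2 * n(non-NA))`, reported to 4 decimals
#' (half away from zero). Insertion genotypes are biallelic
#' presence/absence calls.
#'
#' @param genotypes character vector of genotypes for one locus
#'   (`+/+`, `+/-`, `-/-`, `NA`)
#' @return allele frequency
#' @export
allele_frequency <- function(genotypes) {
  bad <- setdiff(unique(genotypes), GENOTYPE_ALPHABET)
  if (length(bad) > 0)
    stop("invalid genotype symbol: ", bad[1], call. = FALSE)
  g <- genotypes[genotypes != "NA" & !is.na(genotypes)]
  if (length(g) == 0L) stop("all genotypes are NA", call. = FALSE)
  round_half_up((2 * sum(g == "+/+") + sum(g == "+/-")) / (2 * length(g)), 4)
}

#' Place an insertion on the species tree under single-gain logic
#'
#' Retrotransposon insertions are essentially homoplasy-free: one gain, no
#' precise excision. The gain is assigned to the branch immediately
#' ancestral to the MRCA of the species carrying the insertion; `min_age`
#' is that MRCA's age (the insertion is at least that old). A species
#' marked absent inside the presence clade raises `conflict` (unknown
#' states are ignored for the clade test).
#'
#' @param tree dated tree from [read_tree()]
#' @param pattern named character vector: species -> `present`/`absent`/
#'   `unknown` (symbols `+`, `-`, `?` also accepted)
#' @return list: `gain_node`, `gain_branch` label, `min_age_myr`,
#'   `max_age_myr` (age of the node above the gain branch; NA at the
#'   root), `conflict`, `exceptions` (absent species inside the clade)
#' @export
place_insertion <- function(tree, pattern) {
  map <- c("present" = "present", "absent" = "absent",
           "unknown" = "unknown", "+" = "present", "-" = "absent",
           "?" = "unknown")
  state <- map[as.character(pattern)]
  if (anyNA(state))
    stop("unknown presence symbol in pattern", call. = FALSE)
  names(state) <- names(pattern)
  present <- names(state)[state == "present"]
  if (length(present) == 0L)
    stop("pattern has no present species", call. = FALSE)
  missing <- setdiff(names(state), tree$tip.label)
  if (length(missing) > 0)
    stop("species not in tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  ages <- attr(tree, "node_ages")
  n_tip <- length(tree$tip.label)
  if (length(present) == 1L) {
    node <- match(present, tree$tip.label)
    clade_tips <- present
  } else {
    node <- ape::getMRCA(tree, present)
    clade_tips <- ape::extract.clade(tree, node)$tip.label
  }
  inside <- intersect(clade_tips, names(state))
  exceptions <- inside[state[inside] == "absent"]
  parent <- tree$edge[tree$edge[, 2] == node, 1]
  list(gain_node = node,
       gain_branch = paste0("above_",
                            if (node <= n_tip) tree$tip.label[node]
                            else paste0("mrca(", paste(sort(clade_tips),
                                                       collapse = ","), ")")),
       min_age_myr = unname(ages[as.character(node)]),
       max_age_myr = if (length(parent) == 1L)
         unname(ages[as.character(parent)]) else NA_real_,
       conflict = length(exceptions) > 0L,
       exceptions = exceptions)
}

#' Count CpG and non-CpG sites of a consensus
#' @param consensus consensus sequence
#' @return list(L_cpg, L_noncpg)
#' @export
consensus_composition <- function(consensus) {
  cpg <- sum(.cpg_status(seq_chars(consensus)))
  list(L_cpg = cpg, L_noncpg = nchar(consensus) - cpg)
}

#' Estimate insertion age from private-mutation counts
#'
#' Private (non-diagnostic, post-insertion) substitutions accumulate at
#' rate `R = (L_noncpg + beta * L_cpg) * mu` per Myr, so `t_hat = k / R`
#' with `k = k_cpg + k_noncpg`. The 95% CI uses exact Poisson (Garwood)
#' bounds on k - counts are small (0-5), so a normal approximation would
#' be poor; with k = 0 the upper bound is 3.6889/R.
#'
#' @param k_cpg,k_noncpg private substitution counts at CpG / non-CpG
#'   consensus sites
#' @param L_cpg,L_noncpg consensus site counts by class
#' @param mu,beta substitution rates
#' @return list(t_hat_myr, ci_low, ci_high, rate_per_myr)
#' @export
estimate_insertion_time <- function(k_cpg, k_noncpg, L_cpg, L_noncpg,
                                    mu, beta) {
  stopifnot(L_cpg + L_noncpg > 0, mu > 0, beta >= 1,
            k_cpg >= 0, k_noncpg >= 0)
  R <- (L_noncpg + beta * L_cpg) * mu
  k <- k_cpg + k_noncpg
  list(t_hat_myr = k / R,
       ci_low = if (k == 0) 0 else stats::qgamma(0.025, k) / R,
       ci_high = stats::qgamma(0.975, k + 1) / R,
       rate_per_myr = R)
}

#' Order offspring loci by estimated insertion age
#'
#' Primary sort: `t_hat` descending (oldest first); secondary: allele
#' frequency descending (fixation sorts as 1.0); tertiary: locus id for
#' determinism. Consecutive loci whose 95% CIs overlap and whose
#' frequencies differ by less than 0.1 are annotated as alternative
#' orders, mirroring the uncertainty of which insertion came first.
#'
#' @param ages data.frame with columns locus_id, t_hat_myr, ci_low,
#'   ci_high, frequency
#' @return the same data.frame ordered, with `order_rank` and
#'   `alternatives` (semicolon-joined locus ids) columns
#' @export
order_offspring <- function(ages) {
  stopifnot(nrow(ages) >= 1L)
  o <- order(-ages$t_hat_myr, -ages$frequency, ages$locus_id)
  out <- ages[o, , drop = FALSE]
  out$order_rank <- seq_len(nrow(out))
  out$alternatives <- ""
  if (nrow(out) >= 2L) {
    for (i in seq_len(nrow(out) - 1L)) {
      j <- i + 1L
      overlap <- out$ci_low[i] <= out$ci_high[j] &&
        out$ci_low[j] <= out$ci_high[i]
      close_freq <- abs(out$frequency[i] - out$frequency[j]) < 0.1
      if (overlap && close_freq) {
        out$alternatives[i] <- paste(c(
          strsplit(out$alternatives[i], ";")[[1]], out$locus_id[j]),
          collapse = ";")
        out$alternatives[j] <- paste(c(
          strsplit(out$alternatives[j], ";")[[1]], out$locus_id[i]),
          collapse = ";")
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Species-distribution percentages of a subfamily census
#'
#' Converts per-distribution locus counts (e.g. shared-with-siamang versus
#' great-ape-specific) into whole-number percentages of the census total.
#'
#' @param counts named integer vector or data.frame with `distribution`
#'   and `count` columns
#' @return data.frame: distribution, count, percent (rounded to integers,
#'   half away from zero)
#' @export
summarize_species_distribution <- function(counts) {
  if (is.data.frame(counts)) {
    df <- data.frame(distribution = counts$distribution,
                     count = counts$count, stringsAsFactors = FALSE)
  } else {
    df <- data.frame(distribution = names(counts),
                     count = as.integer(counts), stringsAsFactors = FALSE)
  }
  df$percent <- round_half_up(100 * df$count / sum(df$count), 0)
  df
}

#' Fixed/polymorphic partition of loci by allele frequency
#'
#' @param frequencies named numeric vector of allele frequencies
#' @return data.frame: locus_id, frequency, status
#'   (`fixed` at 1, `polymorphic` in (0,1), `absent` at 0)
#' @export
classify_fixation <- function(frequencies) {
  status <- ifelse(frequencies >= 1, "fixed",
                   ifelse(frequencies > 0, "polymorphic", "absent"))
  data.frame(locus_id = names(frequencies),
             frequency = unname(frequencies), status = unname(status),
             stringsAsFactors = FALSE)
}
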
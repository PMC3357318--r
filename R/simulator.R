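# simulator: stealth-driver amplification generator. One long-lived source
# element accumulates CpG-biased neutral substitutions, episodically copies
# itself (TSD + poly(A) generated at insertion), daughters may activate as
# secondary sources, offspring allele frequencies drift under Wright-Fisher
# sampling, and presence/absence follows the insertion branch on a dated
# great-ape tree. Output is truth-tagged so inference can be scored.

#' AluY-like master consensus (synthetic fixture)
#'
#' A 281-nt dimeric Alu-type consensus: left monomer carrying the internal
#' RNA Pol III A- and B-box promoter motifs, a middle A-rich linker, and a
#' right monomer, without a poly(A) tail (tails are generated per
#' insertion). Used as the default master sequence and ancestral consensus.
#'
#' @return nucleotide string
#' @export
alu_master_consensus <- function() {
  paste0(
    "GGCCGGGCGCGGTGGCTCACGCCTGTAATCCCAGCACTTTGGGAGGCCGAGGCGGGCGGATCACGAGG",
    "TCAGGAGATCGAGACCATCCCGGCTAAAACGGTGAAACCCCGTCTCTACTAAAAATACAAAAAATTAG",
    "CCGGGCGTGGTGGCGGGCGCCTGTAGTCCCAGCTACTCGGGAGGCTGAGGCAGGAGAATGGCGTGAAC",
    "CCGGGAGGCGGAGCTTGCAGTGAGCCGAGATCGCGCCACTGCACTCCAGCCTGGGCGACAGAGCGAGA",
    "CTCCGTCTC")
}

DEFAULT_TREE_NEWICK <-
  "((((human:6,chimp:6):3,gorilla:9):7,orangutan:16):4,gibbon:20);"

#' Simulation configuration
#'
#' Defaults encode the study conditions: a single founder ("master") element
#' evolving for `total_myr` = 16 Myr on a dated great-ape tree, non-CpG
#' substitution rate `mu` = 0.0015/site/Myr with CpG sites `beta` = 8x
#' faster, `lambda_per_myr` retained insertions per Myr per active element,
#' and a 15% chance that each new copy activates as a secondary source.
#' `lambda_per_myr` counts insertions that are retained (visible in an
#' assembly); present-day frequencies are drawn by Wright-Fisher drift
#' conditioned on non-loss, and the implied number of drift-lost insertions
#' is reported in the run log.
#'
#' @param master_seq master element body (default [alu_master_consensus()])
#' @param mu non-CpG substitution rate, subs/site/Myr
#' @param beta CpG rate multiplier (>= 1)
#' @param lambda_per_myr retained insertions per Myr per active element
#' @param Ne effective population size (diploid)
#' @param gen_years generation time in years
#' @param total_myr simulated depth in Myr
#' @param tsd_len integer range (length 2) of target-site-duplication lengths
#' @param polyA_init integer range of initial poly(A) tail lengths
#' @param p_daughter_activation probability a new copy becomes an active
#'   secondary source
#' @param panel_size diploid genotyping panel size
#' @param scaffold_len background scaffold length (nt)
#' @param focal_species tree leaf whose genome is simulated
#' @param tree_newick dated species tree (branch lengths in Myr)
#' @param sample_frequencies draw allele frequencies by drift (disable for
#'   copy-count-only studies)
#' @param seed integer RNG seed
#' @return validated `simulation_config` list
#' @export
simulation_config <- function(master_seq = alu_master_consensus(),
                              mu = 0.0015, beta = 8, lambda_per_myr = 2,
                              Ne = 1000, gen_years = 20, total_myr = 16,
                              tsd_len = c(8L, 16L), polyA_init = c(20L, 40L),
                              p_daughter_activation = 0.15,
                              panel_size = 37L, scaffold_len = 50000L,
                              focal_species = "orangutan",
                              tree_newick = DEFAULT_TREE_NEWICK,
                              sample_frequencies = TRUE, seed = 1L) {
  assert_dna(master_seq, "master_seq", allow_n = FALSE)
  stopifnot(mu > 0, beta >= 1, lambda_per_myr > 0, Ne >= 2, gen_years > 0,
            total_myr > 0, length(tsd_len) == 2L, tsd_len[1] <= tsd_len[2],
            length(polyA_init) == 2L, polyA_init[1] <= polyA_init[2],
            p_daughter_activation >= 0, p_daughter_activation <= 1,
            panel_size >= 1, scaffold_len > nchar(master_seq) + 2 * tsd_len[2])
  cfg <- list(master_seq = master_seq, mu = mu, beta = beta,
              lambda_per_myr = lambda_per_myr, Ne = Ne,
              gen_years = gen_years, total_myr = total_myr,
              tsd_len = as.integer(tsd_len), polyA_init = as.integer(polyA_init),
              p_daughter_activation = p_daughter_activation,
              panel_size = as.integer(panel_size),
              scaffold_len = as.integer(scaffold_len),
              focal_species = focal_species, tree_newick = tree_newick,
              sample_frequencies = isTRUE(sample_frequencies),
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

#' Calibrate the insertion rate to a target lineage yield
#'
#' With activation probability `p`, each active element inserts at rate
#' lambda and daughters activate recursively, so the expected total yield of
#' one founder over `t` Myr is `m(t) = (exp(p*lambda*t) - 1)/p`. This
#' inverts that relation: the lambda for which the lineage yields
#' `target_per_myr * t` copies.
#'
#' @param target_per_myr target retained insertions per Myr for the lineage
#' @param p_activation daughter activation probability
#' @param t_myr time horizon in Myr
#' @return lambda (insertions per Myr per active element)
#' @export
calibrate_lambda <- function(target_per_myr, p_activation, t_myr) {
  stopifnot(target_per_myr > 0, t_myr > 0,
            p_activation >= 0, p_activation <= 1)
  if (p_activation == 0) return(target_per_myr)
  log(1 + p_activation * target_per_myr * t_myr) / (p_activation * t_myr)
}

# CpG indicator for a character vector sequence.
.cpg_status <- function(x) {
  L <- length(x)
  cg <- x == "C" & c(x[-1], "") == "G"
  gc <- x == "G" & c("", x[-L]) == "C"
  cg | gc
}

#' Mutate a sequence under a CpG-aware neutral clock
#'
#' Event-based (Gillespie over sites) substitution process: each site
#' mutates at rate `mu`, or `beta * mu` while it sits inside a CG
#' dinucleotide; the substituted base is drawn uniformly from the three
#' alternatives and CpG status is re-evaluated after every event (a
#' destroyed CG stops being fast). Event-based simulation is used instead
#' of a matrix exponential because the CpG context changes with the
#' sequence itself.
#'
#' @param seq sequence over ACGT
#' @param t_myr elapsed time in Myr (>= 0)
#' @param mu non-CpG substitution rate per site per Myr
#' @param beta CpG multiplier
#' @param record if TRUE, also return the event list
#' @return mutated sequence, or (with `record`) a list with `seq` and an
#'   `events` data.frame (t_rel, position, from, to)
#' @export
mutate_sequence <- function(seq, t_myr, mu, beta, record = FALSE) {
  if (t_myr < 0) stop("t_myr must be >= 0", call. = FALSE)
  assert_dna(seq, "seq", allow_n = FALSE)
  x <- seq_chars(seq)
  L <- length(x)
  is_cpg <- .cpg_status(x)
  rates <- mu * ifelse(is_cpg, beta, 1)
  total <- sum(rates)
  t_cur <- 0
  ev_t <- numeric(0); ev_pos <- integer(0); ev_from <- character(0); ev_to <- character(0)
  repeat {
    if (total <= 0) break
    t_cur <- t_cur + stats::rexp(1, total)
    if (t_cur > t_myr) break
    site <- sample.int(L, 1L, prob = rates)
    from <- x[site]
    to <- sample(setdiff(DNA_BASES, from), 1L)
    x[site] <- to
    # CpG context changes only locally
    lo <- max(1L, site - 1L); hi <- min(L, site + 1L)
    upd <- lo:hi
    new_cpg <- .cpg_status(x)[upd]
    total <- total - sum(rates[upd])
    rates[upd] <- mu * ifelse(new_cpg, beta, 1)
    total <- total + sum(rates[upd])
    if (record) {
      ev_t <- c(ev_t, t_cur); ev_pos <- c(ev_pos, site)
      ev_from <- c(ev_from, from); ev_to <- c(ev_to, to)
    }
  }
  out <- chars_seq(x)
  if (!record) return(out)
  list(seq = out,
       events = data.frame(t_rel = ev_t, position = ev_pos,
                           from = ev_from, to = ev_to,
                           stringsAsFactors = FALSE))
}

#' Insert an element copy into a scaffold
#'
#' The insertion site prefers an exact TTAAAA endonuclease-nick motif when
#' one occurs within a sampled window (else the sampled position is used
#' as-is). A target-site duplication of sampled length is duplicated on
#' both sides of the new copy and a poly(A) tail of sampled length is
#' appended; the element body is the source's current sequence (snapshot
#' semantics). No mutations occur in this step.
#'
#' @param source_seq source element body at copy time
#' @param scaffold host sequence to insert into
#' @param config a [simulation_config()] (ranges for TSD and tail lengths)
#' @param prefer_motif prefer a TTAAAA site within the window
#' @param window_len motif search window around the sampled position
#' @return list: `locus` (start, end 0-based half-open, strand "+", tsd,
#'   polyA_len, element_seq) and the updated `scaffold`
#' @export
generate_insertion <- function(source_seq, scaffold,
                               config = simulation_config(),
                               prefer_motif = TRUE, window_len = 200L) {
  tsd <- sample(config$tsd_len[1]:config$tsd_len[2], 1L)
  Ls <- nchar(scaffold)
  margin <- tsd + 10L
  if (Ls < nchar(source_seq) + 2L * margin)
    stop("scaffold too short for insertion", call. = FALSE)
  p <- sample(margin:(Ls - margin), 1L)
  if (prefer_motif) {
    w_start <- max(1L, p - window_len %/% 2L)
    w_end <- min(Ls - margin, p + window_len %/% 2L)
    m <- regexpr("TTAAAA", substr(scaffold, w_start, w_end), fixed = TRUE)
    if (m > 0) p <- max(margin, w_start + as.integer(m) + 1L)  # nick after TT
  }
  polyA_len <- sample(config$polyA_init[1]:config$polyA_init[2], 1L)
  tsd_seq <- substr(scaffold, p + 1L, p + tsd)
  element <- paste0(source_seq, strrep("A", polyA_len))
  new_scaffold <- paste0(substr(scaffold, 1L, p + tsd), element,
                         substr(scaffold, p + 1L, Ls))
  start0 <- p + tsd
  locus <- list(start = start0, end = start0 + nchar(element), strand = "+",
                tsd = tsd_seq, polyA_len = polyA_len, element_seq = element)
  list(locus = locus, scaffold = new_scaffold)
}

#' Wright-Fisher drift endpoint for a new insertion
#'
#' Forward binomial sampling from one copy among 2*Ne chromosomes for
#' `insertion_time_myr * 1e6 / gen_years` generations. Runs longer than
#' 1e5 generations are rescaled (generations capped at 1e5 with Ne shrunk
#' proportionally, preserving drift time t/2Ne). Loss (frequency 0) is a
#' legal outcome; both absorbing states stop the walk.
#'
#' @param insertion_time_myr age of the insertion in Myr
#' @param Ne diploid effective population size (>= 2)
#' @param gen_years generation time in years
#' @param max_gen generation cap before rescaling
#' @return final allele frequency in `[0, 1]`
#' @export
drift_frequency <- function(insertion_time_myr, Ne, gen_years,
                            max_gen = 1e5) {
  stopifnot(Ne >= 2, insertion_time_myr >= 0, gen_years > 0)
  G <- round(insertion_time_myr * 1e6 / gen_years)
  if (G > max_gen) {
    Ne <- max(2, round(Ne * max_gen / G))
    G <- max_gen
  }
  n_chrom <- 2L * as.integer(Ne)
  count <- 1L
  g <- 0L
  while (g < G && count > 0L && count < n_chrom) {
    count <- stats::rbinom(1L, n_chrom, count / n_chrom)
    g <- g + 1L
  }
  count / n_chrom
}

# Present-day frequency conditional on non-loss (retained insertions).
# The walk runs at a reduced population size N_star with diffusion-time
# rescaling (generations = tau * 2*N_star where tau = G/(2Ne), capped at
# tau_max, by which point absorption is essentially certain), making
# rejection sampling over the ~2*N_star-fold loss rate affordable while
# preserving the shape of the conditional frequency distribution.
# Returns the frequency and the number of rejected (lost) trajectories.
.drift_conditional <- function(t_myr, Ne, gen_years, N_star = 50L,
                               tau_max = 20) {
  G_true <- t_myr * 1e6 / gen_years
  tau <- min(G_true / (2 * Ne), tau_max)
  G <- max(1L, as.integer(round(tau * 2 * N_star)))
  n_chrom <- 2L * N_star
  lost <- 0L
  repeat {
    count <- 1L
    g <- 0L
    while (g < G && count > 0L && count < n_chrom) {
      count <- stats::rbinom(1L, n_chrom, count / n_chrom)
      g <- g + 1L
    }
    if (count > 0L) return(list(freq = count / n_chrom, lost = lost))
    lost <- lost + 1L
  }
}
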
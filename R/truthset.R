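# simulate_amplification and the TruthSet container: loci planted in a
# background scaffold plus the hidden truth (parents, insertion times,
# frequencies, per-site event log) needed to score inference.

# Root-to-focal-leaf path of a dated tree, as node indices with ages.
.focal_path <- function(tree, focal) {
  leaf <- match(focal, tree$tip.label)
  if (is.na(leaf)) stop("focal species not in tree: ", focal, call. = FALSE)
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  path <- leaf
  node <- leaf
  root <- length(tree$tip.label) + 1L
  while (node != root) {
    node <- parent[node]
    path <- c(path, node)
  }
  ages <- attr(tree, "node_ages")
  data.frame(node = path, age = unname(ages[as.character(path)]))
}

# Species presence set and branch label for an insertion at time t (Myr
# before present) on the focal lineage: the insertion sits on the branch
# above the deepest path node no older than t, and is present in all
# species descending from that node.
.placement_at_time <- function(tree, path, t) {
  child <- path$node[max(which(path$age <= t + 1e-9))]
  n_tip <- length(tree$tip.label)
  if (child <= n_tip) {
    tips <- tree$tip.label[child]
    label <- paste0(tips, "_terminal")
  } else {
    tips <- ape::extract.clade(tree, child)$tip.label
    label <- paste0("stem_", paste(sort(tips), collapse = "+"))
  }
  list(species = tips, branch = label)
}

# Advance one simulated element (body + tail) from its t_last down to
# t_new, recording substitution events with absolute times.
.advance_element <- function(el, t_new, mu, beta, counter_env) {
  dt <- el$t_last - t_new
  if (dt <= 0) return(el)
  Lb <- nchar(el$body)
  res <- mutate_sequence(paste0(el$body, el$tail), dt, mu, beta, record = TRUE)
  el$body <- substr(res$seq, 1L, Lb)
  el$tail <- substr(res$seq, Lb + 1L, nchar(res$seq))
  ev <- res$events
  if (nrow(ev) > 0) {
    ids <- counter_env$event_id + seq_len(nrow(ev))
    counter_env$event_id <- counter_env$event_id + nrow(ev)
    el$events <- rbind(el$events, data.frame(
      event_id = ids,
      t_myr = el$t_last - ev$t_rel,
      position = ifelse(ev$position <= Lb, ev$position, ev$position - Lb),
      from = ev$from, to = ev$to,
      region = ifelse(ev$position <= Lb, "body", "tail"),
      origin = el$id, stringsAsFactors = FALSE))
  }
  el$t_last <- t_new
  el
}

#' Simulate a stealth-driver Alu amplification
#'
#' A master element is planted on the focal lineage `total_myr` Myr ago and
#' evolves under the CpG-aware neutral clock of [mutate_sequence()]. Active
#' elements spawn retained copies as Poisson events at `lambda_per_myr`
#' each; every copy snapshots its source's current body, receives a fresh
#' poly(A) tail and target-site duplication at insertion, and activates as
#' a secondary source with probability `p_daughter_activation`. Presence
#' across species follows the insertion branch; present-day allele
#' frequencies are drawn by Wright-Fisher drift conditioned on retention
#' (rejected, drift-lost trajectories are counted in the log).
#'
#' @param config a [simulation_config()]
#' @return a `truth_set`: list with `loci` (locus table with sequences and
#'   flanks), `genotypes`, `presence` (locus x species matrix), `truth`
#'   (parent, insertion time and branch, frequency, active flag), `events`
#'   (per-site substitution log with inheritance), `genome`, `tree_newick`,
#'   `config` and `log`
#' @export
simulate_amplification <- function(config = simulation_config()) {
  set.seed(config$seed)
  tree <- read_tree(config$tree_newick)
  path <- .focal_path(tree, config$focal_species)
  if (max(path$age) < config$total_myr)
    stop("tree root (", max(path$age), " Myr) is younger than total_myr",
         call. = FALSE)
  mu <- config$mu; beta <- config$beta
  cnt <- new.env()
  cnt$event_id <- 0L
  new_tail <- function()
    strrep("A", sample(config$polyA_init[1]:config$polyA_init[2], 1L))
  empty_events <- data.frame(event_id = integer(0), t_myr = numeric(0),
                             position = integer(0), from = character(0),
                             to = character(0), region = character(0),
                             origin = character(0), stringsAsFactors = FALSE)
  els <- list(MASTER = list(id = "MASTER", body = config$master_seq,
                            tail = new_tail(), t_birth = config$total_myr,
                            t_last = config$total_myr, active = TRUE,
                            parent = NA_character_, events = empty_events))
  active <- "MASTER"
  t_now <- config$total_myr
  n_copy <- 0L
  repeat {
    rate <- config$lambda_per_myr * length(active)
    t_next <- t_now - stats::rexp(1, rate)
    if (t_next <= 0) break
    src_id <- active[sample.int(length(active), 1L)]
    els[[src_id]] <- .advance_element(els[[src_id]], t_next, mu, beta, cnt)
    n_copy <- n_copy + 1L
    id <- sprintf("L%03d", n_copy)
    child <- list(id = id, body = els[[src_id]]$body, tail = new_tail(),
                  t_birth = t_next, t_last = t_next,
                  active = stats::runif(1) < config$p_daughter_activation,
                  parent = src_id,
                  events = els[[src_id]]$events[
                    els[[src_id]]$events$region == "body", , drop = FALSE])
    els[[id]] <- child
    if (child$active) active <- c(active, id)
    t_now <- t_next
  }
  for (id in names(els))
    els[[id]] <- .advance_element(els[[id]], 0, mu, beta, cnt)

  # ---- plant present-day sequences into a random scaffold ----
  scaffold <- chars_seq(sample(DNA_BASES, config$scaffold_len, replace = TRUE))
  order_ids <- names(els)[order(-vapply(els, `[[`, 0, "t_birth"))]
  placed <- data.frame(locus_id = character(0), start = integer(0),
                       end = integer(0), strand = character(0),
                       tsd = character(0), stringsAsFactors = FALSE)
  for (id in order_ids) {
    el <- els[[id]]
    element <- paste0(el$body, el$tail)
    tsd_n <- sample(config$tsd_len[1]:config$tsd_len[2], 1L)
    strand <- sample(c("+", "-"), 1L)
    Ls <- nchar(scaffold)
    margin <- tsd_n + 10L
    ok <- FALSE
    for (try in 1:200) {
      p <- sample(margin:(Ls - margin), 1L)
      w_start <- max(1L, p - 100L)
      m <- regexpr("TTAAAA", substr(scaffold, w_start, min(Ls - margin, p + 100L)),
                   fixed = TRUE)
      if (m > 0) p <- max(margin, w_start + as.integer(m) + 1L)
      clash <- any(placed$start - 2L < p + tsd_n + 2L & placed$end + 2L > p - 2L)
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place locus ", id, "; scaffold too crowded",
                  call. = FALSE)
    planted <- if (strand == "+") element else revcomp(element)
    scaffold <- paste0(substr(scaffold, 1L, p + tsd_n), planted,
                       substr(scaffold, p + 1L, Ls))
    ins_len <- nchar(element) + tsd_n
    shift <- placed$start >= p
    placed$start[shift] <- placed$start[shift] + ins_len
    placed$end[shift] <- placed$end[shift] + ins_len
    placed <- rbind(placed, data.frame(
      locus_id = id, start = p + tsd_n, end = p + tsd_n + nchar(element),
      strand = strand, tsd = substr(scaffold, p + 1L, p + tsd_n),
      stringsAsFactors = FALSE))
  }
  genome <- c(chr1 = scaffold)

  # ---- frequencies, genotypes, presence, truth ----
  n_lost <- 0L
  loci_rows <- list(); truth_rows <- list(); geno_rows <- list()
  presence <- matrix("-", nrow = length(els), ncol = length(tree$tip.label),
                     dimnames = list(names(els), tree$tip.label))
  samples <- sprintf("ind%02d", seq_len(config$panel_size))
  for (id in names(els)) {
    el <- els[[id]]
    pl <- placement_row <- .placement_at_time(tree, path, el$t_birth)
    presence[id, pl$species] <- "+"
    if (config$sample_frequencies) {
      dr <- .drift_conditional(el$t_birth, config$Ne, config$gen_years)
      freq <- dr$freq
      n_lost <- n_lost + dr$lost
    } else freq <- NA_real_
    fixed <- isTRUE(freq == 1)
    row <- placed[placed$locus_id == id, ]
    loci_rows[[id]] <- data.frame(
      locus_id = id, species = config$focal_species, chrom = "chr1",
      start = row$start, end = row$end, strand = row$strand,
      element_seq = paste0(el$body, el$tail),
      left_flank = NA_character_, right_flank = NA_character_,
      fixed = fixed, stringsAsFactors = FALSE)
    truth_rows[[id]] <- data.frame(
      locus_id = id, parent_id = el$parent %||% NA_character_,
      insertion_time_myr = el$t_birth, insertion_branch = pl$branch,
      final_allele_frequency = freq, is_active_source = el$active,
      stringsAsFactors = FALSE)
    if (config$sample_frequencies) {
      g <- if (fixed) rep("+/+", config$panel_size)
           else sample(c("+/+", "+/-", "-/-"), config$panel_size,
                       replace = TRUE,
                       prob = c(freq^2, 2 * freq * (1 - freq), (1 - freq)^2))
      geno_rows[[id]] <- data.frame(sample_id = samples, locus_id = id,
                                    genotype = g, stringsAsFactors = FALSE)
    }
  }
  loci <- do.call(rbind, loci_rows)
  rownames(loci) <- NULL
  for (i in seq_len(nrow(loci))) {
    fl <- extract_locus(genome, loci$start[i], loci$end[i], loci$strand[i])
    loci$left_flank[i] <- fl$left_flank
    loci$right_flank[i] <- fl$right_flank
  }
  events <- do.call(rbind, c(list(empty_events), lapply(names(els), function(id) {
    ev <- els[[id]]$events
    if (nrow(ev) == 0) return(NULL)
    cbind(locus_id = id, ev, inherited = ev$origin != id)
  })))
  if (is.null(events$locus_id))
    events <- cbind(locus_id = character(0), empty_events,
                    inherited = logical(0))
  ts <- list(loci = loci,
             genotypes = if (length(geno_rows)) do.call(rbind, geno_rows)
                         else NULL,
             presence = presence,
             truth = do.call(rbind, truth_rows),
             events = events,
             genome = genome,
             tree_newick = config$tree_newick,
             config = config,
             log = list(seed = config$seed, n_lost_drift = n_lost,
                        n_copies = n_copy))
  rownames(ts$truth) <- NULL
  if (!is.null(ts$genotypes)) rownames(ts$genotypes) <- NULL
  rownames(ts$events) <- NULL
  class(ts) <- "truth_set"
  ts
}

#' @export
print.truth_set <- function(x, ...) {
  cat("TruthSet:", nrow(x$loci), "loci (",
      sum(x$truth$is_active_source), "active sources ) over",
      x$config$total_myr, "Myr; seed", x$log$seed, "\n")
  invisible(x)
}

#' Standard study conditions for recovery experiments
#'
#' A 16-Myr stealth scenario sized to roughly 40 surviving copies: the
#' insertion rate is derived with [calibrate_lambda()] so that one founder
#' with 15% daughter activation yields about 40 retained insertions over
#' 16 Myr.
#'
#' @param seed integer RNG seed
#' @param n_target expected total retained copies
#' @param ... overrides passed to [simulation_config()]
#' @return a `simulation_config`
#' @export
study_config <- function(seed = 1L, n_target = 40, ...) {
  args <- list(...)
  p <- args$p_daughter_activation %||% 0.15
  t <- args$total_myr %||% 16
  lam <- calibrate_lambda(n_target / t, p, t)
  do.call(simulation_config,
          c(list(seed = seed, lambda_per_myr = lam), args))
}

#' Write a TruthSet to a directory of plain-text files
#' @param ts a `truth_set`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_truthset <- function(ts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(ts$genome, file.path(dir, "background.fa"))
  write_locus_table(ts$loci, file.path(dir, "loci.tsv"))
  if (!is.null(ts$genotypes))
    write_genotype_table(ts$genotypes, file.path(dir, "genotypes.tsv"))
  utils::write.table(data.frame(locus_id = rownames(ts$presence),
                                ts$presence, check.names = FALSE),
                     file.path(dir, "presence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ts$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ts$events, file.path(dir, "events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(ts$tree_newick, file.path(dir, "tree.nwk"))
  cfg <- ts$config
  keys <- c("mu", "beta", "lambda_per_myr", "Ne", "gen_years", "total_myr",
            "p_daughter_activation", "panel_size", "scaffold_len",
            "focal_species", "seed")
  writeLines(c(paste0(keys, " = ", vapply(cfg[keys], as.character, "")),
               paste0("n_lost_drift = ", ts$log$n_lost_drift)),
             file.path(dir, "config.txt"))
  invisible(dir)
}

#' Read a TruthSet directory written by [write_truthset()]
#' @param dir directory path
#' @return a `truth_set` (config echoed as a plain list)
#' @export
read_truthset <- function(dir) {
  loci <- read_locus_table(file.path(dir, "loci.tsv"))
  pres <- utils::read.table(file.path(dir, "presence.tsv"), header = TRUE,
                            sep = "\t", check.names = FALSE,
                            colClasses = "character")
  presence <- as.matrix(pres[, -1, drop = FALSE])
  rownames(presence) <- pres$locus_id
  gt_path <- file.path(dir, "genotypes.tsv")
  ev <- utils::read.table(file.path(dir, "events.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  ts <- list(loci = loci,
             genotypes = if (file.exists(gt_path)) read_genotype_table(gt_path)
                         else NULL,
             presence = presence,
             truth = utils::read.table(file.path(dir, "truth.tsv"),
                                       header = TRUE, sep = "\t",
                                       stringsAsFactors = FALSE),
             events = ev,
             genome = read_fasta(file.path(dir, "background.fa")),
             tree_newick = readLines(file.path(dir, "tree.nwk"))[1],
             config = NULL, log = NULL)
  class(ts) <- "truth_set"
  ts
}

#' True diagnostic carrier sets from the simulator event log
#'
#' Groups body substitutions by event identity (inheritance-based, so later
#' overwrites do not remove a carrier) and returns the distinct carrier
#' sets with at least `k_min_share` carriers - the ground-truth nested
#' subfamily partition.
#'
#' @param ts a `truth_set`
#' @param k_min_share minimum carrier count
#' @return list of character vectors (sorted locus ids), one per true
#'   diagnostic carrier set
#' @export
truth_diagnostic_sets <- function(ts, k_min_share = 3L) {
  ev <- ts$events[ts$events$region == "body", , drop = FALSE]
  if (nrow(ev) == 0) return(list())
  carriers <- tapply(ev$locus_id, ev$event_id,
                     function(x) sort(unique(x)), simplify = FALSE)
  carriers <- carriers[vapply(carriers, length, 0L) >= k_min_share]
  unique(unname(carriers))
}
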
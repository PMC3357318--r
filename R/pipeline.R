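# Pipeline: chains scan -> classify -> infer -> hallmarks -> date -> report
# over a TruthSet directory (or user FASTA + tables) and writes the report
# files. Stages are cumulative; any stage failure aborts with the stage
# name and cause.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full inference pipeline
#'
#' Executes the requested stage prefix of scan, classify, infer,
#' hallmarks, date, report. Input is either a `truth_set` object or a
#' directory in [write_truthset()] layout (genotypes/presence optional for
#' user data). Writes, under `out_dir`: the scan hit table, per-locus
#' variant table, subfamily tree (indented text and newick-like), source
#' ranking TSV, per-locus hallmark TSV, dating TSV, and a run log echoing
#' the seed and configuration.
#'
#' @param config a [pipeline_config()]
#' @param truthset optional `truth_set` object
#' @param input_dir optional input directory (used when `truthset` is NULL)
#' @param out_dir output directory for report files
#' @param consensus ancestral consensus sequence (default
#'   [alu_master_consensus()])
#' @param stages last stage to run ("all" = report)
#' @return invisibly, a list of stage results (loci, hits, variants,
#'   partition, subfamilies, hallmarks, dating, rankings, independence)
#' @export
run_pipeline <- function(config = pipeline_config(), truthset = NULL,
                         input_dir = NULL, out_dir,
                         consensus = alu_master_consensus(),
                         stages = "all") {
  validate_config(config)
  all_stages <- c("scan", "classify", "infer", "hallmarks", "date", "report")
  last <- if (identical(stages, "all")) "report" else match.arg(stages, all_stages)
  todo <- all_stages[seq_len(match(last, all_stages))]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(derive_seed(config$seed, "pipeline"))

  if (is.null(truthset) && !is.null(input_dir))
    truthset <- .stage("input", .read_inputs(input_dir))
  if (is.null(truthset)) stop("either truthset or input_dir is required",
                              call. = FALSE)
  loci <- truthset$loci
  res <- list(loci = loci)
  log_lines <- c(paste0("alusleuth run ", format(Sys.time(), "%Y-%m-%d")),
                 paste0("seed = ", config$seed),
                 paste0(names(unclass(config)), " = ",
                        vapply(unclass(config), function(x)
                          paste(as.character(x), collapse = ","), "")))

  if (is.null(loci) || nrow(loci) == 0L) {
    writeLines(c(log_lines, "no loci: nothing to analyse"),
               file.path(out_dir, "run.log"))
    writeLines("no loci", file.path(out_dir, "report.txt"))
    return(invisible(res))
  }

  if ("scan" %in% todo && !is.null(truthset$genome)) {
    res$hits <- .stage("scan", scan_genome(
      truthset$genome, consensus, min_identity = config$min_identity,
      min_len = config$min_len))
    write_locus_table(res$hits, file.path(out_dir, "hits.tsv"))
    log_lines <- c(log_lines, paste0("scan: ", nrow(res$hits), " hits"))
  }

  if ("classify" %in% todo) {
    res <- .stage("classify", {
      elements <- stats::setNames(loci$element_seq, loci$locus_id)
      variants <- call_variants_set(elements, consensus)
      part <- partition_diagnostic_private(variants, config$k_min_share)
      idy <- vapply(loci$locus_id, function(id) {
        body <- trim_tail(elements[[id]])
        percent_identity(global_align(body, consensus))
      }, 0)
      c(res, list(variants = part$variants, partition = part,
                  identity = stats::setNames(idy, loci$locus_id)))
    })
    utils::write.table(res$variants, file.path(out_dir, "variants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("infer" %in% todo) {
    res$subfamilies <- .stage("infer", infer_subfamilies(
      res$partition, loci$locus_id, consensus,
      lineage_tag = config$lineage_tag,
      ancestral_name = config$ancestral_name))
    writeLines(format_subfamily_tree(res$subfamilies),
               file.path(out_dir, "subfamily_tree.txt"))
    writeLines(subfamily_newick(res$subfamilies),
               file.path(out_dir, "subfamily_tree.nwk"))
    for (w in res$subfamilies$warnings) log_lines <- c(log_lines,
                                                       paste0("warning: ", w))
  }

  if ("hallmarks" %in% todo) {
    res$hallmarks <- .stage("hallmarks", {
      node_of <- .node_of_locus(res$subfamilies)
      rows <- lapply(seq_len(nrow(loci)), function(i) {
        id <- loci$locus_id[i]
        cons_i <- res$subfamilies$nodes[[node_of[[id]]]]$consensus
        hr <- hallmark_report(loci$element_seq[i], loci$left_flank[i],
                              loci$right_flank[i], cons_i,
                              tsd_min_len = config$tsd_min_len,
                              tsd_max_mismatch = config$tsd_max_mismatch)
        data.frame(locus_id = id,
                   left_monomer_mutation_count = hr$left_monomer_mutation_count,
                   a_box_intact = hr$a_box_intact,
                   b_box_intact = hr$b_box_intact,
                   polyA_length = hr$polyA_length,
                   polyA_tolerated_count = hr$polyA_tolerated_count,
                   polyA_severe_count = hr$polyA_severe_count,
                   terminator_distance = hr$terminator_distance,
                   upstream_motif = if (is.null(hr$upstream_motif)) "none"
                                    else hr$upstream_motif$motif,
                   tsd_length = if (is.null(hr$tsd)) 0L else hr$tsd$length,
                   tsd_mismatches = if (is.null(hr$tsd)) NA_integer_
                                    else hr$tsd$mismatches,
                   composite_score = hr$composite_score,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
    utils::write.table(res$hallmarks, file.path(out_dir, "hallmarks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("date" %in% todo) {
    res <- .stage("date", {
      comp <- consensus_composition(consensus)
      freqs <- .locus_frequencies(truthset, loci)
      pc <- res$partition$private_counts
      ages <- do.call(rbind, lapply(loci$locus_id, function(id) {
        i <- match(id, pc$locus_id)
        kc <- if (is.na(i)) 0L else pc$cpg[i]
        kn <- if (is.na(i)) 0L else pc$noncpg[i]
        est <- estimate_insertion_time(kc, kn, comp$L_cpg, comp$L_noncpg,
                                       config$mu, config$beta)
        data.frame(locus_id = id, k_cpg = kc, k_noncpg = kn,
                   t_hat_myr = est$t_hat_myr, ci_low = est$ci_low,
                   ci_high = est$ci_high,
                   frequency = freqs[id] %||% NA_real_,
                   stringsAsFactors = FALSE)
      }))
      ages$frequency[is.na(ages$frequency)] <- 0
      dating <- order_offspring(ages)
      if (!is.null(truthset$presence)) {
        tree <- read_tree(truthset$tree_newick)
        pl <- lapply(loci$locus_id, function(id) {
          place_insertion(tree, truthset$presence[id, ])
        })
        dating$min_age_myr <-
          vapply(pl, `[[`, 0, "min_age_myr")[match(dating$locus_id,
                                                   loci$locus_id)]
        dating$placement_conflict <-
          vapply(pl, `[[`, TRUE, "conflict")[match(dating$locus_id,
                                                   loci$locus_id)]
        res$placements <- stats::setNames(pl, loci$locus_id)
      }
      c(res, list(dating = dating, frequencies = freqs))
    })
    utils::write.table(res$dating, file.path(out_dir, "dating.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("report" %in% todo) {
    res <- .stage("report", {
      scores <- stats::setNames(res$hallmarks$composite_score,
                                res$hallmarks$locus_id)
      presence_list <- if (!is.null(truthset$presence))
        apply(truthset$presence, 1L, function(r)
          colnames(truthset$presence)[r == "+"], simplify = FALSE)
      else stats::setNames(rep(list(character(0)), nrow(loci)),
                           loci$locus_id)
      freqs <- res$frequencies
      freqs[is.na(freqs)] <- 0
      rk <- list(); indep <- list()
      t_hat <- stats::setNames(res$dating$t_hat_myr, res$dating$locus_id)
      for (ni in seq_along(res$subfamilies$nodes)) {
        node <- res$subfamilies$nodes[[ni]]
        if (length(node$members) == 0L) next
        r <- identify_source_candidates(node, res$partition$private_counts,
                                        scores, presence_list, freqs)
        r$candidates <- cbind(subfamily = node$name, r$candidates)
        rk[[node$name]] <- r
        if (ni > 1L) {
          span <- max(t_hat[node$carriers], 0.1, na.rm = TRUE)
          indep[[node$name]] <- data.frame(
            subfamily = node$name, n_carriers = length(node$carriers),
            n_diagnostics = nrow(node$diagnostics),
            t_window_myr = span,
            p_independent = independent_acquisition_probability(
              length(node$carriers), node$diagnostics, config$mu,
              config$beta, span),
            stringsAsFactors = FALSE)
        }
      }
      ranking <- do.call(rbind, lapply(rk, function(r) {
        d <- r$candidates
        d$flag <- r$flag
        d
      }))
      rownames(ranking) <- NULL
      loci_out <- loci[, c("locus_id", "species", "chrom", "start", "end",
                           "strand")]
      loci_out$identity <- unname(res$identity[loci_out$locus_id])
      loci_out$frequency <- unname(freqs[loci_out$locus_id])
      c(res, list(rankings = rk, ranking_table = ranking,
                  independence = if (length(indep)) do.call(rbind, indep)
                                 else NULL,
                  loci_table = loci_out))
    })
    utils::write.table(res$ranking_table, file.path(out_dir, "ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_locus_table(res$loci_table, file.path(out_dir, "loci.tsv"))
    if (!is.null(res$independence))
      utils::write.table(res$independence,
                         file.path(out_dir, "independence.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(res)
}

# Deepest-node index per locus id.
.node_of_locus <- function(tree) {
  out <- list()
  for (ni in seq_along(tree$nodes))
    for (id in tree$nodes[[ni]]$members) out[[id]] <- ni
  out
}

# Allele frequencies per locus from the genotype table (NA when absent).
.locus_frequencies <- function(truthset, loci) {
  out <- stats::setNames(rep(NA_real_, nrow(loci)), loci$locus_id)
  gt <- truthset$genotypes
  if (!is.null(gt)) {
    for (id in intersect(unique(gt$locus_id), loci$locus_id))
      out[id] <- allele_frequency(gt$genotype[gt$locus_id == id])
  }
  out
}

# Tolerant directory reader for pipeline input: loci.tsv is required,
# everything else optional.
.read_inputs <- function(dir) {
  p <- function(f) file.path(dir, f)
  ts <- list(loci = read_locus_table(p("loci.tsv")))
  if (file.exists(p("background.fa"))) ts$genome <- read_fasta(p("background.fa"))
  if (file.exists(p("genotypes.tsv"))) ts$genotypes <- read_genotype_table(p("genotypes.tsv"))
  if (file.exists(p("presence.tsv"))) {
    pres <- utils::read.table(p("presence.tsv"), header = TRUE, sep = "\t",
                              check.names = FALSE, colClasses = "character")
    ts$presence <- as.matrix(pres[, -1, drop = FALSE])
    rownames(ts$presence) <- pres$locus_id
  }
  if (file.exists(p("tree.nwk"))) ts$tree_newick <- readLines(p("tree.nwk"))[1]
  class(ts) <- "truth_set"
  ts
}
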
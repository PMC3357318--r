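# io_core: readers/writers for external formats, configuration and logging.
#
# Formats: FASTA (sequences), newick (dated species tree), TSV locus table
# (chrom, start, end, locus_id, strand, species), TSV genotype table
# (sample_id, locus_id, genotype). Coordinates in tables are 0-based
# half-open; consensus positions reported to users are 1-based.

GENOTYPE_ALPHABET <- c("+/+", "+/-", "-/-", "NA")

#' Read a FASTA file
#'
#' Identifiers are preserved verbatim up to the first whitespace; sequences
#' are uppercased and RNA `U` is mapped to `T`.
#'
#' @param path path to a FASTA file
#' @return named character vector of sequences
#' @export
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "ac", "gt", ">b", "TTTT"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file does not exist: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines) | seq_along(lines) < length(lines)]
  if (length(lines) == 0L)
    stop("FASTA format error at line 1: file is empty", call. = FALSE)
  if (!startsWith(lines[[1]], ">"))
    stop("FASTA format error at line 1: expected '>' header, got '",
         substr(lines[[1]], 1, 30), "'", call. = FALSE)
  ids <- character(0)
  seqs <- character(0)
  buf <- character(0)
  cur <- NULL
  flush <- function() {
    if (!is.null(cur)) {
      ids <<- c(ids, cur)
      seqs <<- c(seqs, paste(buf, collapse = ""))
    }
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (startsWith(ln, ">")) {
      header <- sub("^>", "", ln)
      id <- strsplit(trimws(header), "\\s+")[[1]][1]
      if (is.na(id) || id == "")
        stop("FASTA format error at line ", i, ": empty header", call. = FALSE)
      flush()
      cur <- id
      buf <- character(0)
    } else {
      if (is.null(cur))
        stop("FASTA format error at line ", i, ": sequence before header", call. = FALSE)
      buf <- c(buf, gsub("\\s", "", ln))
    }
  }
  flush()
  seqs <- chartr("u", "t", toupper(seqs))
  seqs <- chartr("U", "T", seqs)
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences
#' @param path output path
#' @param width line wrap width
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[[i]]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a genotype table
#'
#' TSV with header `sample_id`, `locus_id`, `genotype`; genotypes are
#' insertion presence/absence calls from the alphabet `+/+`, `+/-`, `-/-`,
#' `NA` (biallelic insertion polymorphism).
#'
#' @param path TSV path
#' @return data.frame with columns sample_id, locus_id, genotype
#' @export
read_genotype_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", na.strings = NULL,
                          check.names = FALSE)
  need <- c("sample_id", "locus_id", "genotype")
  if (!all(need %in% names(df)))
    stop("genotype table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df <- df[, need]
  validate_genotype_table(df)
}

#' @keywords internal
validate_genotype_table <- function(df) {
  bad <- !(df$genotype %in% GENOTYPE_ALPHABET)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("invalid genotype '", df$genotype[i], "' at row ", i,
         " (sample ", df$sample_id[i], ", locus ", df$locus_id[i],
         "); allowed: ", paste(GENOTYPE_ALPHABET, collapse = " "),
         call. = FALSE)
  }
  key <- paste(df$sample_id, df$locus_id, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    stop("duplicate (sample_id, locus_id) pair at row ", i, ": (",
         df$sample_id[i], ", ", df$locus_id[i], ")", call. = FALSE)
  }
  df
}

#' Write a genotype table
#' @param df genotype data.frame
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_genotype_table <- function(df, path) {
  validate_genotype_table(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dated species tree
#'
#' Reads a newick tree with branch lengths in Myr, verifies ultrametricity
#' and attaches node ages (Myr before present) computed from leaf depths.
#'
#' @param path newick file path, or a newick string
#' @param tol ultrametricity tolerance on root-to-tip depths
#' @return an [ape::read.tree()] `phylo` object with a `node_ages` attribute
#'   (named by node number, leaves at age 0)
#' @export
read_tree <- function(path, tol = 1e-6) {
  tr <- if (file.exists(path)) ape::read.tree(path) else ape::read.tree(text = path)
  if (is.null(tr)) stop("could not parse newick tree: ", path, call. = FALSE)
  validate_species_tree(tr, tol = tol)
}

#' @keywords internal
validate_species_tree <- function(tr, tol = 1e-6) {
  if (is.null(tr$edge.length))
    stop("species tree has no branch lengths", call. = FALSE)
  n_tip <- length(tr$tip.label)
  if (n_tip >= 2L) {
    depths <- ape::node.depth.edgelength(tr)
    tip_depths <- depths[seq_len(n_tip)]
    disc <- max(tip_depths) - min(tip_depths)
    if (disc > tol)
      stop("species tree is not ultrametric: max root-to-tip discrepancy ",
           format(disc), " Myr exceeds tolerance ", format(tol), call. = FALSE)
    ages <- max(tip_depths) - depths
    ages[seq_len(n_tip)] <- 0
  } else {
    ages <- 0
  }
  names(ages) <- as.character(seq_along(ages))
  attr(tr, "node_ages") <- ages
  tr
}

#' Age (Myr) of the most recent common ancestor of a species set
#' @param tree tree from [read_tree()]
#' @param species character vector of leaf labels
#' @return age in Myr
#' @export
mrca_age <- function(tree, species) {
  idx <- match(species, tree$tip.label)
  if (anyNA(species) || anyNA(idx))
    stop("species not in tree: ",
         paste(species[is.na(idx)], collapse = ", "), call. = FALSE)
  ages <- attr(tree, "node_ages")
  if (length(idx) == 1L) return(0)
  node <- ape::getMRCA(tree, idx)
  unname(ages[as.character(node)])
}

#' Read a locus table
#'
#' BED-like TSV with columns chrom, start, end, locus_id, strand, species and
#' optionally element_seq, left_flank, right_flank, fixed. Coordinates are
#' 0-based half-open.
#'
#' @param path TSV path
#' @return data.frame of loci
#' @export
read_locus_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA",
                          check.names = FALSE)
  need <- c("chrom", "start", "end", "locus_id", "strand", "species")
  if (!all(need %in% names(df)))
    stop("locus table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  validate_locus_table(df)
}

#' @keywords internal
validate_locus_table <- function(df) {
  if (anyDuplicated(df$locus_id))
    stop("locus_id values must be unique; duplicated: ",
         df$locus_id[duplicated(df$locus_id)][1], call. = FALSE)
  if (any(df$end <= df$start))
    stop("locus table: end must exceed start (0-based half-open); offending locus ",
         df$locus_id[which(df$end <= df$start)[1]], call. = FALSE)
  if (!all(df$strand %in% c("+", "-")))
    stop("locus table: strand must be '+' or '-'", call. = FALSE)
  if ("element_seq" %in% names(df))
    for (s in df$element_seq) assert_dna(s, "element_seq")
  df
}

#' Write a locus table
#' @param df locus data.frame
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_locus_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- Pipeline configuration -------------------------------------------------

#' Pipeline configuration
#'
#' Flat key-value settings shared by the inference stages. `mu` is the
#' non-CpG substitution rate per site per Myr, `beta` the CpG rate multiplier
#' (CpG dinucleotides deaminate roughly 6-10x faster), `k_min_share` the
#' minimum number of carrier loci for a shared variant to count as a
#' subfamily diagnostic, `alpha_independence` the significance threshold for
#' the independent-acquisition test.
#'
#' @param mu non-CpG substitution rate (subs/site/Myr)
#' @param beta CpG rate multiplier (>= 1)
#' @param k_min_share minimum carrier count for a diagnostic variant (>= 2)
#' @param alpha_independence probability threshold in (0,1)
#' @param min_identity minimum percent identity for genome scan hits
#' @param min_len minimum aligned length for genome scan hits
#' @param tsd_min_len minimum target-site-duplication length
#' @param tsd_max_mismatch maximum mismatches between TSD copies
#' @param polyA_min_len minimum poly(A) run length recognised as a tail
#' @param lineage_tag suffix used when naming subfamilies (e.g. "Pongo")
#' @param ancestral_name name of the ancestral consensus (root subfamily)
#' @param seed integer RNG seed echoed in run logs
#' @return a validated `pipeline_config` list
#' @export
pipeline_config <- function(mu = 0.0015, beta = 8, k_min_share = 3L,
                            alpha_independence = 0.001, min_identity = 90,
                            min_len = 150L, tsd_min_len = 8L,
                            tsd_max_mismatch = 2L, polyA_min_len = 5L,
                            lineage_tag = "Pongo", ancestral_name = "AluY",
                            seed = 1L) {
  cfg <- list(mu = mu, beta = beta, k_min_share = as.integer(k_min_share),
              alpha_independence = alpha_independence,
              min_identity = min_identity, min_len = as.integer(min_len),
              tsd_min_len = as.integer(tsd_min_len),
              tsd_max_mismatch = as.integer(tsd_max_mismatch),
              polyA_min_len = as.integer(polyA_min_len),
              lineage_tag = lineage_tag, ancestral_name = ancestral_name,
              seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @keywords internal
validate_config <- function(cfg) {
  if (!is.numeric(cfg$mu) || cfg$mu <= 0) stop("config: mu must be > 0", call. = FALSE)
  if (!is.numeric(cfg$beta) || cfg$beta < 1) stop("config: beta must be >= 1", call. = FALSE)
  if (cfg$k_min_share < 2) stop("config: k_min_share must be >= 2", call. = FALSE)
  if (cfg$alpha_independence <= 0 || cfg$alpha_independence >= 1)
    stop("config: alpha_independence must be in (0,1)", call. = FALSE)
  if (cfg$min_identity <= 0 || cfg$min_identity > 100)
    stop("config: min_identity must be in (0,100]", call. = FALSE)
  invisible(cfg)
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` comments and blank lines are
#' ignored. Unknown keys produce a warning, not an error.
#'
#' @param path config file path
#' @return a `pipeline_config`
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop("config parse error at line '", lines[bad][1], "'", call. = FALSE)
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, `[[`, "", 2L)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0)
    warning("unknown config keys ignored: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  args <- as.list(vals[keys %in% known])
  names(args) <- keys[keys %in% known]
  numkeys <- setdiff(known, c("lineage_tag", "ancestral_name"))
  for (k in intersect(names(args), numkeys)) args[[k]] <- as.numeric(args[[k]])
  do.call(pipeline_config, args)
}
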
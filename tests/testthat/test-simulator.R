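# Mutation process, insertion machinery, drift, and the amplification
# generator's truth contracts.

test_that("mutate_sequence leaves the sequence alone at t = 0 and rejects t < 0", {
  s <- random_dna(200)
  expect_identical(mutate_sequence(s, 0, 0.0015, 8), s)
  expect_error(mutate_sequence(s, -1, 0.0015, 8), "t_myr")
})

test_that("substitution counts follow the Poisson expectation L*mu*t", {
  # CpG-free alphabet with beta = 1 makes the total rate exactly L*mu
  set.seed(101)
  s <- strrep("AT", 5000)   # L = 10000, no CG dinucleotides
  reps <- 60
  counts <- vapply(seq_len(reps), function(i)
    nrow(mutate_sequence(s, 10, 0.001, 1, record = TRUE)$events), 0L)
  expected <- 10000 * 0.001 * 10
  tol <- 3 * sqrt(expected / reps)
  expect_lt(abs(mean(counts) - expected), tol)
})

test_that("CpG sites substitute about beta times faster", {
  set.seed(102)
  s <- strrep("CGTA", 1000)   # half the sites sit in a CG dinucleotide
  is_cpg_orig <- rep(c(TRUE, TRUE, FALSE, FALSE), 1000)
  hit_cpg <- 0; hit_non <- 0
  for (i in 1:20) {
    ev <- mutate_sequence(s, 2, 0.01, 8, record = TRUE)$events
    first <- ev[!duplicated(ev$position), ]   # first substitution per site
    hit_cpg <- hit_cpg + sum(is_cpg_orig[first$position])
    hit_non <- hit_non + sum(!is_cpg_orig[first$position])
  }
  ratio <- (hit_cpg / 2000) / (hit_non / 2000)
  expect_gt(ratio, 8 * 0.75)
  expect_lt(ratio, 8 * 1.25)
})

test_that("generate_insertion targets TTAAAA, duplicates the target site and snapshots the source", {
  set.seed(103)
  # scaffold free of TTAAAA except one planted motif
  base <- strrep("CGATGGCT", 200)
  scaffold <- paste0(substr(base, 1, 800), "TTAAAA", substr(base, 801, 1600))
  src <- random_dna(120)
  cfg <- simulation_config(scaffold_len = nchar(scaffold))
  res <- generate_insertion(src, scaffold, cfg, window_len = 4000L)
  # insertion lands at the nick inside the motif region
  motif_at <- as.integer(regexpr("TTAAAA", scaffold, fixed = TRUE))
  expect_lt(abs(res$locus$start - motif_at), 30)
  # TSD definition: left flank suffix equals right flank prefix
  g <- res$scaffold
  tsd <- res$locus$tsd
  expect_equal(substr(g, res$locus$start - nchar(tsd) + 1, res$locus$start),
               tsd)
  expect_equal(substr(g, res$locus$end + 1, res$locus$end + nchar(tsd)), tsd)
  # snapshot semantics: element body is the source sequence verbatim
  expect_true(startsWith(res$locus$element_seq, src))
  expect_error(generate_insertion(src, "ACGTACGT", cfg), "too short")
})

test_that("drift_frequency starts at 1/(2Ne), absorbs, and is a martingale", {
  set.seed(104)
  expect_equal(drift_frequency(0, 1000, 20), 1 / 2000)
  # all walks past ~4Ne generations are absorbed at 0 or 1
  ends <- vapply(1:50, function(i) drift_frequency(0.2, 10, 20), 0)
  expect_true(all(ends %in% c(0, 1)))
  # martingale: mean endpoint stays at the initial frequency
  reps <- vapply(1:2000, function(i) drift_frequency(0.002, 50, 20), 0)
  se <- stats::sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 1 / 100), 3 * se + 1e-12)
})

test_that("simulate_amplification with a vanishing rate yields identical copies", {
  ts <- simulate_amplification(simulation_config(
    seed = 5, mu = 1e-12, lambda_per_myr = 0.8, total_myr = 8,
    scaffold_len = 20000L, sample_frequencies = FALSE))
  bodies <- vapply(ts$loci$element_seq, trim_tail, "")
  expect_true(all(bodies == alu_master_consensus()))
})

test_that("same seed gives a byte-identical TruthSet", {
  ts1 <- quick_truthset(seed = 11)
  ts2 <- quick_truthset(seed = 11)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_truthset(ts1, d1); write_truthset(ts2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("TruthSet loci are recoverable from the background at recorded coordinates", {
  ts <- quick_truthset(seed = 12)
  for (i in seq_len(nrow(ts$loci))) {
    ex <- extract_locus(ts$genome, ts$loci$start[i], ts$loci$end[i],
                        ts$loci$strand[i])
    expect_identical(ex$element_seq, ts$loci$element_seq[i],
                     info = ts$loci$locus_id[i])
  }
  expect_true(all(ts$truth$final_allele_frequency >= 0 &
                    ts$truth$final_allele_frequency <= 1))
})

test_that("snapshot heredity: a child's inherited events are its parent's events at copy time", {
  ts <- quick_truthset(seed = 13, n_target = 12, total_myr = 6)
  ev <- ts$events
  for (i in seq_len(nrow(ts$truth))) {
    id <- ts$truth$locus_id[i]; p <- ts$truth$parent_id[i]
    if (is.na(p)) next
    t_ins <- ts$truth$insertion_time_myr[i]
    child_inherited <- sort(ev$event_id[ev$locus_id == id & ev$inherited &
                                          ev$region == "body"])
    parent_by_then <- sort(ev$event_id[ev$locus_id == p &
                                         ev$region == "body" &
                                         ev$t_myr > t_ins])
    expect_identical(child_inherited, parent_by_then, info = id)
  }
})

test_that("parents are never younger than their children", {
  ts <- quick_truthset(seed = 14)
  tr <- ts$truth
  for (i in seq_len(nrow(tr))) {
    p <- tr$parent_id[i]
    if (is.na(p)) next
    expect_gte(tr$insertion_time_myr[tr$locus_id == p],
               tr$insertion_time_myr[i])
  }
})

test_that("older loci carry stochastically more post-insertion substitutions", {
  ts <- simulate_amplification(study_config(
    seed = 15, n_target = 100, scaffold_len = 120000L,
    sample_frequencies = FALSE))
  ev <- ts$events[ts$events$region == "body" & !ts$events$inherited, ]
  own <- table(factor(ev$locus_id, levels = ts$truth$locus_id))
  ct <- suppressWarnings(stats::cor.test(
    ts$truth$insertion_time_myr, as.numeric(own), method = "spearman"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("no-loss conditioning logs the implied drift losses", {
  ts <- quick_truthset(seed = 16)
  expect_gte(ts$log$n_lost_drift, 0L)
  expect_true(all(ts$truth$final_allele_frequency > 0))
})
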
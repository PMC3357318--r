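# TSD detection, poly(A) measurement, terminator, boxes, composite score,
# in-silico PCR.

test_that("find_tsd recovers planted duplications and tolerates mismatches", {
  tsd <- "GGATTTTCTAGC"
  left <- paste0("GCATCAGT", tsd)
  right <- paste0(tsd, "ACCGTAGG")
  hit <- find_tsd(left, right, min_len = 8, max_mismatch = 0)
  expect_equal(hit$sequence, tsd)
  expect_equal(hit$length, 12L)
  expect_equal(hit$mismatches, 0L)

  right_mm <- right
  substr(right_mm, 5, 5) <- "A"
  hit2 <- find_tsd(left, right_mm, min_len = 8, max_mismatch = 1)
  expect_equal(hit2$length, 12L)
  expect_equal(hit2$mismatches, 1L)

  set.seed(41)
  expect_null(find_tsd(random_dna(40), random_dna(40), min_len = 10,
                       max_mismatch = 0))
})

test_that("measure_polyA measures disrupted and perfect tails", {
  perfect <- measure_polyA(strrep("A", 30))
  expect_equal(perfect$length, 30L)
  expect_equal(nrow(perfect$disruptions), 0L)

  # double cytosine after 10 A's, a third after 16: 27 nt, three severe
  tail27 <- paste0(strrep("A", 10), "CC", strrep("A", 4), "C",
                   strrep("A", 10))
  m <- measure_polyA(paste0(tail27, "TTTTGAGTC"))
  expect_equal(m$length, 27L)
  expect_equal(m$disruptions$offset, c(11L, 12L, 17L))
  expect_true(all(m$disruptions$type == "severe"))

  tol <- measure_polyA(paste0(strrep("A", 3), "T", strrep("A", 26)))
  expect_equal(tol$length, 30L)
  expect_equal(tol$disruptions$type, "tolerated")
})

test_that("measure_polyA is invariant to downstream flank content", {
  # holds for flanks that are not themselves A-rich (an A-rich flank start
  # legitimately extends the tail under the 7-of-10 window rule)
  set.seed(42)
  tail <- paste0(strrep("A", 12), "T", strrep("A", 9))
  for (i in 1:10) {
    flank <- paste(sample(c("C", "G", "T"), 30, TRUE), collapse = "")
    expect_equal(measure_polyA(paste0(tail, flank))$length,
                 measure_polyA(tail)$length)
  }
})

test_that("trim_tail splits body from tail at the window boundary", {
  body <- paste0(random_dna(80), "GCTC")   # non-A 3' body end
  el <- paste0(body, strrep("A", 24))
  expect_equal(trim_tail(el), body)
})

test_that("terminator_distance reports the first TTTT offset", {
  expect_equal(terminator_distance("TTTTGC"), 0L)
  expect_equal(terminator_distance("GCTTTTA"), 2L)
  expect_equal(terminator_distance(strrep("GACGC", 20)), -1L)
  # a TTTT starting beyond the window does not count
  expect_equal(terminator_distance(paste0(strrep("G", 51), "TTTT"),
                                   window = 50), -1L)
})

test_that("check_boxes scores interval integrity against the consensus", {
  cons <- alu_master_consensus()
  ok <- check_boxes(call_variants(global_align(cons, cons)), nchar(cons))
  expect_true(ok$a_box_intact); expect_true(ok$b_box_intact)
  expect_equal(ok$left_monomer_mutation_count, 0L)

  q <- cons; substr(q, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                          substr(cons, 20, 20))[1]
  hit <- check_boxes(call_variants(global_align(q, cons)), nchar(cons))
  expect_false(hit$a_box_intact)
  expect_true(hit$b_box_intact)
  expect_equal(hit$left_monomer_mutation_count, 1L)

  # founder-like: pristine left monomer, two right-monomer changes
  q2 <- cons
  for (p in c(154L, 247L))
    substr(q2, p, p) <- setdiff(c("A", "C", "G", "T"),
                                substr(cons, p, p))[1]
  r2 <- check_boxes(call_variants(global_align(q2, cons)), nchar(cons))
  expect_equal(r2$left_monomer_mutation_count, 0L)
  expect_true(r2$a_box_intact && r2$b_box_intact)

  expect_error(check_boxes(data.frame(), 100, a_box = c(6, 200)),
               "outside")
})

perfect_report <- function() list(
  left_monomer_mutation_count = 0L, a_box_intact = TRUE, b_box_intact = TRUE,
  polyA_length = 30L, polyA_tolerated_count = 0L, polyA_severe_count = 0L,
  terminator_distance = 0L, upstream_motif = list(motif = "TATAAAAA"),
  tsd = list(length = 12L))

test_that("score_competence matches worked arithmetic and is monotone", {
  expect_equal(score_competence(perfect_report()), 1.0)

  lm_mut <- perfect_report(); lm_mut$left_monomer_mutation_count <- 2L
  expect_equal(score_competence(lm_mut), 0.7)

  sev <- perfect_report(); sev$polyA_severe_count <- 3L
  tol <- perfect_report(); tol$polyA_tolerated_count <- 3L
  expect_lt(score_competence(sev), score_competence(tol))

  expect_error(score_competence(perfect_report(),
                                weights = c(left_monomer = 0)), "zero")

  set.seed(43)
  for (i in 1:25) {
    r <- perfect_report()
    r$polyA_length <- sample(0:40, 1)
    r$polyA_severe_count <- sample(0:4, 1)
    r$terminator_distance <- sample(c(-1L, 0L, 3L, 20L), 1)
    worse <- r; worse$polyA_severe_count <- r$polyA_severe_count + 1L
    expect_lte(score_competence(worse), score_competence(r))
    longer <- r; longer$polyA_length <- r$polyA_length + 5L
    expect_gte(score_competence(longer), score_competence(r))
  }
})

test_that("predict_pcr_products reproduces the size arithmetic", {
  set.seed(44)
  lf <- random_dna(100)
  body <- random_dna(285)
  el <- paste0(body, strrep("A", 27))
  rf <- paste0("GGATTCCTAGCA", random_dna(100))  # 12 nt TSD then 100 nt flank
  fwd <- substr(lf, 1, 20)
  rev <- chartr("ACGT", "TGCA",
                paste(rev(strsplit(substr(rf, 93, 112), "")[[1]]),
                      collapse = ""))
  sizes <- predict_pcr_products(lf, el, rf, fwd, rev, tsd_len = 12L)
  expect_equal(sizes$filled, 524L)
  expect_equal(sizes$empty, 200L)

  expect_error(predict_pcr_products(lf, el, rf, rev, fwd, 12L),
               "orientation|not found")
  expect_error(predict_pcr_products(lf, el, rf, "ACGTACGTACGTACGTACGT",
                                    rev, 12L), "not found")
  multi <- paste0(lf, substr(lf, 1, 40))
  expect_error(predict_pcr_products(multi, el, rf, fwd, rev, 12L),
               "multiple")
})

test_that("find_tsd recovers every planted TSD on simulator loci", {
  ts <- quick_truthset(seed = 45)
  planted <- setNames(ts$truth$locus_id, ts$truth$locus_id)
  for (i in seq_len(nrow(ts$loci))) {
    hit <- find_tsd(ts$loci$left_flank[i], ts$loci$right_flank[i],
                    min_len = 8, max_mismatch = 0)
    expect_false(is.null(hit), info = ts$loci$locus_id[i])
    expect_gte(hit$length, 8L)
  }
})

test_that("hallmark_report flattens all annotators for a clean locus", {
  cons <- alu_master_consensus()
  tsd <- "TTTTGGATTACC"   # Pol III terminator inside the 3' TSD
  lf <- paste0(random_dna(50), "TATAAAAA", "GT", tsd)
  rf <- paste0(tsd, random_dna(40))
  el <- paste0(cons, strrep("A", 30))
  hr <- hallmark_report(el, lf, rf, cons)
  expect_equal(hr$left_monomer_mutation_count, 0L)
  expect_equal(hr$polyA_length, 30L)
  expect_equal(hr$terminator_distance, 0L)
  expect_equal(hr$tsd$sequence, tsd)
  expect_equal(hr$upstream_motif$motif, "TATAAAAA")
  expect_equal(hr$composite_score, 1.0)
})
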
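# Subfamily hierarchy inference, naming, source ranking, independence test.

mkv <- function(locus, pos, alt = "G", ref = "A") data.frame(
  locus_id = locus, position = as.integer(pos), ref = ref, alt = alt,
  kind = "substitution", cpg = FALSE,
  key = paste("substitution", pos, ref, alt, sep = ":"))

vset <- function(loci, positions) do.call(rbind, lapply(loci, function(l)
  do.call(rbind, lapply(positions, function(p) mkv(l, p)))))

test_that("naming follows the standardized convention", {
  expect_equal(name_subfamily("AluYe5", 2, 0, "Pongo"), "AluYe5a2_Pongo")
  expect_equal(name_subfamily("AluYe5", 5, 1, "Pongo"), "AluYe5b5_Pongo")
  expect_equal(name_subfamily("AluYe5", 0, 0, "Pongo"), "AluYe5")
  # grandchildren do not repeat the lineage tag
  expect_equal(name_subfamily("AluYe5b5_Pongo", 2, 0, "Pongo"),
               "AluYe5b5a2_Pongo")
})

test_that("a shared set plus a deeper shared subset builds a two-level chain", {
  all5 <- sprintf("l%d", 1:5)
  v <- rbind(vset(all5, c(10, 20, 30)), vset(all5[1:3], c(40, 50)))
  part <- partition_diagnostic_private(v, 3L)
  cons <- random_dna(120)
  tree <- infer_subfamilies(part, all5, cons, "Pongo", "AluY")
  expect_equal(length(tree$nodes), 3L)
  a <- tree$nodes[[2]]; b <- tree$nodes[[3]]
  expect_equal(a$n_new, 3L); expect_setequal(a$carriers, all5)
  expect_equal(b$n_new, 2L); expect_setequal(b$carriers, all5[1:3])
  expect_equal(b$parent, 2L)
  expect_equal(a$name, "AluYa3_Pongo")
  expect_equal(b$name, "AluYa3a2_Pongo")
  # assignment to the deepest carried node
  expect_setequal(a$members, c("l4", "l5"))
  expect_setequal(b$members, c("l1", "l2", "l3"))
})

test_that("no shared variants leaves only the root; disjoint sets become siblings", {
  all4 <- sprintf("l%d", 1:4)
  lone <- rbind(mkv("l1", 10), mkv("l2", 20))
  t0 <- infer_subfamilies(partition_diagnostic_private(lone, 3L), all4,
                          random_dna(60))
  expect_equal(length(t0$nodes), 1L)
  expect_setequal(t0$nodes[[1]]$members, all4)

  all6 <- sprintf("l%d", 1:6)
  v <- rbind(vset(all6[1:3], c(10, 20)), vset(all6[4:6], c(30)))
  t1 <- infer_subfamilies(partition_diagnostic_private(v, 3L), all6,
                          random_dna(60))
  expect_equal(length(t1$nodes), 3L)
  expect_equal(t1$nodes[[2]]$parent, 1L)
  expect_equal(t1$nodes[[3]]$parent, 1L)
  # sibling letters are distinct (naming injective within a parent)
  expect_false(t1$nodes[[2]]$name == t1$nodes[[3]]$name)
  expect_equal(length(t1$warnings), 0L)
})

test_that("partially overlapping carrier sets yield siblings plus a warning", {
  all6 <- sprintf("l%d", 1:6)
  v <- rbind(vset(all6[1:4], c(10, 20)), vset(all6[3:6], c(30)))
  tr <- infer_subfamilies(partition_diagnostic_private(v, 3L), all6,
                          random_dna(60))
  expect_equal(length(tr$nodes), 3L)
  expect_gt(length(tr$warnings), 0L)
  expect_match(tr$warnings[1], "overlap")
})

test_that("a single-variant set one carrier short is absorbed as a back-mutation", {
  all5 <- sprintf("l%d", 1:5)
  v <- rbind(vset(all5, c(10, 20)), vset(all5[1:4], 30))
  tr <- infer_subfamilies(partition_diagnostic_private(v, 3L), all5,
                          random_dna(60))
  expect_equal(length(tr$nodes), 2L)
  expect_equal(tr$nodes[[2]]$n_new, 3L)
  expect_equal(tr$discrepancies$locus_id, "l5")
})

test_that("node consensus equals the ancestral consensus edited at chain diagnostics", {
  all5 <- sprintf("l%d", 1:5)
  cons <- strrep("ACGT", 30)
  v <- rbind(vset(all5, c(10, 20, 30)), vset(all5[1:3], c(40, 50)))
  tr <- infer_subfamilies(partition_diagnostic_private(v, 3L), all5, cons)
  deep <- tr$nodes[[3]]
  manual <- cons
  for (p in c(10, 20, 30, 40, 50)) substr(manual, p, p) <- "G"
  expect_equal(deep$consensus, manual)
})

test_that("reconstructed node consensus stays within private noise of the member consensus", {
  ts <- quick_truthset(seed = 31, n_target = 15, total_myr = 6)
  elements <- setNames(ts$loci$element_seq, ts$loci$locus_id)
  part <- partition_diagnostic_private(
    call_variants_set(elements, alu_master_consensus()), 3L)
  tr <- infer_subfamilies(part, ts$loci$locus_id, alu_master_consensus())
  sizes <- vapply(tr$nodes, function(n) length(n$members), 0L)
  ni <- which(sizes >= 3)[length(which(sizes >= 3))]
  skip_if(length(ni) == 0, "no multi-member node in this draw")
  node <- tr$nodes[[ni]]
  bodies <- vapply(node$members, function(id) trim_tail(elements[[id]]), "")
  bodies <- bodies[nchar(bodies) == nchar(node$consensus)]
  skip_if(length(bodies) < 3, "indel-bearing members")
  member_cons <- build_consensus(unname(bodies))
  ham <- sum(strsplit(member_cons, "")[[1]] !=
               strsplit(node$consensus, "")[[1]])
  med_priv <- stats::median(part$private_counts$total[
    part$private_counts$locus_id %in% node$members])
  expect_lte(ham, max(med_priv, 1))
})

test_that("independent-acquisition probability follows the closed form", {
  expect_equal(independent_acquisition_probability(
    1, mkv("l1", 10), 0.001, 8, 5), 1.0)
  v2 <- rbind(mkv("x", 10), mkv("x", 20))
  # mu*t/3 = 0.001 each, n = 3: (1e-3 * 1e-3)^2 = 1e-12
  expect_equal(independent_acquisition_probability(3, v2, 0.003, 8, 1),
               1e-12)
  # capped probabilities give 1
  expect_equal(independent_acquisition_probability(4, v2, 10, 1, 10), 1.0)
  # CpG variants use beta * mu
  vc <- mkv("x", 10); vc$cpg <- TRUE
  expect_equal(independent_acquisition_probability(2, vc, 0.003, 8, 1),
               0.008)
})

test_that("source ranking rewards consensus identity, hallmarks and presence", {
  node <- list(members = c("src", "kid1", "kid2"), carriers = c("src", "kid1", "kid2"))
  pc <- data.frame(locus_id = c("kid1", "kid2"), total = c(2L, 1L),
                   cpg = c(1L, 0L), noncpg = c(1L, 1L))
  scores <- c(src = 1.0, kid1 = 0.8, kid2 = 0.9)
  pres <- list(src = c("human", "chimp", "gorilla", "orangutan"),
               kid1 = "orangutan", kid2 = "orangutan")
  freq <- c(src = 1.0, kid1 = 0.3, kid2 = 0.1)
  r <- identify_source_candidates(node, pc, scores, pres, freq)
  expect_true(is.na(r$flag))
  expect_equal(r$candidates$locus_id[which(r$candidates$rank == 1)], "src")

  # all members private-bearing with identical presence: unidentified
  pc2 <- data.frame(locus_id = c("src", "kid1", "kid2"), total = c(1L, 2L, 1L),
                    cpg = 0L, noncpg = 1L)
  pres2 <- list(src = "orangutan", kid1 = "orangutan", kid2 = "orangutan")
  r2 <- identify_source_candidates(node, pc2, scores, pres2, freq)
  expect_equal(r2$flag, "source unidentified or lost")
  expect_true(all(is.na(r2$candidates$rank)))
})

test_that("ranking order matches a brute-force comparator sort", {
  set.seed(32)
  ids <- sprintf("c%d", 1:8)
  node <- list(members = ids, carriers = ids)
  pc <- data.frame(locus_id = ids, total = 0L, cpg = 0L, noncpg = 0L)
  scores <- setNames(round(runif(8), 2), ids)
  pres <- setNames(rep(list("orangutan"), 8), ids)
  freq <- setNames(round(runif(8), 2), ids)
  r <- identify_source_candidates(node, pc, scores, pres, freq)
  got <- r$candidates$locus_id[order(r$candidates$rank)]
  # brute-force O(n^2) selection by the documented keys
  better <- function(a, b) {
    if (scores[a] != scores[b]) return(scores[a] > scores[b])
    if (freq[a] != freq[b]) return(freq[a] > freq[b])
    a < b
  }
  want <- ids
  for (i in seq_along(want)) for (j in seq_along(want)) {
    if (i < j && better(want[j], want[i])) {
      tmp <- want[i]; want[i] <- want[j]; want[j] <- tmp
    }
  }
  expect_equal(got, want)
})

test_that("top two candidates differing only by frequency are flagged as alternatives", {
  ids <- c("a", "b", "c")
  node <- list(members = ids, carriers = ids)
  pc <- data.frame(locus_id = character(0), total = integer(0),
                   cpg = integer(0), noncpg = integer(0))
  scores <- c(a = 0.9, b = 0.9, c = 0.2)
  pres <- setNames(rep(list("orangutan"), 3), ids)
  freq <- c(a = 0.35, b = 0.09, c = 0.08)
  r <- identify_source_candidates(node, pc, scores, pres, freq)
  expect_true(all(r$candidates$alternative[r$candidates$rank %in% 1:2]))
  expect_false(r$candidates$alternative[which(r$candidates$rank == 3)])
})
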
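# Shared test helpers: independent alignment oracles, random sequences,
# and the seven-species dated tree used by placement tests.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# Seven-species ultrametric tree (Myr): great apes (MRCA 16), hylobatids
# (MRCA 14, joining at 18), macaque outgroup at 25.
seven_species_newick <- paste0(
  "(((((human:6,chimp:6):3,gorilla:9):7,orangutan:16):2,",
  "(siamang:14,gibbon:14):4):7,macaque:25);")

# Independent affine-gap global alignment score: plain-R Gotoh DP.
# Length-k gap costs 4 + (k - 1), matching align_scores().
oracle_align_score <- function(a, b, match = 1, mismatch = -1,
                               open = -4, ext = -1) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- open + (i - 1) * ext
  for (j in seq_len(m)) Y[1, j + 1] <- open + (j - 1) * ext
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (x[i] == y[j]) match else mismatch
    M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
    X[i + 1, j + 1] <- max(M[i, j + 1] + open, X[i, j + 1] + ext,
                           Y[i, j + 1] + open)
    Y[i + 1, j + 1] <- max(M[i + 1, j] + open, Y[i + 1, j] + ext,
                           X[i + 1, j] + open)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Exhaustive enumeration of every alignment (tiny inputs only): recursion
# over the three moves with explicit gap-state costs.
oracle_align_enumerate <- function(a, b, match = 1, mismatch = -1,
                                   open = -4, ext = -1) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  rec2 <- function(i, j, state) {
    if (i > length(x) && j > length(y)) return(0)
    best <- -Inf
    if (i <= length(x) && j <= length(y)) {
      s <- if (x[i] == y[j]) match else mismatch
      best <- max(best, s + rec2(i + 1, j + 1, "M"))
    }
    if (i <= length(x))
      best <- max(best, (if (state == "X") ext else open) +
                    rec2(i + 1, j, "X"))
    if (j <= length(y))
      best <- max(best, (if (state == "Y") ext else open) +
                    rec2(i, j + 1, "Y"))
    best
  }
  rec2(1, 1, "start")
}

# Small fast TruthSet for structural tests: short horizon, few copies.
quick_truthset <- function(seed = 1, n_target = 10, total_myr = 4, ...) {
  simulate_amplification(study_config(
    seed = seed, n_target = n_target, total_myr = total_myr,
    scaffold_len = 20000L, ...))
}
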
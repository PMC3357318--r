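# alusleuth

Inference of Alu subfamily structure and retrotransposition source
("driver") elements, with a truth-tagged simulator of stealth-driver
amplification.

## The problem

Alu elements — ~300-nt primate SINEs mobilized by the L1 machinery —
carry no coding sequence, so a retrotransposition-competent *source*
copy cannot be recognized the way an intact L1 can. It must be inferred
comparatively. A source transmits the mutations it has accumulated to
every later copy, so its post-insertion changes become the *diagnostic*
mutations defining a subfamily, nested hierarchically as amplification
continues; mutations a copy acquires after its own insertion stay
*private* and count its age. `alusleuth` implements this analysis for
anyone studying SINE amplification dynamics:

- **Subfamily inference** from diagnostic variants: variants shared by
  ≥ *k* loci (same position *and* alternative allele) define nodes,
  nested by carrier-set inclusion, named by the standardized convention
  (e.g. a subfamily with five extra diagnostics in the *Pongo* lineage
  becomes `...b5_Pongo`).
- **Source identification**: per subfamily, members are ranked by
  ascending private-mutation count (CpG and non-CpG tallied
  separately), retrotransposition-competence hallmarks, cross-species
  presence and allele frequency; nodes with no plausible parent are
  flagged "source unidentified or lost". A closed form scores whether
  co-occurring variants could instead be independent acquisitions:
  `P = (prod_j min(1, rate_j t / 3))^(n-1)`, with `rate_j = beta*mu` at
  CpG sites, `mu` elsewhere.
- **Hallmark annotation**: target-site duplications, poly(A) tail
  length with tolerated (A→T) versus severe (C/G) disruptions, Pol III
  terminator (TTTT) distance, promoter A/B-box and left-monomer
  integrity, upstream TATAAAAA/TTAAAA motifs, composite score, and
  in-silico PCR product sizes.
- **Dating and ordering**: insertion ages `t_hat = k / R` with
  `R = (L_noncpg + beta * L_cpg) * mu` per Myr and exact Poisson 95%
  intervals; single-gain (Dollo) placement of presence/absence patterns
  on a dated species tree; offspring ordered oldest-first with
  alternative-order annotations.
- **A stealth-driver simulator**: one founder evolving under a
  CpG-aware Gillespie substitution clock, copying itself at a low
  Poisson rate, daughters activating as secondary sources with
  probability 0.15, frequencies drifting under Wright–Fisher sampling,
  presence following the insertion branch on a dated great-ape tree —
  with a per-event truth log so every inference stage is scorable.

## Worked example

Simulate a small 6-Myr amplification and run the full pipeline:

```r
library(alusleuth)
cfg <- study_config(seed = 42, n_target = 12, total_myr = 6,
                    scaffold_len = 20000)
ts  <- simulate_amplification(cfg)
ts
#> TruthSet: 9 loci ( 1 active sources ) over 6 Myr; seed 42
res <- run_pipeline(pipeline_config(seed = 42), truthset = ts,
                    out_dir = "alurun")
res$subfamilies
#> AluY  [0 diagnostics; 0 members]
#>   AluYa1_Pongo  [1 diagnostics; 1 members]
#>     AluYa1a2_Pongo  [2 diagnostics; 4 members]
#>       AluYa1a2a2_Pongo  [2 diagnostics; 4 members]
head(res$dating[, c("locus_id", "k_cpg", "k_noncpg", "t_hat_myr",
                    "frequency", "order_rank")])
#>   locus_id k_cpg k_noncpg t_hat_myr frequency order_rank
#> 1     L001     4        5  9.302326         1          1
#> 2     L002     2        5  7.235142         1          2
#> 3     L005     4        3  7.235142         1          3
#> 4     L004     3        2  5.167959         1          4
#> 5     L003     1        3  4.134367         1          5
#> 6     L006     3        0  3.100775         1          6
```

Reading the output: the pipeline recovered a three-level subfamily
chain under the ancestral consensus; the dating table counts each
locus's private CpG/non-CpG substitutions and converts them to ages
(`t_hat_myr`), ordering loci oldest-first. The ranking table names, for
each subfamily, the members that could plausibly be its source — here
the deepest node's rank-1 candidate is a copy with zero private
variants and a high hallmark score (0.80):

```r
rk <- res$ranking_table
rk[!is.na(rk$rank), c("subfamily", "locus_id", "private_total",
                      "hallmark_score", "rank")]
#>          subfamily locus_id private_total hallmark_score rank
#> 1     AluYa1_Pongo     L001             9           0.45    1
#> 6 AluYa1a2a2_Pongo     L007             0           0.80    1
evaluate_recovery(ts, res)   # scored against the hidden truth
#> $source_rank       : NA          (the founder carried private variants
#>                                   and, at 6 Myr, no presence superset)
#> $tree_exact        : FALSE
#> $kendall_tau       : 0.714       (inferred vs true insertion order)
#> $n_loci            : 9
```

Report files (`hits.tsv`, `variants.tsv`, `subfamily_tree.txt`/`.nwk`,
`ranking.tsv`, `hallmarks.tsv`, `dating.tsv`, `run.log`) are written
under `out_dir`; identical seed and configuration reproduce them
byte-for-byte.

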
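# Bundled fixtures (all synthetic)

No sequence or genotype data were deposited for the study system these
fixtures emulate; each file is a synthetic reconstruction of printed
summary values, built so the pipeline's arithmetic can be exercised.

- `synthetic_orangutan_genotypes.tsv` — a 37-animal diploid insertion
  genotype panel over eight loci; genotype counts are chosen so the
  allele frequencies reproduce the published panel values
  (e.g. 40/74 = 0.5405, 6/74 = 0.0811), with three fixed loci.
- `synthetic_ye5_species_distribution.tsv` — species-distribution census
  of a 118-member subfamily (counts per distribution class).
- `synthetic_secondary_source_tails.fa` — two poly(A) tail regions: a
  27-nt tail disrupted by a double cytosine after 10 A's and a third
  cytosine after 16 A's, and a perfect 30-nt tail; both followed by a
  TTTT Pol III terminator and flank.
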
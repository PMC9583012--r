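# barcodekey

Distance-based species discrimination from DNA barcodes, and
species-diagnostic SNP keys from genotyping-by-sequencing (GBS) calls.

## The problem

DNA barcoding assigns specimens to species from short standardized loci
(for plants typically ITS2, *matK*, *rbcL* and intergenic spacers such
as *psbM-petN*). Identification works when a *barcoding gap* exists:
the distribution of pairwise distances between conspecific accessions
must sit clearly below the distribution between heterospecific ones.
For closely related species connected by gene flow — the motivating case
here is wild wheat relatives in the genus *Aegilops* — the gap collapses,
barcodes fail, and genome-wide SNPs are needed to build a molecular
classification key instead.

`barcodekey` implements that complete workflow for R users:

- **K2P distances and the barcoding gap.** Pairwise
  Kimura two-parameter distances with pairwise deletion of gaps/`N`:
  with transition proportion *P* and transversion proportion *Q* over
  the comparable sites,
  *d* = −½·ln(1 − 2P − Q) − ¼·ln(1 − 2Q).
  Intraspecific and interspecific distance distributions, their means
  and the intra/inter ratio, and binned histograms with an overlap
  flag.
- **Match-based identification.** Best match and best close match
  (nearest-neighbour assignment with an optional threshold, by default
  the 95th percentile of intraspecific distances), with
  correct/incorrect/ambiguous/no-match rates and a combined table over
  markers and marker combinations.
- **Tree-based identification.** Saitou–Nei neighbor joining on the K2P
  matrix (Studier–Keppler Q criterion, deterministic tie rule),
  column-bootstrap support, and monophyly scoring: a species is
  discriminated when its accessions form a single clade, i.e. one side
  of a bipartition of the unrooted tree. Externally inferred trees
  (e.g. ML trees in Newick) are scored by the same machinery.
- **Diversity statistics.** Segregating sites, nucleotide diversity π
  (mean per-site p-distance over pairs) and Tajima's
  D = (Π − S/a₁)/√(e₁S + e₂S(S−1)).
- **Diagnostic SNP keys from GBS.** Tassel-style site filtering
  (max major allele frequency 0.95, max missing 0.05, max heterozygous
  proportion 0.2), then screening: a site is species-diagnostic when at
  least one species' observed allele set is disjoint from the union of
  all other species' allele sets. Keys classify new samples by per-site
  votes. The published 30-SNP × 14-accession key for *Aegilops
  biuncialis* / *Ae. juvenalis* / *Ae. columnaris* ships as a text
  fixture (`aegilops_snp_fixture()`).
- **Pairwise Fst.** Nei Gst ((Ht − Hs)/Ht) and Weir–Cockerham θ for
  haploid (inbred, homozygote-coded) calls, multi-locus by ratio of
  sums, plus the island-model identity Nm = (1 − Fst)/(4·Fst).
- **Synthetic data.** A star-of-stars K2P sequence simulator and a
  Balding–Nichols GBS matrix simulator with planted diagnostic sites
  and a migration/admixture dial, so the whole pipeline is testable
  without external downloads.

## Worked example

```r
library(barcodekey)

cfg <- species_sim_config(n_species = 5, accessions_per_species = 4,
                          locus_lengths = c(ITS2 = 437, matK = 712),
                          intra_divergence = 0.002, inter_divergence = 0.012,
                          seed = 2026)
alns <- simulate_barcode_alignments(cfg)
report <- run_pipeline(alns, seed = 2026)
print(report)
#>       barcode aligned_length variable_characters     pi tajima_D mean_intra
#> 1        ITS2            437                  16 0.0091   -0.446     0.0014
#> 2        matK            712                  26 0.0088   -0.581     0.0017
#> 3 ITS2 + matK           1149                  42 0.0089   -0.553     0.0016
#>   mean_inter ratio nj_monophyly_rate
#> 1     0.0106 0.130                80
#> 2     0.0102 0.166                80
#> 3     0.0103 0.152               100
```

Each row is one barcode or combination: aligned length, variable
characters, nucleotide diversity, Tajima's D, mean intraspecific and
interspecific K2P distance, their ratio (small is good — a wide gap),
and the percentage of species recovered as monophyletic on the NJ tree.
Here the two-locus combination discriminates all 5 simulated species
(100%) while each single locus resolves 4 of 5 (80%).

The packaged *Aegilops* key:

```r
fx <- aegilops_snp_fixture()
key <- screen_diagnostic(fx$genotype)
key
#> Diagnostic SNP key: 30 sites separating 3 species (Ae. biuncialis,
#> Ae. juvenalis, Ae. columnaris)

res <- classify_sample(key, setNames(fx$genotype$calls["W-43", ],
                                     colnames(fx$genotype$calls)))
res$verdict
#> [1] "Ae. juvenalis"
res$votes
#> Ae. biuncialis  Ae. juvenalis Ae. columnaris
#>              0             12              0
```

All 30 published SNPs pass the disjoint-allele-set screen; accession
W-43 collects all 12 votes available at *Ae. juvenalis*-diagnostic
sites and none elsewhere.

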
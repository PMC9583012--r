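---
title: "Methods: barcoding-gap analysis and diagnostic SNP keys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcoding-gap analysis and diagnostic SNP keys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodekey)
```

This vignette documents the statistical methods implemented in
`barcodekey`, the assumptions behind them, the tunable parameters and
their defaults, and the design choices made where the design was
genuinely open.

## Distance model

All sequence comparisons use the Kimura two-parameter (K2P) model,
which distinguishes transitions (purine–purine, pyrimidine–pyrimidine)
from transversions. For a pair of aligned sequences the comparison is
restricted to sites where *both* characters are unambiguous bases —
*pairwise deletion* of gaps and `N`. With transition proportion $P$ and
transversion proportion $Q$ over the $n$ comparable sites,

$$d = -\tfrac{1}{2}\ln(1 - 2P - Q) - \tfrac{1}{4}\ln(1 - 2Q).$$

Assumptions: equal base frequencies, a single transition rate and a
single transversion rate, independence across sites. The correction is
undefined (saturated) when a log argument is non-positive; such pairs
are reported as `NA`, excluded from summaries and counted in a
diagnostics field (`n_undefined`) rather than silently capped —
substituting any finite value would bias the distance means.

**Why pairwise rather than complete deletion?** Plastid spacer regions
commonly carry long indels; complete deletion would discard those
columns for *every* pair, throwing away most of the signal in gappy
regions. Pairwise deletion keeps each pair's full comparable set and is
the default behaviour of the widely used distance software in this
field. The choice is recorded in the pipeline manifest
(`distance_model`).

## The barcoding gap

`distance_summary()` partitions all defined pairwise distances into
conspecific (intraspecific) and heterospecific (interspecific) sets.
The reported ratio is computed from the *unrounded* means; rounding (4
decimals for distances, 3 significant figures for the ratio) is applied
only at serialization, so no derived quantity is ever computed from a
formatted value. Species with a single accession contribute no
intraspecific pairs — they are not treated as zero, which would
artificially shrink the intraspecific mean. `barcoding_gap_histogram()`
bins both distributions on a common grid and flags overlap (any
intraspecific distance at least as large as some interspecific one),
the signature of a failing barcode.

## Match-based identification

*Best match* assigns each query the species of its nearest non-self
neighbour(s). Distance ties are handled by reporting the full tied set,
never by input order: the verdict is `correct` only if all tied
neighbours are conspecific, `incorrect` if all are heterospecific, and
`ambiguous` otherwise. *Best close match* additionally rejects queries
whose nearest distance exceeds a threshold (`no_match`); with an
infinite threshold it reduces exactly to best match, a property the
test suite asserts.

The threshold defaults to the **95th percentile of all intraspecific
distances**, with linear interpolation between order statistics
(`stats::quantile`, type 7). The percentile is a parameter and is
always echoed in the report, because published analyses rarely state
their cutoff and results can be sensitive to it.

Queries from singleton species are excluded from the rate denominators:
no conspecific match is achievable for them, so including them would
deflate the correct rate by an amount that says nothing about the
markers. Their outcomes are still listed.

## Tree-based identification

`nj_tree()` implements Saitou–Nei neighbor joining with the
Studier–Keppler criterion
$Q(i,j) = (n-2)\,d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)$.
Two numerical policies make it deterministic and safe:

- **Tie rule.** Equal $Q$ values are resolved by the lexicographically
  smallest $(i, j)$ pair over the current node ordering — determinism
  without hidden state.
- **Branch clamping.** Negative branch-length estimates are clamped to
  zero in the output; internal distance updates use the unclamped
  values, so on additive matrices the recovery is exact (the suite
  checks random 8-leaf additive matrices to $10^{-9}$).

A species is *discriminated* when its accessions form a single clade.
On an unrooted tree this is evaluated as a bipartition test: the
species' leaf set must be one side of some internal edge. This is
equivalent to rooted-clade monophyly for every rooting outside the
species' subtree, so the score is invariant to rerooting (asserted in
the tests against an independent rooted-clade oracle). Species with one
accession are trivially monophyletic; because published discrimination
percentages typically count them, the default `rate` includes all
species, and `rate_multi` (species with ≥ 2 accessions only) is
reported alongside. Bootstrap support resamples alignment columns with
replacement and counts how often each original bipartition recurs;
the seed is mandatory. Maximum-likelihood inference is out of scope —
ML trees produced elsewhere are read as Newick and scored identically.

## Diversity statistics

- **Segregating sites** $S$: columns with ≥ 2 distinct unambiguous
  bases. Indel columns never count — $S$ is substitutions-only, and
  indel variation should be tallied separately if needed.
- **Nucleotide diversity** $\pi$: the mean over pairs of (differences /
  comparable sites) under pairwise deletion, i.e. the mean per-site
  p-distance.
- **Tajima's D** uses the classical constants
  $a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2$ and
  $D = (\Pi - S/a_1)\big/\sqrt{e_1 S + e_2 S(S-1)}$, where $\Pi$ is the
  mean pairwise difference *count*. With missing data each pair's count
  is rescaled by $L_\mathrm{eff}/\text{comparable}$, with
  $L_\mathrm{eff}$ the number of sites where at least two sequences
  carry bases — this keeps $\Pi$ and $S$ on the same site basis and
  reduces to the raw count on complete alignments. $D$ is undefined for
  $S = 0$ or $n < 4$ and returns a reason rather than a number.
  Significance (beta-distribution p-values) is not computed.

## The diagnostic SNP key

GBS calls enter as one character per accession and site: a base for
homozygotes, an IUPAC ambiguity letter for heterozygotes, `.` for
missing.

- **Site statistics.** Allele counts are taken over non-missing,
  non-ambiguous calls; the major allele frequency is the top count over
  that denominator (so frequencies sum to 1); the heterozygous fraction
  is the share of ambiguity calls among non-missing calls; the missing
  fraction is over all accessions. Frequencies are formatted by
  rounding half away from zero to 5 decimals, matching the convention
  of printed key tables.
- **Filtering** retains sites with major allele frequency ≤ 0.95,
  missing fraction ≤ 0.05 and heterozygous fraction ≤ 0.20 (all three
  are parameters). The filter is idempotent and leaves the accession
  set untouched.
- **Screening rule.** A site is diagnostic when at least one species'
  observed allele set is *disjoint* from the union of all other
  species' allele sets. This is deliberately the weakest rule that
  still guarantees single-site recognition of the diagnosed species: it
  tolerates within-species polymorphism (e.g. a third allele private to
  one accession of a non-diagnosed species) without discarding the
  site. Heterozygous calls are expanded to both constituent alleles
  before the disjointness test — a het call genuinely carries both —
  and missing calls are ignored rather than treated as an allele.
- **Classification** gives each key site one vote: any diagnosed
  species whose private allele set contains the called allele gains a
  vote, and the verdict is the plurality species; ties and zero votes
  are `unclassified`, never a guess.

## Pairwise Fst

Accessions of self-pollinating species are effectively inbred lines and
the key tables show pure homozygous codes, so calls are treated as
**haploid alleles**; heterozygous calls are excluded at that accession
and locus. Two estimators are provided:

- `nei_gst`: $F_{st} = (H_t - H_s)/H_t$ per locus, with $H_t$ the
  expected heterozygosity of the unweighted pooled frequencies and
  $H_s$ the mean within-species expected heterozygosity;
- `weir_cockerham`: the haploid variance-components $\theta$
  (MSP/MSG analysis of variance of allele frequencies).

Multi-locus values combine loci by **ratio of sums**, the standard
small-bias convention; the mean of per-locus ratios is also reported
for transparency because published analyses do not always state which
convention their software applied. Loci where the estimator is
undefined (a species without calls, or $H_t = 0$) are excluded and
counted. Raw (possibly negative) and clamped-to-$[0,1]$ multi-locus
values are both kept. `fst_migration_consistency()` converts an Fst to
the Wright island-model equilibrium $N_m = (1-F_{st})/(4F_{st})$ — a
naive closed-form diagnostic, not a coalescent migration estimate.

## What the synthetic data emulates

`simulate_barcode_alignments()` evolves each locus along a
**star-of-stars** genealogy: a root sequence diverges into species
ancestors (branch $(\delta_\mathrm{inter}-\delta_\mathrm{intra})/2$),
each accession diverges from its ancestor (branch
$\delta_\mathrm{intra}/2$), all under the K2P process with
transition/transversion rate ratio $\kappa$, so the expected pairwise
divergence is $\delta_\mathrm{intra}$ within and
$\delta_\mathrm{inter}$ between species below saturation. Star
genealogies were chosen over random coalescent trees as the default
because they make the expected intra/inter distances available in
closed form, which is what the calibration checks need; a neutral
Kingman coalescent sampler (`simulate_coalescent_alignment()`) is
provided separately for calibrating Tajima's D. Admixture is modelled
as whole-locus lineage replacement — with probability $m$ an accession
draws its sequence from another species' ancestor — mirroring
horizontal transfer of an entire barcode region; events are recorded as
truth metadata.

Defaults describe a genus-scale survey: 17 species, 2–9 accessions each
(84 total), loci of 437/712/582/688 bp, $\delta_\mathrm{intra}=0.002$,
$\delta_\mathrm{inter}=0.01$, $\kappa=2$ — values on the scale typical
of plant barcoding studies of congeneric species.

`simulate_genotype_matrix()` plants three site classes: diagnostic
sites (a private allele in one species, with an optional third-allele
exception in another), background sites whose per-species allele
frequencies follow the **Balding–Nichols** beta model around a shared
ancestral frequency (differentiation parameter `background_fst`,
default 0.13, the scale at which congeneric outcrossing relatives
typically sit) mixed toward the across-species mean by a migration
proportion $m$, and monomorphic sites. Background sites are forced to
share their global major allele across all species, so they can never
satisfy the diagnosticity rule — this makes "the screen recovers
exactly the planted sites" an exact property rather than a
probabilistic one. Missing and heterozygous calls are injected only
outside the diagnostic class so the planted truth stays clean.

What the generators do *not* emulate: recombination within loci, indel
evolution, rate variation across sites and lineages, read-level GBS
error, and non-star coalescent genealogies within species. Passing
tests therefore demonstrate correctness of the estimators and decision
rules under the stated models, not robustness to every feature of real
data.

## Check sizes and numerical conventions

The package's self-checks run at deliberately small, fixed sizes chosen
to give stable statistics: oracle-equivalence suites use ≥ 20 random
instances of 4–10 sequences × 150–500 sites; NJ consistency uses random
8-leaf additive matrices (recovery to $10^{-9}$); Tajima's D
calibration uses 500 neutral coalescent replicates at $n=25$,
$\theta=5$ (mean D within ±0.15 of zero); diversity recovery uses
$n=20$, $L=5000$ (within 15%); Fst–migration monotonicity uses 50
replicates per migration level. Every stochastic component takes an
explicit integer seed; fixed seed implies byte-identical output.

Other conventions: positions are 1-based in all I/O; sequences are
canonicalized to upper case, with non-`ACGT-N` codes mapped to `N`;
accessions missing from a locus are padded with `N` (not gaps) during
concatenation so the padding reads as missing data rather than indels;
and all printed roundings are pure formattings of unrounded stored
values.

## Known limitations

- The K2P model ignores base-composition bias; no other distance
  models (JC69, TN93) or model selection are provided.
- Monophyly scoring applies no bootstrap-support threshold; a species
  can count as discriminated on a weakly supported clade.
- The diagnostic screen assumes the observed allele sets are complete;
  with very few accessions per species, unsampled polymorphism can
  make a site look private. The key should be rebuilt as accession
  panels grow.
- Fst on a handful of loci that pass the disjointness screen is, by
  construction, inflated relative to genome-wide panels; use the full
  filtered site set for differentiation estimates.
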
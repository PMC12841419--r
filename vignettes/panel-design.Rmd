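---
title: "Designing targeted SNP panels and identifying cultivars with panelkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing targeted SNP panels and identifying cultivars with panelkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelkit)
```

## The problem

Targeted genotyping-by-sequencing panels ("liquid-phase chips") genotype
a crop at a fixed set of a few thousand SNPs enriched by in-solution
hybridization probes. A good panel must satisfy two competing demands:
every locus must admit a capture probe (a sequence-context property),
and the loci together must cover the genome evenly while over-weighting
sites of known functional or trait relevance. Once built, the panel's
genotype calls drive cultivar identification: telling apart closely
related breeding material and recognising F~1~ hybrids.

`panelkit` implements that whole chain on standard inputs (soft-masked
FASTA, GFF3, VCF) and ships simulators that generate every input with
known ground truth, so each stage is validated against construction
rather than against irreproducible external data.

## Variant QC

Hard site filters remove records with QUAL < 30, QD < 2.0, FS > 60.0 or
MQ < 40.0. These removal conditions are strict inequalities, so a record
sitting exactly on a threshold (QUAL = 30, FS = 60.0, ...) is **kept**;
the boundary semantics are pinned by tests. Records whose annotation is
absent fail that criterion by default — a capture panel wants
high-confidence sites, and an unannotated site is not that — with
`missing_fails = FALSE` available for permissive runs. Records with
unparseable annotations are rejected and reported, never silently
passed.

Population filters then require call rate ≥ 0.8 (the VCFtools
`--max-missing 0.8` meaning: at least 80% of samples genotyped — stated
explicitly because the flag name invites the opposite reading), minor
allele frequency ≥ 0.01 computed over non-missing genotypes only, and
exactly two **observed** alleles. Allelism is judged from the genotypes,
not the ALT column: a multi-ALT record where only one alternate allele
is actually observed still counts those observed alleles. Rejections
are attributed to the first failing criterion in the fixed order
QUAL → QD → FS → MQ → call rate → MAF → allelism, so filter reports are
deterministic and partition the input exactly.

## Probe feasibility

Each candidate SNP is judged on its 201 bp context (100 bp flanks plus
the site). Four screens, all of which are reported (not just the first
failure):

* **Single-copy**: the context must place exactly once in the genome.
  The search is a self-contained k-mer seed (k = 13, every query
  offset, both strands) with ungapped extension; a placement qualifies
  when identity > 60% over > 60% coverage, read as strict inequalities.
  These published cutoffs are unusually permissive for a single-copy
  test; they are implemented as stated, and both are arguments. Because
  seeding needs one exact shared 13-mer, qualifying placements barely
  above 60% identity could in principle be missed; in practice
  repeat-derived duplications are far more similar than that, and the
  test suite checks the search against a brute-force sliding-window
  oracle.
* **GC content**: (G+C)/(A+C+G+T) of the full context must lie in
  [0.40, 0.60] inclusive; N bases leave the denominator, and an all-N
  context fails. The window is the full context rather than the flanks
  alone — the probe hybridizes across the site — and is configurable.
* **Repeats and Ns**: any soft-masked base in the context fails, the
  reference's own repeat annotation being the primary signal; a
  homopolymer run ≥ 10 bp is a backstop for unmasked synthetic genomes.
  Any N fails.
* **Nearby InDels**: an InDel of length |len(ref) − len(alt)| > 5
  (strictly) overlapping [pos − 100, pos + 100] fails the locus. With
  no InDel set supplied the criterion passes vacuously, with a warning.

Loci whose context is truncated by a chromosome end cannot carry a
full-length probe and fail outright.

## Functional annotation and impact ranking

Regions are assigned with genic precedence — CDS exon, then UTR, then
intron, then strand-aware upstream/downstream within a 5 kb window (the
convention of common variant annotators; configurable), then
intergenic — with overlapping genes resolved to the strongest class and
remaining ties to the lexicographically smaller gene id. Coding effects
are computed by rebuilding the affected codon strand-aware and
translating under the standard genetic code, with the initiator ATG and
stop codons special-cased. The impact order used for selection is
fixed: start/stop variations, missense, synonymous, UTR (and non-coding
exon), upstream/downstream, intron, intergenic.

## Windowed panel integration

Chromosomes are tiled into fixed, non-overlapping 200 kb windows
anchored at 0, the last partial tile included. Tiles — not a sliding
step — are used because one marker per window over a multi-Gb genome is
only consistent with a partition; the window size is a first-class
parameter since its published value is a calibration, not a derivation.
Per window, the trait-locus-priority rule applies: if any
feasibility-passing trait-associated (GWAS) locus falls in the window,
**all** of them are retained and the window takes no resequencing
locus. Retaining all of them (rather than one) is the only reading that
reconciles a ~5k trait-locus set with a ~11k-window genome and the
observed chromosome-level density skew toward trait-rich chromosomes.
Trait loci that fail feasibility are excluded before this rule, so a
window whose only trait loci failed falls through to the resequencing
rule: restrict to feasibility-passing loci, then to the minimal impact
rank, then draw one uniformly. All draws come from a single RNG stream
seeded once, with windows visited in (chromosome, start) order, so a
panel is bit-reproducible from its recorded seed.

Two distance conventions coexist in panel summaries and are kept
separate deliberately: `avg_distance_kb` = chromosome length ÷ locus
count (the convention of published panel tables), while
`spacing_distribution()` bins actual adjacent gaps within chromosomes.
Densities and distances are reported at 2 decimals, percentages at 1,
rounded half-up (base R rounds half to even, which published tables do
not).

## Identification statistics

Genetic similarity between two samples is the fraction of loci with
identical genotype codes — a heterozygote matches neither homozygote —
and Het is a sample's fraction of heterozygous calls. The published
definitions divide by "the total number of SNPs analysed", which is
ambiguous under missingness; the default here analyses the non-missing
loci (pairwise-complete for similarity, per-sample non-missing for
Het), and a `strict` policy dividing by the full panel count (missing
counted as mismatch/non-het) is provided since neither reading can be
ruled out. An `ibs` mode scoring allele sharing (0/0.5/1) is available
but non-default. The decision thresholds — similarity ≥ 0.90 for
close-relative flagging and Het ≥ 0.10 for hybrid calls — are
configurable defaults.

The p-distance 1 − similarity feeds classical neighbor joining
(Saitou–Nei Q criterion), implemented in-package so that its numerical
conventions are pinned: Q-ties resolve to the smallest index pair;
negative branch estimates are clamped to zero with the deficit moved to
the sister branch (preserving the pair's path length) and counted in an
`n_clamped` attribute. Additive distances are inverted exactly, which
the tests verify on 4- and 8-taxon trees against an independent NJ
implementation. Bootstrap support resamples loci with replacement,
rebuilds distance and tree per replicate, and reports bipartition
frequencies of the full-data tree. PCA mean-imputes missing codes per
locus, centres, and eigendecomposes without variance scaling (no
frequency standardisation is applied by default, as none is specified
for the published analysis); component signs follow the
largest-loading-positive convention.

## What the simulators emulate — and what they do not

`simulate_genome()` produces multi-chromosome genomes with a target
base composition, planted soft-masked tracts (the repeat signal),
optional N runs, and genes with valid structure (ATG start, in-frame
stop, no internal stop, UTRs, introns; half on the minus strand), all
with truth tables. `simulate_founders()` draws fully inbred lines with
per-locus alternate-allele frequencies from a configurable sampler
(default uniform on [0.05, 0.5], a flat stand-in for the folded
frequency spectrum of a diversity panel). `cross_f1()` makes the
construction identity Het(F₁) = parental divergence *d* exact, and
`breed_pedigree()` simulates gamete transmission per generation, so
E[Het(BC~n~F~m~)] = *d*·(1/2)^n^·(1/2)^(m−1)^ — the BC~n~F~m~ notation
is read as n backcrosses followed by m − 1 selfing rounds from the
BC~n~F~1~.

Loci segregate independently: every statistic in the identification
layer is a per-locus proportion whose expectation is linkage-free, so a
recombination map would add variance modelling but nothing testable
here. That is the main idealisation — real chromosomes transmit linked
blocks, so real pedigree Het varies more between lines than the
binomial spread these simulations show. The simulators also stay at the
genotype-code level (no reads, no capture efficiency, no allele
dropout), and genome base composition is i.i.d. rather than isochore-
structured. Consequently, passing tests demonstrate the correctness of
the statistics and selection logic, not that any particular organism's
panel would reproduce specific published Het ranges, which reflect that
crop's own divergence structure.

## Numerical choices and degenerate inputs

* Rounding: half-up at the stated precisions, via an epsilon-nudged
  `floor(x·10^d + 0.5)`.
* All-missing sites get call rate 0 and an undefined, flagged MAF; they
  fail the population filter. Sample pairs with no shared non-missing
  locus get a flagged `NA` similarity.
* An empty candidate set or a window with no eligible candidate yields
  an empty (logged) result, never an error mid-pipeline.
* `neighbor_joining()` refuses n < 3 and non-finite distances.
* Genotype codes are validated at construction (`geno_matrix()`
  rejects anything outside {0, 1, 2, NA}).
* Seeds: every stochastic function takes an explicit `seed` (NULL uses
  the caller's RNG stream); seeded evaluation saves and restores
  `.Random.seed`, so library calls never perturb a user's stream.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run at desk scale, chosen so
the full suite completes in a few minutes: feasibility agreement with
the brute-force oracle on 1000 loci over a 48 kb genome; selection-rule
frequency checks over 3000 seeded draws; F₁ and BC₃F₇ pedigrees at
50,000 loci with 200 replicate lines (mean Het compared with *d*/512
within three standard errors); bootstrap determinism at 100–200
replicates on 8–10 samples; and the published 26-row panel table
recomputed exactly from its printed columns. One caveat found while
pinning that table: its printed per-chromosome average distances were
evidently computed from unrounded chromosome lengths, so recomputing
from the printed 2-decimal Mb lengths reproduces them only to the
±0.005 Mb input quantisation (≤ 0.03 kb); the density column and the
genome-wide averages reproduce exactly.

## Limitations

Probe thermodynamics (melting temperature, hairpins,
cross-hybridization) are outside the feasibility model, as are
InDel-effect annotation, splice-site effects, model-based ancestry
estimation, and read-level capture simulation. The uniqueness search is
ungapped; a duplication interrupted by large indels would be seen as
separate shorter placements.
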
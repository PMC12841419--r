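# panelkit

Toolkit for designing targeted SNP genotyping panels — the marker sets
behind in-solution ("liquid-phase") capture arrays used for crop
cultivar identification and marker-assisted selection — and for the
downstream identification statistics those panels are genotyped with.

Such a panel (for example, a ~13,000-locus array for upland cotton,
*Gossypium hirsutum* L.) is assembled from two locus sources: curated
trait-associated SNPs from association studies, and polymorphic sites
from population resequencing. `panelkit` implements the full design
cascade and the application layer:

1. **Variant QC** (`apply_hard_filters`, `population_filter`) — site
   hard filters on the standard annotations (remove records with
   QUAL < 30, QD < 2.0, FS > 60.0 or MQ < 40.0; boundary values are
   kept), then population filters (call rate ≥ 0.8, minor-allele
   frequency ≥ 0.01, exactly two observed alleles).
2. **Probe feasibility** (`assess_feasibility`) — a capture probe is
   designable for a SNP iff its 100 bp-flank context is single-copy in
   the genome (exactly one ungapped placement with identity > 60% and
   coverage > 60%, found by a built-in seed-and-extend search), has GC
   in [40%, 60%], contains no soft-masked repeat bases, homopolymer
   runs or Ns, and has no InDel > 5 bp within the flanks.
3. **Functional annotation** (`annotate_loci`, `impact_rank`) — region
   class against gene models (exon > UTR > intron > upstream/downstream
   > intergenic, 5 kb flank window) and coding effect from rebuilt
   codons, ranked start/stop variants < missense < synonymous < UTR <
   up/downstream < intron < intergenic.
4. **Panel integration** (`make_windows`, `select_panel`) — the genome
   is tiled into 200 kb windows; windows containing trait-associated
   loci retain all of them, other windows contribute the single
   feasibility-passing resequencing SNP with the strongest functional
   impact (ties broken by one seeded uniform draw). Summary statistics
   (`panel_density_stats`, `spacing_distribution`) follow the published
   conventions: density = n/length (SNPs/Mb), average distance =
   length/n (kb), spacing histogram over (0,40], (40,80], (80,120],
   (120,200], (200,300], (300,∞) kb.
5. **Identification layer** (`similarity_matrix`, `heterozygosity`,
   `neighbor_joining`, `bootstrap_support`, `genotype_pca`) — genetic
   similarity = fraction of loci with identical diploid genotype codes
   (pairs at ≥ 90% flag sister lines, backcross material and same-row
   plants); individual heterozygosity Het = fraction of heterozygous
   calls (Het ≥ 10% flags F₁ hybrids); p-distance = 1 − similarity
   feeds a classical neighbor-joining tree with locus-resampling
   bootstrap, plus genotype PCA.
6. **Simulators** (`simulate_genome`, `simulate_founders`, `cross_f1`,
   `breed_pedigree`, `inject_noise`) — genomes with genes and
   soft-masked repeats, inbred founder populations, F₁ and
   backcross-selfing (BCₙFₘ) pedigrees, and noise injection, all
   seed-deterministic with truth tables, so every stage above is
   testable without external data. For fully inbred parents diverging
   at a fraction *d* of loci, Het(F₁) = *d* exactly and
   E[Het(BCₙFₘ)] = *d*·(1/2)ⁿ·(1/2)^(m−1).

## Worked example

```r
library(panelkit)

sim <- simulate_genome(n_chromosomes = 2, chrom_length = 200000,
                       genes_per_chrom = 6, repeat_fraction = 0.08, seed = 42)
sim$genome
#> genome_ref: 2 sequence(s), 400,000 bp, 8.0% soft-masked

set.seed(42)
loci <- data.frame(chrom = sample(c("chr1", "chr2"), 300, TRUE),
                   pos = sample(199000L, 300) + 500L)
feas <- assess_feasibility(sim$genome, loci)
table(feas$passed)
#> FALSE  TRUE
#>   168   132

ann <- annotate_loci(data.frame(loci, alt = "A"), sim$models, sim$genome)
region_summary(ann)
#>   region_class   n  pct
#> 1   downstream  42 14.0
#> 2         exon   3  1.0
#> 3   intergenic 213 71.0
#> 4       intron   2  0.7
#> 5     upstream  40 13.3

cand <- data.frame(loci, source = "RESEQ", trait_category = "none",
                   impact_rank = ann$impact_rank, feasible = feas$passed)
panel <- select_panel(cand, make_windows(sim$genome$lengths, 10000), seed = 1)
panel
#> panel: 38 loci on 2 chromosome(s); 0 trait-associated,
#>        38 resequencing-derived (seed 1)

panel_density_stats(panel, sim$genome$lengths / 1e6)
#>   chrom length_mb n_snps density avg_distance_kb
#> 1  chr1       0.2     18      90           11.11
#> 2  chr2       0.2     20     100           10.00

founders <- simulate_founders(n_samples = 6, n_loci = 2000, seed = 42)$geno
f1 <- cross_f1(unclass(founders)[1, ], unclass(founders)[2, ])
heterozygosity(rbind(unclass(founders)[1:2, ], F1 = f1))
#>   sample    het n_effective      call
#> 1   F001 0.0000        2000 pure_line
#> 2   F002 0.0000        2000 pure_line
#> 3     F1 0.3455        2000    hybrid
```

300 random candidate loci are screened against the four probe criteria
(132 are designable here: this toy genome is deliberately dense in
repeats), annotated by genomic region (intergenic sites dominate, as on
a real genome), and integrated one marker per 10 kb window. The F₁ of
two fully inbred founders is heterozygous exactly where its parents
differ (34.55% of loci), far above the 10% hybrid threshold, while the
founders themselves sit at 0%.

A command-line wrapper for shell pipelines is installed at
`inst/scripts/panel` (subcommands `qc-vcf`, `probe-screen`, `annotate`,
`build`, `identify`, `simulate`).

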
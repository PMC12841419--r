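# hand-built two-gene fixture: a plus-strand and a minus-strand gene with
# UTRs and a two-exon CDS, written through GFF3 to exercise the parser
make_models_fixture <- function() {
  gff <- c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1001\t1500\t.\t+\t.\tID=geneA",
    "chr1\ttest\tmRNA\t1001\t1500\t.\t+\t.\tID=geneA.t1;Parent=geneA",
    "chr1\ttest\texon\t1001\t1220\t.\t+\t.\tID=geneA.e1;Parent=geneA.t1",
    "chr1\ttest\texon\t1301\t1500\t.\t+\t.\tID=geneA.e2;Parent=geneA.t1",
    "chr1\ttest\tfive_prime_UTR\t1001\t1050\t.\t+\t.\tID=geneA.u5;Parent=geneA.t1",
    "chr1\ttest\tCDS\t1051\t1220\t.\t+\t.\tID=geneA.c1;Parent=geneA.t1",
    "chr1\ttest\tCDS\t1301\t1430\t.\t+\t.\tID=geneA.c2;Parent=geneA.t1",
    "chr1\ttest\tthree_prime_UTR\t1431\t1500\t.\t+\t.\tID=geneA.u3;Parent=geneA.t1",
    "chr1\ttest\tgene\t20001\t20400\t.\t-\t.\tID=geneB",
    "chr1\ttest\tmRNA\t20001\t20400\t.\t-\t.\tID=geneB.t1;Parent=geneB",
    "chr1\ttest\texon\t20001\t20400\t.\t-\t.\tID=geneB.e1;Parent=geneB.t1",
    "chr1\ttest\tfive_prime_UTR\t20351\t20400\t.\t-\t.\tID=geneB.u5;Parent=geneB.t1",
    "chr1\ttest\tCDS\t20051\t20350\t.\t-\t.\tID=geneB.c1;Parent=geneB.t1",
    "chr1\ttest\tthree_prime_UTR\t20001\t20050\t.\t-\t.\tID=geneB.u3;Parent=geneB.t1")
  path <- withr::local_tempfile(fileext = ".gff3",
                                .local_envir = parent.frame())
  writeLines(gff, path)
  read_gene_models(path)
}

test_that("region classification follows genic precedence and strand-aware flanks", {
  models <- make_models_fixture()
  loci <- data.frame(
    chrom = "chr1",
    pos = c(1100,    # CDS segment
            1040,    # 5' UTR
            1450,    # 3' UTR
            1260,    # between exons: intron
            900,     # 101 bp before a plus gene: upstream
            1900,    # 400 bp past its end: downstream
            23000,   # 2.6 kb beyond a minus gene's rightmost base: upstream
            19000,   # ~1 kb before the minus gene's leftmost: downstream
            120000)) # far from everything
  cls <- classify_region(loci, models)
  expect_equal(as.character(cls),
               c("exon", "utr5", "utr3", "intron", "upstream", "downstream",
                 "upstream", "downstream", "intergenic"))
})

test_that("every locus gets exactly one region class", {
  models <- make_models_fixture()
  loci <- data.frame(chrom = "chr1", pos = seq(1, 30000, by = 37))
  cls <- as.character(classify_region(loci, models))
  expect_equal(length(cls), nrow(loci))
  expect_true(all(cls %in% c("intergenic", "upstream", "downstream", "exon",
                             "intron", "utr5", "utr3")))
})

# genome whose geneA CDS is a chosen codon string, so effects are knowable
make_coding_fixture <- function(cds, strand = "+") {
  utr <- strrep("ACGT", 15)          # 60 bp per UTR
  gene_plus <- paste0(utr, cds, utr)
  gene <- if (strand == "+") gene_plus else oracle_revcomp(gene_plus)
  left <- random_seq(500, seed = 21)
  s <- paste0(left, gene, random_seq(500, seed = 22))
  glen <- nchar(gene)
  gstart <- 501L
  gend <- gstart + glen - 1L
  cds_local <- c(61L, 60L + nchar(cds))
  cds_chrom <- if (strand == "+") gstart + cds_local - 1L
    else c(gstart + glen - cds_local[2], gstart + glen - cds_local[1])
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = gstart,
                      end = gend, strand = strand)
  feats <- data.frame(
    gene_id = "g1", chrom = "chr1",
    start = c(gstart, cds_chrom[1]),
    end = c(gend, cds_chrom[2]),
    strand = strand, type = c("exon", "CDS"))
  list(genome = genome_ref(c(chr1 = s)),
       models = gene_models(genes, feats),
       cds_chrom = cds_chrom)
}

test_that("coding effects are classified from rebuilt codons", {
  cds <- paste0("ATG", "GGA", "TAC", "CCT", "TAA")
  fx <- make_coding_fixture(cds)
  at <- function(codon, offset) fx$cds_chrom[1] + (codon - 1L) * 3L + offset - 1L
  # wobble GGA -> GGG stays glycine
  expect_equal(coding_effect("chr1", at(2, 3), "G", fx$models, fx$genome),
               "synonymous")
  # ATG -> ATA kills the start
  expect_equal(coding_effect("chr1", at(1, 3), "A", fx$models, fx$genome),
               "start_lost")
  # TAC -> TAA gains a stop
  expect_equal(coding_effect("chr1", at(3, 3), "A", fx$models, fx$genome),
               "stop_gained")
  # TAA -> TAC loses the stop
  expect_equal(coding_effect("chr1", at(5, 3), "C", fx$models, fx$genome),
               "stop_lost")
  # CCT -> CAT is missense
  expect_equal(coding_effect("chr1", at(4, 2), "A", fx$models, fx$genome),
               "missense")
})

test_that("coding effects survive reflection to the minus strand", {
  cds <- paste0("ATG", "GGA", "TAC", "CCT", "TAA")
  plus <- make_coding_fixture(cds, "+")
  minus <- make_coding_fixture(cds, "-")
  # the same CDS-local edit, addressed through each strand's coordinates
  cases <- list(list(codon = 2, off = 3, alt = "G", want = "synonymous"),
                list(codon = 1, off = 3, alt = "A", want = "start_lost"),
                list(codon = 3, off = 3, alt = "A", want = "stop_gained"))
  for (cs in cases) {
    p_pos <- plus$cds_chrom[1] + (cs$codon - 1L) * 3L + cs$off - 1L
    expect_equal(coding_effect("chr1", p_pos, cs$alt, plus$models,
                               plus$genome), cs$want)
    cds_local <- (cs$codon - 1L) * 3L + cs$off
    m_pos <- minus$cds_chrom[2] - cds_local + 1L
    m_alt <- oracle_revcomp(cs$alt)
    expect_equal(coding_effect("chr1", m_pos, m_alt, minus$models,
                               minus$genome), cs$want)
  }
})

test_that("impact ranking is the documented total order", {
  expect_lt(impact_rank("exon", "start_lost"), impact_rank("exon", "missense"))
  expect_lt(impact_rank("exon", "missense"), impact_rank("exon", "synonymous"))
  expect_lt(impact_rank("exon", "synonymous"), impact_rank("utr5"))
  expect_equal(impact_rank("utr5"), impact_rank("utr3"))
  expect_lt(impact_rank("utr3"), impact_rank("upstream"))
  expect_equal(impact_rank("upstream"), impact_rank("downstream"))
  expect_lt(impact_rank("downstream"), impact_rank("intron"))
  expect_lt(impact_rank("intron"), impact_rank("intergenic"))
  expect_equal(impact_rank("intergenic"), impact_rank("intergenic"))
  # stop variants sit with start variants at the top
  expect_equal(impact_rank("exon", "stop_gained"), impact_rank("exon", "start_lost"))
})

test_that("region summaries reproduce construction counts and published shares", {
  # published panel counts: intergenic/upstream/downstream shares
  counts <- c(intergenic = 8361, upstream = 2814, downstream = 1707,
              exon = 414, intron = 205, utr = 70)
  rs <- region_summary(counts)
  expect_equal(rs$pct[rs$region_class == "intergenic"], 61.6)
  expect_equal(rs$pct[rs$region_class == "upstream"], 20.7)
  expect_equal(rs$pct[rs$region_class == "downstream"], 12.6)
  expect_lt(abs(sum(rs$pct) - 100), 0.1 * length(counts))
  # single-locus panel: one class at 100%
  one <- region_summary(data.frame(region_class = "intron"))
  expect_equal(one$pct, 100)
  # synthetic panel with known placement
  models <- make_models_fixture()
  loci <- data.frame(chrom = "chr1",
                     pos = c(rep(1100, 4), rep(1260, 3), rep(120000, 3)))
  ann <- annotate_loci(loci, models)
  rs2 <- region_summary(ann)
  expect_equal(rs2$n[match(c("exon", "intron", "intergenic"),
                           rs2$region_class)], c(4L, 3L, 3L))
  expect_equal(rs2$pct[rs2$region_class == "exon"], 40)
})

test_that("a CDS with length not divisible by three warns and yields no effect", {
  fx <- make_coding_fixture(paste0("ATG", "GGA", "TA"))  # 8 bp CDS
  expect_warning(
    eff <- coding_effect("chr1", fx$cds_chrom[1] + 4L, "G", fx$models,
                         fx$genome),
    "divisible")
  expect_equal(eff, "none")
})
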
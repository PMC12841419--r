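REGION_CLASSES <- c("intergenic", "upstream", "downstream", "exon",
                    "intron", "utr5", "utr3")
EFFECT_CLASSES <- c("synonymous", "missense", "start_lost", "stop_gained",
                    "stop_lost", "noncoding", "none")

#' Classify loci into genomic-region classes
#'
#' Each locus receives exactly one class by precedence: coding exon
#' (`exon`) > `utr5`/`utr3` > `intron` (inside a gene span but outside
#' its exons) > `upstream`/`downstream` (within `flank_window` of a
#' gene, strand-aware) > `intergenic`. Overlapping genes: the most
#' genic class wins, ties broken by the lexicographically smaller
#' gene id. A locus flanked by two genes is assigned to the nearer
#' one (distance ties resolve to upstream).
#'
#' @param loci data.frame with `chrom`, `pos`.
#' @param models a [gene_models] object.
#' @param flank_window upstream/downstream window in bp (default 5000,
#'   the convention of common variant annotators).
#' @return character vector of region classes, one per locus, with the
#'   assigned gene id as attribute `gene_id` (`NA` for intergenic).
#' @export
classify_region <- function(loci, models, flank_window = 5000) {
  pts <- GenomicRanges::GRanges(loci$chrom, IRanges::IRanges(loci$pos, loci$pos))
  n <- length(pts)
  cls <- rep("intergenic", n)
  gene <- rep(NA_character_, n)
  prio <- c(exon = 1, utr5 = 2, utr3 = 2, intron = 3)
  assign_hits <- function(gr, label) {
    if (length(gr) == 0) return()
    ov <- GenomicRanges::findOverlaps(pts, gr, ignore.strand = TRUE)
    for (h in seq_along(ov)) {
      i <- S4Vectors::queryHits(ov)[h]
      gid <- gr$gene_id[S4Vectors::subjectHits(ov)[h]]
      cur <- cls[i]
      better <- !(cur %in% names(prio)) || prio[[label]] < prio[[cur]] ||
        (prio[[label]] == prio[[cur]] &&
           (is.na(gene[i]) || gid < gene[i]))
      if (better) { cls[i] <<- label; gene[i] <<- gid }
    }
  }
  # genic classes, weakest first so stronger labels overwrite
  gspan <- models$genes
  if (length(gspan)) {
    ov <- GenomicRanges::findOverlaps(pts, gspan, ignore.strand = TRUE)
    for (h in seq_along(ov)) {
      i <- S4Vectors::queryHits(ov)[h]
      gid <- gspan$gene_id[S4Vectors::subjectHits(ov)[h]]
      if (cls[i] == "intergenic" || (cls[i] == "intron" && gid < gene[i])) {
        cls[i] <- "intron"; gene[i] <- gid
      }
    }
  }
  assign_hits(models$utr5, "utr5")
  assign_hits(models$utr3, "utr3")
  assign_hits(models$cds, "exon")
  # flanking classes for loci still intergenic
  out_idx <- which(cls == "intergenic")
  if (length(out_idx) && length(gspan)) {
    sub <- pts[out_idx]
    dh <- GenomicRanges::distanceToNearest(sub, gspan, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(dh); sh <- S4Vectors::subjectHits(dh)
    d <- S4Vectors::mcols(dh)$distance
    # GRanges distance counts gap bases, so a locus k bp from the gene
    # boundary has d = k - 1; "within flank_window bp" is d < flank_window
    near <- d < flank_window
    for (j in which(near)) {
      i <- out_idx[qh[j]]
      g <- gspan[sh[j]]
      p <- loci$pos[i]
      plus <- as.character(GenomicRanges::strand(g)) != "-"
      before <- p < GenomicRanges::start(g)
      cls[i] <- if (plus == before) "upstream" else "downstream"
      gene[i] <- g$gene_id
    }
  }
  structure(cls, gene_id = gene)
}

#' Coding effect of a SNP inside a CDS
#'
#' Rebuilds the affected codon strand-aware, substitutes the alternate
#' allele, and compares amino acids under the standard genetic code.
#' The first codon and stop codons are special-cased: a change that
#' destroys the initiator ATG is `start_lost`; a change creating a stop
#' is `stop_gained`; one removing the terminal stop is `stop_lost`.
#' Returns `none` when the locus is not inside a valid CDS (a CDS whose
#' total length is not divisible by 3 triggers a warning and `none`).
#'
#' @param chrom,pos SNP coordinates (1-based).
#' @param alt alternate allele (single base, forward-strand).
#' @param models a [gene_models] object.
#' @param genome a [genome_ref].
#' @return one of `synonymous`, `missense`, `start_lost`, `stop_gained`,
#'   `stop_lost`, `none`.
#' @export
coding_effect <- function(chrom, pos, alt, models, genome) {
  pt <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  ov <- GenomicRanges::findOverlaps(pt, models$cds, ignore.strand = TRUE)
  if (length(ov) == 0) return("none")
  gid <- sort(models$cds$gene_id[S4Vectors::subjectHits(ov)])[1]
  seg <- models$cds[models$cds$gene_id == gid]
  seg <- seg[order(GenomicRanges::start(seg))]
  minus <- as.character(GenomicRanges::strand(seg))[1] == "-"
  cds_seq <- paste(vapply(seq_along(seg), function(k)
    as.character(Biostrings::subseq(
      genome$seq[[chrom]],
      GenomicRanges::start(seg)[k], GenomicRanges::end(seg)[k])), ""),
    collapse = "")
  if (nchar(cds_seq) %% 3 != 0) {
    warning("CDS length of ", gid, " not divisible by 3; effect set to none")
    return("none")
  }
  # CDS-local coordinate of the SNP (plus-strand concatenation)
  w <- GenomicRanges::end(seg) - GenomicRanges::start(seg) + 1L
  offs <- cumsum(c(0L, w[-length(w)]))
  k <- which(GenomicRanges::start(seg) <= pos & GenomicRanges::end(seg) >= pos)
  cpos <- offs[k] + (pos - GenomicRanges::start(seg)[k]) + 1L
  alt_f <- toupper(alt)
  if (minus) {
    cds_seq <- revcomp(cds_seq)
    cpos <- nchar(cds_seq) - cpos + 1L
    alt_f <- revcomp(alt_f)
  }
  codon_i <- (cpos - 1L) %/% 3L + 1L
  in_codon <- (cpos - 1L) %% 3L + 1L
  ref_codon <- substr(cds_seq, (codon_i - 1L) * 3L + 1L, codon_i * 3L)
  alt_codon <- ref_codon
  substr(alt_codon, in_codon, in_codon) <- alt_f
  code <- Biostrings::GENETIC_CODE
  ref_aa <- code[[ref_codon]]
  alt_aa <- code[[alt_codon]]
  if (codon_i == 1L && ref_codon == "ATG" && alt_codon != "ATG")
    return("start_lost")
  if (ref_aa == "*" && alt_aa != "*") return("stop_lost")
  if (ref_aa != "*" && alt_aa == "*") return("stop_gained")
  if (ref_aa == alt_aa) "synonymous" else "missense"
}

#' Functional-impact rank of an annotated SNP
#'
#' Fixed total order used for panel prioritisation (lower = stronger):
#' \enumerate{
#'   \item start/stop codon variations (`start_lost`, `stop_gained`,
#'     `stop_lost`)
#'   \item `missense`
#'   \item `synonymous`
#'   \item untranslated regions (`utr5`, `utr3`) and non-coding exons
#'   \item `upstream` / `downstream`
#'   \item `intron`
#'   \item `intergenic`
#' }
#'
#' @param region_class,effect_class class vectors (recycled).
#' @return integer ranks.
#' @export
impact_rank <- function(region_class, effect_class = "none") {
  n <- max(length(region_class), length(effect_class))
  region_class <- rep_len(region_class, n)
  effect_class <- rep_len(effect_class, n)
  eff_rank <- c(start_lost = 1L, stop_gained = 1L, stop_lost = 1L,
                missense = 2L, synonymous = 3L, noncoding = 4L)
  reg_rank <- c(utr5 = 4L, utr3 = 4L, exon = 4L,
                upstream = 5L, downstream = 5L,
                intron = 6L, intergenic = 7L)
  ifelse(effect_class %in% names(eff_rank),
         eff_rank[effect_class], reg_rank[region_class])
}

#' Annotate loci with region class, coding effect and impact rank
#'
#' @param loci data.frame with `chrom`, `pos` and optionally `alt`
#'   (needed for coding effects; loci without an alternate allele get
#'   `effect_class` `noncoding` when exonic).
#' @param models a [gene_models] object.
#' @param genome a [genome_ref] (needed for coding effects).
#' @param flank_window upstream/downstream window (default 5000).
#' @return data.frame `chrom, pos, region_class, gene_id, effect_class,
#'   impact_rank`.
#' @export
annotate_loci <- function(loci, models, genome = NULL, flank_window = 5000) {
  cls <- classify_region(loci, models, flank_window)
  eff <- rep("none", nrow(loci))
  exonic <- which(cls == "exon")
  if (length(exonic)) {
    if (is.null(genome) || is.null(loci$alt)) {
      eff[exonic] <- "noncoding"
    } else {
      for (i in exonic)
        eff[i] <- coding_effect(loci$chrom[i], loci$pos[i], loci$alt[i],
                                models, genome)
    }
  }
  data.frame(
    chrom = loci$chrom, pos = loci$pos,
    region_class = as.character(cls),
    gene_id = attr(cls, "gene_id"),
    effect_class = eff,
    impact_rank = as.integer(impact_rank(as.character(cls), eff)),
    stringsAsFactors = FALSE)
}

#' Region-class summary of an annotated panel
#'
#' Counts and percentages (one decimal, half-up) per region class.
#' Accepts either an annotation table (with a `region_class` column) or
#' a named count vector, so summaries can be recomputed from published
#' panel counts.
#'
#' @param x annotation data.frame or named numeric counts.
#' @return data.frame `region_class, n, pct` (percentages of the total,
#'   1 dp).
#' @export
region_summary <- function(x) {
  counts <- if (is.data.frame(x)) {
    tab <- table(x$region_class)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(as.integer(x), names(x))
  }
  total <- sum(counts)
  data.frame(
    region_class = names(counts),
    n = as.integer(counts),
    pct = round_half_up(100 * counts / total, 1),
    row.names = NULL, stringsAsFactors = FALSE)
}
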
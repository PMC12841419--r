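#' Gene models for functional annotation
#'
#' A light container of gene structures used by the region and
#' coding-effect classifiers: gene spans plus exon, CDS and UTR
#' segments as [GenomicRanges::GRanges] keyed by `gene_id`. One
#' canonical transcript per gene is assumed; when several transcripts
#' are present their features are pooled and a locus takes the
#' strongest class across them.
#'
#' @param genes data.frame `gene_id, chrom, start, end, strand`.
#' @param features data.frame `gene_id, chrom, start, end, strand, type`
#'   with `type` in `exon`, `CDS`, `five_prime_UTR`, `three_prime_UTR`
#'   (1-based inclusive coordinates).
#' @return an object of class `gene_models`.
#' @export
gene_models <- function(genes, features) {
  gr <- function(df) {
    if (is.null(df) || nrow(df) == 0)
      return(GenomicRanges::GRanges())
    g <- GenomicRanges::GRanges(
      df$chrom, IRanges::IRanges(df$start, df$end), strand = df$strand)
    g$gene_id <- df$gene_id
    g
  }
  f <- split(features, features$type)
  structure(list(
    genes = gr(genes),
    exons = gr(f$exon),
    cds = gr(f$CDS),
    utr5 = gr(f$five_prime_UTR),
    utr3 = gr(f$three_prime_UTR)
  ), class = "gene_models")
}

#' @export
#' @method print gene_models
print.gene_models <- function(x, ...) {
  cat("gene_models:", length(x$genes), "genes,",
      length(x$cds), "CDS segments on",
      length(unique(GenomicRanges::seqnames(x$genes))), "chromosome(s)\n")
  invisible(x)
}

#' Read gene models from GFF3
#'
#' Imports `gene`, `mRNA`, `exon`, `CDS` and UTR records, resolving each
#' feature to its gene through the `Parent` chain.
#'
#' @param path GFF3 file.
#' @return a [gene_models] object.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  parent <- as.character(S4Vectors::sapply(gr$Parent, function(p)
    if (length(p)) p[1] else NA_character_))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(gr$type),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    id = gr$ID,
    parent = parent,
    stringsAsFactors = FALSE)
  genes <- df[df$type == "gene", ]
  genes <- data.frame(gene_id = genes$id, chrom = genes$chrom,
                      start = genes$start, end = genes$end,
                      strand = genes$strand, stringsAsFactors = FALSE)
  # map transcript -> gene, then feature -> gene
  tx <- df[df$type %in% c("mRNA", "transcript"), ]
  tx2gene <- stats::setNames(tx$parent, tx$id)
  feat <- df[df$type %in% c("exon", "CDS", "five_prime_UTR",
                            "three_prime_UTR"), ]
  gid <- ifelse(feat$parent %in% names(tx2gene),
                tx2gene[feat$parent], feat$parent)
  features <- data.frame(gene_id = gid, chrom = feat$chrom,
                         start = feat$start, end = feat$end,
                         strand = feat$strand, type = feat$type,
                         stringsAsFactors = FALSE)
  gene_models(genes, features)
}

#' Write gene models as GFF3
#'
#' @param gm a [gene_models] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(gm, path) {
  row_of <- function(gr, type, id, parent = NULL) {
    if (length(gr) == 0) return(NULL)
    data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      src = "panelkit", type = type,
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
      score = ".", strand = as.character(GenomicRanges::strand(gr)),
      frame = ".",
      attrs = if (is.null(parent)) paste0("ID=", id)
        else paste0("ID=", id, ";Parent=", parent),
      stringsAsFactors = FALSE)
  }
  g <- gm$genes
  rows <- list(row_of(g, "gene", g$gene_id))
  rows <- c(rows, list(row_of(g, "mRNA", paste0(g$gene_id, ".t1"),
                              g$gene_id)))
  for (ft in c("exons", "cds", "utr5", "utr3")) {
    gr <- gm[[ft]]
    if (length(gr) == 0) next
    type <- c(exons = "exon", cds = "CDS", utr5 = "five_prime_UTR",
              utr3 = "three_prime_UTR")[[ft]]
    ids <- paste0(gr$gene_id, ".", type, ".",
                  stats::ave(seq_along(gr), gr$gene_id, FUN = seq_along))
    rows <- c(rows, list(row_of(gr, type, ids, paste0(gr$gene_id, ".t1"))))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start,
                   match(out$type, c("gene", "mRNA", "exon",
                                     "five_prime_UTR", "CDS",
                                     "three_prime_UTR"))), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
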
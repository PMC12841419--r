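#' Tile chromosomes into fixed windows
#'
#' Consecutive non-overlapping tiles anchored at coordinate 0; the
#' final partial tile is included. Every base belongs to exactly one
#' window.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param window_size tile width in bp (default 200000).
#' @return data.frame `window_id, chrom, start, end` (0-based
#'   half-open).
#' @export
make_windows <- function(chrom_lengths, window_size = 200000) {
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  rows <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0L, len - 1L, by = window_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window_size, len),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- data.frame(window_id = paste0(out$chrom, ":", out$start, "-", out$end),
                    out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Select panel loci window by window
#'
#' Implements the trait-locus-priority integration rule over fixed
#' windows. Candidates must carry their source (`GWAS` = curated
#' trait-associated locus, `RESEQ` = resequencing-derived), a
#' feasibility verdict and an impact rank. Per window:
#' \enumerate{
#'   \item if the window holds any feasibility-passing GWAS locus, all
#'     of them are retained and no RESEQ locus is added
#'     (`gwas_retained`);
#'   \item otherwise the feasibility-passing RESEQ loci are restricted
#'     to the minimal (strongest) impact rank; a unique optimum is
#'     taken deterministically (`reseq_best_impact`), and ties are
#'     broken by one uniform seeded draw (`reseq_random`);
#'   \item a window with no eligible candidate stays empty.
#' }
#' Windows are processed in (chrom, start) order under a single RNG
#' stream seeded once, so the selection is reproducible bit-for-bit
#' for a given seed.
#'
#' @param candidates data.frame `chrom, pos, source, feasible,
#'   impact_rank` and optionally `trait_category`.
#' @param windows a [make_windows()] table.
#' @param seed integer seed for the tie-breaking draws.
#' @return a `panel`: data.frame `chrom, pos, source, trait_category,
#'   impact_rank, window_id, rule`, sorted by (chrom, pos), with
#'   attributes `seed` and `n_windows_empty`.
#' @export
select_panel <- function(candidates, windows, seed = 1L) {
  stopifnot(all(c("chrom", "pos", "source", "feasible",
                  "impact_rank") %in% names(candidates)))
  if (nrow(candidates) == 0L) {
    warning("empty candidate set; returning empty panel")
    empty <- data.frame(chrom = character(0), pos = integer(0),
                        source = character(0), trait_category = character(0),
                        impact_rank = integer(0), window_id = character(0),
                        rule = character(0), stringsAsFactors = FALSE)
    return(structure(empty, class = c("panel", "data.frame"),
                     seed = seed, n_windows_empty = nrow(windows)))
  }
  if (is.null(candidates$trait_category))
    candidates$trait_category <- ifelse(candidates$source == "GWAS",
                                        "unspecified", "none")
  cand <- candidates[candidates$feasible, , drop = FALSE]
  # locate each candidate's window (0-based half-open tiles)
  ws <- windows[order(windows$chrom, windows$start), , drop = FALSE]
  wsize <- max(ws$end - ws$start)
  wkey <- paste0(ws$chrom, ":", ws$start %/% wsize)
  ckey <- paste0(cand$chrom, ":", (cand$pos - 1L) %/% wsize)
  cand$window_id <- ws$window_id[match(ckey, wkey)]
  if (anyNA(cand$window_id))
    stop("candidate locus outside the provided windows")
  cmap <- split(seq_len(nrow(cand)), cand$window_id)
  sel <- vector("list", nrow(ws))
  n_empty <- 0L
  with_seed(seed, {
    for (w in seq_len(nrow(ws))) {
      wc <- cand[cmap[[ws$window_id[w]]], , drop = FALSE]
      if (is.null(cmap[[ws$window_id[w]]])) wc <- cand[0, , drop = FALSE]
      if (nrow(wc) == 0L) { n_empty <- n_empty + 1L; next }
      gwas <- wc[wc$source == "GWAS", , drop = FALSE]
      if (nrow(gwas) > 0L) {
        gwas$rule <- "gwas_retained"
        sel[[w]] <- gwas
      } else {
        rs <- wc[wc$source == "RESEQ", , drop = FALSE]
        if (nrow(rs) == 0L) { n_empty <- n_empty + 1L; next }
        best <- rs[rs$impact_rank == min(rs$impact_rank), , drop = FALSE]
        best <- best[order(best$pos), , drop = FALSE]
        if (nrow(best) == 1L) {
          best$rule <- "reseq_best_impact"
          sel[[w]] <- best
        } else {
          pick <- best[sample.int(nrow(best), 1L), , drop = FALSE]
          pick$rule <- "reseq_random"
          sel[[w]] <- pick
        }
      }
    }
  })
  out <- do.call(rbind, sel[!vapply(sel, is.null, TRUE)])
  if (is.null(out)) {
    warning("no eligible candidate in any window; empty panel")
    out <- data.frame(chrom = character(0), pos = integer(0),
                      source = character(0), trait_category = character(0),
                      impact_rank = integer(0), window_id = character(0),
                      rule = character(0), stringsAsFactors = FALSE)
  } else {
    out <- out[order(out$chrom, out$pos),
               c("chrom", "pos", "source", "trait_category", "impact_rank",
                 "window_id", "rule")]
    rownames(out) <- NULL
  }
  structure(out, class = c("panel", "data.frame"),
            seed = seed, n_windows_empty = n_empty)
}

#' @export
#' @method print panel
print.panel <- function(x, ...) {
  cat("panel:", nrow(x), "loci on", length(unique(x$chrom)),
      "chromosome(s);",
      sum(x$source == "GWAS"), "trait-associated,",
      sum(x$source == "RESEQ"), "resequencing-derived",
      "(seed", attr(x, "seed"), ")\n")
  invisible(x)
}

#' Per-chromosome and genome-wide panel density statistics
#'
#' Density = SNP count / chromosome length (SNPs/Mb); average distance
#' = chromosome length / SNP count (kb) — the published-table
#' convention (not the mean adjacent gap, which
#' [spacing_distribution()] measures). Values are reported half-up at
#' 2 decimals. Genome-wide averages are ratios of the totals.
#'
#' @param panel a `panel` (or any data.frame with `chrom`), or a named
#'   vector of per-chromosome SNP counts.
#' @param chrom_lengths_mb named numeric vector of chromosome lengths
#'   in Mb.
#' @return data.frame `chrom, length_mb, n_snps, density, avg_distance_kb`
#'   with one row per chromosome, plus attributes `total_length_mb`,
#'   `total_snps`, `genome_density`, `genome_avg_distance_kb`.
#' @export
panel_density_stats <- function(panel, chrom_lengths_mb) {
  counts <- if (is.data.frame(panel)) {
    tab <- table(factor(panel$chrom, levels = names(chrom_lengths_mb)))
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(as.integer(panel[names(chrom_lengths_mb)]),
                    names(chrom_lengths_mb))
  }
  len <- chrom_lengths_mb[names(counts)]
  out <- data.frame(
    chrom = names(counts),
    length_mb = as.numeric(len),
    n_snps = as.integer(counts),
    density = round_half_up(counts / len, 2),
    avg_distance_kb = ifelse(counts > 0,
                             round_half_up(len * 1000 / counts, 2), NA_real_),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "total_length_mb") <- sum(len)
  attr(out, "total_snps") <- sum(counts)
  attr(out, "genome_density") <- round_half_up(sum(counts) / sum(len), 2)
  attr(out, "genome_avg_distance_kb") <-
    round_half_up(sum(len) * 1000 / sum(counts), 2)
  out
}

#' Distribution of spacing between adjacent panel loci
#'
#' Gaps are computed between adjacent loci within each chromosome
#' (sorted by position); chromosomes with fewer than two loci
#' contribute none. Default bins (kb): (0,40], (40,80], (80,120],
#' (120,200], (200,300], (300,Inf).
#'
#' @param panel a `panel` or data.frame with `chrom`, `pos`.
#' @param breaks_kb bin edges in kb (left-open, right-closed).
#' @return named integer vector of bin counts, with the raw gaps (bp)
#'   as attribute `gaps_bp`.
#' @export
spacing_distribution <- function(panel,
                                 breaks_kb = c(0, 40, 80, 120, 200, 300, Inf)) {
  p <- panel[order(panel$chrom, panel$pos), , drop = FALSE]
  gaps <- unlist(lapply(split(p$pos, p$chrom), function(x)
    if (length(x) >= 2) diff(x) else integer(0)), use.names = FALSE)
  bins <- cut(gaps / 1000, breaks = breaks_kb, right = TRUE)
  out <- stats::setNames(as.integer(table(bins)), levels(bins))
  attr(out, "gaps_bp") <- gaps
  out
}

#' Export a panel to VCF, BED and provenance TSV (plus context FASTA)
#'
#' Writes `<prefix>.vcf` (sites only), `<prefix>.bed` (0-based
#' half-open single-base intervals), `<prefix>.tsv` (full provenance:
#' source, trait category, impact rank, window, selection rule, seed)
#' and, when a genome is supplied, `<prefix>_contexts.fa` with the
#' probe context of each locus. [import_panel()] restores the panel
#' losslessly from the TSV.
#'
#' @param panel a `panel`.
#' @param prefix output path prefix.
#' @param genome optional [genome_ref] for context FASTA.
#' @param flank context flank length (default 100).
#' @return named character vector of the files written, invisibly.
#' @export
export_panel <- function(panel, prefix, genome = NULL, flank = 100) {
  if (nrow(panel) == 0L) stop("cannot export an empty panel")
  files <- c(vcf = paste0(prefix, ".vcf"), bed = paste0(prefix, ".bed"),
             tsv = paste0(prefix, ".tsv"))
  sites <- data.frame(chrom = panel$chrom, pos = panel$pos,
                      id = locus_key(panel$chrom, panel$pos),
                      ref = if (is.null(panel$ref)) "N" else panel$ref,
                      alt = if (is.null(panel$alt)) "." else panel$alt,
                      stringsAsFactors = FALSE)
  write_variants(variant_set(sites), files[["vcf"]])
  write_loci_bed(panel$chrom, panel$pos, files[["bed"]])
  prov <- as.data.frame(panel)
  prov$seed <- attr(panel, "seed")
  utils::write.table(prov, files[["tsv"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(genome)) {
    files[["fasta"]] <- paste0(prefix, "_contexts.fa")
    ctx <- vapply(seq_len(nrow(panel)), function(i)
      extract_flanks(genome, panel$chrom[i], panel$pos[i], flank)$context, "")
    names(ctx) <- locus_key(panel$chrom, panel$pos)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(ctx),
                                files[["fasta"]])
  }
  invisible(files)
}

#' @param prefix the prefix passed to [export_panel()].
#' @rdname export_panel
#' @export
import_panel <- function(prefix) {
  df <- utils::read.table(paste0(prefix, ".tsv"), sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  seed <- df$seed[1]
  df$seed <- NULL
  structure(df, class = c("panel", "data.frame"), seed = seed)
}
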
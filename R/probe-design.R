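#' Extract the flanking context of a candidate SNP
#'
#' Capture probes are designed from the genomic context of a SNP:
#' `flank` bases on each side plus the site itself (201 bp by default).
#' Loci closer than `flank` to a chromosome end yield a truncated
#' context, flagged — such loci cannot carry a full-length probe and
#' fail feasibility downstream.
#'
#' @param genome a [genome_ref].
#' @param chrom chromosome id.
#' @param pos 1-based position.
#' @param flank flank length on each side (default 100).
#' @return a `flank_context`: list with `chrom`, `pos`, `upstream`,
#'   `downstream`, `context` (upstream + ref base + downstream),
#'   `ref_base`, `mask_flags` (logical per context base), `truncated`.
#' @export
extract_flanks <- function(genome, chrom, pos, flank = 100) {
  if (!chrom %in% names(genome$lengths)) stop("unknown chromosome: ", chrom)
  len <- genome$lengths[[chrom]]
  if (pos < 1 || pos > len) stop("position ", pos, " outside ", chrom,
                                 " (length ", len, ")")
  from <- max(1L, pos - flank)
  to <- min(len, pos + flank)
  ctx <- as.character(Biostrings::subseq(genome$seq[[chrom]], from, to))
  up <- substr(ctx, 1L, pos - from)
  down <- substr(ctx, pos - from + 2L, nchar(ctx))
  structure(list(
    chrom = chrom, pos = pos,
    upstream = up, downstream = down,
    context = ctx,
    ref_base = substr(ctx, pos - from + 1L, pos - from + 1L),
    mask_flags = is_masked(genome, chrom, from:to),
    truncated = (pos - flank < 1) || (pos + flank > len)
  ), class = "flank_context")
}

#' GC fraction of a nucleotide sequence
#'
#' (G+C) over the count of unambiguous bases; N bases are excluded from
#' the denominator. Returns `NA` for an empty or all-N sequence (the
#' GC feasibility criterion then fails).
#'
#' @param seq nucleotide string over A/C/G/T/N, case-insensitive.
#' @return fraction in \[0, 1\], or `NA`.
#' @export
gc_content <- function(seq) {
  v <- strsplit(toupper(seq), "")[[1]]
  gc <- sum(v %in% c("G", "C"))
  acgt <- sum(v %in% c("A", "C", "G", "T"))
  if (acgt == 0) return(NA_real_)
  gc / acgt
}

# 2-bit encode a chromosome: A=0 C=1 G=2 T=3, NA for ambiguous bases
encode_bases <- function(s) {
  x <- charToRaw(toupper(s))
  out <- rep(NA_integer_, length(x))
  out[x == charToRaw("A")] <- 0L
  out[x == charToRaw("C")] <- 1L
  out[x == charToRaw("G")] <- 2L
  out[x == charToRaw("T")] <- 3L
  out
}

# rolling base-4 k-mer values over an encoded vector; NA where the
# window covers an ambiguous base
kmer_values <- function(codes, k) {
  n <- length(codes)
  if (n < k) return(numeric(0))
  val <- numeric(n - k + 1L)
  for (j in 0:(k - 1L)) val <- val + codes[(1L + j):(n - k + 1L + j)] * 4^(k - 1L - j)
  val
}

#' Build a k-mer seed index of a genome for the uniqueness search
#'
#' @param genome a [genome_ref].
#' @param k seed length (default 13; must satisfy 4^k < 2^52).
#' @return an opaque index object for [uniqueness_check()].
#' @export
kmer_index <- function(genome, k = 13) {
  vals <- list(); chroms <- character(0); starts <- integer(0)
  all_vals <- numeric(0); all_chrom <- integer(0); all_pos <- integer(0)
  for (i in seq_along(genome$seq)) {
    v <- kmer_values(encode_bases(as.character(genome$seq[[i]])), k)
    ok <- which(!is.na(v))
    all_vals <- c(all_vals, v[ok])
    all_chrom <- c(all_chrom, rep(i, length(ok)))
    all_pos <- c(all_pos, ok)
  }
  o <- order(all_vals)
  structure(list(k = k, vals = all_vals[o], chrom = all_chrom[o],
                 pos = all_pos[o], chrom_names = names(genome$seq)),
            class = "kmer_index")
}

# all (chrom, start) placements of query k-mers in the index, with the
# query offset each seed came from
seed_hits <- function(index, query_codes) {
  qv <- kmer_values(query_codes, index$k)
  offs <- which(!is.na(qv))
  if (!length(offs)) return(NULL)
  res_chrom <- integer(0); res_pos <- integer(0); res_off <- integer(0)
  lo <- findInterval(qv[offs] - 0.5, index$vals)
  hi <- findInterval(qv[offs] + 0.5, index$vals)
  for (i in seq_along(offs)) {
    if (hi[i] > lo[i]) {
      idx <- (lo[i] + 1L):hi[i]
      res_chrom <- c(res_chrom, index$chrom[idx])
      res_pos <- c(res_pos, index$pos[idx])
      res_off <- c(res_off, rep(offs[i], length(idx)))
    }
  }
  if (!length(res_chrom)) return(NULL)
  data.frame(chrom = res_chrom, start = res_pos - res_off + 1L)
}

revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

#' Count qualifying genomic placements of a probe context (single-copy test)
#'
#' Seed-and-extend search for ungapped placements of the context
#' sequence across the genome (both strands). A placement qualifies
#' when its aligned length exceeds `min_coverage` of the query and its
#' identity over the aligned bases exceeds `min_identity` (both strict,
#' defaults 0.60). The locus is single-copy iff exactly one placement
#' qualifies — the source locus itself.
#'
#' Seeding uses exact shared k-mers, so placements barely above the
#' identity cutoff with no surviving seed k-mer can in principle be
#' missed; at the default cutoffs this matters only for alignments far
#' below ~75% identity, which a repeat-derived duplication rarely is.
#'
#' @param genome a [genome_ref].
#' @param context a `flank_context` from [extract_flanks()], or a
#'   nucleotide string.
#' @param min_identity,min_coverage strict lower cutoffs for a hit to
#'   qualify.
#' @param index optional precomputed [kmer_index()] (built on the fly
#'   otherwise; precompute it when screening many loci).
#' @return list `n_qualifying_hits`, `single_copy`, `hits` (data.frame
#'   chrom, start, strand, identity).
#' @export
uniqueness_check <- function(genome, context, min_identity = 0.60,
                             min_coverage = 0.60, index = NULL) {
  q <- if (inherits(context, "flank_context")) context$context else context
  if (is.null(index)) index <- kmer_index(genome)
  qlen <- nchar(q)
  hits <- list()
  for (strand in c("+", "-")) {
    qs <- if (strand == "+") q else revcomp(q)
    qc <- encode_bases(qs)
    sh <- seed_hits(index, qc)
    if (is.null(sh)) next
    sh <- unique(sh)
    for (r in seq_len(nrow(sh))) {
      ci <- sh$chrom[r]
      clen <- genome$lengths[[ci]]
      g_from <- max(1L, sh$start[r])
      g_to <- min(clen, sh$start[r] + qlen - 1L)
      q_from <- g_from - sh$start[r] + 1L
      aligned <- g_to - g_from + 1L
      if (aligned <= min_coverage * qlen) next
      sub <- encode_bases(as.character(
        Biostrings::subseq(genome$seq[[ci]], g_from, g_to)))
      qsub <- qc[q_from:(q_from + aligned - 1L)]
      ident <- sum(sub == qsub, na.rm = TRUE) / aligned
      if (ident > min_identity)
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = index$chrom_names[ci], start = g_from,
          strand = strand, identity = ident,
          stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(hits)) unique(do.call(rbind, hits)) else
    data.frame(chrom = character(0), start = integer(0),
               strand = character(0), identity = numeric(0))
  n <- nrow(hits)
  list(n_qualifying_hits = n, single_copy = n == 1L, hits = hits)
}

#' Repeat and N screen of a probe context
#'
#' The repeat signal is reference soft-masking: any soft-masked base in
#' the context flags `has_repeat`. A homopolymer backstop (a single-base
#' run of at least `homopolymer_min`, default 10) also flags it, so
#' unmasked low-complexity tracts are caught in synthetic genomes.
#' `has_N` flags any ambiguous base. The criterion passes iff both are
#' `FALSE`.
#'
#' @param context a `flank_context`.
#' @param homopolymer_min minimum single-base run length counted as a
#'   repeat; `Inf` disables the backstop.
#' @param use_mask use the soft-mask flags (default TRUE).
#' @return list `has_repeat`, `has_N`.
#' @export
repeat_and_n_screen <- function(context, homopolymer_min = 10,
                                use_mask = TRUE) {
  v <- strsplit(toupper(context$context), "")[[1]]
  has_rep <- use_mask && any(context$mask_flags)
  if (!has_rep && is.finite(homopolymer_min)) {
    r <- rle(v)
    has_rep <- any(r$lengths >= homopolymer_min & r$values %in%
                     c("A", "C", "G", "T"))
  }
  list(has_repeat = has_rep, has_N = any(!(v %in% c("A", "C", "G", "T"))))
}

#' Screen for large InDels near a candidate SNP
#'
#' Fails iff any InDel longer than `max_indel_len` (length =
#' `|nchar(ref) - nchar(alt)|`, strict inequality) overlaps the window
#' `[pos - flank, pos + flank]`; the InDel occupies
#' `[pos, pos + nchar(ref) - 1]`.
#'
#' @param chrom,pos candidate SNP coordinates.
#' @param indels data.frame `chrom, pos, ref, alt` of InDel records, or
#'   `NULL` (criterion passes vacuously, with one warning per call).
#' @param flank window half-width (default 100).
#' @param max_indel_len largest tolerated InDel length (default 5).
#' @return list `pass`, `nearest_large_indel_bp` (distance from the SNP
#'   to the closest offending InDel, `NA` when none).
#' @export
indel_proximity_screen <- function(chrom, pos, indels, flank = 100,
                                   max_indel_len = 5) {
  if (is.null(indels)) {
    warning("no InDel set supplied; InDel proximity criterion passes vacuously")
    return(list(pass = TRUE, nearest_large_indel_bp = NA_real_))
  }
  len <- abs(nchar(indels$ref) - nchar(indels$alt))
  big <- indels$chrom == chrom & len > max_indel_len
  if (!any(big)) return(list(pass = TRUE, nearest_large_indel_bp = NA_real_))
  i_start <- indels$pos[big]
  i_end <- indels$pos[big] + nchar(indels$ref[big]) - 1L
  overlap <- i_start <= pos + flank & i_end >= pos - flank
  dist <- pmax(0L, pmax(i_start - pos, pos - i_end))
  if (any(overlap))
    list(pass = FALSE, nearest_large_indel_bp = min(dist[overlap]))
  else
    list(pass = TRUE, nearest_large_indel_bp = NA_real_)
}

#' Full probe-design feasibility assessment
#'
#' Runs the four screens per candidate locus: single-copy context
#' (seed-and-extend uniqueness), GC content within `[gc_min, gc_max]`
#' of the full context, no repeats or N bases in the context, and no
#' large InDel within the flanks. A locus passes iff all four pass; all
#' failing criteria are reported, not just the first. Loci whose
#' context is truncated by a chromosome end fail outright
#' (`truncated_flank`).
#'
#' @param genome a [genome_ref].
#' @param loci data.frame with `chrom` and `pos` columns.
#' @param indels optional InDel data.frame (see
#'   [indel_proximity_screen()]).
#' @param flank flank length (default 100).
#' @param gc_min,gc_max GC feasibility bounds (inclusive; defaults
#'   0.40, 0.60).
#' @param min_identity,min_coverage uniqueness cutoffs.
#' @param homopolymer_min repeat-backstop run length.
#' @param index optional precomputed [kmer_index()].
#' @return data.frame, one row per locus: coordinates, `gc_fraction`,
#'   `n_qualifying_hits`, `single_copy`, `has_repeat`, `has_N`,
#'   `indel_ok`, `nearest_large_indel_bp`, `truncated`, `passed`,
#'   `failure_reasons` (comma-joined).
#' @export
assess_feasibility <- function(genome, loci, indels = NULL, flank = 100,
                               gc_min = 0.40, gc_max = 0.60,
                               min_identity = 0.60, min_coverage = 0.60,
                               homopolymer_min = 10, index = NULL) {
  if (is.null(index)) index <- kmer_index(genome)
  if (is.null(indels))
    warning("no InDel set supplied; InDel proximity criterion passes vacuously")
  n <- nrow(loci)
  out <- data.frame(
    chrom = loci$chrom, pos = loci$pos,
    gc_fraction = NA_real_, n_qualifying_hits = NA_integer_,
    single_copy = NA, has_repeat = NA, has_N = NA,
    indel_ok = NA, nearest_large_indel_bp = NA_real_,
    truncated = NA, passed = FALSE, failure_reasons = "",
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ctx <- extract_flanks(genome, loci$chrom[i], loci$pos[i], flank)
    out$truncated[i] <- ctx$truncated
    out$gc_fraction[i] <- gc_content(ctx$context)
    rn <- repeat_and_n_screen(ctx, homopolymer_min = homopolymer_min)
    out$has_repeat[i] <- rn$has_repeat
    out$has_N[i] <- rn$has_N
    uq <- uniqueness_check(genome, ctx, min_identity, min_coverage, index)
    out$n_qualifying_hits[i] <- uq$n_qualifying_hits
    out$single_copy[i] <- uq$single_copy
    ind <- if (is.null(indels)) list(pass = TRUE, nearest_large_indel_bp = NA_real_)
      else indel_proximity_screen(loci$chrom[i], loci$pos[i], indels,
                                  flank, max_indel_len = 5)
    out$indel_ok[i] <- ind$pass
    out$nearest_large_indel_bp[i] <- ind$nearest_large_indel_bp
    reasons <- character(0)
    if (ctx$truncated) reasons <- c(reasons, "truncated_flank")
    if (!uq$single_copy) reasons <- c(reasons, "not_single_copy")
    if (is.na(out$gc_fraction[i]) || out$gc_fraction[i] < gc_min ||
        out$gc_fraction[i] > gc_max) reasons <- c(reasons, "gc_out_of_range")
    if (rn$has_repeat || rn$has_N) reasons <- c(reasons, "repeat_or_N")
    if (!ind$pass) reasons <- c(reasons, "large_indel_nearby")
    out$passed[i] <- length(reasons) == 0L
    out$failure_reasons[i] <- paste(reasons, collapse = ",")
  }
  out
}

#' Write feasibility results and the probe-context FASTA of passing loci
#'
#' @param feas an [assess_feasibility()] table.
#' @param path TSV output path.
#' @param genome,fasta_path when both given, the contexts of passing
#'   loci are written as FASTA.
#' @param flank flank length used in the assessment.
#' @return `path`, invisibly.
#' @export
write_feasibility <- function(feas, path, genome = NULL, fasta_path = NULL,
                              flank = 100) {
  utils::write.table(feas, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(genome) && !is.null(fasta_path)) {
    keep <- feas[feas$passed, , drop = FALSE]
    ctx <- vapply(seq_len(nrow(keep)), function(i)
      extract_flanks(genome, keep$chrom[i], keep$pos[i], flank)$context, "")
    names(ctx) <- locus_key(keep$chrom, keep$pos)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(ctx), fasta_path)
  }
  invisible(path)
}
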
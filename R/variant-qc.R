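#' Read population variants with QC annotations from a VCF
#'
#' Parses sites and per-sample genotypes, pulling the four site-quality
#' annotations used by the hard-filter cascade: QUAL, and QD
#' (quality-by-depth), FS (Fisher-strand phred score) and MQ (RMS mapping
#' quality) from the INFO field. An annotation that is present but
#' non-numeric marks the record malformed; an absent annotation is
#' recorded as `NA` (missing), which the filters treat separately.
#'
#' @param path VCF file (plain or bgzip).
#' @return a `variant_set`: list with
#'   \describe{
#'     \item{sites}{data.frame `chrom, pos, id, ref, alt, qual, qd, fs,
#'       mq, malformed` (one row per record; `alt` comma-separated)}
#'     \item{gt}{character matrix sites x samples of genotype strings
#'       (`"0/1"`, `"./."`, ...), or `NULL` when the VCF has no samples}
#'   }
#' @export
read_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info_num <- function(key) {
    raw <- vcfR::extract.info(v, element = key)
    val <- suppressWarnings(as.numeric(raw))
    list(val = val, malformed = !is.na(raw) & is.na(val))
  }
  qd <- info_num("QD"); fs <- info_num("FS"); mq <- info_num("MQ")
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  sites <- data.frame(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    id = ifelse(is.na(fix$ID), ".", fix$ID),
    ref = fix$REF,
    alt = fix$ALT,
    qual = qual,
    qd = qd$val, fs = fs$val, mq = mq$val,
    malformed = (!is.na(fix$QUAL) & fix$QUAL != "." & is.na(qual)) |
      qd$malformed | fs$malformed | mq$malformed,
    stringsAsFactors = FALSE
  )
  gt <- NULL
  if (ncol(v@gt) > 1L) {
    gt <- vcfR::extract.gt(v, element = "GT")
    rownames(gt) <- locus_key(sites$chrom, sites$pos)
  }
  structure(list(sites = sites, gt = gt), class = "variant_set")
}

#' @export
#' @method print variant_set
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$sites), "sites,",
      if (is.null(x$gt)) 0L else ncol(x$gt), "samples\n")
  invisible(x)
}

#' Construct a variant_set in code (mainly for simulation and tests)
#'
#' @param sites data.frame with at least `chrom, pos, ref, alt`; `qual`,
#'   `qd`, `fs`, `mq`, `id`, `malformed` are filled with defaults when
#'   absent.
#' @param gt optional genotype-string matrix (sites x samples).
#' @return a `variant_set`.
#' @export
variant_set <- function(sites, gt = NULL) {
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(sites))) stop("sites needs columns: ",
                                         paste(need, collapse = ", "))
  for (col in c("qual", "qd", "fs", "mq"))
    if (is.null(sites[[col]])) sites[[col]] <- NA_real_
  if (is.null(sites$id)) sites$id <- "."
  if (is.null(sites$malformed)) sites$malformed <- FALSE
  if (!is.null(gt)) {
    gt <- as.matrix(gt)
    if (nrow(gt) != nrow(sites)) stop("gt rows must match sites rows")
    rownames(gt) <- locus_key(sites$chrom, sites$pos)
    if (is.null(colnames(gt))) colnames(gt) <- sprintf("S%d", seq_len(ncol(gt)))
  }
  structure(list(sites = sites, gt = gt), class = "variant_set")
}

#' Hard-filter a variant set on site-quality annotations
#'
#' A record survives iff `QUAL >= qual_min` and `QD >= qd_min` and
#' `FS <= fs_max` and `MQ >= mq_min` (defaults 30, 2.0, 60.0, 40.0).
#' The removal conditions are strict inequalities, so records sitting
#' exactly on a threshold are kept. Records with a missing annotation
#' fail that criterion by default (`missing_fails = TRUE`); malformed
#' records (non-numeric annotation text) are always rejected, with a
#' message. Relative record order is preserved. Rejections are
#' attributed to the first failing criterion in the fixed order
#' QUAL, QD, FS, MQ.
#'
#' @param vs a `variant_set` (or its `sites` data.frame).
#' @param qual_min,qd_min,fs_max,mq_min filter thresholds.
#' @param missing_fails if `FALSE`, a missing (`NA`) annotation passes
#'   its criterion instead of failing it.
#' @return a `variant_set` of survivors, with attributes
#'   `n_input`, `n_kept`, and `rejections` (named counts by first
#'   failing criterion, including `malformed`).
#' @export
apply_hard_filters <- function(vs, qual_min = 30, qd_min = 2.0,
                               fs_max = 60.0, mq_min = 40.0,
                               missing_fails = TRUE) {
  sites <- if (inherits(vs, "variant_set")) vs$sites else vs
  cmp <- function(x, ok) {
    res <- ok(x)
    res[is.na(x)] <- !missing_fails
    res
  }
  pass <- cbind(
    malformed = !sites$malformed,
    qual = cmp(sites$qual, function(x) x >= qual_min),
    qd = cmp(sites$qd, function(x) x >= qd_min),
    fs = cmp(sites$fs, function(x) x <= fs_max),
    mq = cmp(sites$mq, function(x) x >= mq_min)
  )
  keep <- rowSums(!pass) == 0L
  first_fail <- apply(!pass, 1L, function(z) if (any(z)) names(z)[which(z)[1]] else NA)
  rej <- table(factor(first_fail[!keep],
                      levels = c("malformed", "qual", "qd", "fs", "mq")))
  if (rej[["malformed"]] > 0)
    message(rej[["malformed"]], " malformed record(s) rejected")
  out <- structure(
    list(sites = sites[keep, , drop = FALSE],
         gt = if (inherits(vs, "variant_set") && !is.null(vs$gt))
           vs$gt[keep, , drop = FALSE] else NULL),
    class = "variant_set")
  attr(out, "n_input") <- nrow(sites)
  attr(out, "n_kept") <- sum(keep)
  attr(out, "rejections") <- c(rej)
  out
}

# Parse "a/b"-style genotype strings into per-site allele-index pairs.
# Returns list(code = 0/1/2/NA biallelic code, alleles = observed allele
# indices per site).
parse_gt <- function(gt) {
  a1 <- sub("[/|].*$", "", gt)
  a2 <- sub("^.*[/|]", "", gt)
  a1 <- suppressWarnings(matrix(as.integer(a1), nrow = nrow(gt)))
  a2 <- suppressWarnings(matrix(as.integer(a2), nrow = nrow(gt)))
  code <- matrix(NA_integer_, nrow(gt), ncol(gt))
  called <- !is.na(a1) & !is.na(a2)
  code[called] <- (a1 + a2)[called]
  # codes above 2 arise from multi-allelic indices; they stay coded by
  # dosage clamp so the matrix remains in-alphabet, and the observed
  # allele count flags the site as non-biallelic
  code[called & (a1 > 1 | a2 > 1)] <-
    ifelse((a1 == a2)[called & (a1 > 1 | a2 > 1)], 2L, 1L)
  n_alleles <- vapply(seq_len(nrow(gt)), function(i) {
    length(unique(stats::na.omit(c(a1[i, ], a2[i, ]))))
  }, 0L)
  list(code = code, n_alleles = n_alleles)
}

#' Collapse a variant_set's genotypes to a coded geno_matrix
#'
#' Diploid calls become codes 0/1/2 (`NA` missing). The per-site count
#' of distinct observed allele indices is attached as attribute
#' `n_alleles_obs`, so downstream biallelic filtering sees multi-allelic
#' genotypes even though the code alphabet is biallelic.
#'
#' @param vs a `variant_set` with genotypes.
#' @return a [geno_matrix] (samples x loci).
#' @export
as_geno_matrix <- function(vs) {
  if (is.null(vs$gt)) stop("variant_set has no genotypes")
  p <- parse_gt(vs$gt)
  m <- t(p$code)
  rownames(m) <- colnames(vs$gt)
  colnames(m) <- rownames(vs$gt)
  gm <- geno_matrix(m)
  attr(gm, "n_alleles_obs") <-
    stats::setNames(p$n_alleles, rownames(vs$gt))
  gm
}

#' Population-level locus filter (call rate, MAF, biallelic)
#'
#' A locus survives iff its call rate is at least `min_call_rate`
#' (the VCFtools `--max-missing` convention: keep sites with at least
#' that fraction genotyped), its minor-allele frequency is at least
#' `min_maf`, and exactly two alleles are observed in the genotypes
#' (when `biallelic_only`). Rejections are attributed to the first
#' failing criterion in the order call_rate, maf, allelism.
#'
#' @param gm a [geno_matrix] (typically from hard-filter survivors).
#' @param min_call_rate minimum fraction of genotyped samples
#'   (default 0.8).
#' @param min_maf minimum minor-allele frequency (default 0.01).
#' @param biallelic_only require exactly two observed alleles
#'   (default TRUE).
#' @return list with `kept` (locus keys in input order), `stats` (the
#'   [compute_site_stats()] table with a `kept` column), and
#'   `rejections` (named counts by first failing criterion).
#' @export
population_filter <- function(gm, min_call_rate = 0.8, min_maf = 0.01,
                              biallelic_only = TRUE) {
  if (ncol(gm) == 0L) {
    warning("empty genotype matrix; nothing to filter")
    return(list(kept = character(0),
                stats = compute_site_stats(gm),
                rejections = c(call_rate = 0L, maf = 0L, allelism = 0L)))
  }
  st <- compute_site_stats(gm)
  ok_cr <- st$call_rate >= min_call_rate
  ok_maf <- st$maf_defined & st$maf >= min_maf
  ok_bi <- if (biallelic_only) st$n_alleles == 2L else TRUE
  keep <- ok_cr & ok_maf & ok_bi
  first_fail <- ifelse(!ok_cr, "call_rate",
                ifelse(!ok_maf, "maf",
                ifelse(!ok_bi, "allelism", NA)))
  rej <- table(factor(first_fail[!keep],
                      levels = c("call_rate", "maf", "allelism")))
  st$kept <- keep
  list(kept = st$locus[keep], stats = st, rejections = c(rej))
}

#' Write a variant_set as a minimal VCF
#'
#' Sites-only or with genotype columns; intended for exporting filter
#' survivors and designed panels.
#'
#' @param vs a `variant_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(vs, path) {
  s <- vs$sites
  hdr <- c("##fileformat=VCFv4.2",
           "##source=panelkit",
           '##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">',
           '##INFO=<ID=FS,Number=1,Type=Float,Description="Fisher strand phred score">',
           '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  info <- paste0(
    ifelse(is.na(s$qd), "", paste0("QD=", s$qd, ";")),
    ifelse(is.na(s$fs), "", paste0("FS=", s$fs, ";")),
    ifelse(is.na(s$mq), "", paste0("MQ=", s$mq, ";")))
  info <- sub(";$", "", info)
  info[info == ""] <- "."
  body <- data.frame(s$chrom, s$pos, s$id, s$ref, s$alt,
                     ifelse(is.na(s$qual), ".", as.character(s$qual)),
                     "PASS", info, stringsAsFactors = FALSE)
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(vs$gt)) {
    body <- cbind(body, "GT", as.data.frame(vs$gt, stringsAsFactors = FALSE))
    cols <- c(cols, "FORMAT", colnames(vs$gt))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(cols, collapse = "\t"), con)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export loci as BED (0-based half-open) and the QC summary as TSV
#'
#' @param chrom,pos vectors of locus coordinates (1-based positions),
#'   or a single data.frame with `chrom` and `pos` columns as first
#'   argument.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loci_bed <- function(chrom, pos = NULL, path) {
  if (is.data.frame(chrom)) { pos <- chrom$pos; chrom <- chrom$chrom }
  utils::write.table(
    data.frame(chrom, pos - 1L, pos),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @param hard a hard-filtered `variant_set` (from [apply_hard_filters()]).
#' @param pop a [population_filter()] result.
#' @rdname write_loci_bed
#' @export
write_qc_report <- function(hard, pop, path) {
  rows <- rbind(
    data.frame(stage = "hard_filter", criterion = "input",
               n = attr(hard, "n_input")),
    data.frame(stage = "hard_filter",
               criterion = names(attr(hard, "rejections")),
               n = as.integer(attr(hard, "rejections"))),
    data.frame(stage = "hard_filter", criterion = "kept",
               n = attr(hard, "n_kept")),
    data.frame(stage = "population_filter",
               criterion = names(pop$rejections),
               n = as.integer(pop$rejections)),
    data.frame(stage = "population_filter", criterion = "kept",
               n = length(pop$kept)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
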
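#' Coded diploid genotype matrix
#'
#' Genotypes are coded 0 (homozygous reference), 1 (heterozygous),
#' 2 (homozygous alternate) and `NA` (missing call), in a samples x loci
#' integer matrix. Locus names are `"chrom:pos"` keys.
#'
#' @param codes integer matrix (samples in rows, loci in columns) over
#'   \{0, 1, 2, NA\}.
#' @param samples optional sample ids (defaults to existing rownames).
#' @param loci optional locus keys (defaults to existing colnames).
#' @return an integer matrix of class `geno_matrix`.
#' @export
geno_matrix <- function(codes, samples = rownames(codes), loci = colnames(codes)) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  bad <- !is.na(codes) & !(codes %in% 0:2)
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  if (is.null(samples)) samples <- sprintf("S%d", seq_len(nrow(codes)))
  if (is.null(loci)) loci <- sprintf("L%d", seq_len(ncol(codes)))
  dimnames(codes) <- list(samples, loci)
  class(codes) <- c("geno_matrix", "matrix", "array")
  codes
}

#' @export
#' @method print geno_matrix
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x), "samples x", ncol(x), "loci;",
      sprintf("%.1f%% missing\n", 100 * mean(is.na(x))))
  invisible(x)
}

#' @export
`[.geno_matrix` <- function(x, ...) {
  out <- NextMethod()
  if (is.matrix(out)) class(out) <- c("geno_matrix", "matrix", "array")
  out
}

#' Per-site call rate, minor-allele frequency and observed allele count
#'
#' `call_rate` is the fraction of non-missing genotypes, `maf` the
#' minor-allele frequency computed from allele counts over non-missing
#' genotypes only, and `n_alleles` the number of distinct alleles
#' actually observed in the genotypes. An all-missing site gets
#' `call_rate` 0 and an undefined (`NA`) `maf`, flagged by
#' `maf_defined = FALSE`.
#'
#' @param gm a [geno_matrix]. If it carries an `n_alleles_obs` attribute
#'   (set by [as_geno_matrix()] from raw VCF allele-index genotypes, where
#'   more than two alleles can be observed), that count overrides the one
#'   derivable from the biallelic codes.
#' @param loci optional subset of locus keys.
#' @return data.frame with one row per locus: `locus`, `call_rate`,
#'   `maf`, `maf_defined`, `n_alleles`.
#' @export
compute_site_stats <- function(gm, loci = NULL) {
  if (!inherits(gm, "geno_matrix")) gm <- geno_matrix(gm)
  keys <- colnames(gm)
  if (!is.null(loci)) {
    if (!all(loci %in% keys)) stop("unknown locus key(s): ",
                                   paste(setdiff(loci, keys), collapse = ", "))
    keys <- loci
  }
  sub <- unclass(gm)[, keys, drop = FALSE]
  n <- nrow(sub)
  n_called <- colSums(!is.na(sub))
  call_rate <- n_called / n
  n0 <- colSums(sub == 0L, na.rm = TRUE)
  n1 <- colSums(sub == 1L, na.rm = TRUE)
  n2 <- colSums(sub == 2L, na.rm = TRUE)
  ref_ct <- 2L * n0 + n1
  alt_ct <- 2L * n2 + n1
  tot <- ref_ct + alt_ct
  maf <- ifelse(tot > 0, pmin(ref_ct, alt_ct) / tot, NA_real_)
  n_alleles <- (ref_ct > 0) + (alt_ct > 0)
  obs <- attr(gm, "n_alleles_obs")
  if (!is.null(obs)) n_alleles <- as.integer(obs[keys])
  data.frame(
    locus = keys,
    call_rate = call_rate,
    maf = maf,
    maf_defined = !is.na(maf),
    n_alleles = as.integer(n_alleles),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write / read a genotype matrix as TSV
#'
#' Plain-text interchange: loci in rows (`locus` column) and one column
#' per sample, missing as `NA`.
#'
#' @param gm a [geno_matrix].
#' @param path file path.
#' @return `write_geno_tsv`: `path` invisibly; `read_geno_tsv`: a
#'   [geno_matrix].
#' @export
write_geno_tsv <- function(gm, path) {
  df <- data.frame(locus = colnames(gm), t(unclass(gm)), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_geno_tsv
#' @export
read_geno_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- df$locus
  geno_matrix(m)
}
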
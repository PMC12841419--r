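#' Reference genome with soft-mask state
#'
#' A `genome_ref` bundles the chromosome sequences (uppercase
#' [Biostrings::DNAStringSet]) with the soft-masked (lowercase in the
#' source FASTA) intervals, which the probe feasibility screen uses as
#' its repeat signal.
#'
#' @param seqs named character vector or `BStringSet`/`DNAStringSet` of
#'   chromosome sequences; lowercase letters mark soft-masked bases.
#' @return an object of class `genome_ref` with elements
#'   \describe{
#'     \item{seq}{`DNAStringSet`, uppercased sequences}
#'     \item{mask}{named list of [IRanges::IRanges] of soft-masked intervals}
#'     \item{lengths}{named integer vector of chromosome lengths}
#'   }
#' @export
genome_ref <- function(seqs) {
  if (!is.character(seqs)) seqs <- as.character(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("chromosome sequences must have unique names")
  # vectorised lowercase-run detection; fast on Mb-scale chromosomes
  mask <- lapply(seqs, function(s) {
    x <- charToRaw(s)
    lower <- x >= charToRaw("a") & x <= charToRaw("z")
    if (!any(lower)) return(IRanges::IRanges())
    r <- rle(as.vector(lower))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    IRanges::IRanges(starts[r$values], ends[r$values])
  })
  dna <- Biostrings::DNAStringSet(toupper(seqs))
  structure(
    list(seq = dna, mask = mask,
         lengths = stats::setNames(Biostrings::width(dna), names(dna))),
    class = "genome_ref"
  )
}

#' Read a soft-masked FASTA into a genome_ref
#'
#' Case is preserved while reading so that lowercase (soft-masked)
#' tracts are recovered as repeat intervals.
#'
#' @param path FASTA file path.
#' @return a [genome_ref].
#' @export
read_genome <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  names(raw) <- sub("\\s.*$", "", names(raw))
  genome_ref(as.character(raw))
}

#' Write a genome_ref to FASTA, restoring soft-mask case
#'
#' @param genome a [genome_ref].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  out <- vapply(seq_along(genome$seq), function(i) {
    s <- as.character(genome$seq[[i]])
    m <- genome$mask[[names(genome$seq)[i]]]
    if (length(m)) {
      v <- strsplit(s, "")[[1]]
      idx <- unlist(lapply(seq_along(m), function(j)
        IRanges::start(m)[j]:IRanges::end(m)[j]))
      v[idx] <- tolower(v[idx])
      s <- paste(v, collapse = "")
    }
    s
  }, "")
  names(out) <- names(genome$seq)
  Biostrings::writeXStringSet(Biostrings::BStringSet(out), path)
  invisible(path)
}

#' @export
#' @method print genome_ref
print.genome_ref <- function(x, ...) {
  masked <- vapply(x$mask, function(m) sum(IRanges::width(m)), 0L)
  cat("genome_ref:", length(x$seq), "sequence(s),",
      format(sum(x$lengths), big.mark = ","), "bp,",
      sprintf("%.1f%% soft-masked\n", 100 * sum(masked) / sum(x$lengths)))
  invisible(x)
}

# TRUE/FALSE per queried base: is it inside a soft-masked interval?
is_masked <- function(genome, chrom, positions) {
  m <- genome$mask[[chrom]]
  if (is.null(m) || length(m) == 0) return(rep(FALSE, length(positions)))
  IRanges::overlapsAny(IRanges::IRanges(positions, positions), m)
}
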
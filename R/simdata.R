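#' Simulate a small diploid reference genome with gene models
#'
#' Generates a multi-chromosome genome with a target base composition,
#' planted soft-masked (lowercase) repeat tracts, optional N runs, and
#' protein-coding genes with valid structure: 5' UTR, a CDS split over
#' exons that starts with ATG, ends with a stop codon and contains no
#' internal stop, and a 3' UTR; roughly half the genes are placed on
#' the minus strand. A truth table of every planted feature is
#' returned so downstream screens can be checked against construction.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length length of each chromosome in bp (scalar or
#'   vector).
#' @param gc target GC fraction of the background sequence
#'   (default 0.40).
#' @param repeat_fraction fraction of each chromosome soft-masked as
#'   repeat tracts (default 0.10).
#' @param n_runs number of planted N runs per chromosome (default 0).
#' @param n_run_length length of each N run (default 30).
#' @param genes_per_chrom protein-coding genes per chromosome.
#' @param n_exons exons per gene.
#' @param cds_codons coding length per gene, in codons (incl. start
#'   and stop).
#' @param utr_length length of each UTR (default 60).
#' @param intron_length intron length (default 120).
#' @param seed RNG seed (NULL = current stream).
#' @return list with `genome` ([genome_ref]), `models`
#'   ([gene_models]), `genes` (truth data.frame: gene coordinates,
#'   strand, CDS span), `repeats` (truth data.frame of masked tracts).
#' @export
simulate_genome <- function(n_chromosomes = 2, chrom_length = 100000,
                            gc = 0.40, repeat_fraction = 0.10,
                            n_runs = 0, n_run_length = 30,
                            genes_per_chrom = 8, n_exons = 3,
                            cds_codons = 120, utr_length = 60,
                            intron_length = 120, seed = NULL) {
  stopifnot(repeat_fraction >= 0, repeat_fraction < 1)
  lens <- rep_len(as.integer(chrom_length), n_chromosomes)
  with_seed(seed, {
    base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    chroms <- list(); gene_rows <- list(); feat_rows <- list(); rep_rows <- list()
    gi <- 0L
    for (ci in seq_len(n_chromosomes)) {
      ch <- paste0("chr", ci)
      len <- lens[ci]
      v <- sample(names(base_p), len, replace = TRUE, prob = base_p)
      # gene geometry: [utr5][cds piece][intron]...[cds piece][utr3]
      cds_len <- 3L * cds_codons
      piece <- diff(round(seq(0, cds_len, length.out = n_exons + 1)))
      glen <- utr_length + cds_len + (n_exons - 1L) * intron_length + utr_length
      if (genes_per_chrom * (glen + 200) > len)
        stop("gene geometry exceeds chromosome length")
      # evenly spread gene anchors, jittered
      slots <- round(seq(1, len - glen, length.out = genes_per_chrom + 2))
      slots <- slots[2:(genes_per_chrom + 1)]
      occupied <- IRanges::IRanges()
      for (s in slots) {
        gi <- gi + 1L
        gid <- sprintf("gene%03d", gi)
        strand <- if (gi %% 2 == 0) "-" else "+"
        codons <- setdiff(names(Biostrings::GENETIC_CODE)
                          [Biostrings::GENETIC_CODE != "*"], "ATG")
        body <- paste(sample(codons, cds_codons - 2L, replace = TRUE),
                      collapse = "")
        cds_seq <- paste0("ATG", body, "TAA")
        # assemble gene-local plus-strand sequence and feature intervals
        segs <- character(0)
        local <- list()
        cur <- 0L
        add <- function(s_, type_) {
          segs <<- c(segs, s_)
          local[[length(local) + 1L]] <<- list(type = type_,
                                               start = cur + 1L,
                                               end = cur + nchar(s_))
          cur <<- cur + nchar(s_)
        }
        rnd <- function(n_) paste(sample(names(base_p), n_, TRUE, base_p),
                                  collapse = "")
        add(rnd(utr_length), "five_prime_UTR")
        at <- 1L
        for (e in seq_len(n_exons)) {
          add(substr(cds_seq, at, at + piece[e] - 1L), "CDS")
          at <- at + piece[e]
          if (e < n_exons) add(rnd(intron_length), "intron")
        }
        add(rnd(utr_length), "three_prime_UTR")
        gseq <- paste(segs, collapse = "")
        stopifnot(nchar(gseq) == glen)
        if (strand == "-") gseq <- revcomp(gseq)
        v[s:(s + glen - 1L)] <- strsplit(gseq, "")[[1]]
        occupied <- c(occupied, IRanges::IRanges(s, s + glen - 1L))
        # map local feature coordinates to the chromosome
        to_chrom <- function(a, b) {
          if (strand == "+") c(s + a - 1L, s + b - 1L)
          else c(s + glen - b, s + glen - a)
        }
        gene_rows[[gi]] <- data.frame(
          gene_id = gid, chrom = ch, start = s, end = s + glen - 1L,
          strand = strand, cds_len = cds_len, stringsAsFactors = FALSE)
        for (f in local) {
          if (f$type == "intron") next
          cc <- to_chrom(f$start, f$end)
          feat_rows[[length(feat_rows) + 1L]] <- data.frame(
            gene_id = gid, chrom = ch, start = cc[1], end = cc[2],
            strand = strand, type = f$type, stringsAsFactors = FALSE)
        }
        # exons = UTRs fused with their neighbouring CDS pieces
        exon_local <- list()
        ftypes <- vapply(local, `[[`, "", "type")
        fs <- vapply(local, `[[`, 0L, "start")
        fe <- vapply(local, `[[`, 0L, "end")
        brk <- which(ftypes == "intron")
        bounds <- c(0L, brk, length(local) + 1L)
        for (x in seq_len(length(bounds) - 1L)) {
          memb <- (bounds[x] + 1L):(bounds[x + 1L] - 1L)
          cc <- to_chrom(min(fs[memb]), max(fe[memb]))
          feat_rows[[length(feat_rows) + 1L]] <- data.frame(
            gene_id = gid, chrom = ch, start = cc[1], end = cc[2],
            strand = strand, type = "exon", stringsAsFactors = FALSE)
        }
      }
      # repeat tracts: soft-mask random intergenic stretches
      target <- round(repeat_fraction * len)
      tract <- 400L
      tries <- 0L
      masked <- IRanges::IRanges()
      while (sum(IRanges::width(masked)) < target && tries < 10000L) {
        tries <- tries + 1L
        st <- sample.int(len - tract, 1L)
        cand <- IRanges::IRanges(st, st + tract - 1L)
        if (length(IRanges::findOverlaps(cand, occupied)) ||
            length(IRanges::findOverlaps(cand, masked))) next
        masked <- c(masked, cand)
      }
      masked <- IRanges::reduce(masked)
      for (k in seq_along(masked)) {
        idx <- IRanges::start(masked)[k]:IRanges::end(masked)[k]
        v[idx] <- tolower(v[idx])
        rep_rows[[length(rep_rows) + 1L]] <- data.frame(
          chrom = ch, start = IRanges::start(masked)[k],
          end = IRanges::end(masked)[k], type = "softmask",
          stringsAsFactors = FALSE)
      }
      if (n_runs > 0) {
        for (k in seq_len(n_runs)) {
          repeat {
            st <- sample.int(len - n_run_length, 1L)
            cand <- IRanges::IRanges(st, st + n_run_length - 1L)
            if (!length(IRanges::findOverlaps(cand, occupied)) &&
                !length(IRanges::findOverlaps(cand, masked))) break
          }
          idx <- st:(st + n_run_length - 1L)
          v[idx] <- "N"
          rep_rows[[length(rep_rows) + 1L]] <- data.frame(
            chrom = ch, start = st, end = st + n_run_length - 1L,
            type = "N_run", stringsAsFactors = FALSE)
        }
      }
      chroms[[ch]] <- paste(v, collapse = "")
    }
    genes <- do.call(rbind, gene_rows)
    features <- do.call(rbind, feat_rows)
    list(
      genome = genome_ref(unlist(chroms)),
      models = gene_models(genes[, c("gene_id", "chrom", "start", "end",
                                     "strand")], features),
      genes = genes,
      repeats = if (length(rep_rows)) do.call(rbind, rep_rows) else
        data.frame(chrom = character(0), start = integer(0),
                   end = integer(0), type = character(0))
    )
  })
}

#' Simulate a founder population of fully inbred lines
#'
#' Founders are homozygous at every locus (codes 0/2 only): sample `s`
#' carries the alternate homozygote at locus `l` with probability equal
#' to that locus's alternate-allele frequency, drawn from
#' `maf_sampler`.
#'
#' @param n_samples number of founder lines.
#' @param n_loci number of loci.
#' @param maf_sampler function of `n` returning alternate-allele
#'   frequencies in (0, 0.5\]; default uniform on \[0.05, 0.5\].
#' @param loci optional locus keys (default `L1..Ln`).
#' @param seed RNG seed.
#' @return list `geno` ([geno_matrix]) and `truth` (data.frame
#'   `locus, alt_freq`).
#' @export
simulate_founders <- function(n_samples, n_loci,
                              maf_sampler = function(n) stats::runif(n, 0.05, 0.5),
                              loci = NULL, seed = NULL) {
  with_seed(seed, {
    p <- maf_sampler(n_loci)
    m <- matrix(2L * stats::rbinom(n_samples * n_loci, 1L,
                                   rep(p, each = n_samples)),
                nrow = n_samples)
    gm <- geno_matrix(m, samples = sprintf("F%03d", seq_len(n_samples)),
                      loci = if (is.null(loci)) paste0("L", seq_len(n_loci))
                             else loci)
    list(geno = gm, truth = data.frame(locus = colnames(gm), alt_freq = p,
                                       stringsAsFactors = FALSE))
  })
}

#' F1 cross of two fully inbred parents
#'
#' The F1 is heterozygous exactly where the parents carry different
#' homozygotes and homozygous (the shared code) elsewhere, so its Het
#' equals the parental divergence fraction by construction.
#'
#' @param a,b parental genotype code vectors (homozygous: 0/2 only;
#'   a heterozygous parent is an error).
#' @return F1 genotype code vector.
#' @export
cross_f1 <- function(a, b) {
  if (any(stats::na.omit(c(a, b)) == 1L))
    stop("parents must be fully inbred (no heterozygous calls)")
  out <- ifelse(is.na(a) | is.na(b), NA_integer_,
                ifelse(a == b, a, 1L))
  as.integer(out)
}

# one selfing round in donor-dosage space: two independent gametes
self_once <- function(g) {
  het <- which(g == 1L)
  if (length(het))
    g[het] <- stats::rbinom(length(het), 1L, 0.5) +
      stats::rbinom(length(het), 1L, 0.5)
  g
}

#' Self a line for several generations
#'
#' Each generation transmits two independent gametes per locus; loci
#' segregate independently (no linkage).
#'
#' @param g genotype code vector.
#' @param n_generations number of selfing rounds.
#' @param seed RNG seed (NULL = current stream).
#' @return selfed genotype vector.
#' @export
self_line <- function(g, n_generations, seed = NULL) {
  with_seed(seed, {
    for (i in seq_len(n_generations)) g <- self_once(g)
    g
  })
}

#' Breed backcross-selfing pedigrees from two inbred founders
#'
#' Simulates BCnFm material: an F1 of the two parents, `n_backcross`
#' backcrosses to the recurrent parent (`parent_a`), then selfing up to
#' filial generation `n_self` (i.e. `n_self - 1` selfing rounds after
#' the last cross; `n_backcross = 0, n_self = 1` is the F1 itself).
#' Loci segregate independently. Expected heterozygosity of a line is
#' `d * (1/2)^n_backcross * (1/2)^(n_self - 1)` where `d` is the
#' fraction of loci at which the parents differ.
#'
#' @param parent_a recurrent parent genotype vector (inbred).
#' @param parent_b donor parent genotype vector (inbred).
#' @param n_backcross number of backcrosses to `parent_a` (>= 0).
#' @param n_self filial generation index (>= 1).
#' @param n_lines number of independent replicate lines.
#' @param seed RNG seed.
#' @return a [geno_matrix] of `n_lines` x loci.
#' @export
breed_pedigree <- function(parent_a, parent_b, n_backcross = 0, n_self = 1,
                           n_lines = 1, seed = NULL) {
  if (n_backcross < 0 || n_self < 1) stop("need n_backcross >= 0, n_self >= 1")
  f1 <- cross_f1(parent_a, parent_b)
  diff_loci <- which(parent_a != parent_b &
                       !is.na(parent_a) & !is.na(parent_b))
  L <- length(parent_a)
  with_seed(seed, {
    lines <- matrix(rep(f1, n_lines), nrow = n_lines, byrow = TRUE)
    if (length(diff_loci)) {
      # donor dosage at divergent loci: F1 is 1 everywhere there
      dos <- matrix(1L, n_lines, length(diff_loci))
      for (bc in seq_len(n_backcross)) {
        # gamete from the line meets a recurrent (dosage-0) gamete
        dos <- matrix(stats::rbinom(length(dos), 1L, dos / 2),
                      nrow = n_lines)
      }
      for (sf in seq_len(n_self - 1L)) {
        dos <- matrix(stats::rbinom(length(dos), 1L, dos / 2) +
                        stats::rbinom(length(dos), 1L, dos / 2),
                      nrow = n_lines)
      }
      # back to code space: 0 -> recurrent code, 2 -> donor code, 1 -> het
      pa <- matrix(rep(parent_a[diff_loci], each = n_lines), nrow = n_lines)
      pb <- matrix(rep(parent_b[diff_loci], each = n_lines), nrow = n_lines)
      lines[, diff_loci] <- ifelse(dos == 0L, pa, ifelse(dos == 2L, pb, 1L))
    }
    geno_matrix(lines,
                samples = sprintf("BC%dF%d_%03d", n_backcross, n_self,
                                  seq_len(n_lines)),
                loci = names(parent_a) %||% paste0("L", seq_len(L)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inject missingness and genotype errors
#'
#' Masks each call to missing with probability `missing_rate`, then
#' flips a fraction `error_rate` of the remaining calls to a different
#' code chosen uniformly. The truth masks are returned alongside.
#'
#' @param gm a [geno_matrix].
#' @param missing_rate,error_rate rates in \[0, 1).
#' @param seed RNG seed.
#' @return list `geno` (perturbed matrix), `missing_mask`,
#'   `error_mask` (logical matrices).
#' @export
inject_noise <- function(gm, missing_rate = 0, error_rate = 0, seed = NULL) {
  stopifnot(missing_rate >= 0, missing_rate < 1,
            error_rate >= 0, error_rate < 1)
  with_seed(seed, {
    m <- unclass(gm)
    miss <- matrix(stats::runif(length(m)) < missing_rate, nrow(m))
    miss <- miss & !is.na(m)
    m[miss] <- NA_integer_
    err <- matrix(stats::runif(length(m)) < error_rate, nrow(m))
    err <- err & !is.na(m)
    if (any(err)) {
      old <- m[err]
      shift <- sample.int(2L, sum(err), replace = TRUE)
      m[err] <- (old + shift) %% 3L
    }
    out <- geno_matrix(m, samples = rownames(gm), loci = colnames(gm))
    list(geno = out, missing_mask = miss, error_mask = err)
  })
}
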
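# Shared fixture builders and independent oracles used across tests.

# deterministic random sequence without long homopolymers
random_seq <- function(n, seed = NULL, gc = 0.5) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, TRUE,
                                 prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                          (1 - gc) / 2)), collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# genotype matrix with prescribed codes laid out loci-major for readability
gm_from_rows <- function(...) {
  rows <- list(...)
  geno_matrix(do.call(rbind, rows))
}

# --- independent feasibility oracle (brute force, no package internals) ---

oracle_encode <- function(s) {
  v <- strsplit(toupper(s), "")[[1]]
  match(v, c("A", "C", "G", "T"))  # NA for N and others
}

oracle_revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# count full-length ungapped placements with identity strictly above the
# cutoff, by sliding-window comparison over every chromosome and strand
oracle_hit_count <- function(chrom_codes, query, min_identity = 0.6) {
  m <- nchar(query)
  total <- 0L
  for (qs in c(query, oracle_revcomp(query))) {
    q <- oracle_encode(qs)
    for (cc in chrom_codes) {
      n <- length(cc)
      if (n < m) next
      acc <- integer(n - m + 1L)
      for (j in seq_len(m)) {
        eq <- cc[j:(n - m + j)] == q[j]
        eq[is.na(eq)] <- FALSE
        acc <- acc + eq
      }
      total <- total + sum(acc > min_identity * m)
    }
  }
  total
}

# the four probe predicates recomputed from the raw soft-masked strings
oracle_feasibility <- function(fasta_chroms, loci, indels,
                               flank = 100, chrom_codes = NULL) {
  if (is.null(chrom_codes)) chrom_codes <- lapply(fasta_chroms, oracle_encode)
  vapply(seq_len(nrow(loci)), function(i) {
    ch <- loci$chrom[i]; p <- loci$pos[i]
    s <- fasta_chroms[[ch]]
    len <- nchar(s)
    if (p - flank < 1 || p + flank > len) return(FALSE)
    ctx <- substr(s, p - flank, p + flank)
    up <- toupper(ctx)
    # GC over unambiguous bases
    nb <- nchar(gsub("[^ACGT]", "", up))
    gc <- if (nb == 0) NA else nchar(gsub("[^GC]", "", up)) / nb
    if (is.na(gc) || gc < 0.40 || gc > 0.60) return(FALSE)
    # repeat: any soft-masked (lowercase) base, or a homopolymer run
    if (grepl("[a-z]", ctx)) return(FALSE)
    if (grepl("A{10,}|C{10,}|G{10,}|T{10,}", up)) return(FALSE)
    if (grepl("[^ACGT]", up)) return(FALSE)
    # large InDel in the window
    if (!is.null(indels)) {
      ilen <- abs(nchar(indels$ref) - nchar(indels$alt))
      iend <- indels$pos + nchar(indels$ref) - 1L
      if (any(indels$chrom == ch & ilen > 5 &
              indels$pos <= p + flank & iend >= p - flank)) return(FALSE)
    }
    # single copy by brute-force sliding-window count
    oracle_hit_count(chrom_codes, ctx) == 1L
  }, TRUE)
}

# mutate a sequence to approximately the given identity
mutate_to_identity <- function(s, identity, seed = NULL) {
  f <- function() {
    v <- strsplit(s, "")[[1]]
    k <- round((1 - identity) * length(v))
    idx <- sample(length(v), k)
    v[idx] <- vapply(v[idx], function(b)
      sample(setdiff(c("A", "C", "G", "T"), toupper(b)), 1), "")
    paste(v, collapse = "")
  }
  if (is.null(seed)) f() else withr::with_seed(seed, f())
}
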
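#' Pairwise genetic similarity of two genotype vectors
#'
#' Genetic similarity is the proportion of loci at which two samples
#' carry the identical diploid genotype code (a heterozygote never
#' matches either homozygote) relative to the loci analysed. Under the
#' default `pairwise_complete` policy the denominator is the loci
#' non-missing in both samples; under `strict` it is the full locus
#' count, with any missing call counted as a mismatch. An `ibs` mode
#' scores allele sharing (0, 0.5, 1 per locus) instead of exact code
#' identity.
#'
#' @param a,b equal-length genotype code vectors over \{0, 1, 2, NA\}.
#' @param policy `"pairwise_complete"` (default) or `"strict"`.
#' @param mode `"exact"` (default) or `"ibs"`.
#' @return list `similarity` (`NA` and flagged if no locus is
#'   comparable), `n_effective`.
#' @export
genetic_similarity <- function(a, b, policy = c("pairwise_complete", "strict"),
                               mode = c("exact", "ibs")) {
  policy <- match.arg(policy)
  mode <- match.arg(mode)
  if (length(a) != length(b)) stop("genotype vectors differ in length")
  both <- !is.na(a) & !is.na(b)
  score <- if (mode == "exact") as.numeric(a[both] == b[both])
    else 1 - abs(a[both] - b[both]) / 2
  n_eff <- if (policy == "pairwise_complete") sum(both) else length(a)
  if (n_eff == 0L)
    return(list(similarity = NA_real_, n_effective = 0L))
  list(similarity = sum(score) / n_eff, n_effective = n_eff)
}

#' All-pairs genetic similarity matrix
#'
#' @param gm a [geno_matrix] with at least two samples.
#' @inheritParams genetic_similarity
#' @return a `similarity_matrix`: list with `sim` (symmetric matrix,
#'   unit diagonal), `n_eff` (per-pair effective locus counts),
#'   `policy`, `mode`.
#' @export
similarity_matrix <- function(gm, policy = c("pairwise_complete", "strict"),
                              mode = c("exact", "ibs")) {
  policy <- match.arg(policy)
  mode <- match.arg(mode)
  n <- nrow(gm)
  if (n < 2L) stop("need at least two samples")
  sim <- matrix(1, n, n, dimnames = list(rownames(gm), rownames(gm)))
  neff <- matrix(ncol(gm), n, n, dimnames = dimnames(sim))
  m <- unclass(gm)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    gs <- genetic_similarity(m[i, ], m[j, ], policy, mode)
    sim[i, j] <- sim[j, i] <- gs$similarity
    neff[i, j] <- neff[j, i] <- gs$n_effective
  }
  diag(neff) <- if (policy == "pairwise_complete") rowSums(!is.na(m))
    else ncol(m)
  structure(list(sim = sim, n_eff = neff, policy = policy, mode = mode),
            class = "similarity_matrix")
}

#' @export
#' @method print similarity_matrix
print.similarity_matrix <- function(x, ...) {
  off <- x$sim[upper.tri(x$sim)]
  cat("similarity_matrix:", nrow(x$sim), "samples; off-diagonal range",
      sprintf("%.4f-%.4f (%s, %s)\n", min(off, na.rm = TRUE),
              max(off, na.rm = TRUE), x$policy, x$mode))
  invisible(x)
}

#' Flag sample pairs above a similarity threshold
#'
#' Pairs at or above the threshold (default 0.90, the close-relative
#' screen for sister lines, backcross material and same-row plants),
#' sorted by descending similarity.
#'
#' @param sim a [similarity_matrix()] result (or plain symmetric matrix).
#' @param threshold flagging threshold (default 0.90).
#' @return data.frame `sample_a, sample_b, similarity, n_effective`.
#' @export
flag_close_relatives <- function(sim, threshold = 0.90) {
  s <- if (inherits(sim, "similarity_matrix")) sim$sim else sim
  ne <- if (inherits(sim, "similarity_matrix")) sim$n_eff else
    matrix(NA_integer_, nrow(s), ncol(s))
  idx <- which(upper.tri(s) & !is.na(s) & s >= threshold, arr.ind = TRUE)
  out <- data.frame(
    sample_a = rownames(s)[idx[, 1]],
    sample_b = colnames(s)[idx[, 2]],
    similarity = s[idx],
    n_effective = ne[idx],
    stringsAsFactors = FALSE)
  out[order(-out$similarity, out$sample_a), , drop = FALSE]
}

#' Individual heterozygosity and hybrid calls
#'
#' Het is the proportion of a sample's loci called heterozygous
#' relative to the loci analysed: non-missing loci under the default
#' policy, the full panel count under `strict`. Samples at or above
#' the threshold (default 0.10) are called `hybrid`, others
#' `pure_line`; an all-missing sample gets `NA` and no call.
#'
#' @param gm a [geno_matrix] (or single genotype vector).
#' @param threshold hybrid-call threshold on Het (default 0.10).
#' @param policy `"non_missing"` (default) or `"strict"`.
#' @return data.frame `sample, het, n_effective, call`.
#' @export
heterozygosity <- function(gm, threshold = 0.10,
                           policy = c("non_missing", "strict")) {
  policy <- match.arg(policy)
  if (is.null(dim(gm))) gm <- geno_matrix(matrix(gm, nrow = 1))
  m <- unclass(gm)
  n_het <- rowSums(m == 1L, na.rm = TRUE)
  n_called <- rowSums(!is.na(m))
  n_eff <- if (policy == "non_missing") n_called else rep(ncol(m), nrow(m))
  het <- ifelse(n_eff > 0, n_het / n_eff, NA_real_)
  data.frame(
    sample = rownames(m),
    het = het,
    n_effective = as.integer(n_eff),
    call = ifelse(is.na(het), NA_character_,
                  ifelse(het >= threshold, "hybrid", "pure_line")),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' p-distance matrix from genotypes
#'
#' `d(a, b) = 1 - similarity(a, b)` under the same missing-data policy
#' as [similarity_matrix()]; symmetric with a zero diagonal.
#'
#' @inheritParams similarity_matrix
#' @return a base [stats::dist]-compatible square matrix.
#' @export
p_distance <- function(gm, policy = c("pairwise_complete", "strict"),
                       mode = c("exact", "ibs")) {
  sm <- similarity_matrix(gm, policy, mode)
  1 - sm$sim
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical agglomerative neighbor joining (Saitou-Nei Q criterion).
#' Distances that are additive over a tree are inverted to that exact
#' tree (topology and branch lengths). Negative branch-length
#' estimates are clamped to zero with the deficit moved to the sister
#' branch, preserving the pair's path length; the number of clamped
#' edges is reported in attribute `n_clamped`. Ties in the Q matrix
#' resolve to the smallest row/column pair, making the result
#' deterministic.
#'
#' @param d square symmetric distance matrix (or `dist`), n >= 3,
#'   finite entries.
#' @return an unrooted [ape::phylo] tree with branch lengths and
#'   attribute `n_clamped`.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (any(!is.finite(d))) stop("distance matrix has non-finite entries")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  frag <- labels          # Newick fragment per active node
  active <- seq_len(n)
  D <- d
  n_clamped <- 0L
  fmt <- function(x) sprintf("%.12g", x)
  while (length(active) > 3L) {
    m <- length(active)
    Dm <- D[active, active]
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    ij <- which(Q == min(Q), arr.ind = TRUE)
    ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE][1, ]
    i <- min(ij); j <- max(ij)
    li <- Dm[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- Dm[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0; n_clamped <- n_clamped + 1L }
    if (lj < 0) { li <- li + lj; lj <- 0; n_clamped <- n_clamped + 1L }
    ai <- active[i]; aj <- active[j]
    newfrag <- paste0("(", frag[ai], ":", fmt(li), ",",
                      frag[aj], ":", fmt(lj), ")")
    # distances from the new node u to every other active node
    others <- active[-c(i, j)]
    du <- (D[ai, others] + D[aj, others] - D[ai, aj]) / 2
    D <- rbind(cbind(D, 0), 0)
    u <- nrow(D)
    D[u, others] <- du; D[others, u] <- du
    frag <- c(frag, newfrag)
    active <- c(others, u)
  }
  # terminal star of three: three-point branch lengths
  a <- active[1]; b <- active[2]; c3 <- active[3]
  la <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
  lb <- (D[a, b] + D[b, c3] - D[a, c3]) / 2
  lc <- (D[a, c3] + D[b, c3] - D[a, b]) / 2
  for (v in c("la", "lb", "lc")) {
    if (get(v) < 0) {
      assign(v, 0)
      n_clamped <- n_clamped + 1L
    }
  }
  nwk <- paste0("(", frag[a], ":", fmt(la), ",", frag[b], ":", fmt(lb),
                ",", frag[c3], ":", fmt(lc), ");")
  tree <- ape::read.tree(text = nwk)
  attr(tree, "n_clamped") <- n_clamped
  tree
}

#' Bootstrap support for the NJ tree by locus resampling
#'
#' Resamples loci with replacement `n_reps` times, rebuilds the
#' p-distance NJ tree per replicate, and reports the bipartition
#' frequency (percent) of each internal edge of the full-data tree as
#' node labels.
#'
#' @param gm a [geno_matrix].
#' @param n_reps bootstrap replicates (default 1000).
#' @param seed RNG seed for the resampling.
#' @inheritParams similarity_matrix
#' @return the full-data NJ tree with percent supports in
#'   `node.label` (the basal node is blank) and attribute
#'   `boot_counts`.
#' @export
bootstrap_support <- function(gm, n_reps = 1000, seed = 1L,
                              policy = c("pairwise_complete", "strict")) {
  policy <- match.arg(policy)
  full <- neighbor_joining(p_distance(gm, policy))
  L <- ncol(gm)
  boots <- with_seed(seed, lapply(seq_len(n_reps), function(r) {
    idx <- sample.int(L, L, replace = TRUE)
    neighbor_joining(p_distance(gm[, idx, drop = FALSE], policy))
  }))
  counts <- ape::prop.clades(full, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round_half_up(100 * counts / n_reps, 1)
  full$node.label <- as.character(support)
  full$node.label[1] <- ""   # basal trichotomy, not a bipartition
  attr(full, "boot_counts") <- counts
  full
}

#' Principal components of a genotype matrix
#'
#' Missing codes are mean-imputed per locus, columns centred (no
#' variance scaling), and the sample configuration eigendecomposed.
#' Component signs follow the convention that the largest-magnitude
#' locus loading is positive. A constant (zero-variance) matrix is
#' flagged.
#'
#' @param gm a [geno_matrix], >= 2 samples and >= 2 loci.
#' @param n_components number of components to return (default 3).
#' @return list `scores` (samples x components), `explained` (fraction
#'   of variance per returned component), `sdev` (all singular values
#'   / sqrt(n-1)), `zero_variance` flag.
#' @export
genotype_pca <- function(gm, n_components = 3) {
  if (nrow(gm) < 2L || ncol(gm) < 2L) stop("need >= 2 samples and >= 2 loci")
  X <- unclass(gm) * 1.0
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  X <- sweep(X, 2, colMeans(X))
  if (all(abs(X) < .Machine$double.eps * 100)) {
    k <- min(n_components, nrow(X) - 1L)
    return(list(scores = matrix(0, nrow(X), k,
                                dimnames = list(rownames(gm), paste0("PC", seq_len(k)))),
                explained = rep(0, k), sdev = rep(0, k),
                zero_variance = TRUE))
  }
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (c in seq_len(k)) {
    top <- which.max(abs(rot[, c]))
    if (rot[top, c] < 0) { rot[, c] <- -rot[, c]; scores[, c] <- -scores[, c] }
  }
  ev <- pc$sdev^2
  list(scores = scores, explained = ev[seq_len(k)] / sum(ev),
       sdev = pc$sdev, zero_variance = FALSE)
}

#' Write identification outputs
#'
#' Similarity matrix, Het report and PCA coordinates as TSV; the NJ
#' tree as Newick (supports as internal node labels).
#'
#' @param x a `similarity_matrix`, [heterozygosity()] table,
#'   [genotype_pca()] result or `phylo` tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ident <- function(x, path) {
  if (inherits(x, "similarity_matrix")) {
    utils::write.table(data.frame(sample = rownames(x$sim), x$sim,
                                  check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (inherits(x, "phylo")) {
    ape::write.tree(x, file = path)
  } else if (is.list(x) && !is.null(x$scores)) {
    utils::write.table(data.frame(sample = rownames(x$scores), x$scores,
                                  check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
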
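test_that("genetic similarity counts identical genotype codes over shared loci", {
  a <- rep(c(0L, 1L, 2L), length.out = 120)
  expect_equal(genetic_similarity(a, a)$similarity, 1.0)
  expect_equal(genetic_similarity(rep(0L, 100), rep(2L, 100))$similarity, 0.0)
  # het never matches a homozygote under exact-code identity
  expect_equal(genetic_similarity(c(1L, 1L), c(0L, 2L))$similarity, 0.0)
  # 100 loci: 90 equal, 6 unequal, 4 missing in one sample
  a <- rep(0L, 100)
  b <- rep(0L, 100)
  b[1:6] <- 2L
  b[7:10] <- NA
  gs <- genetic_similarity(a, b)
  expect_equal(gs$n_effective, 96L)
  expect_equal(gs$similarity, 90 / 96)
  # strict policy keeps the full panel in the denominator
  gs2 <- genetic_similarity(a, b, policy = "strict")
  expect_equal(gs2$similarity, 90 / 100)
  # IBS mode scores allele sharing
  expect_equal(genetic_similarity(c(0L, 0L), c(1L, 2L),
                                  mode = "ibs")$similarity, 0.25)
  # no shared locus: undefined
  expect_true(is.na(genetic_similarity(c(NA, 0L), c(1L, NA))$similarity))
})

test_that("the similarity matrix is symmetric and matches a double-loop recompute", {
  withr::local_seed(31)
  founders <- simulate_founders(12, 400)$geno
  noisy <- inject_noise(founders, missing_rate = 0.05)$geno
  sm <- similarity_matrix(noisy)
  expect_equal(sm$sim, t(sm$sim))
  expect_equal(unname(diag(sm$sim)), rep(1, 12))
  # independent recompute
  m <- unclass(noisy)
  oracle <- matrix(1, 12, 12)
  for (i in 1:12) for (j in 1:12) {
    if (i == j) next
    both <- !is.na(m[i, ]) & !is.na(m[j, ])
    oracle[i, j] <- sum(m[i, both] == m[j, both]) / sum(both)
  }
  expect_equal(unname(sm$sim), oracle)
  # three identical samples: unit off-diagonals
  tri <- geno_matrix(matrix(rep(c(0L, 1L, 2L, 0L), 3), 3, byrow = TRUE))
  expect_true(all(similarity_matrix(tri)$sim == 1))
})

test_that("similarity is invariant to sample and locus ordering", {
  withr::local_seed(5)
  gm <- inject_noise(simulate_founders(8, 300)$geno, missing_rate = 0.1)$geno
  sm <- similarity_matrix(gm)$sim
  sp <- sample(nrow(gm)); lp <- sample(ncol(gm))
  sm_perm <- similarity_matrix(gm[sp, lp])$sim
  expect_equal(sm_perm, sm[sp, sp])
})

test_that("close relatives are flagged at and above the threshold, sorted", {
  s <- matrix(c(1, .9133, .7738,
                .9133, 1, .95,
                .7738, .95, 1), 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  fl <- flag_close_relatives(s, 0.90)
  expect_equal(nrow(fl), 2L)
  expect_equal(fl$similarity, c(0.95, 0.9133))   # descending; 0.7738 excluded
  # threshold 1.0 keeps only exact duplicates
  expect_equal(nrow(flag_close_relatives(s, 1.0)), 0L)
  s["x", "y"] <- s["y", "x"] <- 1
  expect_equal(flag_close_relatives(s, 1.0)$sample_b, "y")
})

test_that("heterozygosity counts het calls over the analysed loci", {
  all_het <- heterozygosity(rep(1L, 50))
  expect_equal(all_het$het, 1.0)
  expect_equal(all_het$call, "hybrid")
  all_hom <- heterozygosity(rep(c(0L, 2L), 25))
  expect_equal(all_hom$het, 0.0)
  expect_equal(all_hom$call, "pure_line")
  # 1000 loci: 120 het, 850 hom, 30 missing
  g <- c(rep(1L, 120), rep(0L, 425), rep(2L, 425), rep(NA, 30))
  hp <- heterozygosity(g)
  expect_equal(hp$n_effective, 970L)
  expect_equal(hp$het, 120 / 970)
  expect_equal(hp$call, "hybrid")
  # strict policy divides by the panel size instead
  expect_equal(heterozygosity(g, policy = "strict")$het, 0.12)
  # all-missing sample: undefined and uncalled
  expect_true(is.na(heterozygosity(rep(NA_integer_, 10))$het))
})

test_that("p-distance is one minus similarity with metric basics", {
  withr::local_seed(17)
  gm <- simulate_founders(6, 200)$geno
  d <- p_distance(gm)
  s <- similarity_matrix(gm)$sim
  expect_equal(d, 1 - s)
  expect_equal(unname(diag(d)), rep(0, 6))
  expect_equal(d, t(d))
  two <- geno_matrix(matrix(c(rep(0L, 10), rep(2L, 10)), 2, byrow = TRUE))
  expect_equal(p_distance(two)[1, 2], 1)
})

# distances along a fixed 4-taxon tree: ((A:1,B:2):5,C:3,D:4) unrooted
additive_4taxon <- function() {
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 1 + 2
  d["A", "C"] <- d["C", "A"] <- 1 + 5 + 3
  d["A", "D"] <- d["D", "A"] <- 1 + 5 + 4
  d["B", "C"] <- d["C", "B"] <- 2 + 5 + 3
  d["B", "D"] <- d["D", "B"] <- 2 + 5 + 4
  d["C", "D"] <- d["D", "C"] <- 3 + 4
  d
}

test_that("neighbor joining inverts additive distances exactly", {
  tr <- neighbor_joining(additive_4taxon())
  expect_s3_class(tr, "phylo")
  expect_equal(attr(tr, "n_clamped"), 0L)
  # recovered path lengths equal the input distances
  paths <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(paths, additive_4taxon(), tolerance = 1e-9)
  # topology: A-B form a cherry
  pair <- ape::extract.clade(ape::root(tr, "D"),
                             ape::getMRCA(ape::root(tr, "D"), c("A", "B")))
  expect_setequal(pair$tip.label, c("A", "B"))
})

test_that("three taxa solve by the three-point formulas", {
  d <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  expect_equal(sort(tr$edge.length), sort(c(1, 2, 4)))
  expect_equal(ape::cophenetic.phylo(tr)[c("a", "b", "c"), c("a", "b", "c")],
               d, tolerance = 1e-9)
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
  d[1, 2] <- d[2, 1] <- NaN
  expect_error(neighbor_joining(d), "non-finite")
})

test_that("an 8-taxon tree is recovered and matches an independent NJ run", {
  withr::local_seed(23)
  ref <- ape::rtree(8)
  ref$edge.length <- runif(nrow(ref$edge), 0.5, 2)
  d <- ape::cophenetic.phylo(ref)
  mine <- neighbor_joining(d)
  # additive inversion: path lengths reproduce the generating tree's
  expect_equal(ape::cophenetic.phylo(mine)[rownames(d), colnames(d)], d,
               tolerance = 1e-8)
  # topology agrees with the reference implementation
  expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ape::nj(d))), 0,
               ignore_attr = TRUE)
})

test_that("negative branch estimates are clamped and flagged", {
  # three-point formulas give la = (2 + 2 - 5)/2 = -0.5 here
  d <- matrix(c(0, 2, 2, 2, 0, 5, 2, 5, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
  expect_gte(attr(tr, "n_clamped"), 1L)
})

test_that("bootstrap supports separate well-separated clusters and are seeded", {
  withr::local_seed(41)
  # two 5-sample clusters: divergence between clusters far above within
  base1 <- sample(c(0L, 2L), 300, TRUE)
  base2 <- ifelse(base1 == 0L, 2L, 0L)
  base2[1:150] <- base1[1:150]          # 50% divergence between clusters
  jitter_line <- function(base, k = 6) {
    x <- base
    idx <- sample(300, k)
    x[idx] <- 2L - x[idx]
    x
  }
  m <- rbind(t(replicate(5, jitter_line(base1))),
             t(replicate(5, jitter_line(base2))))
  gm <- geno_matrix(m, samples = paste0("s", 1:10))
  bt <- bootstrap_support(gm, n_reps = 200, seed = 7)
  # find the edge splitting s1-5 from s6-10: its support must be high
  supports <- as.numeric(bt$node.label[bt$node.label != ""])
  expect_gte(max(supports), 95)
  # determinism under the same seed
  bt2 <- bootstrap_support(gm, n_reps = 200, seed = 7)
  expect_identical(bt$node.label, bt2$node.label)
  # a single replicate can only give 0 or 100
  b1 <- bootstrap_support(gm, n_reps = 1, seed = 3)
  sup1 <- as.numeric(b1$node.label[b1$node.label != ""])
  expect_true(all(sup1 %in% c(0, 100)))
})

test_that("genotype PCA separates constructed clusters and is well-ordered", {
  withr::local_seed(51)
  base1 <- sample(c(0L, 2L), 200, TRUE)
  base2 <- base1
  flip <- sample(200, 100)               # clusters differ at 50% of loci
  base2[flip] <- 2L - base2[flip]
  jit <- function(b) { i <- sample(200, 3); b[i] <- 2L - b[i]; b }
  m <- rbind(t(replicate(6, jit(base1))), t(replicate(6, jit(base2))))
  gm <- geno_matrix(m)
  pc <- genotype_pca(gm)
  expect_gt(pc$explained[1], 0.9)
  # PC1 splits the clusters
  expect_true(all(sign(pc$scores[1:6, 1]) != sign(pc$scores[7:12, 1])))
  # explained variances are non-increasing and non-negative
  expect_true(all(diff(pc$sdev) <= 1e-12))
  expect_true(all(pc$explained >= 0))
  # a duplicated sample lands on identical coordinates
  gm2 <- geno_matrix(rbind(m, m[1, ]))
  pc2 <- genotype_pca(gm2)
  expect_equal(unname(pc2$scores[13, ]), unname(pc2$scores[1, ]))
  # constant matrix: flagged zero variance
  flat <- geno_matrix(matrix(1L, 4, 10))
  expect_true(genotype_pca(flat)$zero_variance)
})
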
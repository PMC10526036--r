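test_that("allele-sharing distance matches its closed-form examples", {
  gt <- rbind(a = c(0L, 0L), b = c(1L, 0L), c = c(2L, 2L))
  tab <- variant_table(rep("chr1", 2), c(100L, 200L), c("A", "A"),
                       c("G", "G"), gt, samples = c("a", "b", "c"))
  d <- allele_sharing_distance(tab)
  expect_equal(unname(diag(d)), c(0, 0, 0))
  expect_equal(d["a", "b"], 1 - (0.5 + 1) / 2)   # pairs (0,1), (0,0) -> 0.25
  expect_equal(d["a", "c"], 1)                   # 0 vs 2 at both sites
  expect_true(isSymmetric(d))
  expect_true(all(d >= 0 & d <= 1))

  gt2 <- rbind(a = c(1L, NA), b = c(NA, 1L))
  tab2 <- variant_table(rep("chr1", 2), c(100L, 200L), c("A", "A"),
                        c("G", "G"), gt2, samples = c("a", "b"))
  expect_error(allele_sharing_distance(tab2), "co-typed")
})

test_that("PCA standardization centers columns and caps rank", {
  set.seed(5)
  gt <- matrix(rbinom(5 * 40, 2, 0.5), 5, 40)
  tab <- variant_table(rep("chr1", 40), seq_len(40) * 10L, rep("A", 40),
                       rep("G", 40), gt)
  pc <- pca_genotypes(tab)
  expect_true(all(diff(pc$varfrac) <= 1e-12))
  expect_equal(sum(pc$varfrac), 1, tolerance = 1e-9)
  # rank bound: 2 samples -> a single positive eigenvalue with fraction 1
  tab2 <- subset_sites(tab, 1:20)
  tab2$gt <- tab2$gt[1:2, ]; tab2$dp <- tab2$dp[1:2, ]
  tab2$samples <- tab2$samples[1:2]; tab2$hap <- NULL; tab2$phased <- FALSE
  pc2 <- pca_genotypes(tab2)
  expect_equal(pc2$varfrac[1], 1, tolerance = 1e-9)

  # explicit centering check on the standardized matrix the PCA uses
  p <- colMeans(gt) / 2
  poly <- p > 0 & p < 1
  x <- sweep(gt[, poly], 2, 2 * p[poly], "-")
  expect_true(all(abs(colMeans(x)) < 1e-9))
})

test_that("PC1 separates two drifted populations", {
  skip_if_not_installed("cluster")
  d <- generate_dataset(sim_config(seed = 9, n_chromosomes = 1,
                                   chrom_length = 500000, drift_F = 0.2))
  qc <- apply_qc_filters(d$table)
  kept <- ld_prune(qc)
  pc <- pca_genotypes(subset_sites(qc, kept))
  grp <- d$popmap$group[match(rownames(pc$coords), d$popmap$sample)]
  sil <- cluster::silhouette(as.integer(factor(grp)),
                             stats::dist(pc$coords[, 1]))
  expect_gt(mean(sil[, "sil_width"]), 0)
})

test_that("neighbor joining reproduces the worked 4-taxon additive matrix", {
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- 3; D["A", "C"] <- 5; D["A", "D"] <- 6
  D["B", "C"] <- 6; D["B", "D"] <- 7; D["C", "D"] <- 7
  D <- D + t(D)
  tr <- neighbor_joining(D)
  expect_s3_class(tr, "phylo")
  # leaf branch lengths 1, 2, 3, 4 and internal branch 1
  tip_len <- setNames(tr$edge.length[match(seq_len(4), tr$edge[, 2])],
                      tr$tip.label)
  expect_equal(tip_len[c("A", "B", "C", "D")], c(A = 1, B = 2, C = 3, D = 4))
  internal <- tr$edge.length[tr$edge[, 2] > 4]
  expect_equal(sort(internal), 1)
  # topology (A,B) | (C,D): path A-B = 3 and C-D = 7 exactly
  pd <- ape::cophenetic.phylo(tr)
  expect_equal(pd[LETTERS[1:4], LETTERS[1:4]], D, tolerance = 1e-9)
})

test_that("neighbor joining handles 3 taxa and equidistant ties", {
  D3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr3 <- neighbor_joining(D3)
  # three-point formulas: x = (2+3-4)/2 = 0.5, y = 1.5, z = 2.5
  len <- setNames(tr3$edge.length[match(1:3, tr3$edge[, 2])], tr3$tip.label)
  expect_equal(len[c("x", "y", "z")], c(x = 0.5, y = 1.5, z = 2.5))

  De <- matrix(2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(De) <- 0
  tre <- neighbor_joining(De)
  internal <- tre$edge.length[tre$edge[, 2] > 4]
  expect_equal(unname(internal), 0)
  # lowest-index pair joined first
  pairs <- ape::cophenetic.phylo(tre)
  expect_equal(unname(pairs["a", "b"]), 2)
  expect_error(neighbor_joining(De[1:2, 1:2]), ">= 3")
  Dasym <- De; Dasym[1, 2] <- 3
  expect_error(neighbor_joining(Dasym), "symmetric")
})

test_that("random additive trees are recovered exactly (vs ape oracle)", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    src <- random_additive_tree(n)
    tr <- neighbor_joining(src$D)
    expect_equal(ape::dist.topo(ape::unroot(src$tree), tr), 0,
                 ignore_attr = TRUE)
    pd <- ape::cophenetic.phylo(tr)
    expect_equal(pd[rownames(src$D), colnames(src$D)], src$D,
                 tolerance = 1e-6)
    # ape's own NJ agrees on the topology
    expect_equal(ape::dist.topo(ape::nj(src$D), tr), 0, ignore_attr = TRUE)
  }
})

test_that("between-group distances exceed within-group distances", {
  hits <- vapply(1:10, function(s) {
    d <- small_sim(s + 100)
    qc <- apply_qc_filters(d$table)
    dm <- allele_sharing_distance(qc)
    grp <- d$popmap$group[match(rownames(dm), d$popmap$sample)]
    same <- outer(grp, grp, "==")
    ut <- upper.tri(dm)
    mean(dm[ut & !same]) > mean(dm[ut & same])
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("newick serialization round-trips through ape", {
  src <- random_additive_tree(6)
  tr <- neighbor_joining(src$D)
  f <- tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- ape::read.tree(f)
  expect_equal(sort(back$tip.label), sort(tr$tip.label))
  expect_equal(ape::dist.topo(back, tr), 0, ignore_attr = TRUE)
})
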
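# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: scalar arithmetic, pair enumeration, ape.

# Naive scalar transcription of the two-population Weir-Cockerham (1984)
# variance components. One site, plain scalars, no vectorization.
wc_fst_scalar <- function(cA, cB) {
  nA <- sum(cA); nB <- sum(cB)
  if (nA < 2 || nB < 2) return(list(a = NA_real_, total = NA_real_, fst = NA_real_))
  pA <- (cA[2] + 2 * cA[3]) / (2 * nA)
  pB <- (cB[2] + 2 * cB[3]) / (2 * nB)
  hA <- cA[2] / nA
  hB <- cB[2] / nB
  r <- 2
  nbar <- (nA + nB) / r
  nc <- (r * nbar - (nA * nA + nB * nB) / (r * nbar)) / (r - 1)
  pbar <- (nA * pA + nB * pB) / (r * nbar)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
  hbar <- (nA * hA + nB * hB) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  tot <- a + b + cc
  if (pbar <= 0 || pbar >= 1 || tot <= 0) {
    return(list(a = NA_real_, total = NA_real_, fst = NA_real_))
  }
  list(a = a, total = tot, fst = a / tot)
}

# Random per-site genotype count vectors (hom_ref, het, hom_alt).
random_genotype_counts <- function(n_dip, polymorphic = FALSE) {
  repeat {
    cnt <- as.vector(stats::rmultinom(1, n_dip, prob = stats::runif(3)))
    if (!polymorphic) return(cnt)
    p <- (cnt[2] + 2 * cnt[3]) / (2 * sum(cnt))
    if (p > 0 && p < 1) return(cnt)
  }
}

# Pair-enumeration nucleotide diversity at one site: the fraction of
# distinct sequence pairs that differ, from an explicit double loop.
pi_enumeration <- function(ref_count, alt_count) {
  alleles <- c(rep(0L, ref_count), rep(1L, alt_count))
  n <- length(alleles)
  if (n < 2) return(NA_real_)
  diffs <- 0L; pairs <- 0L
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      pairs <- pairs + 1L
      if (alleles[i] != alleles[j]) diffs <- diffs + 1L
    }
  }
  diffs / pairs
}

# Random binary tree with positive branch lengths and its path-length
# (additive) distance matrix.
random_additive_tree <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, rooted = FALSE,
                   br = function(k) stats::runif(k, 0.1, 2))
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

# Small random variant table (genotypes only) for filter / pruning checks.
random_small_table <- function(n_dip = 20, m = 30, miss_rate = 0.08,
                               depth_mean = 8) {
  gt <- matrix(stats::rbinom(n_dip * m, 2, stats::runif(m, 0.05, 0.95)[
    rep(seq_len(m), each = n_dip)]), n_dip, m)
  gt[stats::runif(n_dip * m) < miss_rate] <- NA_integer_
  dp <- matrix(stats::rpois(n_dip * m, depth_mean), n_dip, m)
  variant_table(rep("chr1", m), seq_len(m) * 100L,
                rep("A", m), rep("G", m), gt, dp = dp)
}

# Phased table built directly from a haplotype matrix (complete data).
table_from_haps <- function(hap, positions = NULL, chrom = "chr1") {
  m <- ncol(hap); n_dip <- nrow(hap) / 2
  if (is.null(positions)) positions <- seq_len(m) * 1000L
  gt <- hap[seq(1, nrow(hap), 2), , drop = FALSE] +
    hap[seq(2, nrow(hap), 2), , drop = FALSE]
  variant_table(rep(chrom, m), positions, rep("A", m), rep("G", m),
                gt, hap = hap)
}

# A small simulated scenario used by several tests (one chromosome keeps
# the haplotype scans quick).
small_sim <- function(seed, sweeps = list(), chrom_length = 500000L,
                      n_chromosomes = 1L) {
  generate_dataset(sim_config(seed = seed, n_chromosomes = n_chromosomes,
                              chrom_length = chrom_length, sweeps = sweeps))
}
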
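toy_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chr1,length=100000>",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
               '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="DP">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
               lines), path)
  path
}

test_that("read_vcf loads biallelic SNPs and skips the rest", {
  p <- toy_vcf(c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:DP\t0|1:9\t1|1:8\t0|0:7",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t1|1\t0|1\t./.",
    "chr1\t300\t.\tA\tA,T\t.\tPASS\t.\tGT:DP\t0|1:5\t0|0:5\t0|0:5",
    "chr1\t400\t.\tAT\tA\t.\tPASS\t.\tGT:DP\t0|1:5\t0|0:5\t0|0:5"))
  tab <- read_vcf(p)
  expect_equal(n_sites(tab), 2)
  expect_equal(length(tab$samples), 3)
  expect_equal(attr(tab, "n_skipped"), 2)       # multi-allelic + indel
  expect_equal(unname(tab$gt[, 1]), c(1L, 2L, 0L))
  # GT without DP -> unknown-large depth; "./." -> missing genotype
  expect_equal(unname(tab$gt[2, 2]), 1L)
  expect_true(all(tab$dp[, 2] == DP_UNKNOWN))
  expect_true(is.na(tab$gt[3, 2]))
  expect_true(tab$phased)
  expect_equal(attr(tab, "chrom_lengths"), c(chr1 = 100000L))
})

test_that("half-missing genotypes are fully missing and ragged rows error", {
  p <- toy_vcf("chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:DP\t0|.:9\t1|1:8\t0|0:7")
  tab <- read_vcf(p)
  expect_true(is.na(tab$gt[1, 1]))
  expect_true(is.na(tab$hap[1, 1]) && is.na(tab$hap[2, 1]))

  p2 <- toy_vcf("chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:DP\t0|1:9\t1|1:8")
  expect_error(read_vcf(p2), "line 6")
  p3 <- tempfile(fileext = ".vcf")
  writeLines("chr1\t100", p3)
  expect_error(read_vcf(p3), "header")
})

test_that("QC filters apply depth, missingness and MAF rules in order", {
  # 28 diploids, 4 sites engineered one per rule
  n <- 28
  gt <- matrix(1L, n, 4)
  dp <- matrix(10L, n, 4)
  # site 1: healthy, MAF 0.5 (all het) -> retained
  # site 2: 3 genotypes at low depth -> masked -> 3/28 >= 0.10 -> dropped
  dp[1:3, 2] <- 2L
  # site 3: alt frequency 2/56 = 0.036 <= 0.05, fully called
  gt[, 3] <- 0L; gt[1, 3] <- 2L
  # site 4: monomorphic -> MAF 0 -> dropped
  gt[, 4] <- 0L
  tab <- variant_table(rep("chr1", 4), c(100L, 200L, 300L, 400L),
                       rep("A", 4), rep("G", 4), gt, dp = dp)
  out <- apply_qc_filters(tab)
  cnt <- attr(out, "qc_counts")
  expect_equal(n_sites(out), 1)
  expect_equal(out$pos, 100L)
  expect_equal(cnt$masked_genotypes, 3)
  expect_equal(cnt$dropped_missing, 1)
  expect_equal(cnt$dropped_maf, 2)
  expect_error(apply_qc_filters(tab, max_missing = 1.5), "max_missing")
})

test_that("site-level depth mode drops whole sites", {
  gt <- matrix(1L, 4, 2)
  dp <- cbind(rep(2L, 4), rep(8L, 4))
  tab <- variant_table(rep("chr1", 2), c(10L, 20L), c("A", "A"), c("G", "G"),
                       gt, dp = dp)
  out <- apply_qc_filters(tab, depth_mode = "site")
  expect_equal(out$pos, 20L)
  expect_equal(attr(out, "qc_counts")$dropped_low_depth_sites, 1)
})

test_that("pairwise_r2 matches its stated examples and degeneracies", {
  expect_equal(pairwise_r2(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1.0)
  expect_equal(pairwise_r2(c(0, 0, 2, 2), c(0, 2, 0, 2)), 0.0)
  expect_true(is.na(pairwise_r2(c(0, 1), c(1, 1))))
  expect_true(is.na(pairwise_r2(c(0, NA), c(1, 1))))
  expect_error(pairwise_r2(c(0, 1), c(1, 1, 2)), "length")
})

test_that("ld_prune removes the later member of correlated pairs", {
  set.seed(7)
  base <- rbinom(20, 2, 0.5)
  other <- rbinom(20, 2, 0.5)
  gt <- cbind(base, base, other)   # duplicate pair (1,2)
  tab <- variant_table(rep("chr1", 3), c(100L, 200L, 300L),
                       rep("A", 3), rep("G", 3), gt)
  kept <- ld_prune(tab)
  expect_true(1 %in% kept)
  expect_false(2 %in% kept)

  # perfect chain A~B~C: greedy removal keeps only A
  gt3 <- cbind(base, base, base)
  tab3 <- variant_table(rep("chr1", 3), c(100L, 200L, 300L),
                        rep("A", 3), rep("G", 3), gt3)
  expect_equal(ld_prune(tab3), 1L)
  expect_error(ld_prune(tab3, window_snps = 1), "window_snps")
})

test_that("after pruning no kept within-window pair exceeds the threshold", {
  set.seed(42)
  # correlated blocks: each block derived from one latent column
  blocks <- replicate(10, {
    z <- rbinom(24, 2, 0.5)
    sapply(1:10, function(i) ifelse(runif(24) < 0.2, rbinom(24, 2, 0.5), z))
  }, simplify = FALSE)
  gt <- do.call(cbind, blocks)
  m <- ncol(gt)
  tab <- variant_table(rep("chr1", m), seq_len(m) * 50L,
                       rep("A", m), rep("G", m), gt)
  kept <- ld_prune(tab, window_snps = 25, step_snps = 5, r2_threshold = 0.05)
  for (s in seq(1, m, by = 5)) {
    w <- intersect(s:min(s + 24, m), kept)
    if (length(w) < 2) next
    for (i in seq_along(w)[-length(w)]) {
      for (j in (i + 1):length(w)) {
        r2 <- pairwise_r2(tab$gt[, w[i]], tab$gt[, w[j]])
        if (!is.na(r2)) expect_lte(r2, 0.05)
      }
    }
  }
  expect_lt(length(kept), m)
})

test_that("read_gff3 validates structure and resolves parents", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t1000\t2000\t.\t+\t.\tID=gA",
               "chr1\tx\tmRNA\t1000\t2000\t.\t+\t.\tID=gA.t1;Parent=gA",
               "chr1\tx\texon\t1000\t2500\t.\t+\t.\tID=gA.e1;Parent=gA.t1"),
             gff)
  expect_error(read_gff3(gff), "outside gene span")

  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t1000\t2000\t.\t+\t.\tID=gA",
               "chr1\tx\tCDS\t1000\t1500\t.\t+\t0\tID=orphan;Parent=missing"),
             gff)
  expect_error(read_gff3(gff), "orphan")
})
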
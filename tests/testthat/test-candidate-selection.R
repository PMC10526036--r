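mk_windows <- function(values, chrom = "chr1") {
  n <- length(values)
  data.frame(chrom = chrom, start = (seq_len(n) - 1L) * 50000L + 1L,
             end = seq_len(n) * 50000L, n_snps = 1L, value = values,
             stringsAsFactors = FALSE)
}

test_that("top-window selection is rank-based with deterministic ties", {
  w <- mk_windows(1:100)
  sel <- select_top_windows(w)
  expect_equal(nrow(sel), 5)
  expect_equal(sort(sel$value), 96:100)

  tied <- mk_windows(rep(7, 100))
  sel2 <- select_top_windows(tied)
  expect_equal(sel2$start, tied$start[1:5])  # genomic order breaks ties

  expect_error(select_top_windows(mk_windows(1:10)), "at least")

  # Inf sentinels rank above everything; NAs are not rankable
  w3 <- mk_windows(c(rep(1, 38), Inf, NA))
  sel3 <- select_top_windows(w3)   # 39 rankable -> k = 1
  expect_equal(nrow(sel3), 1)
  expect_equal(sel3$value, Inf)
})

test_that("floor(fraction * N) holds regardless of tie structure", {
  set.seed(3)
  for (n in c(20, 57, 100, 400)) {
    vals <- sample(c(1, 2, 3), n, replace = TRUE)   # heavy ties
    expect_equal(nrow(select_top_windows(mk_windows(vals))), floor(0.05 * n))
  }
})

test_that("joint Fst/ratio candidates are the SNPs of intersected windows", {
  fst <- mk_windows(c(10, 9, 1, 1, 1, 1, rep(0, 34)))
  ratio <- mk_windows(c(10, 0, 9, 1, 1, 1, rep(0, 34)))
  hap <- matrix(rep(c(0L, 1L), each = 28), 56, 4)
  tab <- table_from_haps(hap,
                         positions = c(10000L, 60000L, 110000L, 1999000L))
  joint <- joint_fst_pi_candidates(fst, ratio, tab)
  # top-2 of each track: fst {w1, w2}, ratio {w1, w3} -> joint {w1}
  expect_equal(nrow(joint$windows), 1)
  expect_equal(joint$windows$start, 1L)
  expect_equal(joint$snps$pos, 10000L)

  disj_ratio <- mk_windows(c(0, 0, 10, 9, rep(0, 36)))
  joint2 <- joint_fst_pi_candidates(fst, disj_ratio, tab)
  expect_equal(nrow(joint2$snps), 0)

  ident <- joint_fst_pi_candidates(fst, fst, tab)
  expect_equal(ident$windows$start, c(1L, 50001L))
  expect_equal(ident$snps$pos, c(10000L, 60000L))

  shifted <- fst; shifted$start <- shifted$start + 10L
  expect_error(joint_fst_pi_candidates(fst, shifted, tab), "grids")
})

test_that("flanking clips to the chromosome and merges book-ended runs", {
  cl <- c(chr1 = 2000000L)
  r1 <- flank_and_merge(data.frame(chrom = "chr1", pos = c(10000L, 40000L)),
                        chrom_lengths = cl)
  expect_equal(nrow(r1), 1)
  expect_equal(c(r1$start, r1$end), c(1L, 90000L))
  expect_equal(r1$n_snps, 2L)

  r2 <- flank_and_merge(data.frame(chrom = "chr1", pos = 1000000L),
                        chrom_lengths = cl)
  expect_equal(c(r2$start, r2$end), c(950000L, 1050000L))

  r3 <- flank_and_merge(data.frame(chrom = "chr1", pos = c(200000L, 500000L)),
                        chrom_lengths = cl)
  expect_equal(nrow(r3), 2)

  expect_error(flank_and_merge(data.frame(chrom = "chr1", pos = 3000000L),
                               chrom_lengths = cl), "beyond")

  # merged regions are disjoint, sorted, and no longer than the raw total
  set.seed(9)
  pos <- sort(sample(60000:1940000, 40))
  rr <- flank_and_merge(data.frame(chrom = "chr1", pos = pos),
                        chrom_lengths = cl)
  expect_true(all(diff(rr$start) > 0))
  expect_true(all(rr$start[-1] > rr$end[-nrow(rr)] + 1L))
  expect_lte(sum(rr$end - rr$start + 1), 40 * 100001)
})

test_that("gene overlap uses closed intervals with >= 1 bp", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      start = c(85000L, 90001L), end = c(95000L, 95000L),
                      stringsAsFactors = FALSE)
  region <- data.frame(chrom = "chr1", start = 1L, end = 90000L)
  gs <- genes_in_regions(region, genes, "fst_pi")
  expect_equal(gs$genes, "g1")
  expect_equal(gs$method, "fst_pi")
  empty <- genes_in_regions(region[0, ], genes)
  expect_equal(empty$genes, character(0))
})

test_that("venn overlap is exact set algebra", {
  a <- structure(list(method = "fst_pi", genes = c("X", "Y")),
                 class = "gene_set")
  b <- structure(list(method = "xpehh", genes = c("Y", "Z")),
                 class = "gene_set")
  v <- venn_overlap(a, b)
  expect_equal(c(v$a_only, v$b_only, v$both), c(1, 1, 1))
  expect_equal(v$intersection$genes, "Y")
  v2 <- venn_overlap(a, a)
  expect_equal(v2$both, 2)
  v3 <- venn_overlap(a, structure(list(method = "x", genes = "Q"),
                                  class = "gene_set"))
  expect_equal(v3$both, 0)
  expect_equal(v3$intersection$genes, character(0))
})

test_that("BED conversion round-trips 1-based inclusive regions", {
  reg <- data.frame(chrom = c("chr1", "chr2"), start = c(1L, 950000L),
                    end = c(90000L, 1050000L), stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".bed")
  write_regions_bed(reg, f)
  raw <- read.table(f, sep = "\t")
  expect_equal(raw[[2]], c(0L, 949999L))   # 0-based half-open on disk
  back <- read_regions_bed(f)
  expect_equal(back$start, reg$start)
  expect_equal(back$end, reg$end)
})

test_that("a seeded sweep run recovers the sweep gene in the fst_pi set", {
  d <- generate_dataset(
    sim_config(seed = 23, sweeps = list(sweep_spec("chr1", 1000000, "F"))))
  qc <- apply_qc_filters(d$table)
  cl <- c(chr1 = 2000000L, chr2 = 2000000L)
  w <- make_windows(cl)
  fst <- windowed_fst(qc, d$popmap, w)
  piF <- windowed_pi(qc, group_samples(d$popmap, qc, "F"), w)
  piC <- windowed_pi(qc, group_samples(d$popmap, qc, "C"), w)
  ratio <- theta_pi_ratio(piF, piC)
  joint <- joint_fst_pi_candidates(fst, ratio, qc)
  core_window <- joint$windows$chrom == "chr1" &
    joint$windows$start <= 1000000 & joint$windows$end >= 1000000
  expect_true(any(core_window))
  regions <- flank_and_merge(joint$snps, chrom_lengths = cl)
  gs <- genes_in_regions(regions, gene_tiles(cl), "fst_pi")
  expect_true("chr1_g011" %in% gs$genes)   # the gene overlapping the core
})
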
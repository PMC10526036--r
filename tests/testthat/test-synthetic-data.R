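test_that("equal seeds give identical datasets and invalid configs are named", {
  cfg <- sim_config(seed = 1, n_chromosomes = 1, chrom_length = 500000)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$table$gt, d2$table$gt)
  expect_identical(d1$table$hap, d2$table$hap)
  expect_identical(d1$table$pos, d2$table$pos)
  expect_identical(d1$table$dp, d2$table$dp)

  expect_error(sim_config(drift_F = 0), "drift_F")
  expect_error(sim_config(drift_F = 1), "drift_F")
  expect_error(sim_config(n_diploids_A = 0), "n_diploids_A")
  expect_error(sim_config(chrom_length = 100000), "chrom_length")
  expect_error(sweep_spec("chr1", 1000, carrier_frequency = 0.4),
               "carrier_frequency")
})

test_that("positions are sorted and unique, and phase is consistent", {
  d <- small_sim(3)
  expect_true(all(diff(d$table$pos) > 0))
  expect_true(validate_phase(d$table))
  expect_true(all(d$table$ref != d$table$alt))
  expect_true(all(d$table$dp >= 1))
})

test_that("sample allele frequencies track the drawn population frequencies", {
  d <- generate_dataset(sim_config(seed = 1, n_chromosomes = 1,
                                   chrom_length = 2000000))
  expect_gt(nrow(d$freqs), 3000)
  iF <- group_samples(d$popmap, d$table, "F")
  hF <- d$table$hap[hap_rows(iF), ]
  freq_obs <- colMeans(hF)
  expect_lt(mean(abs(freq_obs - d$freqs$p_F)), 0.15)
  expect_gt(stats::cor(freq_obs, d$freqs$p_F), 0.8)
})

test_that("plant_sweep follows the carrier-count and founder rules", {
  set.seed(99)
  hap <- matrix(rbinom(40 * 50, 1, 0.5), 40, 50)
  sites <- seq_len(50) * 1000L
  spec <- sweep_spec("chr1", 25000, "F", carrier_frequency = 0.95,
                     span = 10000)
  res <- plant_sweep(hap, sites, spec, target_rows = 1:20, seed = 5)
  expect_length(res$carrier_rows, round(0.95 * 20))  # 19 carriers
  span_cols <- which(sites >= 15000 & sites <= 35000)
  founder <- res$haplotypes[res$founder_row, span_cols]
  for (r in res$carrier_rows) {
    expect_identical(res$haplotypes[r, span_cols], founder)
  }
  # non-target rows and out-of-span sites untouched
  expect_identical(res$haplotypes[21:40, ], hap[21:40, ])
  expect_identical(res$haplotypes[, -span_cols], hap[, -span_cols])

  full <- plant_sweep(hap, sites, sweep_spec("chr1", 25000, "F",
                                             carrier_frequency = 1,
                                             span = 10000),
                      target_rows = 1:20, seed = 5)
  expect_equal(length(unique(apply(full$haplotypes[1:20, span_cols], 1,
                                   paste, collapse = ""))), 1)
  expect_error(plant_sweep(hap, sites, sweep_spec("chr1", 500, span = 10),
                           target_rows = 1:20, seed = 1),
               "zero sites")
})

test_that("a requested sweep is recorded once in the truth", {
  d <- small_sim(4, sweeps = list(sweep_spec("chr1", 250000, "F",
                                             span = 40000)))
  expect_length(d$truth, 1)
  expect_equal(d$truth[[1]]$spec$position, 250000)
  expect_true(d$truth[[1]]$founder_row %in% d$truth[[1]]$carrier_rows)
})

test_that("fixture bundle roundtrips through VCF and tiles genes correctly", {
  d <- small_sim(11, sweeps = list(sweep_spec("chr1", 250000, "F",
                                              span = 40000)))
  out <- file.path(tempfile("fix"), "bundle")
  fb <- write_fixture_bundle(d, out_dir = out)
  back <- read_vcf(fb$vcf)
  expect_identical(unname(back$gt), unname(d$table$gt))
  expect_identical(unname(back$hap), unname(d$table$hap))
  expect_identical(back$pos, d$table$pos)
  expect_true(back$phased)

  pm <- read_popmap(fb$popmap)
  expect_equal(nrow(pm), 28)  # n_diploids_A + n_diploids_B under defaults
  expect_equal(sum(pm$group == "F"), 10)
  expect_equal(sum(pm$group == "C"), 18)

  expect_equal(nrow(gene_tiles(c(chr1 = 2000000))), 20)
  gm <- read_gff3(fb$gff3)
  # the fixture tiles genes over the contig length rounded up to 100 kb
  expect_equal(nrow(gm$genes), 5)
  # fixture CDS lengths are divisible by 3
  cds_len <- vapply(gm$cds, function(x) sum(x$end - x$start + 1L), integer(1))
  expect_true(all(cds_len %% 3 == 0))

  tm <- read_term_map(fb$terms)
  expect_true(all(c("term_id", "term_name", "gene_id") %in% names(tm)))
  expect_true(all(fb$designated_genes %in%
                    tm$gene_id[tm$term_id == fb$designated_term]))
})

test_that("null simulations calibrate to the drift parameter", {
  fsts <- vapply(1:10, function(s) {
    d <- generate_dataset(sim_config(seed = s))
    genome_fst(apply_qc_filters(d$table), d$popmap)
  }, numeric(1))
  expect_true(mean(fsts) >= 0.05 / 2 && mean(fsts) <= 2 * 0.05)
})

test_that("a planted sweep puts the Fst maximum inside the swept region", {
  # the sweep copies the founder uniformly over the whole +/- 75 kb span,
  # so all three covered windows are equally elevated: the detectable
  # guarantee is that the chromosome's maximum lies within the span
  hits <- vapply(1:10, function(s) {
    d <- generate_dataset(
      sim_config(seed = s, sweeps = list(sweep_spec("chr1", 1000000, "F"))))
    qc <- apply_qc_filters(d$table)
    w <- make_windows(c(chr1 = 2000000, chr2 = 2000000))
    fst <- windowed_fst(qc, d$popmap, w)
    f1 <- fst[fst$chrom == "chr1", ]
    top <- f1[which.max(f1$value), ]
    top$end >= 1000000 - 75000 && top$start <= 1000000 + 75000
  }, logical(1))
  expect_gte(sum(hits), 8)
})
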
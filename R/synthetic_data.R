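#' Simulation configuration for the two-population sweep generator
#'
#' Defines a two-population phased diploid dataset. Population A is the "F"
#' (fine-wool) scan group, population B the "C" (coarse-wool) group; defaults
#' mirror the 10 + 18 = 28 animal design the scan is built around. Allele
#' frequencies follow the Balding-Nichols model: an ancestral frequency
#' p ~ Beta(0.8, 0.8) per site, then an independent per-population frequency
#' Beta(p(1-F)/F, (1-p)(1-F)/F) with F = `drift_F`.
#'
#' @param seed integer seed; equal seeds give byte-identical datasets.
#' @param n_diploids_A diploids in group F (default 10).
#' @param n_diploids_B diploids in group C (default 18).
#' @param n_chromosomes number of chromosomes (default 2).
#' @param chrom_length chromosome length in bp (default 2,000,000; must be at
#'   least 500,000 so a 50 kb window grid has >= 10 windows).
#' @param snp_spacing_mean mean inter-SNP distance in bp (default 500).
#' @param drift_F Balding-Nichols drift parameter, strictly in (0, 1)
#'   (default 0.05).
#' @param mean_depth mean per-genotype Poisson read depth (default 8; draws of
#'   zero are promoted to one read).
#' @param sweeps list of [sweep_spec()] objects to plant (default none).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_diploids_A = 10L, n_diploids_B = 18L,
                       n_chromosomes = 2L, chrom_length = 2000000L,
                       snp_spacing_mean = 500, drift_F = 0.05,
                       mean_depth = 8, sweeps = list()) {
  chk_count <- function(x, name) {
    if (length(x) != 1L || is.na(x) || x < 1 || x != round(x)) {
      stop("invalid ", name, ": must be a count >= 1")
    }
  }
  chk_count(seed, "seed"); chk_count(n_diploids_A, "n_diploids_A")
  chk_count(n_diploids_B, "n_diploids_B"); chk_count(n_chromosomes, "n_chromosomes")
  chk_count(chrom_length, "chrom_length")
  if (chrom_length < 500000) stop("invalid chrom_length: must be >= 500000 bp")
  if (snp_spacing_mean < 1) stop("invalid snp_spacing_mean: must be >= 1 bp")
  if (!(drift_F > 0 && drift_F < 1)) {
    stop("invalid drift_F: must lie strictly inside (0, 1)")
  }
  if (mean_depth <= 0) stop("invalid mean_depth: must be positive")
  if (!is.list(sweeps) || (length(sweeps) &&
                           !all(vapply(sweeps, inherits, logical(1), "sweep_spec")))) {
    stop("invalid sweeps: must be a list of sweep_spec objects")
  }
  for (sw in sweeps) {
    if (sw$position < 1 || sw$position > chrom_length) {
      stop("invalid sweeps: position outside [1, chrom_length]")
    }
  }
  structure(list(seed = as.integer(seed),
                 n_diploids_A = as.integer(n_diploids_A),
                 n_diploids_B = as.integer(n_diploids_B),
                 n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = as.integer(chrom_length),
                 snp_spacing_mean = snp_spacing_mean,
                 drift_F = drift_F, mean_depth = mean_depth,
                 sweeps = sweeps),
            class = "sim_config")
}

#' Specify a planted selective sweep
#'
#' A sweep copies one founder haplotype onto a fraction `carrier_frequency`
#' of the target group's haplotypes across `position +/- span`, creating the
#' locally elevated Fst, depressed diversity and extended haplotype
#' homozygosity a real sweep leaves behind.
#'
#' @param chrom chromosome identifier (e.g. "chr1").
#' @param position sweep core position in bp.
#' @param target_group "F" or "C".
#' @param carrier_frequency fraction of target haplotypes carrying the founder
#'   haplotype, in (0.5, 1] (default 0.95).
#' @param span half-width of the swept interval in bp (default 75,000).
#' @return A list of class `sweep_spec`.
#' @export
sweep_spec <- function(chrom, position, target_group = "F",
                       carrier_frequency = 0.95, span = 75000L) {
  if (!(carrier_frequency > 0.5 && carrier_frequency <= 1)) {
    stop("invalid carrier_frequency: must lie in (0.5, 1]")
  }
  if (span <= 0) stop("invalid span: must be positive")
  if (!target_group %in% c("F", "C")) {
    stop("invalid target_group: must be 'F' or 'C'")
  }
  if (position < 1) stop("invalid position: must be >= 1")
  structure(list(chrom = as.character(chrom), position = as.integer(position),
                 target_group = target_group,
                 carrier_frequency = carrier_frequency,
                 span = as.integer(span)),
            class = "sweep_spec")
}

#' Generate a two-population phased dataset
#'
#' Draws SNP positions with exponential spacing, Balding-Nichols population
#' allele frequencies, independent Bernoulli haplotypes given the population
#' frequency, and per-genotype Poisson read depths, then plants any requested
#' sweeps via [plant_sweep()]. Diploids pair consecutive haplotype rows.
#' The REF base is uniform over A/C/G/T and the ALT base is a transition with
#' probability 2/3 (the genome-wide expectation), so the raw ts/tv ratio of a
#' simulated dataset is near 2.
#'
#' @param config a [sim_config()].
#' @return A list with elements `table` (a [variant_table()]), `popmap`
#'   (a [population_map()]; breed labels mirror the 2/3/3/2 + 5/3/5/5 design
#'   when the default 10 + 18 sizes are used), `truth` (a list of class
#'   `sweep_truth`: one element per planted sweep, carrying the realized spec,
#'   the founder haplotype row and the carrier rows) and `freqs` (the drawn
#'   per-population Balding-Nichols allele frequencies, for calibration
#'   diagnostics).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nA <- config$n_diploids_A; nB <- config$n_diploids_B
  n_hap <- 2L * (nA + nB)
  hapA_rows <- seq_len(2L * nA)
  hapB_rows <- seq(2L * nA + 1L, n_hap)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))

  chrom_v <- character(0); pos_v <- integer(0)
  ref_v <- character(0); alt_v <- character(0)
  pA_v <- numeric(0); pB_v <- numeric(0)
  hap <- NULL
  F <- config$drift_F
  bases <- c("A", "C", "G", "T")
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  for (chr in chroms) {
    n_try <- ceiling(config$chrom_length / config$snp_spacing_mean * 1.3) + 10
    gaps <- pmax(1, round(stats::rexp(n_try, rate = 1 / config$snp_spacing_mean)))
    pos <- cumsum(gaps)
    pos <- pos[pos <= config$chrom_length]
    m <- length(pos)
    p_anc <- stats::rbeta(m, 0.8, 0.8)
    p_anc <- pmin(pmax(p_anc, 1e-6), 1 - 1e-6)
    pA <- stats::rbeta(m, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
    pB <- stats::rbeta(m, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
    h <- matrix(0L, n_hap, m)
    h[hapA_rows, ] <- matrix(stats::rbinom(length(hapA_rows) * m, 1L,
                                           rep(pA, each = length(hapA_rows))),
                             length(hapA_rows), m)
    h[hapB_rows, ] <- matrix(stats::rbinom(length(hapB_rows) * m, 1L,
                                           rep(pB, each = length(hapB_rows))),
                             length(hapB_rows), m)
    ref <- sample(bases, m, replace = TRUE)
    is_ts <- stats::runif(m) < 2 / 3
    alt <- character(m)
    alt[is_ts] <- transition[ref[is_ts]]
    tv_choices <- list(A = c("C", "T"), G = c("C", "T"),
                       C = c("A", "G"), T = c("A", "G"))
    for (i in which(!is_ts)) {
      alt[i] <- sample(tv_choices[[ref[i]]], 1L)
    }
    chrom_v <- c(chrom_v, rep(chr, m)); pos_v <- c(pos_v, pos)
    ref_v <- c(ref_v, ref); alt_v <- c(alt_v, alt)
    pA_v <- c(pA_v, pA); pB_v <- c(pB_v, pB)
    hap <- if (is.null(hap)) h else cbind(hap, h)
  }

  truth <- list()
  for (i in seq_along(config$sweeps)) {
    sw <- config$sweeps[[i]]
    target_rows <- if (sw$target_group == "F") hapA_rows else hapB_rows
    on_chr <- chrom_v == sw$chrom
    if (!any(on_chr)) stop("sweep chromosome ", sw$chrom, " not simulated")
    res <- plant_sweep(hap[, on_chr, drop = FALSE], pos_v[on_chr], sw,
                       target_rows = target_rows,
                       seed = config$seed + 1000L * i)
    hap[, on_chr] <- res$haplotypes
    truth[[i]] <- list(spec = sw, founder_row = res$founder_row,
                       carrier_rows = res$carrier_rows)
  }
  class(truth) <- "sweep_truth"

  n_dip <- nA + nB
  gt <- hap[seq(1, n_hap, 2), , drop = FALSE] + hap[seq(2, n_hap, 2), , drop = FALSE]
  dp <- matrix(pmax(1L, stats::rpois(n_dip * length(pos_v), config$mean_depth)),
               n_dip, length(pos_v))
  samples <- sprintf("S%02d", seq_len(n_dip))
  tab <- variant_table(chrom_v, pos_v, ref_v, alt_v, gt, hap, dp,
                       samples = samples, phased = TRUE)
  popmap <- population_map(samples,
                           population = breed_labels(nA, nB),
                           group = c(rep("F", nA), rep("C", nB)))
  # the drawn Balding-Nichols frequencies, for calibration diagnostics
  freqs <- data.frame(chrom = chrom_v, pos = pos_v, p_F = pA_v, p_C = pB_v,
                      stringsAsFactors = FALSE)
  list(table = tab, popmap = popmap, truth = truth, freqs = freqs)
}

# Breed labels mirroring the eight-breed design (F: AME 2, GME 3, TON 3,
# HZS 2; C: LOP 5, HUS 3, STH 5, UJI 5) when sizes are the default 10 + 18;
# other sizes cycle through the same breed names.
breed_labels <- function(nA, nB) {
  f_breeds <- c("AME", "GME", "TON", "HZS")
  c_breeds <- c("LOP", "HUS", "STH", "UJI")
  if (nA == 10 && nB == 18) {
    c(rep(f_breeds, times = c(2, 3, 3, 2)), rep(c_breeds, times = c(5, 3, 5, 5)))
  } else {
    c(rep(f_breeds, length.out = nA), rep(c_breeds, length.out = nB))
  }
}

#' Plant a selective sweep into a haplotype matrix
#'
#' Chooses carriers among the target-group haplotype rows (count =
#' `round(carrier_frequency * n_target)`, sampled uniformly without
#' replacement under `seed`), takes the first selected carrier as the founder,
#' and copies the founder's alleles onto every carrier at all sites within
#' `position +/- span`. Rows outside the target group and sites outside the
#' span are untouched.
#'
#' @param haplotypes 0/1 haplotype matrix (rows = haplotypes, columns = sites
#'   of one chromosome).
#' @param sites integer positions (bp) of the matrix columns.
#' @param spec a [sweep_spec()].
#' @param target_rows integer row indices of the target group's haplotypes.
#' @param seed integer seed for carrier selection.
#' @return list with `haplotypes` (modified matrix), `founder_row`,
#'   `carrier_rows`.
#' @export
plant_sweep <- function(haplotypes, sites, spec, target_rows, seed) {
  stopifnot(inherits(spec, "sweep_spec"))
  span_cols <- which(sites >= spec$position - spec$span &
                     sites <= spec$position + spec$span)
  if (!length(span_cols)) stop("sweep span contains zero sites")
  n_target <- length(target_rows)
  n_carriers <- round(spec$carrier_frequency * n_target)
  set.seed(seed)
  carriers <- sample(target_rows, n_carriers)
  founder <- carriers[1L]
  founder_alleles <- haplotypes[founder, span_cols]
  haplotypes[carriers, span_cols] <-
    matrix(founder_alleles, n_carriers, length(span_cols), byrow = TRUE)
  list(haplotypes = haplotypes, founder_row = founder, carrier_rows = carriers)
}
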
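#' Build a genomic window grid
#'
#' Windows tile from position 1 on each chromosome: starts are
#' `1, 1 + step, 1 + 2*step, ...` while the start lies on the chromosome, and
#' each window spans `[start, start + size - 1]`. `step = size` gives the
#' non-overlapping 50 kb grid used for pi and Fst; `step = 20000` gives the
#' sliding XP-EHH grid.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param size window size in bp (default 50,000).
#' @param step step in bp (default `size`).
#' @return data.frame with columns chrom, start, end, size, step.
#' @export
make_windows <- function(chrom_lengths, size = 50000L, step = size) {
  stopifnot(size >= 1, step >= 1)
  out <- lapply(names(chrom_lengths), function(chr) {
    starts <- seq(1L, chrom_lengths[[chr]], by = step)
    data.frame(chrom = chr, start = as.integer(starts),
               end = as.integer(starts + size - 1L),
               size = as.integer(size), step = as.integer(step),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

window_key <- function(w) paste(w$chrom, w$start, w$end, sep = ":")

#' Per-site nucleotide diversity from allele counts
#'
#' The fraction of distinct haplotype pairs that differ at the site:
#' `2 * c0 * c1 / (n * (n - 1))` with `n = c0 + c1` non-missing alleles.
#'
#' @param ref_count,alt_count non-missing allele counts (vectors allowed).
#' @return per-site pi; NA where fewer than two alleles were observed.
#' @export
site_pi <- function(ref_count, alt_count) {
  n <- ref_count + alt_count
  ifelse(n >= 2, 2 * ref_count * alt_count / (n * (n - 1)), NA_real_)
}

# Non-missing ref/alt allele counts for a set of samples, from haplotypes
# when phased (identical for biallelic data) else from genotypes.
group_allele_counts <- function(table, sample_idx) {
  if (table$phased && !is.null(table$hap)) {
    h <- table$hap[hap_rows(sample_idx), , drop = FALSE]
    alt <- colSums(h, na.rm = TRUE)
    n <- colSums(!is.na(h))
  } else {
    g <- table$gt[sample_idx, , drop = FALSE]
    alt <- colSums(g, na.rm = TRUE)
    n <- 2 * colSums(!is.na(g))
  }
  list(ref = n - alt, alt = alt, n = n)
}

#' Windowed nucleotide diversity for one group
#'
#' Sums [site_pi()] over the SNPs of each window and divides by the window
#' size in bp (per-bp diversity, the windowed-pi convention of the standard
#' VCF tools; invariant sites contribute zero). `per = "snp"` divides by the
#' SNP count instead. Windows without SNPs are reported with value 0.
#'
#' @param table a QC-filtered [variant_table()].
#' @param sample_idx sample indices of the group (e.g. [group_samples()]).
#' @param windows a window grid from [make_windows()].
#' @param per "bp" (default) or "snp".
#' @return data.frame: chrom, start, end, n_snps, value.
#' @export
windowed_pi <- function(table, sample_idx, windows, per = c("bp", "snp")) {
  per <- match.arg(per)
  ac <- group_allele_counts(table, sample_idx)
  pi_site <- site_pi(ac$ref, ac$alt)
  agg_windows(windows, table, pi_site,
              function(v, w) {
                s <- sum(v, na.rm = TRUE)
                if (per == "bp") s / w$size else if (length(v)) s / length(v) else 0
              })
}

agg_windows <- function(windows, table, values, f) {
  out <- windows[, c("chrom", "start", "end")]
  out$n_snps <- 0L
  out$value <- 0
  for (chr in unique(windows$chrom)) {
    wi <- which(windows$chrom == chr)
    si <- which(table$chrom == chr)
    if (!length(si)) next
    pos <- table$pos[si]
    for (k in wi) {
      inw <- si[pos >= windows$start[k] & pos <= windows$end[k]]
      out$n_snps[k] <- length(inw)
      out$value[k] <- f(values[inw], windows[k, ])
    }
  }
  out
}

#' Windowed diversity ratio between two groups
#'
#' `ratio = pi_contrast / pi_target` per window, so a swept (low-diversity)
#' target group yields a large ratio and both scan directions take the upper
#' tail. Windows with `pi_target = 0` but positive contrast diversity are
#' reported as `Inf` and rank above every finite ratio; windows with both
#' diversities zero get NA and are dropped from ranking.
#'
#' @param pi_target,pi_contrast window data.frames from [windowed_pi()] on
#'   the identical grid; the target is the group tested for the sweep.
#' @return data.frame: chrom, start, end, n_snps (summed), value.
#' @export
theta_pi_ratio <- function(pi_target, pi_contrast) {
  if (nrow(pi_target) != nrow(pi_contrast) ||
      !all(window_key(pi_target) == window_key(pi_contrast))) {
    stop("window grids differ between the two pi tracks")
  }
  value <- ifelse(pi_target$value > 0, pi_contrast$value / pi_target$value,
                  ifelse(pi_contrast$value > 0, Inf, NA_real_))
  data.frame(chrom = pi_target$chrom, start = pi_target$start,
             end = pi_target$end,
             n_snps = pi_target$n_snps + pi_contrast$n_snps,
             value = value, stringsAsFactors = FALSE)
}

#' Weir-Cockerham (1984) variance components for two populations
#'
#' Given per-site genotype counts (hom-ref, het, hom-alt) for each
#' population, returns the between-population component `a` and the total
#' `a + b + c` of the r = 2 estimator with observed heterozygosity. Per-site
#' Fst is `a / (a + b + c)`; sites where the total is not positive
#' (monomorphic across both populations) or where either population has
#' fewer than two genotyped diploids are undefined (NA) and must be excluded
#' from sums.
#'
#' @param countsA,countsB numeric matrices (sites x 3) or length-3 vectors of
#'   genotype counts `(hom_ref, het, hom_alt)`.
#' @return list with vectors `a`, `total` and `fst` (`a/total`, NA where
#'   undefined).
#' @export
wc_fst_components <- function(countsA, countsB) {
  if (is.null(dim(countsA))) countsA <- matrix(countsA, 1)
  if (is.null(dim(countsB))) countsB <- matrix(countsB, 1)
  nA <- rowSums(countsA); nB <- rowSums(countsB)
  pA <- (countsA[, 2] + 2 * countsA[, 3]) / (2 * nA)
  pB <- (countsB[, 2] + 2 * countsB[, 3]) / (2 * nB)
  hA <- countsA[, 2] / nA
  hB <- countsB[, 2] / nB
  r <- 2
  nbar <- (nA + nB) / r
  nc <- (r * nbar - (nA^2 + nB^2) / (r * nbar)) / (r - 1)
  pbar <- (nA * pA + nB * pB) / (r * nbar)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
  hbar <- (nA * hA + nB * hB) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  total <- a + b + cc
  defined <- nA >= 2 & nB >= 2 & pbar > 0 & pbar < 1 & total > 0
  a[!defined] <- NA_real_
  total[!defined] <- NA_real_
  list(a = a, total = total, fst = a / total)
}

# Per-site genotype count matrices (hom_ref, het, hom_alt) for a group.
group_genotype_counts <- function(table, sample_idx) {
  g <- table$gt[sample_idx, , drop = FALSE]
  cbind(hom_ref = colSums(g == 0L, na.rm = TRUE),
        het = colSums(g == 1L, na.rm = TRUE),
        hom_alt = colSums(g == 2L, na.rm = TRUE))
}

#' Windowed Weir-Cockerham Fst between the two scan groups
#'
#' The weighted window estimate: `sum(a) / sum(a + b + c)` over the defined
#' sites of each window. Windows with no defined site are omitted.
#'
#' @param table a QC-filtered [variant_table()].
#' @param popmap a [population_map()].
#' @param windows grid from [make_windows()].
#' @return data.frame: chrom, start, end, n_snps (defined sites), value.
#' @export
windowed_fst <- function(table, popmap, windows) {
  iF <- group_samples(popmap, table, "F")
  iC <- group_samples(popmap, table, "C")
  if (length(iF) < 2 || length(iC) < 2) stop("both groups need >= 2 diploids")
  comp <- wc_fst_components(group_genotype_counts(table, iF),
                            group_genotype_counts(table, iC))
  out <- windows[, c("chrom", "start", "end")]
  out$n_snps <- 0L
  out$value <- NA_real_
  for (chr in unique(windows$chrom)) {
    wi <- which(windows$chrom == chr)
    si <- which(table$chrom == chr & !is.na(comp$a))
    if (!length(si)) next
    pos <- table$pos[si]
    for (k in wi) {
      inw <- si[pos >= windows$start[k] & pos <= windows$end[k]]
      if (!length(inw)) next
      out$n_snps[k] <- length(inw)
      out$value[k] <- sum(comp$a[inw]) / sum(comp$total[inw])
    }
  }
  out[!is.na(out$value), , drop = FALSE]
}

#' Genome-wide (ratio-of-sums) Weir-Cockerham Fst
#'
#' @param table a [variant_table()].
#' @param popmap a [population_map()].
#' @return single Fst value over all defined sites.
#' @export
genome_fst <- function(table, popmap) {
  iF <- group_samples(popmap, table, "F")
  iC <- group_samples(popmap, table, "C")
  comp <- wc_fst_components(group_genotype_counts(table, iF),
                            group_genotype_counts(table, iC))
  sum(comp$a, na.rm = TRUE) / sum(comp$total, na.rm = TRUE)
}
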
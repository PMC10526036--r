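#' Construct a variant table
#'
#' The central container for biallelic SNP data: per-site metadata plus a
#' samples x sites genotype matrix (0/1/2/NA alt-allele counts), an optional
#' phased haplotype matrix (2*samples x sites, 0/1/NA), and a per-genotype
#' read-depth matrix. All downstream statistics consume this object.
#'
#' Haplotype rows `2s - 1` and `2s` belong to sample `s`; when the table is
#' phased, the genotype code equals the sum of the two haplotype codes at
#' every non-missing entry.
#'
#' @param chrom character vector of chromosome identifiers, one per site.
#' @param pos integer vector of 1-based positions, strictly increasing within
#'   each chromosome.
#' @param ref,alt single reference / alternate bases (A, C, G or T).
#' @param gt samples x sites integer matrix of alt-allele counts (NA missing).
#' @param hap 2*samples x sites 0/1 matrix, or NULL for unphased data.
#' @param dp samples x sites read-depth matrix; `Inf`-like unknown depths are
#'   stored as [DP_UNKNOWN].
#' @param samples character vector of sample identifiers (matrix row order).
#' @param phased logical; TRUE when `hap` carries valid phase.
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(chrom, pos, ref, alt, gt, hap = NULL, dp = NULL,
                          samples = rownames(gt), phased = !is.null(hap)) {
  n_sites <- length(pos)
  stopifnot(length(chrom) == n_sites, length(ref) == n_sites,
            length(alt) == n_sites, ncol(gt) == n_sites)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(gt)))
  if (is.null(dp)) {
    dp <- matrix(DP_UNKNOWN, nrow(gt), ncol(gt))
  }
  for (chr in unique(chrom)) {
    p <- pos[chrom == chr]
    if (any(diff(p) <= 0)) {
      stop("positions must be strictly increasing within chromosome ", chr)
    }
  }
  if (!is.null(hap) && nrow(hap) != 2L * nrow(gt)) {
    stop("haplotype matrix must have exactly two rows per sample")
  }
  obj <- structure(
    list(chrom = as.character(chrom), pos = as.integer(pos),
         ref = as.character(ref), alt = as.character(alt),
         gt = gt, hap = hap, dp = dp,
         samples = as.character(samples), phased = isTRUE(phased)),
    class = "variant_table")
  obj
}

#' Sentinel depth for genotypes whose DP is not recorded.
#'
#' A VCF without FORMAT/DP still passes the depth filter; unknown depths are
#' stored as this large value so `dp >= min_depth` is always true for them.
#' @export
DP_UNKNOWN <- 10000000L

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d samples x %d SNPs on %d chromosome(s)%s\n",
              length(x$samples), n_sites(x), length(unique(x$chrom)),
              if (x$phased) ", phased" else ""))
  invisible(x)
}

#' Number of SNP sites in a variant table
#' @param table a `variant_table`.
#' @export
n_sites <- function(table) length(table$pos)

#' Subset a variant table by site index
#' @param table a `variant_table`.
#' @param keep logical or integer site index.
#' @return the subsetted `variant_table`.
#' @export
subset_sites <- function(table, keep) {
  variant_table(table$chrom[keep], table$pos[keep], table$ref[keep],
                table$alt[keep],
                table$gt[, keep, drop = FALSE],
                if (!is.null(table$hap)) table$hap[, keep, drop = FALSE],
                table$dp[, keep, drop = FALSE],
                samples = table$samples, phased = table$phased)
}

#' Check genotype/haplotype consistency of a phased table
#'
#' Verifies that each genotype equals the sum of its two haplotype codes
#' wherever both are non-missing.
#' @param table a phased `variant_table`.
#' @return TRUE invisibly, or an error.
#' @export
validate_phase <- function(table) {
  if (!table$phased) stop("table is not phased")
  gsum <- table$hap[seq(1, nrow(table$hap), 2), , drop = FALSE] +
    table$hap[seq(2, nrow(table$hap), 2), , drop = FALSE]
  ok <- is.na(gsum) | is.na(table$gt) | gsum == table$gt
  if (!all(ok)) stop("genotypes disagree with haplotype sums")
  invisible(TRUE)
}

#' Build a sample-to-population map
#'
#' @param sample character vector of sample ids.
#' @param population character vector of population (breed) labels.
#' @param group character vector of scan-group labels, each "F" or "C".
#' @return A data.frame of class `population_map` with columns
#'   `sample`, `population`, `group`.
#' @export
population_map <- function(sample, population, group) {
  if (anyDuplicated(sample)) stop("duplicate sample ids in population map")
  if (!all(group %in% c("F", "C"))) {
    stop("group labels must be 'F' or 'C'")
  }
  structure(data.frame(sample = as.character(sample),
                       population = as.character(population),
                       group = as.character(group),
                       stringsAsFactors = FALSE),
            class = c("population_map", "data.frame"))
}

#' Sample indices belonging to one scan group
#' @param popmap a `population_map`.
#' @param table a `variant_table` whose samples the indices refer to.
#' @param group "F" or "C".
#' @return integer vector of sample indices.
#' @export
group_samples <- function(popmap, table, group) {
  miss <- setdiff(table$samples, popmap$sample)
  if (length(miss)) {
    stop("samples absent from population map: ", paste(miss, collapse = ", "))
  }
  grp <- popmap$group[match(table$samples, popmap$sample)]
  idx <- which(grp == group)
  if (!length(idx)) stop("group ", group, " has no samples")
  idx
}

#' Haplotype row indices for a set of samples
#' @param sample_idx integer sample indices.
#' @return integer haplotype-row indices (two per sample).
#' @export
hap_rows <- function(sample_idx) {
  as.integer(rbind(2L * sample_idx - 1L, 2L * sample_idx))
}

#' Chromosome lengths implied by a table (max position per chromosome)
#' @param table a `variant_table`.
#' @return named integer vector.
#' @export
table_chrom_lengths <- function(table) {
  vapply(split(table$pos, table$chrom), max, integer(1))
}
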
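#' Read a phased multi-sample VCF into a variant table
#'
#' Loads biallelic SNP records only: multi-allelic records and indels are
#' skipped and counted. Phased "0|1" genotypes populate the haplotype matrix;
#' any "/"-separated genotype marks the table unphased. Half-missing calls
#' ("0/.") are treated as fully missing. Records without FORMAT/DP get the
#' sentinel depth [DP_UNKNOWN] so they pass depth filtering.
#'
#' @param path VCF 4.2 file (uncompressed or gzipped).
#' @return a [variant_table()]; attributes `n_skipped` (non-biallelic/indel
#'   records) and `chrom_lengths` (from ##contig headers, when present).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  check_vcf_shape(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- !is.na(alt) & ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snp)
  gt_str <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  dp_str <- if ("DP" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    vcfR::extract.gt(v, element = "DP")[snp, , drop = FALSE]
  } else NULL
  chrom <- fix[snp, "CHROM"]; pos <- as.integer(fix[snp, "POS"])
  samples <- colnames(gt_str)
  m <- sum(snp); n_dip <- length(samples)

  a1 <- substr(gt_str, 1, 1)
  sepc <- substr(gt_str, 2, 2)
  a2 <- substr(gt_str, 3, 3)
  miss <- is.na(gt_str) | a1 == "." | a2 == "." | sepc == ""
  phased <- all(sepc[!miss] == "|")
  h1 <- suppressWarnings(as.integer(a1)); h1[miss] <- NA_integer_
  h2 <- suppressWarnings(as.integer(a2)); h2[miss] <- NA_integer_
  # extract.gt returns sites x samples; transpose to samples x sites
  h1 <- t(matrix(h1, m, n_dip)); h2 <- t(matrix(h2, m, n_dip))
  gt <- h1 + h2
  hap <- NULL
  if (phased) {
    hap <- matrix(NA_integer_, 2L * n_dip, m)
    hap[seq(1, 2 * n_dip, 2), ] <- h1
    hap[seq(2, 2 * n_dip, 2), ] <- h2
  }
  dp <- matrix(DP_UNKNOWN, n_dip, m)
  if (!is.null(dp_str)) {
    d <- suppressWarnings(as.integer(dp_str))
    d <- t(matrix(d, m, n_dip))
    dp[!is.na(d)] <- d[!is.na(d)]
  }
  tab <- variant_table(chrom, pos, ref[snp], alt[snp], gt, hap, dp,
                       samples = samples, phased = phased)
  attr(tab, "n_skipped") <- n_skipped
  attr(tab, "chrom_lengths") <- contig_lengths(v@meta)
  tab
}

check_vcf_shape <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM\t", lines)
  if (!length(grep("^##fileformat=VCF", lines)) || !length(hdr)) {
    stop("malformed VCF header in ", path)
  }
  want <- length(strsplit(lines[hdr[1]], "\t", fixed = TRUE)[[1]])
  body <- lines[seq_along(lines) > hdr[1] & nzchar(lines)]
  nf <- lengths(strsplit(body, "\t", fixed = TRUE))
  bad <- which(nf != want)
  if (length(bad)) {
    stop("ragged VCF record at line ", hdr[1] + bad[1],
         ": expected ", want, " fields, found ", nf[bad[1]])
  }
  invisible(TRUE)
}

contig_lengths <- function(meta) {
  m <- regmatches(meta, regexec("##contig=<ID=([^,>]+),length=([0-9]+)", meta))
  m <- m[lengths(m) == 3]
  if (!length(m)) return(NULL)
  stats::setNames(as.integer(vapply(m, `[`, character(1), 3)),
                  vapply(m, `[`, character(1), 2))
}

#' Apply the SNP quality-control filters
#'
#' Three rules in fixed order: (1) genotypes with depth below `min_depth` are
#' set missing; (2) sites whose missing-genotype fraction is `>= max_missing`
#' are dropped; (3) sites whose minor allele frequency, computed over
#' non-missing alleles, is `<= min_maf` are dropped (monomorphic sites fall
#' to this rule).
#'
#' The read-depth rule can be evaluated per genotype (`depth_mode =
#' "genotype"`, the default) or against the per-site mean depth
#' (`depth_mode = "site"`, which drops whole sites instead of masking calls).
#'
#' @param table a [variant_table()].
#' @param min_depth minimum read depth in reads (default 3, i.e. depth > 2).
#' @param max_missing maximum tolerated missing fraction (default 0.10).
#' @param min_maf minimum minor allele frequency (default 0.05; kept when
#'   strictly greater).
#' @param depth_mode "genotype" or "site".
#' @return the filtered [variant_table()] with attribute `qc_counts`, a list
#'   with `masked_genotypes`, `dropped_low_depth_sites`, `dropped_missing`
#'   and `dropped_maf`.
#' @export
apply_qc_filters <- function(table, min_depth = 3L, max_missing = 0.10,
                             min_maf = 0.05,
                             depth_mode = c("genotype", "site")) {
  depth_mode <- match.arg(depth_mode)
  if (max_missing < 0 || max_missing > 1) {
    stop("max_missing must lie in [0, 1]")
  }
  if (min_maf < 0 || min_maf > 1) stop("min_maf must lie in [0, 1]")
  if (min_depth < 0) stop("min_depth must be non-negative")

  dropped_depth_sites <- 0L
  masked <- 0L
  if (depth_mode == "genotype") {
    low <- table$dp < min_depth & !is.na(table$gt)
    masked <- sum(low)
    if (masked) {
      table$gt[low] <- NA_integer_
      if (!is.null(table$hap)) {
        idx <- which(low, arr.ind = TRUE)
        table$hap[cbind(2L * idx[, 1] - 1L, idx[, 2])] <- NA_integer_
        table$hap[cbind(2L * idx[, 1], idx[, 2])] <- NA_integer_
      }
    }
  } else {
    keep <- colMeans(table$dp) >= min_depth
    dropped_depth_sites <- sum(!keep)
    table <- subset_sites(table, keep)
  }

  miss_frac <- colMeans(is.na(table$gt))
  keep1 <- miss_frac < max_missing
  dropped_missing <- sum(!keep1)
  table <- subset_sites(table, keep1)

  n_called <- colSums(!is.na(table$gt))
  alt_count <- colSums(table$gt, na.rm = TRUE)
  p <- ifelse(n_called > 0, alt_count / (2 * n_called), NA_real_)
  maf <- pmin(p, 1 - p)
  keep2 <- !is.na(maf) & maf > min_maf
  dropped_maf <- sum(!keep2)
  table <- subset_sites(table, keep2)

  attr(table, "qc_counts") <- list(masked_genotypes = masked,
                                   dropped_low_depth_sites = dropped_depth_sites,
                                   dropped_missing = dropped_missing,
                                   dropped_maf = dropped_maf)
  table
}

#' Squared Pearson correlation between two genotype vectors
#'
#' Computed over samples non-missing in both vectors (pairwise deletion).
#' Undefined (NA) when either vector has zero variance after deletion or
#' fewer than two complete pairs remain; undefined pairs are never pruned.
#'
#' @param g1,g2 numeric genotype vectors (0/1/2 codes, NA missing).
#' @return r-squared in \[0, 1\], or NA when undefined.
#' @export
pairwise_r2 <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("genotype vectors differ in length")
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2) return(NA_real_)
  x <- g1[ok]; y <- g2[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' PLINK-style sliding-window LD pruning
#'
#' Within each window of `window_snps` consecutive SNPs (advancing by
#' `step_snps`, per chromosome), repeatedly removes one SNP of the pair with
#' the largest r-squared above the threshold until no kept pair exceeds it.
#' Removal is deterministic: the pair with the largest r-squared wins (ties
#' broken by lowest site-index pair) and its *later* member is removed.
#'
#' @param table a QC-filtered [variant_table()].
#' @param window_snps window width in SNPs (default 25).
#' @param step_snps step in SNPs (default 5).
#' @param r2_threshold prune when r-squared exceeds this (default 0.05).
#' @return integer vector of kept site indices (columns of `table$gt`).
#' @export
ld_prune <- function(table, window_snps = 25L, step_snps = 5L,
                     r2_threshold = 0.05) {
  if (window_snps < 2) stop("window_snps must be >= 2")
  if (step_snps < 1) stop("step_snps must be >= 1")
  keep <- rep(TRUE, n_sites(table))
  for (chr in unique(table$chrom)) {
    idx <- which(table$chrom == chr)
    n <- length(idx)
    starts <- seq(1L, max(1L, n), by = step_snps)
    for (s in starts) {
      w <- idx[s:min(s + window_snps - 1L, n)]
      w <- w[keep[w]]
      if (length(w) < 2) next
      g <- table$gt[, w, drop = FALSE]
      # single-shot pairwise r^2 for the window; zero-variance / short
      # overlaps come back NA and are never treated as offending
      r2m <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))^2
      r2m[lower.tri(r2m, diag = TRUE)] <- NA
      alive <- rep(TRUE, length(w))
      repeat {
        cur <- r2m
        cur[!alive, ] <- NA; cur[, !alive] <- NA
        off <- which(!is.na(cur) & cur > r2_threshold, arr.ind = TRUE)
        if (!nrow(off)) break
        vals <- cur[off]
        worst <- off[order(-vals, off[, 1], off[, 2])[1], ]
        alive[worst[2]] <- FALSE
        keep[w[worst[2]]] <- FALSE
      }
    }
  }
  which(keep)
}

#' Read gene models from a GFF3 file
#'
#' Resolves exon and CDS children to their gene via Parent attributes
#' (exon/CDS -> mRNA -> gene). Coordinates stay 1-based inclusive.
#'
#' @param path GFF3 file with gene/mRNA/exon/CDS features.
#' @return an object of class `gene_models`: list with `genes` (data.frame
#'   gene_id, chrom, start, end, strand), `exons` and `cds` (per-gene
#'   data.frames of intervals; CDS rows carry `phase`).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$ID <- as.character(df$ID)
  parent1 <- vapply(as.list(df$Parent), function(p) {
    if (length(p)) as.character(p[1]) else NA_character_
  }, character(1))
  df$parent <- parent1
  genes <- df[df$type == "gene", ]
  gene_df <- data.frame(gene_id = genes$ID, chrom = as.character(genes$seqnames),
                        start = genes$start, end = genes$end,
                        strand = as.character(genes$strand),
                        stringsAsFactors = FALSE)
  id2gene <- stats::setNames(gene_df$gene_id, gene_df$gene_id)
  mrna <- df[df$type == "mRNA", ]
  for (i in seq_len(nrow(mrna))) {
    if (!is.na(mrna$parent[i]) && mrna$parent[i] %in% names(id2gene)) {
      id2gene[mrna$ID[i]] <- id2gene[[mrna$parent[i]]]
    }
  }
  resolve_gene <- function(row) {
    p <- row$parent
    if (is.na(p) || !p %in% names(id2gene)) {
      id <- if (is.na(row$ID)) "(unnamed)" else row$ID
      stop(row$type, " feature ", id, " has no resolvable parent gene")
    }
    id2gene[[p]]
  }
  exons <- stats::setNames(vector("list", nrow(gene_df)), gene_df$gene_id)
  cds <- exons
  for (i in which(df$type %in% c("exon", "CDS"))) {
    row <- df[i, ]
    g <- resolve_gene(row)
    rec <- data.frame(start = row$start, end = row$end,
                      phase = suppressWarnings(as.integer(as.character(row$phase))),
                      stringsAsFactors = FALSE)
    if (row$type == "exon") exons[[g]] <- rbind(exons[[g]], rec)
    else cds[[g]] <- rbind(cds[[g]], rec)
  }
  for (g in gene_df$gene_id) {
    span <- gene_df[gene_df$gene_id == g, ]
    for (part in list(exons[[g]], cds[[g]])) {
      if (!is.null(part) && (any(part$start < span$start) ||
                             any(part$end > span$end))) {
        stop("exon/CDS outside gene span for ", g)
      }
    }
    if (!is.null(exons[[g]])) exons[[g]] <- exons[[g]][order(exons[[g]]$start), ]
    if (!is.null(cds[[g]])) cds[[g]] <- cds[[g]][order(cds[[g]]$start), ]
  }
  structure(list(genes = gene_df, exons = exons, cds = cds),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes on %d chromosome(s)\n",
              nrow(x$genes), length(unique(x$genes$chrom))))
  invisible(x)
}

genes_granges <- function(genes) {
  GenomicRanges::GRanges(genes$genes$chrom,
                         IRanges::IRanges(genes$genes$start, genes$genes$end),
                         strand = genes$genes$strand,
                         gene_id = genes$genes$gene_id)
}
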
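#' Select the top fraction of windows by statistic value
#'
#' Rank-based selection: exactly `floor(fraction * N)` windows with the
#' largest values, where N counts windows with a rankable (non-NA) value.
#' `Inf` sentinel values (diversity ratios over a zero-diversity target) rank
#' above every finite value. Ties at the selection boundary are broken by
#' genomic order (chrom, then start), so the count is deterministic.
#'
#' @param stats window data.frame with columns chrom, start, end, value.
#' @param fraction top fraction to keep (default 0.05).
#' @return the selected rows of `stats`, in genomic order.
#' @export
select_top_windows <- function(stats, fraction = 0.05) {
  ranked <- stats[!is.na(stats$value), , drop = FALSE]
  n <- nrow(ranked)
  k <- floor(fraction * n)
  if (k < 1) {
    stop("top-fraction selection needs at least ", ceiling(1 / fraction),
         " rankable windows (have ", n, ")")
  }
  ord <- order(-ranked$value, ranked$chrom, ranked$start)
  sel <- ranked[ord[seq_len(k)], , drop = FALSE]
  sel[order(sel$chrom, sel$start), , drop = FALSE]
}

#' Candidate SNPs from the joint Fst / diversity-ratio top windows
#'
#' Intersects the top-fraction window sets of the Fst track and the
#' theta-pi-ratio track (same non-overlapping grid) and returns every SNP of
#' the table that falls inside a jointly selected window.
#'
#' @param fst_windows,ratio_windows window data.frames on the identical
#'   50 kb grid (chrom/start/end/value).
#' @param table the [variant_table()] the windows were computed from.
#' @param fraction top fraction for each track (default 0.05).
#' @return list with `windows` (the joint window data.frame) and `snps`
#'   (data.frame chrom, pos).
#' @export
joint_fst_pi_candidates <- function(fst_windows, ratio_windows, table,
                                    fraction = 0.05) {
  grid_of <- function(w) paste(w$chrom, w$start, w$end, sep = ":")
  # tracks may drop different undefined windows but must share one tiling:
  # same window size, starts aligned to multiples of it
  sz <- unique(c(fst_windows$end - fst_windows$start,
                 ratio_windows$end - ratio_windows$start)) + 1L
  if (length(sz) != 1L ||
      any((c(fst_windows$start, ratio_windows$start) - 1L) %% sz != 0L)) {
    stop("window grids of the two tracks do not match")
  }
  top_fst <- select_top_windows(fst_windows, fraction)
  top_ratio <- select_top_windows(ratio_windows, fraction)
  joint_keys <- intersect(grid_of(top_fst), grid_of(top_ratio))
  joint <- top_fst[grid_of(top_fst) %in% joint_keys, , drop = FALSE]
  snps <- snps_in_windows(data.frame(chrom = table$chrom, pos = table$pos,
                                     stringsAsFactors = FALSE), joint)
  list(windows = joint, snps = snps)
}

#' SNP loci falling inside a set of windows
#'
#' @param loci data.frame with columns chrom, pos.
#' @param windows data.frame with columns chrom, start, end.
#' @return the unique rows of `loci` covered by at least one window.
#' @export
snps_in_windows <- function(loci, windows) {
  hits <- rep(FALSE, nrow(loci))
  for (k in seq_len(nrow(windows))) {
    hits <- hits | (loci$chrom == windows$chrom[k] &
                    loci$pos >= windows$start[k] &
                    loci$pos <= windows$end[k])
  }
  out <- unique(loci[hits, c("chrom", "pos")])
  rownames(out) <- NULL
  out
}

#' Flank candidate SNPs and merge into selection-signaling regions
#'
#' Each SNP becomes the closed interval `[pos - flank, pos + flank]`, clipped
#' to `[1, chromosome length]`; overlapping or book-ended intervals are
#' merged. The merged regions are pairwise disjoint and sorted.
#'
#' @param snps data.frame with columns chrom, pos.
#' @param flank flank size in bp (default 50,000).
#' @param chrom_lengths named vector of chromosome lengths.
#' @return data.frame: chrom, start, end, n_snps (source SNPs per region).
#' @export
flank_and_merge <- function(snps, flank = 50000L, chrom_lengths) {
  if (!nrow(snps)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_snps = integer(0)))
  }
  if (any(!snps$chrom %in% names(chrom_lengths))) {
    stop("SNP on a chromosome without a known length")
  }
  len <- chrom_lengths[snps$chrom]
  if (any(snps$pos > len)) stop("SNP position beyond chromosome length")
  gr <- GenomicRanges::GRanges(
    snps$chrom,
    IRanges::IRanges(pmax(1L, snps$pos - as.integer(flank)),
                     pmin(as.integer(len), snps$pos + as.integer(flank))))
  merged <- GenomicRanges::reduce(gr)   # merges overlapping and book-ended
  cov <- GenomicRanges::countOverlaps(merged, gr)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(merged)),
                   start = GenomicRanges::start(merged),
                   end = GenomicRanges::end(merged),
                   n_snps = cov, stringsAsFactors = FALSE)
  df[order(df$chrom, df$start), , drop = FALSE]
}

#' Genes overlapping candidate regions
#'
#' A gene is included when its `[start, end]` span overlaps any region by at
#' least 1 bp (closed-interval overlap). The result is a sorted, duplicate-
#' free gene-id set, invariant to the input SNP order.
#'
#' @param regions data.frame chrom/start/end from [flank_and_merge()].
#' @param genes a `gene_models` object (or a data.frame with gene_id, chrom,
#'   start, end).
#' @param method_tag label recorded with the set (e.g. "fst_pi", "xpehh").
#' @return list of class `gene_set`: `method`, `genes` (sorted ids).
#' @export
genes_in_regions <- function(regions, genes, method_tag = "unknown") {
  gdf <- if (inherits(genes, "gene_models")) genes$genes else genes
  if (!nrow(regions)) {
    return(structure(list(method = method_tag, genes = character(0)),
                     class = "gene_set"))
  }
  rgr <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(regions$start, regions$end))
  ggr <- GenomicRanges::GRanges(gdf$chrom,
                                IRanges::IRanges(gdf$start, gdf$end))
  hit <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(ggr, rgr)))
  structure(list(method = method_tag, genes = sort(unique(gdf$gene_id[hit]))),
            class = "gene_set")
}

#' Two-way Venn overlap of candidate gene sets
#'
#' @param set_a,set_b `gene_set` objects (or plain character vectors).
#' @return list: `a_only`, `b_only`, `both` (counts) and `intersection`
#'   (a `gene_set`, the final candidate list).
#' @export
venn_overlap <- function(set_a, set_b) {
  ga <- if (inherits(set_a, "gene_set")) set_a$genes else unique(set_a)
  gb <- if (inherits(set_b, "gene_set")) set_b$genes else unique(set_b)
  both <- intersect(ga, gb)
  list(a_only = length(setdiff(ga, gb)),
       b_only = length(setdiff(gb, ga)),
       both = length(both),
       intersection = structure(list(method = "intersection",
                                     genes = sort(both)),
                                class = "gene_set"))
}

#' Write candidate regions as a BED file
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so
#' each row is written as `(start - 1, end)`.
#'
#' @param regions data.frame chrom/start/end.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  df <- data.frame(regions$chrom, regions$start - 1L, regions$end)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file back into 1-based inclusive regions
#' @param path BED file.
#' @return data.frame chrom, start, end (1-based inclusive).
#' @export
read_regions_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(chrom = df[[1]], start = df[[2]] + 1L, end = df[[3]],
             stringsAsFactors = FALSE)
}
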
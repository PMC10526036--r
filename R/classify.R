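#' Classify SNPs by genomic context with ts/tv accounting
#'
#' Assigns every SNP exactly one category with the precedence
#' exonic > splicing > intronic > upstream/downstream > intergenic:
#' \itemize{
#'   \item exonic SNPs falling in a CDS are translated through the standard
#'     genetic code and split into `exonic:stopgain`, `exonic:stoploss`,
#'     `exonic:synonymous`, `exonic:nonsynonymous`;
#'   \item `splicing`: within 2 bp of an exon-intron boundary (intron side),
#'     inside the gene span;
#'   \item `intronic`: inside a gene span but outside exons and splice pads;
#'   \item `upstream` / `downstream`: within 1,000 bp of a gene span on the
#'     strand-aware 5' / 3' side (`upstream/downstream` when both apply,
#'     possibly through different genes);
#'   \item `intergenic`: everything else.
#' }
#' Transitions are A<->G and C<->T; all other substitutions are
#' transversions. Exonic SNPs whose fetched reference base disagrees with the
#' VCF REF (or which fall in an exon with no CDS) cannot be given a synonymy
#' call: they are excluded from the classification with a warning and counted
#' in `n_excluded`.
#'
#' @param table a [variant_table()].
#' @param genes a `gene_models` object from [read_gff3()].
#' @param reference_fetch function `(chrom, start, end)` returning the
#'   reference bases of the closed interval, e.g. from
#'   [reference_fetch_for()].
#' @param updown_bp upstream/downstream distance in bp (default 1,000).
#' @param splice_bp splice-pad width in bp (default 2).
#' @return a list of class `variant_classification`: `category` (per-SNP
#'   factor, NA for excluded), `counts` (named vector over categories),
#'   `ts`, `tv`, `tstv` (over classified SNPs), `n_excluded`.
#' @export
classify_variants <- function(table, genes, reference_fetch,
                              updown_bp = 1000L, splice_bp = 2L) {
  m <- n_sites(table)
  snp_gr <- GenomicRanges::GRanges(table$chrom,
                                   IRanges::IRanges(table$pos, width = 1))
  gdf <- genes$genes
  gene_gr <- genes_granges(genes)

  exon_list <- lapply(gdf$gene_id, function(g) genes$exons[[g]])
  exon_gr <- build_part_granges(gdf, exon_list)
  splice_gr <- build_splice_pads(gdf, exon_list, splice_bp)

  category <- rep(NA_character_, m)
  in_exon <- unique(S4Vectors::queryHits(
    GenomicRanges::findOverlaps(snp_gr, exon_gr)))
  in_splice <- unique(S4Vectors::queryHits(
    GenomicRanges::findOverlaps(snp_gr, splice_gr)))
  in_gene <- unique(S4Vectors::queryHits(
    GenomicRanges::findOverlaps(snp_gr, gene_gr)))

  up_gr <- flank_regions(gdf, updown_bp, side = "upstream")
  down_gr <- flank_regions(gdf, updown_bp, side = "downstream")
  in_up <- unique(S4Vectors::queryHits(
    GenomicRanges::findOverlaps(snp_gr, up_gr)))
  in_down <- unique(S4Vectors::queryHits(
    GenomicRanges::findOverlaps(snp_gr, down_gr)))

  category[] <- "intergenic"
  both <- intersect(in_up, in_down)
  category[in_up] <- "upstream"
  category[in_down] <- "downstream"
  category[both] <- "upstream/downstream"
  category[in_gene] <- "intronic"
  category[in_splice] <- "splicing"

  n_excluded <- 0L
  if (length(in_exon)) {
    exon_hits <- GenomicRanges::findOverlaps(snp_gr, exon_gr)
    first_gene <- tapply(S4Vectors::subjectHits(exon_hits),
                         S4Vectors::queryHits(exon_hits), min)
    for (q in in_exon) {
      g <- exon_gr$gene_id[first_gene[[as.character(q)]]]
      res <- synonymy_call(table, q, genes, g, reference_fetch)
      if (is.na(res)) {
        category[q] <- NA_character_
        n_excluded <- n_excluded + 1L
      } else {
        category[q] <- res
      }
    }
  }
  if (n_excluded) {
    warning(n_excluded,
            " exonic SNP(s) excluded from classification (reference ",
            "mismatch or exon without CDS)")
  }
  lv <- c("exonic:stopgain", "exonic:stoploss", "exonic:synonymous",
          "exonic:nonsynonymous", "splicing", "intronic", "upstream",
          "downstream", "upstream/downstream", "intergenic")
  classified <- !is.na(category)
  is_ts <- (table$ref == "A" & table$alt == "G") |
    (table$ref == "G" & table$alt == "A") |
    (table$ref == "C" & table$alt == "T") |
    (table$ref == "T" & table$alt == "C")
  ts <- sum(is_ts & classified); tv <- sum(!is_ts & classified)
  structure(list(category = factor(category, levels = lv),
                 counts = base::table(factor(category, levels = lv)),
                 ts = ts, tv = tv,
                 tstv = if (tv > 0) ts / tv else NA_real_,
                 n_excluded = n_excluded),
            class = "variant_classification")
}

#' @export
print.variant_classification <- function(x, ...) {
  cat("variant_classification\n")
  print(x$counts)
  cat(sprintf("ts %d, tv %d, ts/tv %.3f; excluded %d\n",
              x$ts, x$tv, x$tstv, x$n_excluded))
  invisible(x)
}

#' Classification summary as a Table-2-style data frame
#' @param x a `variant_classification`.
#' @return data.frame with columns `catalogue`, `snp_numbers` including the
#'   ts, tv, ts/tv and total rows.
#' @export
classification_summary <- function(x) {
  data.frame(
    catalogue = c(names(x$counts), "ts", "tv", "ts/tv", "Total"),
    snp_numbers = c(as.numeric(x$counts), x$ts, x$tv, round(x$tstv, 2),
                    sum(x$counts)),
    stringsAsFactors = FALSE)
}

build_part_granges <- function(gdf, part_list) {
  rows <- lapply(seq_len(nrow(gdf)), function(i) {
    p <- part_list[[i]]
    if (is.null(p) || !nrow(p)) return(NULL)
    GenomicRanges::GRanges(gdf$chrom[i], IRanges::IRanges(p$start, p$end),
                           strand = gdf$strand[i], gene_id = gdf$gene_id[i])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(GenomicRanges::GRanges(gene_id = character(0)))
  }
  do.call(c, rows)
}

build_splice_pads <- function(gdf, exon_list, splice_bp) {
  rows <- lapply(seq_len(nrow(gdf)), function(i) {
    p <- exon_list[[i]]
    if (is.null(p) || nrow(p) < 1) return(NULL)
    pads <- rbind(data.frame(start = p$start - splice_bp, end = p$start - 1L),
                  data.frame(start = p$end + 1L, end = p$end + splice_bp))
    pads$start <- pmax(pads$start, gdf$start[i])
    pads$end <- pmin(pads$end, gdf$end[i])
    pads <- pads[pads$start <= pads$end, , drop = FALSE]
    if (!nrow(pads)) return(NULL)
    GenomicRanges::GRanges(gdf$chrom[i], IRanges::IRanges(pads$start, pads$end))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(GenomicRanges::GRanges())
  do.call(c, rows)
}

flank_regions <- function(gdf, updown_bp, side) {
  left <- xor(side == "upstream", gdf$strand == "-")
  start <- ifelse(left, gdf$start - updown_bp, gdf$end + 1L)
  end <- ifelse(left, gdf$start - 1L, gdf$end + updown_bp)
  start <- pmax(start, 1L)
  ok <- start <= end
  GenomicRanges::GRanges(gdf$chrom[ok], IRanges::IRanges(start[ok], end[ok]))
}

# Translate the ref and alt codon of one exonic SNP; returns the exonic
# category, or NA when no synonymy call is possible.
synonymy_call <- function(table, q, genes, gene_id, reference_fetch) {
  cds <- genes$cds[[gene_id]]
  if (is.null(cds) || !nrow(cds)) return(NA_character_)
  gdf <- genes$genes
  strand <- gdf$strand[gdf$gene_id == gene_id]
  pos <- table$pos[q]; chrom <- table$chrom[q]
  coding_pos <- unlist(lapply(seq_len(nrow(cds)),
                              function(i) cds$start[i]:cds$end[i]))
  coding_pos <- sort(coding_pos)
  if (strand == "-") coding_pos <- rev(coding_pos)
  idx <- match(pos, coding_pos)
  if (is.na(idx)) return(NA_character_)       # in exon but outside CDS
  genome_base <- reference_fetch(chrom, pos, pos)
  if (genome_base != table$ref[q]) {
    warning("reference mismatch at ", chrom, ":", pos, " (VCF REF ",
            table$ref[q], ", reference ", genome_base, ")")
    return(NA_character_)
  }
  codon_i <- ceiling(idx / 3)
  codon_pos <- coding_pos[(3 * (codon_i - 1) + 1):(3 * codon_i)]
  if (anyNA(codon_pos)) return(NA_character_)  # CDS length not multiple of 3
  bases <- vapply(codon_pos, function(p) reference_fetch(chrom, p, p),
                  character(1))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref_allele <- table$ref[q]; alt_allele <- table$alt[q]
  if (strand == "-") {
    bases <- comp[bases]
    ref_allele <- comp[[ref_allele]]; alt_allele <- comp[[alt_allele]]
  }
  offset <- which(codon_pos == pos)
  stopifnot(bases[offset] == ref_allele)
  alt_bases <- bases
  alt_bases[offset] <- alt_allele
  code <- Biostrings::GENETIC_CODE
  aa_ref <- code[[paste(bases, collapse = "")]]
  aa_alt <- code[[paste(alt_bases, collapse = "")]]
  if (aa_ref != "*" && aa_alt == "*") return("exonic:stopgain")
  if (aa_ref == "*" && aa_alt != "*") return("exonic:stoploss")
  if (aa_ref == aa_alt) return("exonic:synonymous")
  "exonic:nonsynonymous"
}
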
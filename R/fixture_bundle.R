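#' Write a variant table as an uncompressed VCF 4.2 file
#'
#' Emits `##fileformat=VCFv4.2`, one `##contig` line per chromosome, GT:DP
#' genotypes with "|"-separated phased alleles (or "/" when unphased), and
#' "./." for missing genotypes. Reading the file back with [read_vcf()]
#' reproduces the genotype and haplotype matrices exactly.
#'
#' @param table a [variant_table()].
#' @param path output file path.
#' @param chrom_lengths named vector of contig lengths; defaults to the
#'   maximum observed position per chromosome.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(table, path, chrom_lengths = table_chrom_lengths(table)) {
  sep <- if (table$phased) "|" else "/"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=woolscan",
               sprintf("##contig=<ID=%s,length=%d>",
                       names(chrom_lengths), as.integer(chrom_lengths)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", table$samples), collapse = "\t")),
             con)
  n_dip <- length(table$samples)
  m <- n_sites(table)
  if (table$phased) {
    h1 <- table$hap[seq(1, 2 * n_dip, 2), , drop = FALSE]
    h2 <- table$hap[seq(2, 2 * n_dip, 2), , drop = FALSE]
    gt_str <- matrix(paste0(h1, sep, h2), n_dip, m)
    gt_str[is.na(h1) | is.na(h2)] <- "./."
  } else {
    codes <- c("0/0", "0/1", "1/1")
    gt_str <- matrix(codes[table$gt + 1L], n_dip, m)
    gt_str[is.na(table$gt)] <- "./."
  }
  dp_str <- matrix(as.character(table$dp), n_dip, m)
  dp_str[table$dp >= DP_UNKNOWN] <- "."
  cell <- matrix(paste0(gt_str, ":", dp_str), n_dip, m)
  body <- apply(cell, 2, paste, collapse = "\t")
  writeLines(paste(table$chrom, table$pos, ".", table$ref, table$alt,
                   ".", "PASS", ".", "GT:DP", body, sep = "\t"),
             con)
  invisible(path)
}

#' Write a complete fixture bundle for an end-to-end scan
#'
#' Serializes a simulated dataset into the four files the pipeline consumes:
#' `sample.vcf` (phased VCF 4.2 with GT:DP), `popmap.tsv` (columns sample,
#' population, group), `genes.gff3` (genes tiled every 100 kb, 20 kb long,
#' alternating strand, each a gene/mRNA/exon/CDS chain with two 9 kb exons),
#' and `terms.tsv` (columns term_id, term_name, gene_id; each gene carries
#' 1-3 terms from a 20-term pool). Genes overlapping a sweep span (or the
#' spans in `designated_spans`) additionally share the designated term
#' `T01`, so term enrichment of recovered sweep genes can be tested.
#'
#' @param dataset list from [generate_dataset()].
#' @param truth a `sweep_truth` (defaults to `dataset$truth`).
#' @param out_dir output directory, created if needed.
#' @param designated_spans optional data.frame with columns `chrom`, `start`,
#'   `end` marking spans whose genes share the designated term; defaults to
#'   the spans of the sweeps in `truth`.
#' @return list with the four file paths, the designated term id, and the
#'   gene ids that carry it.
#' @export
write_fixture_bundle <- function(dataset, truth = dataset$truth, out_dir,
                                 designated_spans = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  tab <- dataset$table
  chrom_lengths <- fixture_chrom_lengths(dataset)
  vcf <- file.path(out_dir, "sample.vcf")
  write_vcf(tab, vcf, chrom_lengths)
  popmap_path <- file.path(out_dir, "popmap.tsv")
  utils::write.table(dataset$popmap, popmap_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  genes <- gene_tiles(chrom_lengths)
  gff <- file.path(out_dir, "genes.gff3")
  write_gene_tiles_gff3(genes, gff)
  if (is.null(designated_spans) && length(truth)) {
    designated_spans <- do.call(rbind, lapply(truth, function(tr) {
      data.frame(chrom = tr$spec$chrom,
                 start = tr$spec$position - tr$spec$span,
                 end = tr$spec$position + tr$spec$span)
    }))
  }
  terms_path <- file.path(out_dir, "terms.tsv")
  designated <- write_term_fixture(genes, terms_path,
                                   designated_spans = designated_spans,
                                   seed = attr(dataset, "seed") %||% 20260101L)
  list(vcf = vcf, popmap = popmap_path, gff3 = gff, terms = terms_path,
       designated_term = designated$term_id,
       designated_genes = designated$genes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fixture_chrom_lengths <- function(dataset) {
  obs <- table_chrom_lengths(dataset$table)
  # round contig length up to the tiling unit so gene counts are exact
  stats::setNames(pmax(obs, ceiling(obs / 100000) * 100000), names(obs))
}

#' Deterministic gene tiling for fixtures
#'
#' One gene per 100 kb of chromosome: gene i spans
#' `[(i-1)*100000 + 1, (i-1)*100000 + 20000]`, strands alternate +/-, and each
#' gene holds one mRNA with two 9,000 bp exons (intron 2,000 bp) whose CDS
#' equals the exons (total coding length 18,000 bp, divisible by 3).
#'
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @return data.frame with columns gene_id, chrom, start, end, strand.
#' @export
gene_tiles <- function(chrom_lengths) {
  out <- lapply(names(chrom_lengths), function(chr) {
    n <- floor(chrom_lengths[[chr]] / 100000)
    i <- seq_len(n)
    start <- (i - 1L) * 100000L + 1L
    data.frame(gene_id = sprintf("%s_g%03d", chr, i), chrom = chr,
               start = start, end = start + 19999L,
               strand = ifelse(i %% 2 == 1, "+", "-"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

write_gene_tiles_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    e1 <- c(g$start, g$start + 8999L)
    e2 <- c(g$start + 11000L, g$end)
    row <- function(type, s, e, phase, attrs) {
      paste(g$chrom, "woolscan", type, s, e, ".", g$strand, phase, attrs,
            sep = "\t")
    }
    mrna_id <- paste0(g$gene_id, ".t1")
    # CDS phase: translation starts at the 5' end, which is exon 1 on "+"
    # and exon 2 on "-"; both exons are 9000 bp (0 mod 3) so phase is 0.
    writeLines(c(
      row("gene", g$start, g$end, ".", paste0("ID=", g$gene_id)),
      row("mRNA", g$start, g$end, ".",
          paste0("ID=", mrna_id, ";Parent=", g$gene_id)),
      row("exon", e1[1], e1[2], ".",
          paste0("ID=", mrna_id, ".e1;Parent=", mrna_id)),
      row("exon", e2[1], e2[2], ".",
          paste0("ID=", mrna_id, ".e2;Parent=", mrna_id)),
      row("CDS", e1[1], e1[2], "0",
          paste0("ID=", mrna_id, ".c1;Parent=", mrna_id)),
      row("CDS", e2[1], e2[2], "0",
          paste0("ID=", mrna_id, ".c2;Parent=", mrna_id))), con)
  }
  invisible(path)
}

write_term_fixture <- function(genes, path, designated_spans = NULL,
                               seed = 20260101L) {
  pool <- sprintf("T%02d", 1:20)
  pool_names <- c("sweep_response", sprintf("process_%02d", 2:20))
  set.seed(seed)
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    k <- sample(1:3, 1L)
    ids <- sample(pool[-1L], k)
    data.frame(term_id = ids, term_name = pool_names[match(ids, pool)],
               gene_id = genes$gene_id[i], stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  designated_genes <- character(0)
  if (!is.null(designated_spans) && nrow(designated_spans)) {
    for (i in seq_len(nrow(designated_spans))) {
      sp <- designated_spans[i, ]
      hit <- genes$chrom == sp$chrom & genes$start <= sp$end &
        genes$end >= sp$start
      designated_genes <- union(designated_genes, genes$gene_id[hit])
    }
    if (length(designated_genes)) {
      rows <- rbind(rows,
                    data.frame(term_id = pool[1L], term_name = pool_names[1L],
                               gene_id = designated_genes,
                               stringsAsFactors = FALSE))
    }
  }
  rows <- rows[order(rows$term_id, rows$gene_id), ]
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(term_id = pool[1L], genes = sort(designated_genes))
}

#' Deterministic reference-base accessor for a simulated dataset
#'
#' Builds, per chromosome, a random background sequence (seeded from the
#' dataset) and patches the simulated REF allele in at every SNP position, so
#' codon translation in [classify_variants()] sees bases consistent with the
#' VCF. The sequence is synthetic: it carries no homology structure.
#'
#' @param dataset list from [generate_dataset()] (or any object with a
#'   `table` element).
#' @param chrom_lengths named lengths; defaults to fixture tiling lengths.
#' @param seed integer seed for the background bases.
#' @return a function `(chrom, start, end) -> character vector of bases`.
#' @export
reference_fetch_for <- function(dataset, chrom_lengths = NULL,
                                seed = 991L) {
  tab <- dataset$table
  if (is.null(chrom_lengths)) chrom_lengths <- fixture_chrom_lengths(dataset)
  seqs <- list()
  for (chr in names(chrom_lengths)) {
    set.seed(seed + match(chr, names(chrom_lengths)))
    s <- sample(c("A", "C", "G", "T"), chrom_lengths[[chr]], replace = TRUE)
    idx <- which(tab$chrom == chr)
    s[tab$pos[idx]] <- tab$ref[idx]
    seqs[[chr]] <- s
  }
  function(chrom, start, end) {
    if (!chrom %in% names(seqs)) stop("unknown chromosome ", chrom)
    seqs[[chrom]][start:end]
  }
}
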
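#' Configuration for a full selection-signature scan
#'
#' Bundles input paths and all tunables of the composite scan. Defaults are
#' the standard analysis settings: QC at depth >= 3 / missingness < 10% /
#' MAF > 5%, 50 kb non-overlapping windows for pi and Fst, 50 kb windows
#' sliding by 20 kb for XP-EHH, top 5% thresholding, and 50 kb flanks around
#' candidate SNPs.
#'
#' @param vcf,popmap,gff3,terms input file paths (phased VCF 4.2; TSV
#'   sample/population/group; GFF3 gene models; TSV term map).
#' @param out_dir output directory (created; never an input location).
#' @param directions subset of `c("F_vs_C", "C_vs_F")`; the first letter
#'   names the target (experimental) group of the direction.
#' @param min_depth,max_missing,min_maf QC thresholds, see
#'   [apply_qc_filters()].
#' @param window_size,window_step pi/Fst grid (default 50,000 / 50,000).
#' @param xpehh_window,xpehh_step XP-EHH grid (default 50,000 / 20,000).
#' @param top_fraction top-window fraction (default 0.05).
#' @param flank candidate-SNP flank in bp (default 50,000).
#' @param xpehh_cutoff EHH integration cutoff (default 0.05).
#' @param alpha enrichment significance level (default 0.05).
#' @param seed integer seed (set before any stage; the scan itself is
#'   deterministic, the seed guards any future resampling hook).
#' @param make_plots write Manhattan-style PDF plots (default TRUE).
#' @return list of class `scan_config`.
#' @export
scan_config <- function(vcf, popmap, gff3, terms, out_dir,
                        directions = c("F_vs_C", "C_vs_F"),
                        min_depth = 3L, max_missing = 0.10, min_maf = 0.05,
                        window_size = 50000L, window_step = 50000L,
                        xpehh_window = 50000L, xpehh_step = 20000L,
                        top_fraction = 0.05, flank = 50000L,
                        xpehh_cutoff = 0.05, alpha = 0.05, seed = 1L,
                        make_plots = TRUE) {
  if (!all(directions %in% c("F_vs_C", "C_vs_F")) || !length(directions)) {
    stop("directions must be a non-empty subset of F_vs_C, C_vs_F")
  }
  for (v in c(min_depth, max_missing, min_maf, window_size, window_step,
              xpehh_window, xpehh_step, top_fraction, flank, xpehh_cutoff,
              alpha)) {
    if (v < 0) stop("scan thresholds must be non-negative")
  }
  structure(list(vcf = vcf, popmap = popmap, gff3 = gff3, terms = terms,
                 out_dir = out_dir, directions = directions,
                 min_depth = min_depth, max_missing = max_missing,
                 min_maf = min_maf, window_size = window_size,
                 window_step = window_step, xpehh_window = xpehh_window,
                 xpehh_step = xpehh_step, top_fraction = top_fraction,
                 flank = flank, xpehh_cutoff = xpehh_cutoff, alpha = alpha,
                 seed = as.integer(seed), make_plots = isTRUE(make_plots)),
            class = "scan_config")
}

#' Read a sample-to-population map file
#' @param path TSV with columns sample, population, group.
#' @return a [population_map()].
#' @export
read_popmap <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("sample", "population", "group")
  if (!all(need %in% names(df))) {
    stop("population map must have columns ", paste(need, collapse = ", "))
  }
  population_map(df$sample, df$population, df$group)
}

#' Run the full composite selection-signature scan
#'
#' Executes, per requested direction: QC -> windowed pi / theta-pi ratio /
#' Weir-Cockerham Fst -> XP-EHH -> top-fraction selection -> candidate-SNP
#' flanking and merging -> gene annotation -> two-way Venn intersection ->
#' hypergeometric term enrichment. All intermediate tables are written under
#' `config$out_dir` as TSV/BED/JSON, together with a `summary.json` (fully
#' deterministic: identical config and inputs give byte-identical JSON), a
#' `scan.log` with per-stage timings, and diagnostic Manhattan-style plots.
#'
#' @param config a [scan_config()].
#' @return the summary list, invisibly.
#' @export
run_scan <- function(config) {
  stopifnot(inherits(config, "scan_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  log_path <- file.path(config$out_dir, "scan.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  t0 <- proc.time()[["elapsed"]]
  logln <- function(...) {
    writeLines(sprintf("[%8.2fs] %s", proc.time()[["elapsed"]] - t0,
                       paste0(...)), log_con)
  }
  stage <- function(name, expr) {
    t1 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      logln("stage ", name, " FAILED: ", conditionMessage(e))
      stop("scan stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    logln("stage ", name, " done in ",
          sprintf("%.2fs", proc.time()[["elapsed"]] - t1))
    res
  }
  logln("woolscan ", as.character(utils::packageVersion("woolscan")),
        " on R ", getRversion())
  logln("config: ", jsonlite::toJSON(unclass(config), auto_unbox = TRUE))

  inputs <- stage("read_inputs", {
    tab <- read_vcf(config$vcf)
    pm <- read_popmap(config$popmap)
    if (!setequal(tab$samples, pm$sample)) {
      stop("VCF samples and population map disagree")
    }
    list(table = tab, popmap = pm, genes = read_gff3(config$gff3),
         terms = read_term_map(config$terms),
         chrom_lengths = attr(tab, "chrom_lengths") %||%
           table_chrom_lengths(tab))
  })
  tab0 <- inputs$table
  tab <- stage("qc", apply_qc_filters(tab0, config$min_depth,
                                      config$max_missing, config$min_maf))
  qc <- attr(tab, "qc_counts")
  cl <- inputs$chrom_lengths
  win_pi <- make_windows(cl, config$window_size, config$window_step)
  win_xp <- make_windows(cl, config$xpehh_window, config$xpehh_step)

  iF <- group_samples(inputs$popmap, tab, "F")
  iC <- group_samples(inputs$popmap, tab, "C")
  shared <- stage("diversity_fst", {
    pi_F <- windowed_pi(tab, iF, win_pi)
    pi_C <- windowed_pi(tab, iC, win_pi)
    fst <- windowed_fst(tab, inputs$popmap, win_pi)
    wtsv <- merge(merge(stats::setNames(pi_F, c("chrom", "start", "end",
                                                "n_snps", "pi_F")),
                        stats::setNames(pi_C[, -4], c("chrom", "start", "end",
                                                      "pi_C"))),
                  stats::setNames(fst[, -4], c("chrom", "start", "end",
                                               "fst")),
                  all.x = TRUE)
    wtsv <- wtsv[order(wtsv$chrom, wtsv$start), ]
    utils::write.table(wtsv, file.path(config$out_dir, "windows_fst_pi.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(pi_F = pi_F, pi_C = pi_C, fst = fst)
  })

  all_genes <- inputs$genes$genes$gene_id
  summary <- list(
    config = unclass(config),
    n_samples = length(tab0$samples),
    snps_loaded = n_sites(tab0),
    snps_skipped = attr(tab0, "n_skipped"),
    snps_after_qc = n_sites(tab),
    qc_counts = qc,
    n_windows_fst_grid = nrow(win_pi),
    n_windows_xpehh_grid = nrow(win_xp),
    directions = list())

  for (dir_name in config$directions) {
    target <- substr(dir_name, 1, 1)
    pi_target <- if (target == "F") shared$pi_F else shared$pi_C
    pi_contrast <- if (target == "F") shared$pi_C else shared$pi_F
    ratio <- theta_pi_ratio(pi_target, pi_contrast)
    utils::write.table(ratio,
                       file.path(config$out_dir,
                                 paste0("windows_ratio_", dir_name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    joint <- stage(paste0("fst_pi_candidates_", dir_name),
                   joint_fst_pi_candidates(shared$fst, ratio, tab,
                                           config$top_fraction))
    reg_fp <- flank_and_merge(joint$snps, config$flank, cl)
    write_regions_bed(reg_fp, file.path(config$out_dir,
                                        paste0("regions_fst_pi_", dir_name,
                                               ".bed")))
    set_fp <- genes_in_regions(reg_fp, inputs$genes, "fst_pi")

    scores <- stage(paste0("xpehh_", dir_name),
                    xpehh_scan(tab, inputs$popmap, target,
                               config$xpehh_cutoff))
    utils::write.table(scores,
                       file.path(config$out_dir,
                                 paste0("xpehh_scores_", dir_name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    xw <- windowed_xpehh(scores, win_xp)
    top_xw <- select_top_windows(xw, config$top_fraction)
    snps_xp <- snps_in_windows(scores[, c("chrom", "pos")], top_xw)
    reg_xp <- flank_and_merge(snps_xp, config$flank, cl)
    write_regions_bed(reg_xp, file.path(config$out_dir,
                                        paste0("regions_xpehh_", dir_name,
                                               ".bed")))
    set_xp <- genes_in_regions(reg_xp, inputs$genes, "xpehh")

    venn <- venn_overlap(set_fp, set_xp)
    writeLines(set_fp$genes, file.path(config$out_dir,
                                       paste0("genes_fst_pi_", dir_name,
                                              ".txt")))
    writeLines(set_xp$genes, file.path(config$out_dir,
                                       paste0("genes_xpehh_", dir_name,
                                              ".txt")))
    writeLines(venn$intersection$genes,
               file.path(config$out_dir,
                         paste0("genes_final_", dir_name, ".txt")))
    jsonlite::write_json(list(a_only = venn$a_only, b_only = venn$b_only,
                              both = venn$both,
                              intersection = venn$intersection$genes),
                         file.path(config$out_dir,
                                   paste0("venn_", dir_name, ".json")),
                         auto_unbox = TRUE, pretty = TRUE)

    enr <- NULL
    if (length(venn$intersection$genes)) {
      enr <- tryCatch(enrich_genes(venn$intersection, all_genes,
                                   inputs$terms, config$alpha),
                      error = function(e) NULL)
    }
    if (!is.null(enr)) {
      utils::write.table(enr,
                         file.path(config$out_dir,
                                   paste0("enrichment_", dir_name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (config$make_plots) {
      plot_manhattan(shared$fst, file.path(config$out_dir,
                                           "manhattan_fst.pdf"),
                     ylab = "windowed Fst")
      plot_manhattan(xw, file.path(config$out_dir,
                                   paste0("manhattan_xpehh_", dir_name,
                                          ".pdf")),
                     ylab = "mean XP-EHH z")
    }
    summary$directions[[dir_name]] <- list(
      target_group = target,
      windows_ranked_fst = sum(!is.na(shared$fst$value)),
      windows_selected_fst = nrow(select_top_windows(shared$fst,
                                                     config$top_fraction)),
      windows_ranked_ratio = sum(!is.na(ratio$value)),
      windows_selected_ratio = nrow(select_top_windows(ratio,
                                                       config$top_fraction)),
      joint_windows = nrow(joint$windows),
      candidate_snps_fst_pi = nrow(joint$snps),
      snps_scored_xpehh = nrow(scores),
      windows_selected_xpehh = nrow(top_xw),
      candidate_snps_xpehh = nrow(snps_xp),
      genes_fst_pi = length(set_fp$genes),
      genes_xpehh = length(set_xp$genes),
      venn = list(a_only = venn$a_only, b_only = venn$b_only,
                  both = venn$both),
      final_genes = venn$intersection$genes,
      top_terms = if (!is.null(enr)) {
        utils::head(enr[, c("term_id", "k", "K", "p", "significant")], 5)
      } else NULL)
  }

  jsonlite::write_json(summary,
                       file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10,
                       null = "null")
  logln("scan complete")
  invisible(summary)
}

plot_manhattan <- function(windows, path, ylab) {
  df <- windows[!is.na(windows$value) & is.finite(windows$value), ]
  df$mid_mb <- (df$start + df$end) / 2 / 1e6
  p <- ggplot2::ggplot(df, ggplot2::aes(x = mid_mb, y = value,
                                        colour = chrom)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~chrom, nrow = 1, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = ylab) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
  suppressMessages(ggplot2::ggsave(path, p, width = 8, height = 3,
                                   device = "pdf"))
  invisible(path)
}
utils::globalVariables(c("mid_mb", "value", "chrom"))
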
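#' Extended haplotype homozygosity decay curve around a core SNP
#'
#' At extension k, haplotypes are grouped by their alleles over the sites
#' from the core out to k (core included); EHH is the probability that two
#' distinct haplotypes drawn from the group are identical over that span:
#' `sum(C(n_h, 2)) / C(n, 2)` over the distinct extended haplotypes h. The
#' value at offset 0 is 1 by definition. EHH is computed over all group
#' haplotypes, unconditional on the core allele - the two-population form
#' that XP-EHH contrasts between groups.
#'
#' Haplotypes missing at the core are dropped before the scan; a haplotype
#' that hits a missing call during extension stops counting as homozygous
#' with any other from that point on (the pair denominator stays fixed, so
#' the curve is non-increasing by construction).
#'
#' @param haplotypes 0/1 matrix (haplotypes x sites) for one group, one
#'   chromosome.
#' @param positions site positions in bp (ascending).
#' @param core core site index (column).
#' @param direction "both" (default), "left" or "right".
#' @return list of class `ehh_curve`: `core`, `offsets` (bp, ascending,
#'   0 at the core, negative left), `ehh`, `n_haplotypes`.
#' @export
ehh_curve <- function(haplotypes, positions, core,
                      direction = c("both", "left", "right")) {
  direction <- match.arg(direction)
  ok <- !is.na(haplotypes[, core])
  if (sum(ok) < 2) stop("fewer than 2 haplotypes defined at the core")
  h <- haplotypes[ok, , drop = FALSE]
  res_l <- res_r <- NULL
  if (direction %in% c("both", "left")) {
    res_l <- ehh_decay(h, positions, core, -1L, cutoff = NULL)
  }
  if (direction %in% c("both", "right")) {
    res_r <- ehh_decay(h, positions, core, +1L, cutoff = NULL)
  }
  offsets <- c(if (!is.null(res_l)) rev(positions[res_l$idx] - positions[core]),
               0,
               if (!is.null(res_r)) positions[res_r$idx] - positions[core])
  ehh <- c(if (!is.null(res_l)) rev(res_l$ehh), 1,
           if (!is.null(res_r)) res_r$ehh)
  structure(list(core = core, offsets = offsets, ehh = ehh,
                 n_haplotypes = nrow(h)),
            class = "ehh_curve")
}

# Walk outward from the core, tracking extended-haplotype classes.
# Returns site indices visited and EHH after each extension. With a cutoff,
# stops after the first site whose EHH drops below it (that site is still
# returned, so the crossing trapezoid can be integrated).
ehh_decay <- function(h, positions, core, step, cutoff = NULL) {
  n <- nrow(h)
  denom <- n * (n - 1) / 2
  m <- ncol(h)
  id <- h[, core] + 1L
  id[is.na(id)] <- 0L          # retired from the start (shouldn't happen)
  alive <- !is.na(h[, core])
  idx <- integer(0); ehh <- numeric(0)
  j <- core + step
  while (j >= 1 && j <= m) {
    v <- h[, j]
    newly_na <- alive & is.na(v)
    alive[newly_na] <- FALSE
    z <- id
    z[alive] <- id[alive] * 3L + v[alive]
    u <- z[alive]
    id[alive] <- match(u, unique(u))
    cnt <- tabulate(id[alive])
    e <- sum(cnt * (cnt - 1) / 2) / denom
    idx <- c(idx, j); ehh <- c(ehh, e)
    if (!is.null(cutoff) && e < cutoff) break
    if (e == 0) break          # nothing left to lose; curve stays at 0
    j <- j + step
  }
  list(idx = idx, ehh = ehh)
}

#' Integrate an EHH curve to iHH
#'
#' Trapezoidal integration of EHH against physical distance, summed over the
#' two directions. In each direction, segments accumulate while the proximal
#' endpoint's EHH is at least `cutoff`; the first segment crossing below the
#' cutoff is included, then integration stops. If the chromosome end is
#' reached while EHH is still at or above the cutoff, the integral runs to
#' the last site and the `edge` flag is set.
#'
#' @param curve an [ehh_curve()].
#' @param cutoff EHH decay cutoff (default 0.05).
#' @return list with `ihh` (bp units) and `edge` (logical).
#' @export
integrated_ehh <- function(curve, cutoff = 0.05) {
  zero_at <- which(curve$offsets == 0)
  total <- 0; edge <- FALSE
  for (side in c("left", "right")) {
    ord <- if (side == "left") {
      c(zero_at, rev(which(curve$offsets < 0)))
    } else {
      c(zero_at, which(curve$offsets > 0))
    }
    if (length(ord) < 2) next
    off <- abs(curve$offsets[ord]); e <- curve$ehh[ord]
    for (s in seq_len(length(ord) - 1)) {
      if (e[s] < cutoff) break
      total <- total + (e[s] + e[s + 1]) / 2 * (off[s + 1] - off[s])
      if (e[s + 1] < cutoff) break
      if (s == length(ord) - 1 && e[s + 1] >= cutoff) edge <- TRUE
    }
  }
  list(ihh = total, edge = edge)
}

# iHH for one core directly (bounded walk; no curve object). Returns the
# two-sided integral and edge flag.
ihh_core <- function(h, positions, core, cutoff) {
  ok <- !is.na(h[, core])
  if (sum(ok) < 2) return(NULL)
  hh <- h[ok, , drop = FALSE]
  total <- 0; edge <- FALSE
  for (step in c(-1L, 1L)) {
    dec <- ehh_decay(hh, positions, core, step, cutoff = cutoff)
    e_prev <- 1; p_prev <- positions[core]
    ks <- seq_along(dec$idx)
    for (k in ks) {
      p_k <- positions[dec$idx[k]]; e_k <- dec$ehh[k]
      if (e_prev < cutoff) break
      total <- total + (e_prev + e_k) / 2 * abs(p_k - p_prev)
      e_prev <- e_k; p_prev <- p_k
      if (e_k < cutoff) break
    }
    hit_end <- length(dec$idx) &&
      (dec$idx[length(dec$idx)] == if (step < 0) 1L else ncol(hh))
    if (hit_end && dec$ehh[length(dec$ehh)] >= cutoff) edge <- TRUE
  }
  list(ihh = total, edge = edge)
}

#' Cross-population XP-EHH scan
#'
#' For every core SNP, integrates the unconditional EHH curve to iHH in the
#' target and reference groups and scores `raw = ln(iHH_target / iHH_ref)`.
#' Cores where either group has fewer than two defined haplotypes or a zero
#' iHH are skipped. Raw scores are standardized genome-wide:
#' `z = (raw - mean) / sd` with the population (denominator n) standard
#' deviation over all scored SNPs. Positive z means long haplotypes - a
#' sweep signal - in the target group.
#'
#' @param table a phased, QC-filtered [variant_table()].
#' @param popmap a [population_map()].
#' @param target_group "F" or "C" (the experimental population).
#' @param cutoff EHH decay cutoff for the integration (default 0.05).
#' @return data.frame of class `xpehh_scores`: chrom, pos, raw, z,
#'   ihh_target, ihh_ref, edge_flag.
#' @export
xpehh_scan <- function(table, popmap, target_group = "F", cutoff = 0.05) {
  if (!table$phased || is.null(table$hap)) {
    stop("XP-EHH needs phased haplotypes: phase the input VCF first")
  }
  ref_group <- setdiff(c("F", "C"), target_group)
  rows_t <- hap_rows(group_samples(popmap, table, target_group))
  rows_r <- hap_rows(group_samples(popmap, table, ref_group))
  if (length(rows_t) < 2 || length(rows_r) < 2) {
    stop("both groups need >= 2 haplotypes")
  }
  out <- vector("list", length(unique(table$chrom)))
  names(out) <- unique(table$chrom)
  for (chr in unique(table$chrom)) {
    si <- which(table$chrom == chr)
    pos <- table$pos[si]
    ht <- table$hap[rows_t, si, drop = FALSE]
    hr <- table$hap[rows_r, si, drop = FALSE]
    m <- length(si)
    raw <- rep(NA_real_, m); it <- rep(NA_real_, m); ir <- rep(NA_real_, m)
    edge <- rep(FALSE, m)
    for (k in seq_len(m)) {
      rt <- ihh_core(ht, pos, k, cutoff)
      if (is.null(rt) || rt$ihh <= 0) next
      rr <- ihh_core(hr, pos, k, cutoff)
      if (is.null(rr) || rr$ihh <= 0) next
      raw[k] <- log(rt$ihh / rr$ihh)
      it[k] <- rt$ihh; ir[k] <- rr$ihh
      edge[k] <- rt$edge || rr$edge
    }
    out[[chr]] <- data.frame(chrom = chr, pos = pos, raw = raw,
                             ihh_target = it, ihh_ref = ir,
                             edge_flag = edge, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[!is.na(res$raw), , drop = FALSE]
  rownames(res) <- NULL
  mu <- mean(res$raw)
  sd_pop <- sqrt(mean((res$raw - mu)^2))
  res$z <- if (sd_pop > 0) (res$raw - mu) / sd_pop else 0
  res <- res[, c("chrom", "pos", "raw", "z", "ihh_target", "ihh_ref",
                 "edge_flag")]
  class(res) <- c("xpehh_scores", "data.frame")
  res
}

#' Sliding-window mean XP-EHH z score
#'
#' Arithmetic mean of z over the scored SNPs inside each window; a SNP
#' contributes to every window covering it. Windows without scored SNPs are
#' omitted.
#'
#' @param scores an `xpehh_scores` data.frame from [xpehh_scan()].
#' @param windows sliding grid from [make_windows()] (50 kb / 20 kb step in
#'   the standard scan).
#' @return data.frame: chrom, start, end, n_snps, value (mean z).
#' @export
windowed_xpehh <- function(scores, windows) {
  out <- windows[, c("chrom", "start", "end")]
  out$n_snps <- 0L
  out$value <- NA_real_
  for (chr in unique(windows$chrom)) {
    wi <- which(windows$chrom == chr)
    sc <- scores[scores$chrom == chr, ]
    if (!nrow(sc)) next
    for (k in wi) {
      inw <- sc$pos >= windows$start[k] & sc$pos <= windows$end[k]
      if (!any(inw)) next
      out$n_snps[k] <- sum(inw)
      out$value[k] <- mean(sc$z[inw])
    }
  }
  out[!is.na(out$value), , drop = FALSE]
}
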
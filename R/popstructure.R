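#' Allele-sharing (1 - IBS) distance matrix
#'
#' For each sample pair, IBS is the mean over sites non-missing in both of
#' `(2 - |g_i - g_j|) / 2`; the distance is `1 - IBS`. Used as input to the
#' neighbor-joining tree.
#'
#' @param table a [variant_table()].
#' @return symmetric matrix in \[0, 1\] with zero diagonal, sample ids as
#'   dimnames.
#' @export
allele_sharing_distance <- function(table) {
  g <- table$gt
  n <- nrow(g)
  if (n < 2 || n_sites(table) < 1) stop("need >= 2 samples and >= 1 site")
  d <- matrix(0, n, n, dimnames = list(table$samples, table$samples))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(g[i, ]) & !is.na(g[j, ])
      if (!any(ok)) {
        stop("samples ", table$samples[i], " and ", table$samples[j],
             " share no co-typed sites")
      }
      ibs <- mean((2 - abs(g[i, ok] - g[j, ok])) / 2)
      d[i, j] <- d[j, i] <- 1 - ibs
    }
  }
  d
}

#' Principal component analysis of the genotype matrix
#'
#' Columns are standardized the way population-genetic PCA expects: centered
#' at `2 * p_hat` and scaled by `sqrt(2 * p_hat * (1 - p_hat))`, where
#' `p_hat` is the alt-allele frequency over non-missing genotypes. Missing
#' entries become 0 after centering (mean imputation). Monomorphic sites and
#' sites with no called genotypes are excluded. Eigendecomposition is of the
#' sample covariance of the standardized matrix; variance fractions are
#' eigenvalues over their trace.
#'
#' @param table a [variant_table()] (LD-prune first if desired; no thinning
#'   happens here).
#' @param n_components number of components to keep (default all).
#' @return list of class `pca_result`: `coords` (samples x components),
#'   `varfrac` (per-component variance fractions), `n_sites_used`.
#' @export
pca_genotypes <- function(table, n_components = NULL) {
  g <- table$gt
  n <- nrow(g)
  if (n < 2) stop("need >= 2 samples")
  n_called <- colSums(!is.na(g))
  p <- colSums(g, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  poly <- n_called > 0 & p > 0 & p < 1
  if (sum(poly) < 2) stop("fewer than 2 polymorphic sites")
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  x <- sweep(g, 2, 2 * p, "-")
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  x[is.na(x)] <- 0
  cv <- tcrossprod(x) / ncol(x)
  e <- eigen(cv, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  k <- if (is.null(n_components)) length(ev) else min(n_components, length(ev))
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k, k)
  rownames(coords) <- table$samples
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(list(coords = coords,
                 varfrac = ev[seq_len(k)] / sum(ev),
                 n_sites_used = ncol(x)),
            class = "pca_result")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration with the Studier-Keppler Q-criterion.
#' Additive distance matrices are recovered exactly (topology and branch
#' lengths). Ties in Q are broken by the lexicographically lowest index pair,
#' so results are deterministic. Negative branch lengths are clamped to zero
#' with the deficit transferred to the sibling branch. The tree is assembled
#' as a newick string during agglomeration and returned as an unrooted
#' `phylo` object.
#'
#' @param d symmetric distance matrix with >= 3 labelled taxa.
#' @return an [ape::read.tree] `phylo` object with edge lengths.
#' @export
neighbor_joining <- function(d) {
  D <- unname(as.matrix(d))
  if (!isSymmetric(D)) stop("distance matrix must be symmetric")
  n0 <- nrow(D)
  if (n0 < 3) stop("need >= 3 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n0))
  cl <- labels   # newick substring per active cluster

  fmt <- function(x) sprintf("%.12g", x)
  while (nrow(D) > 3) {
    m <- nrow(D)
    rs <- rowSums(D)
    Q <- (m - 2) * D - outer(rs, rs, "+")
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[[1]]; j <- best[[2]]
    li <- D[i, j] / 2 + (rs[i] - rs[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_cl <- paste0("(", cl[i], ":", fmt(li), ",", cl[j], ":", fmt(lj), ")")
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    cl <- c(cl[keep], new_cl)
  }
  # final trifurcation via the three-point formulas
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  ls <- c(l1, l2, l3)
  for (k in which(ls < 0)) {         # clamp, deficit to the first sibling
    sib <- setdiff(seq_len(3), k)[1]
    ls[sib] <- ls[sib] + ls[k]
    ls[k] <- 0
  }
  nwk <- paste0("(", cl[1], ":", fmt(ls[1]), ",", cl[2], ":", fmt(ls[2]),
                ",", cl[3], ":", fmt(ls[3]), ");")
  ape::read.tree(text = nwk)
}

#' Serialize a tree to a newick file
#'
#' Branch lengths are written with six decimal digits.
#' @param tree a `phylo` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}
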
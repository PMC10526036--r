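#' Upper-tail hypergeometric probability
#'
#' The probability of drawing at least `k` marked genes when `n` genes are
#' drawn without replacement from a background of `N` genes of which `K` are
#' marked:
#' `p = sum_{i = k..min(K, n)} C(K, i) C(N - K, n - i) / C(N, n)`.
#' The sum is accumulated in log space (log-binomials combined by
#' log-sum-exp) for numerical stability; `k = 0` returns exactly 1.
#'
#' @param k observed marked genes in the draw.
#' @param K marked genes in the background.
#' @param n draw (candidate set) size.
#' @param N background size.
#' @return the upper-tail probability in (0, 1].
#' @export
hypergeometric_p <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > K || K > N || n > N || k > n) {
    stop("hypergeometric bounds violated: need 0 <= k <= min(K, n), ",
         "K <= N, n <= N")
  }
  if (k == 0) return(1)
  i <- k:min(K, n)
  lg <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  mx <- max(lg)
  min(1, exp(mx + log(sum(exp(lg - mx)))))
}

#' Read a gene-to-term map
#'
#' @param path TSV with columns term_id, term_name, gene_id.
#' @return data.frame with those columns.
#' @export
read_term_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  need <- c("term_id", "term_name", "gene_id")
  if (!all(need %in% names(df))) {
    stop("term map must have columns ", paste(need, collapse = ", "))
  }
  unique(df[, need])
}

#' Hypergeometric term enrichment of a candidate gene set
#'
#' The background is restricted to genes carrying at least one term in the
#' map (intersected with `background`), and the candidate set to its members
#' inside that background. Each term with `K >= 1` background genes is tested
#' one-sided for over-representation; terms are flagged significant at raw
#' `p < alpha` (the headline rule), with Benjamini-Hochberg q-values
#' additionally reported. Results are sorted by (p, term_id).
#'
#' @param candidates a `gene_set` or character vector of candidate gene ids.
#' @param background a `gene_set` or character vector of background gene ids.
#' @param term_map data.frame from [read_term_map()].
#' @param alpha significance level on the raw p (default 0.05).
#' @return data.frame: term_id, term_name, k, K, n, N, p, q, significant.
#' @export
enrich_genes <- function(candidates, background, term_map, alpha = 0.05) {
  cand <- if (inherits(candidates, "gene_set")) candidates$genes else unique(candidates)
  bg <- if (inherits(background, "gene_set")) background$genes else unique(background)
  mapped <- unique(term_map$gene_id)
  bg <- intersect(bg, mapped)
  cand <- intersect(cand, bg)
  if (!length(cand)) {
    stop("candidate set is empty after intersecting with the term-mapped ",
         "background")
  }
  N <- length(bg); n <- length(cand)
  tm <- term_map[term_map$gene_id %in% bg, ]
  terms <- unique(tm[, c("term_id", "term_name")])
  terms <- terms[order(terms$term_id), ]
  res <- lapply(seq_len(nrow(terms)), function(i) {
    genes_t <- unique(tm$gene_id[tm$term_id == terms$term_id[i]])
    K <- length(genes_t)
    k <- length(intersect(genes_t, cand))
    data.frame(term_id = terms$term_id[i], term_name = terms$term_name[i],
               k = k, K = K, n = n, N = N,
               p = hypergeometric_p(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$p < alpha
  res <- res[order(res$p, res$term_id), ]
  rownames(res) <- NULL
  res
}
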
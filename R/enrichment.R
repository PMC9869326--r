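#' Hypergeometric overlap (Fisher) test
#'
#' Upper-tail hypergeometric probability of drawing at least k genes of a
#' K-gene set in a sample of n from a background of N, plus the 2x2-table
#' odds ratio (Haldane 0.5 correction when any cell is zero).
#'
#' @param k observed overlap.
#' @param K gene-set size within the background.
#' @param n query size.
#' @param N background size.
#' @return list(pvalue, odds_ratio).
#' @export
hypergeom_overlap_test <- function(k, K, n, N) {
  cells <- c(k, n - k, K - k, N - n - K + k)
  if (any(cells < 0) || k > min(K, n) || min(K, n) > N)
    stop("inconsistent 2x2 table: k=", k, " K=", K, " n=", n, " N=", N)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  list(pvalue = p, odds_ratio = or)
}

#' Ranked (ordered) hypergeometric enrichment of one gene set
#'
#' Scans every prefix of a ranked query list, computing the hypergeometric
#' upper-tail p-value of the prefix's overlap with the term, and reports
#' the minimum over depths (smallest depth on ties) together with the
#' overlapping genes at that depth. Genes outside the background are
#' ignored on both sides.
#'
#' @param query character vector of genes, most significant first.
#' @param term character vector, the gene set.
#' @param background character vector, the statistical background.
#' @return list(pvalue, best_rank_depth, overlap_genes, odds_ratio).
#' @export
ranked_hypergeometric <- function(query, term, background) {
  background <- unique(as.character(background))
  query <- query[query %in% background]
  query <- query[!duplicated(query)]
  term <- unique(term[term %in% background])
  N <- length(background); K <- length(term)
  if (!length(query) || K == 0L)
    return(list(pvalue = 1, best_rank_depth = 0L,
                overlap_genes = character(0), odds_ratio = NA_real_))
  hits <- query %in% term
  k_at_d <- cumsum(hits)
  d_all <- seq_along(query)
  p_all <- stats::phyper(k_at_d - 1, K, N - K, d_all, lower.tail = FALSE)
  best <- which.min(p_all)  # which.min takes the first (smallest depth) on ties
  ov <- query[seq_len(best)][hits[seq_len(best)]]
  or <- hypergeom_overlap_test(k_at_d[best], K, best, N)$odds_ratio
  list(pvalue = p_all[best], best_rank_depth = best,
       overlap_genes = ov, odds_ratio = or)
}

#' Empirical Brown fusion of dependent p-values
#'
#' Combines the p-value channels of each item the way Fisher's method
#' would, but calibrates the chi-square null using the empirical
#' covariance of the transformed channels, so dependence between channels
#' does not inflate significance. Each channel is transformed as
#' w = -2 ln(ECDF(p)) with a right-continuous ECDF whose minimum value is
#' 1/n; the fused statistic sum_c w_c is referred to a scaled chi-square
#' with moments matched to E = 2m and the empirical variance. A single
#' channel is returned unchanged.
#'
#' @param P numeric matrix (items x channels) of p-values in (0, 1].
#' @return Numeric vector of fused p-values, one per item.
#' @export
empirical_brown_fuse <- function(P) {
  P <- as.matrix(P)
  m <- ncol(P)
  if (m == 0L) stop("need at least one channel")
  if (any(is.na(P)) || any(P <= 0) || any(P > 1))
    stop("p-values must lie in (0, 1]")
  if (m == 1L) return(as.numeric(P[, 1]))
  W <- apply(P, 2, function(p) {
    e <- stats::ecdf(p)(p)   # right-continuous; min value is 1/n
    -2 * log(e)
  })
  X <- rowSums(W)
  E <- 2 * m
  V <- sum(stats::cov(W))
  if (V <= 0) return(rep(1, nrow(P)))
  f <- 2 * E^2 / V
  scale <- V / (2 * E)
  stats::pchisq(X / scale, df = f, lower.tail = FALSE)
}

#' Enrich a ranked gene list against a gene-set database
#'
#' Runs the ranked hypergeometric test for every set in the database; when
#' the query carries several p-value channels, each channel's ranking is
#' tested separately and the per-term p-values are fused with
#' \code{\link{empirical_brown_fuse}} before BH correction across terms.
#'
#' @param query either a character vector of genes ranked most significant
#'   first, or a data.frame with a \code{gene} column plus one or more
#'   numeric p-value columns (one ranking per column, ascending p, ties
#'   broken by gene id).
#' @param db a \code{gene_set_db}, already size-filtered.
#' @param background character vector of background genes.
#' @param alpha significance threshold recorded in the \code{significant}
#'   column.
#' @return data.frame(term_id, pvalue, fdr, best_rank_depth, n_overlap,
#'   overlap_genes, significant), sorted by fdr then pvalue.
#' @export
enrich_list_against_db <- function(query, db, background, alpha = 0.05) {
  stopifnot(inherits(db, "gene_set_db"))
  empty <- data.frame(term_id = character(0), pvalue = numeric(0),
                      fdr = numeric(0), best_rank_depth = integer(0),
                      n_overlap = integer(0), overlap_genes = I(list()),
                      significant = logical(0))
  if (!length(db$sets)) return(empty)
  rankings <- query_rankings(query)
  if (!length(rankings[[1]])) return(empty)
  per_channel <- lapply(rankings, function(rk) {
    lapply(db$sets, function(term) ranked_hypergeometric(rk, term, background))
  })
  pmat <- vapply(per_channel,
                 function(ch) vapply(ch, `[[`, numeric(1), "pvalue"),
                 numeric(length(db$sets)))
  pmat <- matrix(pmat, nrow = length(db$sets))
  pmat[pmat <= 0] <- .Machine$double.xmin
  fused <- empirical_brown_fuse(pmat)
  # report depth/overlap from the channel attaining the smallest raw p
  best_ch <- apply(pmat, 1, which.min)
  hits <- lapply(seq_along(db$sets), function(i) per_channel[[best_ch[i]]][[i]])
  out <- data.frame(
    term_id = names(db$sets),
    pvalue = fused,
    fdr = bh_fdr(fused),
    best_rank_depth = vapply(hits, `[[`, integer(1), "best_rank_depth"),
    n_overlap = vapply(hits, function(h) length(h$overlap_genes), integer(1)),
    stringsAsFactors = FALSE
  )
  out$overlap_genes <- I(lapply(hits, `[[`, "overlap_genes"))
  out$significant <- out$fdr < alpha
  out[order(out$fdr, out$pvalue, out$term_id), , drop = FALSE]
}

# Normalize the two accepted query forms into a list of rankings
# (one character vector per p-value channel).
query_rankings <- function(query) {
  if (is.character(query)) return(list(query[!duplicated(query)]))
  stopifnot(is.data.frame(query), "gene" %in% names(query))
  pcols <- setdiff(names(query), "gene")
  pcols <- pcols[vapply(query[pcols], is.numeric, logical(1))]
  if (!length(pcols)) return(list(unique(as.character(query$gene))))
  lapply(pcols, function(col) {
    ord <- order(query[[col]], query$gene)
    unique(as.character(query$gene[ord]))
  })
}
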
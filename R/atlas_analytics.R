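#' Pairwise comparison correlation matrix
#'
#' For each pair of comparisons, the gene universe is the genes DE in at
#' least one of the two and detected in both; the squared Pearson
#' correlation of their FDR vectors over that universe is stored.
#' Entries are missing when fewer than three co-usable genes exist or a
#' vector is constant. The signed correlation is retained alongside for
#' clustering on |r|.
#'
#' @param comp a \code{compendium} with >= 2 comparisons.
#' @return list of class \code{comparison_corr}: \code{r2} and \code{r}
#'   (symmetric matrices, diagonal 1).
#' @export
pairwise_comparison_correlation <- function(comp) {
  stopifnot(inherits(comp, "compendium"))
  ids <- names(comp$comparisons)
  n <- length(ids)
  if (n < 2L) stop("need at least 2 comparisons")
  fdr_list <- lapply(comp$comparisons, function(rec)
    stats::setNames(rec$deg_table$fdr, rec$deg_table$gene))
  de_list <- lapply(comp$comparisons, function(rec)
    rec$deg_table$gene[rec$deg_table$is_de %in% TRUE])
  det_list <- lapply(comp$comparisons, `[[`, "detected_genes")
  r <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(r) <- 1
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      genes <- intersect(union(de_list[[i]], de_list[[j]]),
                         intersect(det_list[[i]], det_list[[j]]))
      if (length(genes) < 3L) next
      x <- fdr_list[[i]][genes]; y <- fdr_list[[j]][genes]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
      r[i, j] <- r[j, i] <- stats::cor(x[ok], y[ok])
    }
  }
  structure(list(r2 = r^2, r = r), class = "comparison_corr")
}

#' Cluster comparisons by their DE-profile correlation
#'
#' Ward.D2 agglomeration on the Euclidean distances between rows of the
#' absolute correlation matrix, cut either at a height or into a fixed
#' number of clusters. Missing entries are imputed as 0 similarity before
#' the distance computation. Labels are renumbered 1..K in order of first
#' appearance so the labelling is invariant to dendrogram internals.
#'
#' @param M a \code{comparison_corr} (or a square similarity matrix).
#' @param height dendrogram cut height (default 30).
#' @param n_clusters alternative cut by cluster count (overrides height).
#' @param use square the correlations (\code{"r2"}) instead of |r|.
#' @return Integer cluster labels named by comparison id.
#' @export
cluster_comparisons <- function(M, height = 30, n_clusters = NULL,
                                use = c("abs_r", "r2")) {
  use <- match.arg(use)
  sim <- if (inherits(M, "comparison_corr")) {
    if (use == "abs_r") abs(M$r) else M$r2
  } else as.matrix(M)
  sim[is.na(sim)] <- 0
  n <- nrow(sim)
  if (n < 2L) return(stats::setNames(rep(1L, n), rownames(sim)))
  hc <- stats::hclust(stats::dist(sim), method = "ward.D2")
  labels <- if (!is.null(n_clusters)) {
    stats::cutree(hc, k = min(n_clusters, n))
  } else if (height <= 0) {
    seq_len(n)
  } else {
    stats::cutree(hc, h = height)
  }
  # renumber in order of first appearance
  stats::setNames(as.integer(factor(labels, levels = unique(labels))),
                  rownames(sim))
}

#' Median within-cluster DEG overlap
#'
#' For every ordered pair (i, j) of distinct comparisons within a
#' cluster, the fraction |DEG_i intersect DEG_j| / |DEG_i|; the per-cluster
#' median summarizes how much of its DEGs a member typically shares with
#' another member. Singleton clusters are missing.
#'
#' @param comp a \code{compendium}.
#' @param labels integer labels named by comparison id (from
#'   \code{\link{cluster_comparisons}}).
#' @return Named numeric vector, one median per cluster.
#' @export
median_cluster_overlap <- function(comp, labels) {
  stopifnot(inherits(comp, "compendium"))
  ids <- names(comp$comparisons)
  stopifnot(all(ids %in% names(labels)))
  de_list <- lapply(comp$comparisons, function(rec)
    rec$deg_table$gene[rec$deg_table$is_de %in% TRUE])
  out <- sapply(sort(unique(labels)), function(cl) {
    members <- ids[labels[ids] == cl]
    if (length(members) < 2L) return(NA_real_)
    fracs <- c()
    for (i in members) for (j in setdiff(members, i)) {
      ni <- length(de_list[[i]])
      fracs <- c(fracs, if (ni) length(intersect(de_list[[i]], de_list[[j]])) / ni else NA)
    }
    stats::median(fracs, na.rm = TRUE)
  })
  stats::setNames(out, sort(unique(labels)))
}

#' Annotate clusters by fused-enrichment of member comparisons
#'
#' Each member comparison contributes its per-gene FDR vector as one
#' channel (genes missing in a member contribute p = 1); the channels are
#' fused per gene with empirical Brown's method, the fused ranking is
#' enriched against the database, and the per-cluster hits are returned.
#'
#' @param comp a \code{compendium}.
#' @param labels cluster labels named by comparison id.
#' @param db a \code{gene_set_db}.
#' @param size inclusive size window applied per cluster background.
#' @param alpha significance threshold.
#' @return Named list of per-cluster enrichment data.frames.
#' @export
annotate_clusters <- function(comp, labels, db, size = c(15L, 2000L),
                              alpha = 0.05) {
  stopifnot(inherits(comp, "compendium"), inherits(db, "gene_set_db"))
  ids <- names(comp$comparisons)
  out <- list()
  for (cl in sort(unique(labels))) {
    members <- ids[labels[ids] == cl]
    genes <- unique(unlist(lapply(comp$comparisons[members],
                                  `[[`, "detected_genes"), use.names = FALSE))
    P <- vapply(members, function(id) {
      tab <- comp$comparisons[[id]]$deg_table
      p <- stats::setNames(tab$fdr, tab$gene)[genes]
      p[is.na(p)] <- 1
      pmin(pmax(p, .Machine$double.xmin), 1)
    }, numeric(length(genes)))
    P <- matrix(P, nrow = length(genes))
    fused <- empirical_brown_fuse(P)
    ranked <- genes[order(fused, genes)]
    dbf <- filter_gene_sets(db, size[1], size[2], universe = genes)
    out[[as.character(cl)]] <- enrich_list_against_db(ranked, dbf, genes, alpha)
  }
  out
}

#' Differential-expression prior
#'
#' Per-gene frequency of being DE among the comparisons in which the gene
#' is detected, with a dense descending rank (1 = most frequently DE,
#' ties broken lexicographically by gene id).
#'
#' @param comp a \code{compendium}.
#' @return data.frame(gene, de_frequency, n_de, n_detected, rank) of
#'   class \code{de_prior}.
#' @export
de_prior <- function(comp) {
  stopifnot(inherits(comp, "compendium"), length(comp$comparisons) >= 1L)
  genes <- sort(comp$universe)
  n_det <- n_de <- stats::setNames(integer(length(genes)), genes)
  for (rec in comp$comparisons) {
    n_det[rec$detected_genes] <- n_det[rec$detected_genes] + 1L
    de <- rec$deg_table$gene[rec$deg_table$is_de %in% TRUE]
    n_de[de] <- n_de[de] + 1L
  }
  freq <- ifelse(n_det > 0, n_de / n_det, 0)
  ord <- order(-freq, genes)
  out <- data.frame(gene = genes, de_frequency = freq, n_de = as.integer(n_de),
                    n_detected = as.integer(n_det), row.names = NULL,
                    stringsAsFactors = FALSE)[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("de_prior", class(out))
  out
}

#' Percentile overlap curve between two DE priors
#'
#' At each cumulative fraction q (1% steps by default), the top-q genes
#' of each prior are intersected and their over-representation within the
#' shared universe is tested; p-values are BH-corrected across
#' increments. The q = 1 increment has an undefined odds ratio (the two
#' sets equal the universe) and is reported missing.
#'
#' @param a,b \code{de_prior} objects.
#' @param step increment (default 0.01).
#' @return data.frame(q, n_top, n_overlap, odds_ratio, pvalue, fdr).
#' @export
prior_overlap_curve <- function(a, b, step = 0.01) {
  universe <- intersect(a$gene, b$gene)
  if (!length(universe)) stop("priors share no genes")
  a <- a[a$gene %in% universe, ]
  b <- b[b$gene %in% universe, ]
  a <- a[order(a$rank), ]; b <- b[order(b$rank), ]
  N <- length(universe)
  qs <- seq(step, 1, by = step)
  rows <- lapply(qs, function(q) {
    k <- max(1L, floor(q * N))
    ta <- a$gene[seq_len(k)]; tb <- b$gene[seq_len(k)]
    inter <- length(intersect(ta, tb))
    ht <- hypergeom_overlap_test(inter, k, k, N)
    or <- if (k == N) NA_real_ else ht$odds_ratio
    data.frame(q = q, n_top = k, n_overlap = inter, odds_ratio = or,
               pvalue = ht$pvalue)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$pvalue)
  out
}
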
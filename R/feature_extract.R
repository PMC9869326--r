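#' Fold-change matrix across a compendium
#'
#' Genes x comparisons matrix of log2 fold-changes, restricted to genes
#' detected in at least \code{min_detect} of the comparisons. Cells where
#' a gene was not detected are filled with 0 and flagged in the detection
#' mask; highly sparse genes are excluded because they over-predict the
#' fold-changes of genes detected in the same few studies.
#'
#' @param comp a \code{compendium}.
#' @param min_detect minimum detection fraction (default 0.70).
#' @return list of class \code{fc_matrix}: \code{fc} (genes x
#'   comparisons), \code{mask} (logical, TRUE = detected),
#'   \code{detection_fraction}.
#' @export
build_fc_matrix <- function(comp, min_detect = 0.70) {
  stopifnot(inherits(comp, "compendium"), length(comp$comparisons) >= 1L)
  ids <- names(comp$comparisons)
  genes <- sort(comp$universe)
  mask <- vapply(comp$comparisons, function(rec) genes %in% rec$detected_genes,
                 logical(length(genes)))
  mask <- matrix(mask, nrow = length(genes), dimnames = list(genes, ids))
  frac <- rowMeans(mask)
  keep <- frac >= min_detect
  if (!any(keep))
    stop("no gene is detected in >= ", round(100 * min_detect),
         "% of comparisons; lower min_detect")
  genes <- genes[keep]
  mask <- mask[keep, , drop = FALSE]
  fc <- vapply(comp$comparisons, function(rec) {
    v <- stats::setNames(rec$deg_table$log2fc, rec$deg_table$gene)[genes]
    v[is.na(v)] <- 0
    v
  }, numeric(length(genes)))
  fc <- matrix(fc, nrow = length(genes), dimnames = list(genes, ids))
  fc[!mask] <- 0
  structure(list(fc = fc, mask = mask, detection_fraction = frac[keep]),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("fc_matrix: %d genes x %d comparisons (median detection %.0f%%)\n",
              nrow(x$fc), ncol(x$fc), 100 * stats::median(x$detection_fraction)))
  invisible(x)
}

#' Elastic-net extraction of predictive genes
#'
#' Fits an elastic net (mixing parameter alpha = 0.5) of the response on
#' the comparisons x genes fold-change matrix, with the penalty chosen by
#' 10-fold cross-validation at the 1-SE rule under a fixed seed, and
#' returns the per-gene coefficients at that penalty (for multinomial
#' responses, the largest |coefficient| across classes).
#'
#' @param fcm an \code{fc_matrix} (or a genes x comparisons matrix).
#' @param y response of length ncol(fc): numeric (gaussian), two-level
#'   (binomial), or >2-level (multinomial).
#' @param family gaussian, binomial, or multinomial.
#' @param alpha elastic-net mixing parameter.
#' @param seed RNG seed for the CV fold assignment.
#' @param exclude gene names to drop from the predictors.
#' @return Named numeric vector of coefficients, one per gene.
#' @export
elastic_net_extract <- function(fcm, y, family = c("gaussian", "binomial",
                                                   "multinomial"),
                                alpha = 0.5, seed = 1L, exclude = character()) {
  family <- match.arg(family)
  fc <- if (inherits(fcm, "fc_matrix")) fcm$fc else as.matrix(fcm)
  fc <- fc[setdiff(rownames(fc), exclude), , drop = FALSE]
  X <- t(fc)  # comparisons x genes
  stopifnot(length(y) == nrow(X))
  zero <- stats::setNames(rep(0, ncol(X)), colnames(X))
  if (family == "gaussian" && stats::sd(y) == 0) {
    warning("constant response; returning zero coefficients")
    return(zero)
  }
  if (family != "gaussian" && length(unique(y)) < 2L) {
    warning("constant response; returning zero coefficients")
    return(zero)
  }
  set.seed(seed)
  nfolds <- min(10L, nrow(X))
  cv <- glmnet::cv.glmnet(X, y, family = family, alpha = alpha,
                          nfolds = nfolds)
  co <- stats::coef(cv, s = "lambda.1se")
  if (family == "multinomial") {
    mats <- lapply(co, function(m) abs(as.numeric(m[-1, 1])))
    out <- do.call(pmax, mats)
  } else {
    out <- as.numeric(co[-1, 1])
  }
  stats::setNames(out, colnames(X))
}

#' Univariate gene-response association
#'
#' The simple counterpart to the elastic net: Spearman correlation for a
#' continuous response, one-way ANOVA for a multi-class response, and a
#' Wilcoxon rank-sum test for a two-class response, BH-corrected across
#' genes.
#'
#' @inheritParams elastic_net_extract
#' @return data.frame(gene, stat, pvalue, fdr).
#' @export
univariate_assoc <- function(fcm, y, family = c("gaussian", "binomial",
                                                "multinomial")) {
  family <- match.arg(family)
  fc <- if (inherits(fcm, "fc_matrix")) fcm$fc else as.matrix(fcm)
  stopifnot(length(y) == ncol(fc))
  one <- function(x) {
    if (family == "gaussian") {
      if (stats::sd(x) == 0 || stats::sd(y) == 0)
        return(c(NA_real_, NA_real_))
      ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
      c(unname(ct$estimate), ct$p.value)
    } else if (family == "binomial") {
      g <- split(x, y)
      if (length(g) != 2L || any(lengths(g) < 2L)) return(c(NA_real_, NA_real_))
      wt <- suppressWarnings(stats::wilcox.test(g[[1]], g[[2]]))
      c(unname(wt$statistic), wt$p.value)
    } else {
      g <- factor(y)
      if (nlevels(g) < 2L || any(table(g) < 2L)) return(c(NA_real_, NA_real_))
      fit <- stats::aov(x ~ g)
      s <- summary(fit)[[1]]
      c(s$`F value`[1], s$`Pr(>F)`[1])
    }
  }
  res <- t(apply(fc, 1, one))
  out <- data.frame(gene = rownames(fc), stat = res[, 1], pvalue = res[, 2],
                    row.names = NULL, stringsAsFactors = FALSE)
  out$fdr <- bh_fdr(out$pvalue)
  out
}

#' Rank genes by how well they predict other genes' fold-changes
#'
#' For every target gene, fits an elastic net of its fold-change profile
#' on all other genes and records the absolute coefficients; a gene's
#' importance is its column sum over all targets — how much predictive
#' weight it carries across the compendium.
#'
#' @param comp a \code{compendium} (or a prebuilt \code{fc_matrix}).
#' @param min_detect detection-fraction filter when building the matrix.
#' @param max_genes cap on the number of genes (fits are O(genes^2));
#'   when exceeded, the genes with the highest fold-change variance are
#'   kept.
#' @param seed RNG seed for the CV folds.
#' @return data.frame(gene, importance) sorted descending, of class
#'   \code{predictor_importance}.
#' @export
predictor_importance <- function(comp, min_detect = 0.70, max_genes = 2000L,
                                 seed = 1L) {
  fcm <- if (inherits(comp, "fc_matrix")) comp else build_fc_matrix(comp, min_detect)
  fc <- fcm$fc
  if (nrow(fc) > max_genes) {
    v <- apply(fc, 1, stats::var)
    fc <- fc[order(-v)[seq_len(max_genes)], , drop = FALSE]
  }
  genes <- rownames(fc)
  importance <- stats::setNames(rep(0, length(genes)), genes)
  for (g in genes) {
    co <- elastic_net_extract(fc, y = fc[g, ], family = "gaussian",
                              seed = seed, exclude = g)
    importance[names(co)] <- importance[names(co)] + abs(co)
  }
  out <- data.frame(gene = genes, importance = unname(importance[genes]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("predictor_importance", class(out))
  out
}
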
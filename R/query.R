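#' Normalize user input into a query
#'
#' Three input shapes are accepted. A full query carries per-gene p-values
#' and coefficients and enables every channel. An ordered list (genes in
#' decreasing significance, no p-values) gets evenly spaced surrogate
#' p-values with the least significant being 0.049, and the Pearson
#' correlation channel is disabled. An unordered list sets every p-value
#' to 0.049 and disables both correlation channels. Duplicate symbols are
#' collapsed, by default keeping the minimum p-value.
#'
#' @param genes character vector of gene identifiers.
#' @param pvalues optional numeric p-values in (0, 1].
#' @param coefficients optional numeric coefficients (e.g. log2
#'   fold-changes).
#' @param ordered when no p-values are given, is the list ordered by
#'   significance?
#' @param background optional character vector of background genes.
#' @param collapse how duplicate symbols are resolved: the occurrence with
#'   minimum p, or the first occurrence.
#' @param uppercase upper-case symbols before matching (human symbol
#'   convention); disable for Ensembl ids.
#' @return An object of class \code{user_query} with fields genes,
#'   pvalues, coefficients, mode (full/ordered/unordered), background.
#' @export
prepare_user_input <- function(genes, pvalues = NULL, coefficients = NULL,
                               ordered = FALSE, background = NULL,
                               collapse = c("min_p", "first"),
                               uppercase = FALSE) {
  collapse <- match.arg(collapse)
  genes <- as.character(genes)
  if (!length(genes)) stop("empty gene list")
  if (uppercase) genes <- toupper(genes)
  if (!is.null(pvalues)) {
    if (length(pvalues) != length(genes))
      stop("pvalues must match genes in length")
    if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1))
      stop("p-values must lie in (0, 1]")
    if (is.null(coefficients))
      stop("a full query needs both p-values and coefficients")
    if (length(coefficients) != length(genes))
      stop("coefficients must match genes in length")
    mode <- "full"
  } else if (ordered) {
    n <- length(genes)
    pvalues <- 0.049 * seq_len(n) / n
    coefficients <- NULL
    mode <- "ordered"
  } else {
    pvalues <- rep(0.049, length(genes))
    coefficients <- NULL
    mode <- "unordered"
  }
  if (anyDuplicated(genes)) {
    # collapse to one row per gene, preserving first-occurrence order
    ug <- unique(genes)
    sel <- vapply(ug, function(g) {
      idx <- which(genes == g)
      if (collapse == "min_p") idx[which.min(pvalues[idx])] else idx[1]
    }, integer(1))
    genes <- genes[sel]
    pvalues <- pvalues[sel]
    if (!is.null(coefficients)) coefficients <- coefficients[sel]
    if (mode == "ordered") {
      ord <- order(pvalues)
      pvalues[ord] <- 0.049 * seq_along(genes) / length(genes)
    }
  }
  structure(list(genes = genes, pvalues = pvalues,
                 coefficients = coefficients, mode = mode,
                 background = background),
            class = "user_query")
}

#' @export
print.user_query <- function(x, ...) {
  cat(sprintf("user_query: %d genes, mode = %s%s\n", length(x$genes), x$mode,
              if (is.null(x$background)) "" else
                sprintf(", background of %d", length(x$background))))
  invisible(x)
}

#' Resolve the statistical background for a query
#'
#' The user's background when given, otherwise every gene detected in the
#' compendium. Query genes absent from the background are appended with a
#' warning so the hypergeometric accounting stays consistent.
#'
#' @param q a \code{user_query}.
#' @param comp a \code{compendium}.
#' @return Character vector of background genes.
#' @export
resolve_background <- function(q, comp) {
  bg <- if (!is.null(q$background)) unique(as.character(q$background))
        else comp$universe
  if (!length(bg)) stop("no background available: compendium universe is empty")
  missing <- setdiff(q$genes, bg)
  if (length(missing)) {
    warning(length(missing), " query gene(s) absent from the background; appended")
    bg <- c(bg, missing)
  }
  bg
}

# query genes ranked by ascending p (ties by input order)
query_ranking <- function(q) q$genes[order(q$pvalues, seq_along(q$genes))]

#' Query a compendium with a user gene list
#'
#' The primary analysis. Four channels are computed: (1) user pathways
#' and TF targets — ranked hypergeometric enrichment of the query against
#' the two term databases; (2) deg_overlap — ranked enrichment of the
#' query against every comparison's DEG set; (3) pathway_overlap and
#' tf_overlap — hypergeometric overlap of the user's significant terms
#' with each comparison's significant terms over the term universe;
#' (4) correlation — Spearman (and, for full queries, Pearson)
#' correlation between the user's coefficients and each enriched
#' comparison's DEG log2 fold-changes. Every channel is BH-corrected.
#'
#' @param q a \code{user_query}.
#' @param comp a \code{compendium}.
#' @param pathway_db,tf_db optional \code{gene_set_db}s.
#' @param alpha significance threshold (default 0.05).
#' @param pathway_size,tf_size size windows for term filtering.
#' @return An object of class \code{enrichment_report} with elements
#'   \code{deg_overlap}, \code{pathway_overlap}, \code{tf_overlap},
#'   \code{correlations}, \code{user_pathways}, \code{user_tfs},
#'   \code{mode}.
#' @export
query_compendium <- function(q, comp, pathway_db = NULL, tf_db = NULL,
                             alpha = 0.05, pathway_size = c(15L, 2000L),
                             tf_size = c(15L, 5000L)) {
  stopifnot(inherits(q, "user_query"), inherits(comp, "compendium"))
  if (!length(comp$comparisons)) stop("compendium is empty")
  bg <- resolve_background(q, comp)
  ranked <- query_ranking(q)

  user_terms <- function(db, window) {
    if (is.null(db)) return(empty_annotation())
    dbf <- filter_gene_sets(db, window[1], window[2], universe = bg)
    enrich_list_against_db(ranked, dbf, bg, alpha)
  }
  user_pathways <- user_terms(pathway_db, pathway_size)
  user_tfs <- user_terms(tf_db, tf_size)

  deg_db <- compendium_to_gmt(comp, "all")
  deg_overlap <- enrich_list_against_db(ranked, deg_db, bg, alpha)
  deg_overlap <- add_rank(deg_overlap)

  pathway_overlap <- term_overlap_channel(user_pathways, comp,
                                          "enriched_pathways", alpha)
  tf_overlap <- term_overlap_channel(user_tfs, comp, "enriched_tfs", alpha)

  correlations <- correlation_channel(q, comp, deg_overlap, alpha)

  structure(list(deg_overlap = deg_overlap,
                 pathway_overlap = pathway_overlap,
                 tf_overlap = tf_overlap,
                 correlations = correlations,
                 user_pathways = user_pathways, user_tfs = user_tfs,
                 mode = q$mode, alpha = alpha),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat("enrichment_report\n")
  for (ch in c("deg_overlap", "pathway_overlap", "tf_overlap", "correlations"))
    cat(sprintf("  %s: %d rows, %d significant\n", ch, nrow(x[[ch]]),
                sum(x[[ch]]$significant %in% TRUE)))
  invisible(x)
}

add_rank <- function(tab) {
  if (!nrow(tab)) { tab$rank <- integer(0); return(tab) }
  tab <- tab[order(tab$fdr, tab$pvalue, tab$term_id), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  tab
}

# overlap of the user's significant terms with each comparison's
# significant terms, over the universe of all term ids in the channel
term_overlap_channel <- function(user_hits, comp, field, alpha) {
  empty <- data.frame(term_id = character(0), pvalue = numeric(0),
                      fdr = numeric(0), n_overlap = integer(0),
                      significant = logical(0), rank = integer(0))
  if (!nrow(user_hits)) return(empty)
  universe <- unique(unlist(lapply(comp$comparisons,
                                   function(r) r[[field]]$term_id),
                            use.names = FALSE))
  if (!length(universe)) return(empty)
  user_sig <- intersect(user_hits$term_id[user_hits$significant], universe)
  rows <- lapply(comp$comparisons, function(r) {
    comp_sig <- intersect(r[[field]]$term_id[r[[field]]$significant], universe)
    inter <- intersect(user_sig, comp_sig)
    ht <- hypergeom_overlap_test(length(inter), length(comp_sig),
                                 length(user_sig), length(universe))
    data.frame(term_id = r$id, pvalue = ht$pvalue,
               n_overlap = length(inter), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr <- bh_fdr(out$pvalue)
  out$significant <- out$fdr < alpha
  add_rank(out)
}

#' Correlate user coefficients with one comparison's fold-changes
#'
#' Computed on genes DE in the comparison and present in the user list;
#' returns missing correlations when fewer than three genes overlap or a
#' vector is constant.
#'
#' @param coefs named numeric vector of user coefficients (names = genes).
#' @param record a \code{comparison_record}.
#' @return list(spearman_rho, pearson_r, p_spearman, p_pearson, n).
#' @export
correlate_with_comparison <- function(coefs, record) {
  de <- record$deg_table[record$deg_table$is_de %in% TRUE, , drop = FALSE]
  common <- intersect(names(coefs), de$gene)
  n <- length(common)
  miss <- list(spearman_rho = NA_real_, pearson_r = NA_real_,
               p_spearman = NA_real_, p_pearson = NA_real_, n = n)
  if (n < 3L) return(miss)
  x <- coefs[common]
  y <- de$log2fc[match(common, de$gene)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(miss)
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  pe <- stats::cor.test(x, y, method = "pearson")
  list(spearman_rho = unname(sp$estimate), pearson_r = unname(pe$estimate),
       p_spearman = sp$p.value, p_pearson = pe$p.value, n = n)
}

# Spearman/Pearson correlations for comparisons significant in deg_overlap
correlation_channel <- function(q, comp, deg_overlap, alpha) {
  empty <- data.frame(term_id = character(0), spearman_rho = numeric(0),
                      pearson_r = numeric(0), p = numeric(0),
                      fdr = numeric(0), n_overlap = integer(0),
                      significant = logical(0), rank = integer(0))
  if (q$mode == "unordered") return(empty)
  enriched <- deg_overlap$term_id[deg_overlap$significant %in% TRUE]
  if (!length(enriched)) return(empty)
  coefs <- if (q$mode == "full") {
    stats::setNames(q$coefficients, q$genes)
  } else {
    # ordered mode: rank order stands in for the coefficient (higher = more
    # significant); only the Spearman channel is meaningful
    stats::setNames(rev(seq_along(q$genes)), query_ranking(q))
  }
  rows <- lapply(enriched, function(id) {
    cc <- correlate_with_comparison(coefs, comp$comparisons[[id]])
    data.frame(term_id = id, spearman_rho = cc$spearman_rho,
               pearson_r = if (q$mode == "full") cc$pearson_r else NA_real_,
               p = cc$p_spearman, n_overlap = cc$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr <- bh_fdr(out$p)
  out$significant <- !is.na(out$fdr) & out$fdr < alpha
  out <- out[order(out$fdr, out$p, out$term_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}

#' Gene-centric query (no pathway/TF channels)
#'
#' \code{\link{query_compendium}} restricted to the DEG-overlap and
#' correlation channels; suitable for identifier namespaces (e.g. Ensembl)
#' with no term annotation, in which case symbol upper-casing should be
#' disabled in \code{\link{prepare_user_input}}.
#'
#' @inheritParams query_compendium
#' @return An \code{enrichment_report} with empty pathway/TF channels.
#' @export
enrich_genes_only <- function(q, comp, alpha = 0.05) {
  rep <- query_compendium(q, comp, pathway_db = NULL, tf_db = NULL,
                          alpha = alpha)
  if (!sum(rep$deg_overlap$n_overlap))
    warning("query has zero overlap with every comparison; ",
            "check that identifier namespaces match")
  rep
}

#' Enrich each comparison's DEG list against a user gene set
#'
#' Input-as-reference mode: the user's genes become a single-set database
#' and each comparison's DEG list, ranked by ascending FDR, is the query.
#' Useful when the user list is unranked but the compendium's weights
#' should drive the enrichment.
#'
#' @param user_genes character vector.
#' @param comp a \code{compendium}.
#' @param alpha significance threshold.
#' @return data.frame(term_id = comparison id, pvalue, fdr,
#'   best_rank_depth, n_overlap, significant), BH-corrected across
#'   comparisons and sorted by fdr then p.
#' @export
input_as_reference <- function(user_genes, comp, alpha = 0.05) {
  stopifnot(inherits(comp, "compendium"))
  user_genes <- unique(as.character(user_genes))
  if (!length(user_genes)) stop("empty user gene list")
  bg <- unique(c(comp$universe, user_genes))
  rows <- lapply(comp$comparisons, function(r) {
    ranked <- rank_degs(r$deg_table)$gene
    hit <- ranked_hypergeometric(ranked, user_genes, bg)
    data.frame(term_id = r$id, pvalue = hit$pvalue,
               best_rank_depth = hit$best_rank_depth,
               n_overlap = length(hit$overlap_genes),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr <- bh_fdr(out$pvalue)
  out$significant <- out$fdr < alpha
  out[order(out$fdr, out$pvalue, out$term_id), , drop = FALSE]
}

#' Tidy top-hit tables for plotting and export
#'
#' For each channel, the top rows with a -log10(FDR) column; and, for a
#' chosen comparison, a scatter table pairing user coefficients with the
#' comparison's DEG log2 fold-changes, classified by sign agreement.
#'
#' @param rep an \code{enrichment_report}.
#' @param q the \code{user_query} that produced it (needed for the
#'   scatter table; optional).
#' @param comp the queried \code{compendium} (optional).
#' @param top_n rows per channel.
#' @param scatter_comparison id of the comparison to build the scatter
#'   table for (default: top deg_overlap hit).
#' @return list(channels = named list of data.frames, scatter =
#'   data.frame(gene, user_coefficient, comparison_log2fc, agreement)).
#' @export
report_tables <- function(rep, q = NULL, comp = NULL, top_n = 15L,
                          scatter_comparison = NULL) {
  stopifnot(inherits(rep, "enrichment_report"))
  channels <- lapply(rep[c("deg_overlap", "pathway_overlap", "tf_overlap",
                           "correlations")], function(tab) {
    tab <- utils::head(tab, top_n)
    fdr_col <- if ("fdr" %in% names(tab)) tab$fdr else numeric(0)
    tab$neg_log10_fdr <- -log10(pmax(fdr_col, .Machine$double.xmin))
    tab
  })
  scatter <- data.frame(gene = character(0), user_coefficient = numeric(0),
                        comparison_log2fc = numeric(0),
                        agreement = character(0))
  if (!is.null(q) && !is.null(comp) && !is.null(q$coefficients) &&
      nrow(rep$deg_overlap)) {
    id <- if (is.null(scatter_comparison)) rep$deg_overlap$term_id[1]
          else scatter_comparison
    rec <- comp$comparisons[[id]]
    if (!is.null(rec)) {
      de <- rec$deg_table[rec$deg_table$is_de %in% TRUE, , drop = FALSE]
      genes <- union(q$genes, de$gene)
      uc <- stats::setNames(q$coefficients, q$genes)[genes]
      cf <- de$log2fc[match(genes, de$gene)]
      agree <- ifelse(is.na(uc) | is.na(cf), "one-only",
                      ifelse(sign(uc) == sign(cf), "same-sign", "opposite"))
      scatter <- data.frame(gene = genes, user_coefficient = unname(uc),
                            comparison_log2fc = cf, agreement = agree,
                            stringsAsFactors = FALSE)
    }
  }
  list(channels = channels, scatter = scatter)
}
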
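#' Construct a counts experiment for one pairwise comparison
#'
#' Bundles a genes x samples count matrix with its sample metadata and the
#' two-level condition column being contrasted. Requires at least three
#' biological replicates in each condition.
#'
#' @param counts nonnegative integer matrix with gene rownames.
#' @param sample_meta data.frame aligned with the columns of counts.
#' @param condition name of the metadata column holding the two compared
#'   levels.
#' @return An object of class \code{counts_experiment}.
#' @export
counts_experiment <- function(counts, sample_meta, condition) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene rownames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  stopifnot(is.data.frame(sample_meta), nrow(sample_meta) == ncol(counts))
  if (!condition %in% names(sample_meta))
    stop("condition column not found: ", condition)
  cond <- as.character(sample_meta[[condition]])
  levs <- sort(unique(cond))
  if (length(levs) != 2L)
    stop("condition must have exactly 2 levels, found ", length(levs))
  if (min(table(cond)) < 3L)
    stop("each condition needs >= 3 biological replicates")
  structure(list(counts = counts, sample_meta = sample_meta,
                 condition = condition, levels = levs),
            class = "counts_experiment")
}

#' @export
print.counts_experiment <- function(x, ...) {
  cat(sprintf("counts_experiment: %d genes x %d samples; %s: %s vs %s\n",
              nrow(x$counts), ncol(x$counts), x$condition,
              x$levels[1], x$levels[2]))
  invisible(x)
}

#' Negative-binomial likelihood-ratio differential expression
#'
#' Fits, per gene, a log-link NB GLM under the full design
#' (intercept + covariates + condition) and the reduced design without the
#' condition term, and tests 2(ll_full - ll_reduced) against chi-square
#' with 1 df. The reference level is the alphabetically first condition
#' label (the "downregulated" group convention), so log2 fold-changes are
#' non-reference over reference. P-values are BH-adjusted across tested
#' genes and \code{is_de} marks FDR < \code{fdr_cut}.
#'
#' @param e a \code{counts_experiment}.
#' @param covariates optional samples x k numeric matrix (e.g. from
#'   \code{\link{build_covariates}}).
#' @param fdr_cut FDR threshold defining DEGs (default 0.05).
#' @param pseudo_reference passed to \code{\link{size_factors}}.
#' @return An object of class \code{de_result}: \code{deg_table}
#'   (gene, log2fc, pvalue, fdr, is_de), \code{size_factors},
#'   \code{dispersions}, \code{reference_level}, \code{detected_genes}.
#' @export
run_comparison <- function(e, covariates = NULL, fdr_cut = 0.05,
                           pseudo_reference = FALSE) {
  stopifnot(inherits(e, "counts_experiment"))
  counts <- e$counts
  n <- ncol(counts)
  if (is.null(covariates))
    covariates <- matrix(numeric(0), nrow = n, ncol = 0)
  covariates <- as.matrix(covariates)
  stopifnot(nrow(covariates) == n)
  cond <- as.character(e$sample_meta[[e$condition]])
  ref <- e$levels[1]
  cond_ind <- as.numeric(cond != ref)
  X_reduced <- cbind(`(Intercept)` = rep(1, n), covariates)
  # guard against covariates collinear with the intercept or condition
  qrX <- qr(cbind(X_reduced, cond = cond_ind))
  if (qrX$rank < ncol(X_reduced) + 1L) {
    keep <- setdiff(qrX$pivot[seq_len(qrX$rank)], c(1L, ncol(X_reduced) + 1L))
    keep_cov <- keep - 1L
    covariates <- covariates[, keep_cov[keep_cov <= ncol(covariates)], drop = FALSE]
    X_reduced <- cbind(`(Intercept)` = rep(1, n), covariates)
  }
  X_full <- cbind(X_reduced, cond = cond_ind)

  sf <- size_factors(counts, pseudo_reference = pseudo_reference)
  offsets <- log(sf)

  detected <- rownames(counts)[rowSums(counts) > 0]
  genes <- rownames(counts)
  log2fc <- pvalue <- rep(NA_real_, length(genes))
  disp <- rep(NA_real_, length(genes))
  names(log2fc) <- names(pvalue) <- names(disp) <- genes
  n_fail <- 0L
  for (g in detected) {
    y <- counts[g, ]
    # dispersion is estimated under the reduced design: excluding the tested
    # term keeps the estimate from absorbing chance between-group differences,
    # which calibrates the LRT at small n (conservative for true DE genes)
    a <- tryCatch(estimate_dispersion(y, X_reduced, offsets),
                  error = function(err) NA_real_)
    if (is.na(a)) { n_fail <- n_fail + 1L; next }
    full <- fit_nb_glm(y, X_full, offsets, a)
    red <- fit_nb_glm(y, X_reduced, offsets, a)
    if (!full$converged || !red$converged) { n_fail <- n_fail + 1L; next }
    lrt <- max(0, 2 * (full$loglik - red$loglik))
    pvalue[g] <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
    log2fc[g] <- full$coefficients[["cond"]] / log(2)
    disp[g] <- a
  }
  if (length(detected) && n_fail > 0.5 * length(detected))
    stop("more than half of detected genes failed to fit")
  fdr <- bh_fdr(pvalue)
  deg_table <- data.frame(gene = genes, log2fc = log2fc, pvalue = pvalue,
                          fdr = fdr, is_de = !is.na(fdr) & fdr < fdr_cut,
                          row.names = NULL, stringsAsFactors = FALSE)
  structure(list(deg_table = deg_table, size_factors = sf,
                 dispersions = disp, reference_level = ref,
                 detected_genes = detected,
                 condition_levels = e$levels, n_flagged = n_fail),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("de_result: %d genes tested, %d DE (reference = %s)\n",
              sum(!is.na(x$deg_table$pvalue)), sum(x$deg_table$is_de),
              x$reference_level))
  invisible(x)
}

#' Filter comparisons by DEG count
#'
#' A comparison is kept only when it yields between 5 and 10000 DEGs
#' inclusive; fewer suggests an uninformative contrast and more a
#' pathological one.
#'
#' @param r a \code{de_result} (or anything with a \code{deg_table}).
#' @param min_deg,max_deg inclusive bounds.
#' @return list(keep = logical, reason = character or NA, n_deg).
#' @export
deg_count_filter <- function(r, min_deg = 5L, max_deg = 10000L) {
  n_deg <- sum(r$deg_table$is_de, na.rm = TRUE)
  if (n_deg < min_deg)
    list(keep = FALSE, reason = "too-few-degs", n_deg = n_deg)
  else if (n_deg > max_deg)
    list(keep = FALSE, reason = "too-many-degs", n_deg = n_deg)
  else
    list(keep = TRUE, reason = NA_character_, n_deg = n_deg)
}

#' Re-threshold a DEG table
#'
#' Recomputes \code{is_de} under a new FDR cutoff and a linear
#' fold-change cutoff (applied as |log2fc| >= log2(abs_fc_cut)). The
#' validation analyses use fdr_cut = 0.05 with abs_fc_cut = 1.5.
#'
#' @param deg_table data.frame with columns fdr and log2fc.
#' @param fdr_cut FDR threshold in (0, 1].
#' @param abs_fc_cut linear fold-change threshold >= 1.
#' @return The table with \code{is_de} recomputed.
#' @export
apply_cutoffs <- function(deg_table, fdr_cut = 0.05, abs_fc_cut = 1.0) {
  stopifnot(fdr_cut > 0, fdr_cut <= 1, abs_fc_cut >= 1)
  lfc_cut <- log2(abs_fc_cut)
  deg_table$is_de <- !is.na(deg_table$fdr) & deg_table$fdr < fdr_cut &
    !is.na(deg_table$log2fc) & abs(deg_table$log2fc) >= lfc_cut
  deg_table
}
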
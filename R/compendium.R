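#' Name a pairwise comparison
#'
#' Canonical display name "STUDY: Tissue.cond1 vs cond2" with the two
#' condition labels in alphabetical order (so the same contrast always
#' yields the same name regardless of argument order).
#'
#' @param study_id,tissue,cond1,cond2 non-empty strings.
#' @return The comparison name.
#' @export
name_comparison <- function(study_id, tissue, cond1, cond2) {
  args <- c(study_id, tissue, cond1, cond2)
  if (any(!nzchar(args))) stop("all naming fields must be non-empty")
  conds <- sort(c(cond1, cond2))
  sprintf("%s: %s.%s vs %s", study_id, tissue, conds[1], conds[2])
}

#' Describe one candidate comparison for inclusion screening
#'
#' @param study_id study accession or label.
#' @param tissue tissue/cell type of the comparison (use \code{tissue2}
#'   when the second group comes from a different tissue).
#' @param cond1,cond2 the two condition labels.
#' @param n1,n2 biological replicates per condition.
#' @param group_meta optional data.frame of per-sample metadata with a
#'   \code{group} column of 1/2 identifying the condition each sample
#'   belongs to; used for the stratification check.
#' @param controlled_vars names of categorical metadata columns the design
#'   controls for.
#' @param generic_ids TRUE when the conditions are generic identifiers
#'   (e.g. patient-ID groupings); cannot be detected automatically.
#' @param tissue2 tissue of the second group if different from
#'   \code{tissue}.
#' @param time_levels for time-series/dosage designs, the ordered level
#'   sequence with the reference first.
#' @param n_study_comparisons number of candidate comparisons in the study.
#' @param control_label the untreated/control label, when one exists.
#' @return A list of class \code{design_spec}.
#' @export
design_spec <- function(study_id, tissue, cond1, cond2, n1, n2,
                        group_meta = NULL, controlled_vars = character(),
                        generic_ids = FALSE, tissue2 = NULL,
                        time_levels = NULL, n_study_comparisons = 1L,
                        control_label = NULL) {
  structure(list(study_id = study_id, tissue = tissue, cond1 = cond1,
                 cond2 = cond2, n1 = n1, n2 = n2, group_meta = group_meta,
                 controlled_vars = controlled_vars,
                 generic_ids = generic_ids, tissue2 = tissue2,
                 time_levels = time_levels,
                 n_study_comparisons = n_study_comparisons,
                 control_label = control_label),
            class = "design_spec")
}

#' Screen a candidate comparison against the inclusion rules
#'
#' Applies the interpretability rules used while assembling the atlas:
#' at least three replicates per condition; no generic condition ids; no
#' cross-tissue contrasts; no controlled-for categorical variable may
#' perfectly stratify the two groups; neither condition may be
#' NA/unknown; time-series pairs must involve the reference or be
#' adjacent levels; in studies with more than three candidate comparisons
#' only treatment-vs-control contrasts are kept.
#'
#' @param spec a \code{\link{design_spec}}.
#' @return list(include = logical, reasons = character vector of
#'   machine-readable reason codes, empty when included).
#' @export
check_inclusion <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  reasons <- character(0)
  if (spec$n1 < 3 || spec$n2 < 3) reasons <- c(reasons, "replicates")
  if (isTRUE(spec$generic_ids)) reasons <- c(reasons, "generic-conditions")
  if (!is.null(spec$tissue2) && !identical(spec$tissue2, spec$tissue))
    reasons <- c(reasons, "cross-tissue")
  conds <- c(spec$cond1, spec$cond2)
  if (anyNA(conds) || any(tolower(conds) %in% c("na", "unknown")))
    reasons <- c(reasons, "na-or-unknown-condition")
  if (!is.null(spec$group_meta) && length(spec$controlled_vars)) {
    gm <- spec$group_meta
    for (v in intersect(spec$controlled_vars, names(gm))) {
      a <- unique(as.character(gm[[v]][gm$group == 1]))
      b <- unique(as.character(gm[[v]][gm$group == 2]))
      if (length(a) == 1L && length(b) == 1L && a != b) {
        reasons <- c(reasons, "stratification")
        break
      }
    }
  }
  if (!is.null(spec$time_levels)) {
    pos <- match(conds, spec$time_levels)
    if (!anyNA(pos)) {
      ref <- spec$time_levels[1]
      if (!ref %in% conds && abs(diff(pos)) > 1L)
        reasons <- c(reasons, "nonlinear-timepoint")
    }
  }
  if (spec$n_study_comparisons > 3L && !is.null(spec$control_label) &&
      !spec$control_label %in% conds)
    reasons <- c(reasons, "treatment-vs-treatment")
  list(include = length(reasons) == 0L, reasons = reasons)
}

# Rank a DEG table's DE genes: ascending FDR, ties broken by descending
# |log2fc|, then gene id. The convention used for enrichment input and
# summary cards.
rank_degs <- function(deg_table, direction = c("all", "up", "down")) {
  direction <- match.arg(direction)
  t <- deg_table[deg_table$is_de %in% TRUE, , drop = FALSE]
  if (direction == "up") t <- t[t$log2fc > 0, , drop = FALSE]
  if (direction == "down") t <- t[t$log2fc < 0, , drop = FALSE]
  t[order(t$fdr, -abs(t$log2fc), t$gene), , drop = FALSE]
}

#' Annotate a comparison with pathway and TF-target enrichment
#'
#' Runs ranked hypergeometric enrichment of the comparison's DEG list
#' (both directions together, ranked by ascending FDR) against the
#' pathway database filtered to 15-2000 genes and the TF-target database
#' filtered to 15-5000, with the comparison's detected genes as the
#' statistical background. All terms are stored regardless of
#' significance; significance is marked at FDR < 0.05.
#'
#' @param record a \code{comparison_record}.
#' @param pathway_db,tf_db \code{gene_set_db} objects (unfiltered).
#' @param pathway_size,tf_size inclusive size windows.
#' @return The record with \code{enriched_pathways} and
#'   \code{enriched_tfs} filled.
#' @export
annotate_comparison <- function(record, pathway_db = NULL, tf_db = NULL,
                                pathway_size = c(15L, 2000L),
                                tf_size = c(15L, 5000L)) {
  ranked <- rank_degs(record$deg_table)$gene
  bg <- record$detected_genes
  ann <- function(db, window) {
    if (is.null(db)) return(empty_annotation())
    dbf <- filter_gene_sets(db, window[1], window[2], universe = bg)
    hits <- enrich_list_against_db(ranked, dbf, bg)
    hits[, c("term_id", "pvalue", "fdr", "n_overlap", "significant")]
  }
  record$enriched_pathways <- ann(pathway_db, pathway_size)
  record$enriched_tfs <- ann(tf_db, tf_size)
  record
}

empty_annotation <- function() {
  data.frame(term_id = character(0), pvalue = numeric(0), fdr = numeric(0),
             n_overlap = integer(0), significant = logical(0))
}

#' Construct a comparison record
#'
#' @param id unique comparison id.
#' @param name display name (see \code{\link{name_comparison}}).
#' @param source one of SRA, TCGA, GTEx, SRA-manual, synthetic.
#' @param deg_table per-gene table (gene, log2fc, pvalue, fdr, is_de).
#' @param detected_genes genes detected in the comparison.
#' @param category free-text comparison category.
#' @param n_samples_total,n_samples_up,n_samples_down sample counts.
#' @return An object of class \code{comparison_record}.
#' @export
comparison_record <- function(id, name, source, deg_table, detected_genes,
                              category = "uncategorized",
                              n_samples_total = NA_integer_,
                              n_samples_up = NA_integer_,
                              n_samples_down = NA_integer_) {
  source <- match.arg(source, c("SRA", "TCGA", "GTEx", "SRA-manual", "synthetic"))
  de_genes <- deg_table$gene[deg_table$is_de %in% TRUE]
  if (!all(de_genes %in% detected_genes))
    stop("DEG set must be a subset of detected genes")
  structure(list(id = id, name = name, source = source, category = category,
                 deg_table = deg_table, detected_genes = detected_genes,
                 n_samples_total = n_samples_total,
                 n_samples_up = n_samples_up, n_samples_down = n_samples_down,
                 enriched_pathways = empty_annotation(),
                 enriched_tfs = empty_annotation(),
                 summary_card = NULL),
            class = "comparison_record")
}

#' @export
print.comparison_record <- function(x, ...) {
  cat(sprintf("comparison_record %s [%s]: %d DEGs / %d detected\n",
              x$name, x$source, sum(x$deg_table$is_de, na.rm = TRUE),
              length(x$detected_genes)))
  invisible(x)
}

#' Build the summary card for a comparison
#'
#' Top 15 up- and downregulated genes (by FDR then |log2fc|), top 5
#' enriched pathways and TFs, DEG and sample counts, and a free-text
#' description.
#'
#' @param record an annotated \code{comparison_record}.
#' @param description free text.
#' @return The record with \code{summary_card} filled.
#' @export
build_summary_card <- function(record, description = "") {
  up <- rank_degs(record$deg_table, "up")$gene
  down <- rank_degs(record$deg_table, "down")$gene
  top_terms <- function(ann) {
    if (!nrow(ann)) return(character(0))
    utils::head(ann$term_id[order(ann$fdr, ann$pvalue)], 5L)
  }
  record$summary_card <- list(
    top_up = utils::head(up, 15L),
    top_down = utils::head(down, 15L),
    top_pathways = top_terms(record$enriched_pathways),
    top_tfs = top_terms(record$enriched_tfs),
    n_de_total = sum(record$deg_table$is_de, na.rm = TRUE),
    n_de_up = length(up), n_de_down = length(down),
    n_samples_total = record$n_samples_total,
    n_samples_up = record$n_samples_up,
    n_samples_down = record$n_samples_down,
    description = description)
  record
}

#' Construct a compendium from comparison records
#'
#' @param comparisons list of \code{comparison_record}s with unique ids.
#' @return An object of class \code{compendium}: \code{comparisons}
#'   (named by id) and \code{universe} (union of detected genes).
#' @export
compendium <- function(comparisons = list()) {
  ids <- vapply(comparisons, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate comparison ids")
  names(comparisons) <- ids
  universe <- unique(unlist(lapply(comparisons, `[[`, "detected_genes"),
                            use.names = FALSE))
  structure(list(comparisons = comparisons,
                 universe = if (is.null(universe)) character(0) else universe),
            class = "compendium")
}

#' @export
print.compendium <- function(x, ...) {
  cat(sprintf("compendium: %d comparisons, %d genes in universe\n",
              length(x$comparisons), length(x$universe)))
  invisible(x)
}

#' @export
length.compendium <- function(x) length(x$comparisons)

#' Assemble a compendium with inclusion screening and annotation
#'
#' Applies \code{\link{check_inclusion}} and \code{\link{deg_count_filter}}
#' to every candidate, names the survivors, annotates them against the
#' pathway/TF databases, builds summary cards, and reports every exclusion
#' with its machine-readable reason.
#'
#' @param results list of entries, each a list with elements \code{de} (a
#'   \code{de_result}), \code{spec} (a \code{design_spec}), and optional
#'   \code{source} and \code{category}.
#' @param pathway_db,tf_db optional \code{gene_set_db}s for annotation.
#' @return list(compendium, report) where report is a data.frame of one
#'   row per candidate with its decision and reason.
#' @export
build_compendium <- function(results, pathway_db = NULL, tf_db = NULL) {
  records <- list()
  report <- data.frame(id = character(0), name = character(0),
                       included = logical(0), reason = character(0),
                       stringsAsFactors = FALSE)
  seen_names <- character(0)
  for (i in seq_along(results)) {
    entry <- results[[i]]
    sp <- entry$spec
    nm <- name_comparison(sp$study_id, sp$tissue, sp$cond1, sp$cond2)
    inc <- check_inclusion(sp)
    reason <- NA_character_
    if (!inc$include) {
      reason <- paste(inc$reasons, collapse = ";")
    } else {
      dc <- deg_count_filter(entry$de)
      if (!dc$keep) reason <- dc$reason
    }
    included <- is.na(reason)
    if (included) {
      id <- nm
      if (id %in% seen_names) {
        k <- sum(seen_names == id) + 1L
        message("duplicate comparison name '", id, "'; suffixing with .", k)
        id <- paste0(nm, ".", k)
      }
      seen_names <- c(seen_names, nm)
      src <- if (is.null(entry$source)) "synthetic" else entry$source
      cat_ <- if (is.null(entry$category)) "uncategorized" else entry$category
      rec <- comparison_record(
        id = id, name = nm, source = src, category = cat_,
        deg_table = entry$de$deg_table,
        detected_genes = entry$de$detected_genes,
        n_samples_total = sp$n1 + sp$n2,
        n_samples_up = sp$n2, n_samples_down = sp$n1)
      rec <- annotate_comparison(rec, pathway_db, tf_db)
      rec <- build_summary_card(rec)
      records[[id]] <- rec
    }
    report <- rbind(report, data.frame(id = nm, name = nm,
                                       included = included, reason = reason,
                                       stringsAsFactors = FALSE))
  }
  list(compendium = compendium(records), report = report)
}

#' Export a compendium's DEG lists as a gene-set database
#'
#' One gene set per comparison holding its DEGs, optionally restricted to
#' one direction of change; comparisons with no DEGs in the chosen
#' direction are omitted.
#'
#' @param comp a \code{compendium}.
#' @param direction all, up, or down (sign of log2fc).
#' @return A \code{gene_set_db}.
#' @export
compendium_to_gmt <- function(comp, direction = c("all", "up", "down")) {
  stopifnot(inherits(comp, "compendium"))
  if (!length(comp$comparisons)) stop("compendium is empty")
  direction <- match.arg(direction)
  sets <- lapply(comp$comparisons, function(r) rank_degs(r$deg_table, direction)$gene)
  sets <- sets[lengths(sets) > 0]
  if (!length(sets))
    return(structure(list(sets = list(), descriptions = character(0),
                          source_label = "compendium"),
                     class = "gene_set_db"))
  descr <- vapply(comp$comparisons[names(sets)], `[[`, character(1), "name")
  gene_set_db(sets, descr, source_label = "compendium")
}

#' Overlap statistics against a reference DEG list
#'
#' The validation arithmetic used when comparing a recomputed comparison
#' to the DEG list published by the original study: a Fisher/hypergeometric
#' overlap test within the background, the counts of atlas-specific,
#' study-specific, and intersecting DEGs, and "genes captured" — the
#' percentage of the study's DEGs recovered by the atlas.
#'
#' @param atlas_genes DEGs from the recomputed comparison.
#' @param study_genes DEGs reported by the original study.
#' @param background detected-gene background (defaults to the union).
#' @return list(n_atlas_specific, n_study_specific, n_intersect,
#'   genes_captured (percent), odds_ratio, pvalue).
#' @export
overlap_with_reference <- function(atlas_genes, study_genes, background = NULL) {
  atlas_genes <- unique(as.character(atlas_genes))
  study_genes <- unique(as.character(study_genes))
  if (is.null(background)) background <- union(atlas_genes, study_genes)
  background <- unique(as.character(background))
  atlas_genes <- intersect(atlas_genes, background)
  study_genes <- intersect(study_genes, background)
  inter <- intersect(atlas_genes, study_genes)
  ht <- hypergeom_overlap_test(length(inter), length(study_genes),
                               length(atlas_genes), length(background))
  list(n_atlas_specific = length(setdiff(atlas_genes, study_genes)),
       n_study_specific = length(setdiff(study_genes, atlas_genes)),
       n_intersect = length(inter),
       genes_captured = if (length(study_genes))
         100 * length(inter) / length(study_genes) else NA_real_,
       odds_ratio = ht$odds_ratio, pvalue = ht$pvalue)
}
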
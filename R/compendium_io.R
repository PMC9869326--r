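#' Save a compendium as plain-text files
#'
#' One DEG table TSV per comparison, an index TSV of comparison-level
#' fields, per-comparison detected-gene lists, annotation TSVs, and the
#' DEG lists as a GMT file — everything needed to reload the compendium
#' or to feed the GMT to external enrichment tools.
#'
#' @param comp a \code{compendium}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
save_compendium <- function(comp, dir) {
  stopifnot(inherits(comp, "compendium"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "deg_tables"), showWarnings = FALSE)
  dir.create(file.path(dir, "detected"), showWarnings = FALSE)
  dir.create(file.path(dir, "annotation"), showWarnings = FALSE)
  idx <- do.call(rbind, lapply(comp$comparisons, function(r) {
    data.frame(id = r$id, name = r$name, source = r$source,
               category = r$category, n_samples_total = r$n_samples_total,
               n_samples_up = r$n_samples_up,
               n_samples_down = r$n_samples_down,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(idx, file.path(dir, "index.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (r in comp$comparisons) {
    slug <- gsub("[^A-Za-z0-9._-]+", "_", r$id)
    utils::write.table(r$deg_table,
                       file.path(dir, "deg_tables", paste0(slug, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(r$detected_genes,
               file.path(dir, "detected", paste0(slug, ".txt")))
    for (field in c("enriched_pathways", "enriched_tfs")) {
      ann <- r[[field]]
      utils::write.table(ann, file.path(dir, "annotation",
                                        paste0(slug, ".", field, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (length(comp$comparisons)) {
    db <- compendium_to_gmt(comp, "all")
    if (length(db$sets)) write_gmt(db, file.path(dir, "compendium.gmt"))
  }
  writeLines(comp$universe, file.path(dir, "universe.txt"))
  invisible(dir)
}

#' Load a compendium saved by \code{\link{save_compendium}}
#'
#' @param dir directory written by \code{save_compendium}.
#' @return A \code{compendium}.
#' @export
load_compendium <- function(dir) {
  idx_path <- file.path(dir, "index.tsv")
  if (!file.exists(idx_path)) stop("not a compendium directory: ", dir)
  idx <- utils::read.delim(idx_path, stringsAsFactors = FALSE)
  records <- lapply(seq_len(nrow(idx)), function(i) {
    slug <- gsub("[^A-Za-z0-9._-]+", "_", idx$id[i])
    tab <- utils::read.delim(file.path(dir, "deg_tables", paste0(slug, ".tsv")),
                             stringsAsFactors = FALSE)
    detected <- readLines(file.path(dir, "detected", paste0(slug, ".txt")))
    r <- comparison_record(id = idx$id[i], name = idx$name[i],
                           source = idx$source[i], deg_table = tab,
                           detected_genes = detected,
                           category = idx$category[i],
                           n_samples_total = idx$n_samples_total[i],
                           n_samples_up = idx$n_samples_up[i],
                           n_samples_down = idx$n_samples_down[i])
    for (field in c("enriched_pathways", "enriched_tfs")) {
      p <- file.path(dir, "annotation", paste0(slug, ".", field, ".tsv"))
      if (file.exists(p)) {
        ann <- utils::read.delim(p, stringsAsFactors = FALSE,
                                 colClasses = c(term_id = "character"))
        if (nrow(ann)) r[[field]] <- ann
      }
    }
    build_summary_card(r)
  })
  comp <- compendium(records)
  upath <- file.path(dir, "universe.txt")
  if (file.exists(upath)) {
    stored <- readLines(upath)
    extra <- setdiff(stored, comp$universe)
    if (length(extra)) comp$universe <- c(comp$universe, extra)
  }
  comp
}
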
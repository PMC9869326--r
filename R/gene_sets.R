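#' Construct a gene-set database
#'
#' A gene-set database is an ordered collection of named gene sets, the
#' in-memory analogue of a Broad GMT file. Set ids must be unique; genes
#' within a set are de-duplicated, preserving first occurrence.
#'
#' @param sets named list of character vectors (names are set ids).
#' @param descriptions optional character vector of per-set descriptions,
#'   recycled from the set id when absent.
#' @param source_label free-text provenance label.
#' @return An object of class \code{gene_set_db}.
#' @export
gene_set_db <- function(sets, descriptions = NULL, source_label = "") {
  if (!is.list(sets)) stop("`sets` must be a named list of character vectors")
  ids <- names(sets)
  if (is.null(ids) || any(!nzchar(ids))) stop("every gene set needs a non-empty id")
  if (anyDuplicated(ids)) stop("duplicate gene-set ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sets <- lapply(sets, function(g) {
    g <- as.character(g)
    g <- g[nzchar(g)]
    unique(g)
  })
  if (any(lengths(sets) == 0L)) stop("gene sets must be non-empty")
  if (is.null(descriptions)) descriptions <- ids
  descriptions <- rep_len(as.character(descriptions), length(sets))
  names(descriptions) <- ids
  structure(list(sets = sets, descriptions = descriptions,
                 source_label = source_label),
            class = "gene_set_db")
}

#' @export
print.gene_set_db <- function(x, ...) {
  cat(sprintf("gene_set_db: %d sets%s\n", length(x$sets),
              if (nzchar(x$source_label)) paste0(" [", x$source_label, "]") else ""))
  sz <- lengths(x$sets)
  if (length(sz)) cat(sprintf("  set sizes: min %d, median %g, max %d\n",
                              min(sz), stats::median(sz), max(sz)))
  invisible(x)
}

#' @export
length.gene_set_db <- function(x) length(x$sets)

#' Read a GMT gene-set file
#'
#' Parses the Broad gene-matrix-transpose format: one set per line,
#' tab-separated fields \code{id}, \code{description}, then member genes.
#' Duplicate genes within a line are dropped, as are empty gene fields.
#'
#' @param path path to a GMT file.
#' @param source_label provenance label stored on the database.
#' @return A \code{gene_set_db}.
#' @export
read_gmt <- function(path, source_label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- vector("list", length(lines))
  descriptions <- character(length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields", i))
    ids[[i]] <- fields[[1]]
    descriptions[[i]] <- fields[[2]]
    sets[[i]] <- fields[-(1:2)]
  }
  names(sets) <- ids
  gene_set_db(sets, descriptions, source_label)
}

#' Write a gene-set database to GMT
#'
#' Inverse of \code{\link{read_gmt}} on (id, description, genes). Genes or
#' ids containing tab characters are rejected since they would corrupt the
#' format.
#'
#' @param db a \code{gene_set_db}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(db, path) {
  stopifnot(inherits(db, "gene_set_db"))
  if (!length(db$sets)) stop("refusing to write an empty gene_set_db")
  all_tokens <- c(names(db$sets), db$descriptions, unlist(db$sets, use.names = FALSE))
  if (any(grepl("\t", all_tokens, fixed = TRUE)))
    stop("ids, descriptions and genes must not contain tab characters")
  lines <- vapply(seq_along(db$sets), function(i) {
    paste(c(names(db$sets)[i], db$descriptions[[i]], db$sets[[i]]), collapse = "\t")
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Filter gene sets by size, optionally within a background universe
#'
#' Pathway annotation keeps sets of 15-2000 genes and transcription-factor
#' target annotation keeps 15-5000; when a universe is supplied each set is
#' intersected with it before its size is measured, so genes never detected
#' in the data do not count toward set size.
#'
#' @param db a \code{gene_set_db}.
#' @param min_size,max_size inclusive size window.
#' @param universe optional character vector of background genes.
#' @return A filtered \code{gene_set_db} (possibly with zero sets).
#' @export
filter_gene_sets <- function(db, min_size = 15L, max_size = 2000L, universe = NULL) {
  stopifnot(inherits(db, "gene_set_db"))
  if (!(min_size > 0 && min_size <= max_size))
    stop("need 0 < min_size <= max_size")
  sets <- db$sets
  if (!is.null(universe)) {
    universe <- unique(as.character(universe))
    sets <- lapply(sets, function(g) g[g %in% universe])
  }
  keep <- lengths(sets) >= min_size & lengths(sets) <= max_size
  out <- db
  out$sets <- sets[keep]
  out$descriptions <- db$descriptions[keep]
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; output order matches input order. NA values are
#' passed through and excluded from the adjustment.
#'
#' @param pvalues numeric vector in [0, 1] (NAs allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
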
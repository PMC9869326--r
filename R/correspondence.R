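#' Correspondence analysis of a nonnegative table
#'
#' Classical CA: with P the table scaled to sum 1 and r, c its margins,
#' the SVD of S = Dr^(-1/2) (P - r c') Dc^(-1/2) yields principal inertias
#' (squared singular values) summing to chi-square / grand total, and
#' principal row coordinates Dr^(-1/2) U D_sigma.
#'
#' @param M nonnegative numeric matrix, no all-zero row or column.
#' @return A list of class \code{ca_result} with elements
#'   \code{eigenvalues}, \code{row_scores}, \code{total_inertia},
#'   \code{k_selected} (filled by \code{\link{select_components}}).
#' @export
correspondence_analysis <- function(M) {
  M <- as.matrix(M)
  if (any(M < 0)) stop("CA requires a nonnegative table")
  total <- sum(M)
  if (total <= 0) stop("grand total must be positive")
  rs <- rowSums(M); cs <- colSums(M)
  if (any(rs == 0)) stop("all-zero row(s): ", paste(which(rs == 0), collapse = ", "))
  if (any(cs == 0)) stop("all-zero column(s): ", paste(which(cs == 0), collapse = ", "))
  P <- M / total
  r <- rs / total; cc <- cs / total
  S <- sweep(sweep(P - tcrossprod(r, cc), 1, sqrt(r), "/"), 2, sqrt(cc), "/")
  sv <- svd(S)
  keep <- seq_len(min(nrow(M), ncol(M)) - 1L)
  if (!length(keep)) keep <- 1L
  d <- sv$d[keep]
  eig <- d^2
  row_scores <- sweep(sv$u[, keep, drop = FALSE], 1, sqrt(r), "/")
  row_scores <- sweep(row_scores, 2, d, "*")
  rownames(row_scores) <- rownames(M)
  res <- list(eigenvalues = eig, row_scores = row_scores,
              total_inertia = sum(eig), k_selected = NA_integer_)
  class(res) <- "ca_result"
  res$k_selected <- select_components(eig)
  res
}

#' @export
print.ca_result <- function(x, ...) {
  cat(sprintf("correspondence analysis: %d components, total inertia %.4g, k = %d\n",
              length(x$eigenvalues), x$total_inertia, x$k_selected))
  invisible(x)
}

#' Scree-elbow component selection
#'
#' Operationalizes the visual elbow as the scree point with maximum
#' perpendicular distance to the chord joining the first and last
#' eigenvalues (ties toward the smaller index); the components retained
#' are those strictly before that elbow point, with a minimum of one. A
#' linear scree (all distances zero) or fewer than three eigenvalues
#' selects k = 1.
#'
#' @param eigenvalues nonnegative values in descending order.
#' @return Integer k >= 1.
#' @export
select_components <- function(eigenvalues) {
  m <- length(eigenvalues)
  if (m < 1L) stop("need at least one eigenvalue")
  if (m <= 2L) return(1L)
  x <- seq_len(m)
  # distance from (x_i, y_i) to the line through (1, y_1) and (m, y_m)
  dx <- m - 1
  dy <- eigenvalues[m] - eigenvalues[1]
  d <- abs(dy * x - dx * eigenvalues + dx * eigenvalues[1] - dy) / sqrt(dx^2 + dy^2)
  if (max(d) < .Machine$double.eps^0.5 * max(1, abs(eigenvalues[1]))) return(1L)
  max(1L, which.max(d) - 1L)
}

#' Build design covariates from mixed metadata
#'
#' The covariate pipeline used ahead of every differential comparison:
#' impute missing values, double continuous columns (Escoffier) and
#' indicator-code categorical columns, concatenate the blocks, run a
#' correspondence analysis, and keep the first k principal row coordinates
#' at the scree elbow. Variables equal to the comparison's condition (or
#' explicitly dropped) never enter; constant and single-level columns are
#' dropped with a warning.
#'
#' @param meta data.frame of per-sample metadata (will be imputed).
#' @param drop_variables column names to exclude (the condition variable
#'   and anything identical to it).
#' @param strata_column stratum column for imputation (see
#'   \code{\link{impute_metadata}}).
#' @param k override the selected number of components.
#' @return A samples x k numeric matrix; zero columns when no metadata
#'   column is usable.
#' @export
build_covariates <- function(meta, drop_variables = character(),
                             strata_column = "sex", k = NULL) {
  stopifnot(is.data.frame(meta))
  n <- nrow(meta)
  meta <- impute_metadata(meta, strata_column)
  use <- setdiff(names(meta), drop_variables)
  blocks <- list()
  for (col in use) {
    x <- meta[[col]]
    block <- if (is.numeric(x)) {
      if (length(unique(x)) < 2L) NULL else escoffier_transform(x)
    } else {
      if (length(unique(as.character(x))) < 2L) NULL else disjunctive_code(x)
    }
    if (is.null(block)) {
      warning("dropping uninformative metadata column: ", col)
    } else {
      colnames(block) <- paste(col, colnames(block), sep = ".")
      blocks[[col]] <- block
    }
  }
  if (!length(blocks)) {
    warning("no usable metadata columns; returning empty covariate matrix")
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  M <- do.call(cbind, blocks)
  ca <- correspondence_analysis(M)
  k_use <- if (is.null(k)) ca$k_selected else as.integer(k)
  k_use <- min(k_use, ncol(ca$row_scores))
  out <- ca$row_scores[, seq_len(k_use), drop = FALSE]
  colnames(out) <- paste0("CA", seq_len(k_use))
  out
}
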
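#' Impute missing metadata values
#'
#' Continuous columns get mean imputation stratified by a grouping column
#' (typically sex); categorical columns get the literal level "unknown".
#' When the stratum column is absent, not categorical, or itself has
#' missing values, continuous imputation falls back to the global mean.
#'
#' @param meta data.frame of per-sample metadata. Columns of type numeric
#'   are treated as continuous, everything else as categorical.
#' @param strata_column name of the stratifying column, or NULL.
#' @return The imputed data.frame.
#' @export
impute_metadata <- function(meta, strata_column = "sex") {
  stopifnot(is.data.frame(meta), nrow(meta) >= 1L)
  use_strata <- !is.null(strata_column) &&
    strata_column %in% names(meta) &&
    !is.numeric(meta[[strata_column]]) &&
    !anyNA(meta[[strata_column]])
  strata <- if (use_strata) as.character(meta[[strata_column]]) else rep("all", nrow(meta))
  for (col in names(meta)) {
    x <- meta[[col]]
    if (is.numeric(x)) {
      if (all(is.na(x)))
        stop("continuous column ", col, " is entirely missing; cannot impute")
      if (anyNA(x)) {
        for (s in unique(strata)) {
          idx <- strata == s
          m <- mean(x[idx], na.rm = TRUE)
          if (is.nan(m)) m <- mean(x, na.rm = TRUE)  # empty stratum -> global
          x[idx & is.na(x)] <- m
        }
        meta[[col]] <- x
      }
    } else {
      x <- as.character(x)
      x[is.na(x) | !nzchar(x)] <- "unknown"
      meta[[col]] <- x
    }
  }
  meta
}

#' Escoffier doubling of a continuous variable
#'
#' Rescales x linearly to z in [-1, 1] and returns the two complementary
#' columns ((1+z)/2, (1-z)/2), so every row sums to 1 and the variable can
#' enter a correspondence analysis with the same mass as an indicator-coded
#' categorical variable.
#'
#' @param x numeric vector with at least two distinct finite values.
#' @return A numeric matrix with columns \code{pos} and \code{neg}.
#' @export
escoffier_transform <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("x must be finite numeric")
  rng <- range(x)
  if (rng[1] == rng[2]) stop("constant column cannot be doubled")
  z <- 2 * (x - rng[1]) / (rng[2] - rng[1]) - 1
  cbind(pos = (1 + z) / 2, neg = (1 - z) / 2)
}

#' Disjunctive (one-hot) coding of a categorical variable
#'
#' One indicator column per level, columns ordered by sorted level name;
#' each row has exactly one 1.
#'
#' @param x character or factor vector with at least two observed levels.
#' @return A 0/1 matrix with one column per level.
#' @export
disjunctive_code <- function(x) {
  x <- as.character(x)
  levs <- sort(unique(x))
  if (length(levs) < 2L) stop("categorical column has fewer than 2 observed levels")
  out <- vapply(levs, function(l) as.numeric(x == l), numeric(length(x)))
  dimnames(out) <- list(NULL, levs)
  out
}
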
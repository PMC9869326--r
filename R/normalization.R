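#' Median-of-ratios size factors
#'
#' Per-gene geometric-mean reference computed over genes with positive
#' counts in every sample; each sample's factor is the median of its
#' count/reference ratios, rescaled so the factors have geometric mean 1.
#'
#' @param counts genes x samples nonnegative integer matrix.
#' @param pseudo_reference when TRUE, fall back to a reference computed
#'   with a 0.5 pseudocount if no gene is positive in all samples.
#' @return Positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  counts <- as.matrix(counts)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    if (!pseudo_reference)
      stop("no gene has positive counts in every sample; ",
           "set pseudo_reference = TRUE to use a pseudocount reference")
    work <- counts + 0.5
    all_pos <- rep(TRUE, nrow(work))
  } else {
    work <- counts
  }
  log_ref <- rowMeans(log(work[all_pos, , drop = FALSE]))
  sf <- apply(work[all_pos, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - log_ref))
  })
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(counts)
  sf
}
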
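#' Median-of-ratios size factors
#'
#' Per-sample scaling factors computed as the median across features of
#' the ratio of each sample's counts to the feature-wise geometric mean,
#' using only features with all-positive counts.
#'
#' @param counts Feature-by-sample count matrix.
#' @return Named numeric vector of size factors (geometric mean 1 when
#'   possible).
#' @export
size_factors <- function(counts) {
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no feature has positive counts in all samples")
  lg <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(lg, 2, function(col) exp(median(col - geo)))
  sf / exp(mean(log(sf)))
}

#' Variance-stabilizing transform stand-in
#'
#' `log2(normalized count + 1)` with median-of-ratios normalization.  This
#' is a deliberately simple variance-stabilizing transform used wherever
#' continuous expression values are needed (mediation, co-expression);
#' its behaviour for the statistics computed here tracks more elaborate
#' dispersion-aware transforms at the count depths the package targets.
#'
#' @param counts Feature-by-sample count matrix.
#' @param sf Optional precomputed size factors.
#' @return Matrix of transformed values, same dimensions as `counts`.
#' @export
vst_counts <- function(counts, sf = size_factors(counts)) {
  log2(sweep(counts, 2, sf, "/") + 1)
}
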
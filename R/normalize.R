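# Median-of-ratios size factors and depth normalization. This is the
# size-factor step of negative-binomial count normalization: each sample is
# scaled by the median, over reference genes, of its ratio to the per-gene
# geometric mean.

#' Median-of-ratios size factors
#'
#' Reference genes are rows with a nonzero count in every sample; for each
#' such gene the geometric mean across samples is computed, and a sample's
#' size factor is the median of its count/geometric-mean ratios. When no row
#' is nonzero everywhere, falls back to total-count scaling (column totals
#' scaled to geometric mean 1) with a warning.
#'
#' @param counts Counts tibble or matrix.
#' @return Named numeric vector of strictly positive size factors.
#' @export
size_factors <- function(counts) {
  m <- counts_matrix(counts)
  ref <- rowSums(m == 0) == 0
  if (!any(ref)) {
    warning("no gene has nonzero counts in all samples; ",
            "falling back to total-count size factors")
    tot <- colSums(m)
    return(tot / exp(mean(log(tot))))
  }
  lm <- log(m[ref, , drop = FALSE])
  loggeo <- rowMeans(lm)
  apply(lm, 2, function(col) exp(median(col - loggeo)))
}

#' Normalize counts by size factors
#'
#' @param counts Counts tibble or matrix.
#' @param sf Size factors; computed with [size_factors()] when NULL.
#' @return List with `normalized` (tibble of counts / size factor) and
#'   `size_factors`.
#' @export
normalize_counts <- function(counts, sf = NULL) {
  m <- counts_matrix(counts)
  if (is.null(sf)) sf <- size_factors(m)
  stopifnot(all(sf > 0), length(sf) == ncol(m))
  list(normalized = counts_tbl(sweep(m, 2, sf, "/")),
       size_factors = sf)
}
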
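#' Fractional read-count table for one tier
#'
#' Multi-mapped reads contribute `1/n` to each of the `n` references tied
#' for their best placement, so each sample column sums to its mapped read
#' count for the tier.
#'
#' @param mapping_results named list of `mapping_result` objects, one per
#'   sample.
#' @param reference_set the common `reference_set` (fixes the row universe).
#' @param tier `"mature"` (default) or `"precursor"`.
#' @return numeric matrix, rows = ref ids, columns = samples.
#' @export
count_reads <- function(mapping_results, reference_set, tier = "mature") {
  refs <- vapply(reference_set[[tier]], `[[`, "", "ref_id")
  samples <- names(mapping_results)
  if (is.null(samples)) samples <- paste0("sample", seq_along(mapping_results))
  m <- matrix(0, nrow = length(refs), ncol = length(mapping_results),
              dimnames = list(refs, samples))
  for (j in seq_along(mapping_results)) {
    w <- fractional_weights(mapping_results[[j]])
    w <- w[w$tier == tier, , drop = FALSE]
    if (nrow(w)) {
      agg <- tapply(w$weight, w$ref_id, sum)
      m[names(agg), j] <- as.numeric(agg)
    }
  }
  m
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over references of the
#' ratio of that sample's count to the reference's geometric mean across
#' samples; references with a zero count in any sample are excluded from
#' the median. This is the classic count-normalization used for comparing
#' library depths without assuming equal totals.
#'
#' @param count_table matrix from [count_reads()] (>= 2 samples).
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(count_table) {
  stopifnot(ncol(count_table) >= 2L)
  keep <- apply(count_table > 0, 1L, all)
  if (!any(keep))
    stop("no reference has nonzero counts in all samples")
  lg <- log(count_table[keep, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(lg, 2L, function(col) exp(median(col - geo)))
  if (any(!is.finite(sf) | sf <= 0)) stop("degenerate size factors")
  sf
}

#' Apply size-factor normalization
#'
#' @param count_table matrix from [count_reads()].
#' @param factors size factors (computed with [size_factors()] if omitted).
#' @return normalized matrix (`count / factor` per column).
#' @export
normalize_counts <- function(count_table, factors = NULL) {
  if (is.null(factors)) factors <- size_factors(count_table)
  sweep(count_table, 2L, factors, "/")
}

#' Cross-sample correlation of normalized log counts
#'
#' @param normalized_table matrix from [normalize_counts()].
#' @param pair length-2 character (or index) vector naming the two samples.
#' @param pseudo pseudo-count added before `log2` (default 1).
#' @return list with `pearson_r` (`NA` for a degenerate constant column)
#'   and `scatter` (data.frame `ref_id`, `x`, `y` of log2 normalized
#'   counts, plot-ready).
#' @export
correlation_summary <- function(normalized_table, pair, pseudo = 1) {
  stopifnot(length(pair) == 2L)
  x <- log2(normalized_table[, pair[1]] + pseudo)
  y <- log2(normalized_table[, pair[2]] + pseudo)
  r <- if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
  list(pearson_r = r,
       scatter = data.frame(ref_id = rownames(normalized_table),
                            x = unname(x), y = unname(y),
                            stringsAsFactors = FALSE))
}
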
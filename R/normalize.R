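#' Filter low-information samples and strains
#'
#' Drops samples whose total assigned reads fall below `min_sample_reads`,
#' then strains whose total across the remaining samples falls below
#' `min_strain_reads`. The dropped ids are recorded in the attributes
#' `dropped_samples` / `dropped_strains`. The operation is idempotent.
#'
#' @param counts Count matrix or `barseq_counts`.
#' @param min_sample_reads Minimum sample total (default 15).
#' @param min_strain_reads Minimum strain total (default 3).
#' @return Filtered count matrix.
#' @export
filter_counts <- function(counts, min_sample_reads = 15L,
                          min_strain_reads = 3L) {
  stopifnot(min_sample_reads >= 0, min_strain_reads >= 0)
  m <- .counts(counts)
  keep_s <- colSums(m) >= min_sample_reads
  if (!any(keep_s)) {
    stop("all ", ncol(m), " samples fall below ", min_sample_reads,
         " assigned reads; sample totals range ",
         paste(range(colSums(m)), collapse = "-"))
  }
  dropped_samples <- colnames(m)[!keep_s]
  m <- m[, keep_s, drop = FALSE]
  keep_g <- rowSums(m) >= min_strain_reads
  dropped_strains <- rownames(m)[!keep_g]
  m <- m[keep_g, , drop = FALSE]
  attr(m, "dropped_samples") <- dropped_samples
  attr(m, "dropped_strains") <- dropped_strains
  m
}

#' RLE (median-of-ratios) size factors
#'
#' Per-sample scale factors by the relative-log-expression method: the
#' reference for each strain is its geometric mean across samples (computed
#' over strains with no zero count), and the factor for sample `j` is the
#' median over those strains of `count[i, j] / reference[i]`. The raw
#' median-of-ratios convention is used (factors carry sequencing depth; they
#' are not rescaled to geometric mean 1), so `log(c_j)` serves directly as the
#' GLM offset. Because each strain is compared only to its own reference, the
#' factors are exactly invariant to multiplying any one strain's counts by a
#' constant in every sample.
#'
#' When counts contain zeros the strict estimator restricts both the reference
#' and the median to the strains that are nonzero everywhere — a subset that,
#' in a competition assay, is enriched for high-fitness strains and can bias
#' the factors. `pseudo_reference = TRUE` instead computes each strain's
#' reference over its positive counts and takes the per-sample median over all
#' strains with a positive count (the positive-counts variant); on zero-free
#' matrices the two are identical.
#'
#' @param counts Count matrix or `barseq_counts`.
#' @param pseudo_reference If `TRUE`, use the positive-counts variant (also
#'   the required fallback when no strain is nonzero in all samples).
#' @return Named positive numeric vector of per-sample factors.
#' @export
rle_size_factors <- function(counts, pseudo_reference = FALSE) {
  m <- .counts(counts)
  all_pos <- rowSums(m == 0) == 0L
  if (!any(all_pos) && !pseudo_reference) {
    stop("no strain has nonzero counts in every sample; ",
         "rerun with pseudo_reference = TRUE")
  }
  if (!pseudo_reference) {
    sub <- m[all_pos, , drop = FALSE]
    ref <- exp(rowMeans(log(sub)))
    ratios <- sub / ref
  } else {
    logs <- log(m)
    logs[!is.finite(logs)] <- NA
    ref <- exp(rowMeans(logs, na.rm = TRUE))
    ratios <- m / ref
    ratios[m == 0] <- NA
  }
  cf <- apply(ratios, 2L, stats::median, na.rm = TRUE)
  if (any(!is.finite(cf)) || any(cf <= 0)) {
    stop("degenerate size factors; check for samples with no usable counts")
  }
  cf
}

#' Normalized log2 counts
#'
#' `log2(count / size_factor + prior_count)`: the pseudo-count is added on the
#' normalized scale, so jointly rescaling a sample's counts and its size
#' factor leaves the values unchanged. Used for descriptive outputs
#' (clustering, CVs, reporting); inference uses offsets on the raw counts,
#' never these values.
#'
#' @param counts Count matrix or `barseq_counts`.
#' @param size_factors Per-sample factors (default: [rle_size_factors()]).
#' @param prior_count Pseudo-count stabilizing the log at zero (default 0.5).
#' @return Real-valued strain-by-sample matrix.
#' @export
normalized_log_counts <- function(counts, size_factors = NULL,
                                  prior_count = 0.5) {
  m <- .counts(counts)
  if (is.null(size_factors)) size_factors <- rle_size_factors(m)
  stopifnot(prior_count > 0, length(size_factors) == ncol(m),
            all(size_factors > 0))
  log2(sweep(m, 2L, size_factors, "/") + prior_count)
}
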
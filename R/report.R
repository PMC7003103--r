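#' Optical-density calibration model
#'
#' The log-log line relating absorbance at 600 nm to viable cell number:
#' `log10(cells) = slope * log10(abs) + intercept`. The published calibration
#' for semi-anaerobic growth in defined medium has slope 1.011 and intercept
#' 7.489.
#'
#' @param slope Log10 cells per log10 absorbance unit (> 0).
#' @param intercept Log10 cells at absorbance 1.
#' @return An `od_calibration` object.
#' @export
calibration_model <- function(slope, intercept) {
  stopifnot(is.finite(slope), is.finite(intercept))
  if (slope <= 0) stop("calibration slope must be positive (monotone model)")
  structure(list(slope = slope, intercept = intercept),
            class = "od_calibration")
}

#' Fit the OD-to-cell-number calibration
#'
#' Ordinary least squares of `log10(cells)` on `log10(absorbance)`.
#'
#' @param absorbance Positive absorbance readings (>= 3 points, or exactly 2
#'   for the interpolating line).
#' @param cells Positive cell counts, same length.
#' @return An `od_calibration` with the underlying `lm` in `$fit`.
#' @export
fit_calibration <- function(absorbance, cells) {
  stopifnot(length(absorbance) == length(cells))
  if (length(absorbance) < 2L) stop("need at least 2 calibration points")
  if (any(absorbance <= 0) || any(cells <= 0)) {
    stop("calibration points must be strictly positive")
  }
  x <- log10(absorbance)
  if (stats::var(x) < 1e-12) {
    stop("degenerate calibration: no variance in log10(absorbance)")
  }
  fit <- stats::lm(log10(cells) ~ x)
  model <- calibration_model(unname(stats::coef(fit)[2L]),
                             unname(stats::coef(fit)[1L]))
  model$fit <- fit
  model
}

#' @export
print.od_calibration <- function(x, ...) {
  cat(sprintf("OD600 calibration: log10(cells) = %.4g * log10(abs) + %.4g\n",
              x$slope, x$intercept))
  invisible(x)
}

#' Estimate cell numbers from absorbance
#'
#' `cells = 10 ^ (slope * log10(absorbance) + intercept)`; strictly increasing
#' in absorbance.
#'
#' @param absorbance Positive absorbance value(s).
#' @param model An `od_calibration`.
#' @return Estimated cell numbers.
#' @examples
#' od_to_cells(1.0, calibration_model(1.011, 7.489))  # 10^7.489 cells
#' @export
od_to_cells <- function(absorbance, model) {
  stopifnot(inherits(model, "od_calibration"))
  if (any(absorbance <= 0)) stop("absorbance must be positive")
  10^(model$slope * log10(absorbance) + model$intercept)
}

#' @export
predict.od_calibration <- function(object, absorbance, ...) {
  od_to_cells(absorbance, object)
}

#' Classify strain tolerance from grouped contrasts
#'
#' A strain is called `tolerant` in a condition group when at least
#' `min_support` of the group's contrasts are significant (FDR below `fdr`)
#' with positive log fold-change, `sensitive` likewise with negative
#' fold-change, and `unclassified` otherwise (including mixed signs among the
#' significant contrasts). The mean and SD of the group's fold-changes are
#' reported alongside. With `rule = "mean"`, significance support is tallied
#' the same way but the sign comes from the mean fold-change across the group.
#'
#' @param results A fitness table ([fitness_table()] output, possibly from
#'   several fits combined with `rbind`) with columns `strain`, `contrast`,
#'   `logFC`, `fdr`.
#' @param contrast_group Character vector of contrast names forming the group
#'   (e.g. the three "copper only" contrasts).
#' @param min_support Minimum number of supporting contrasts (default 2).
#' @param fdr Significance threshold (default 0.05).
#' @param rule `"support"` (same-sign significant contrasts, default) or
#'   `"mean"`.
#' @return A `tolerance_call` data frame: `strain`, `label`, `n_significant`,
#'   `support`, `mean_logFC`, `sd_logFC`, `n_contrasts`.
#' @export
classify_tolerance <- function(results, contrast_group, min_support = 2L,
                               fdr = 0.05, rule = c("support", "mean")) {
  rule <- match.arg(rule)
  stopifnot(length(contrast_group) >= 1L, min_support >= 1L,
            min_support <= length(contrast_group))
  req <- c("strain", "contrast", "logFC", "fdr")
  if (!all(req %in% names(results))) {
    stop("results needs columns: ", paste(req, collapse = ", "))
  }
  sub <- results[results$contrast %in% contrast_group, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no rows match the requested contrast group")
  out <- do.call(rbind, lapply(split(sub, sub$strain), function(d) {
    sig <- !is.na(d$fdr) & d$fdr < fdr & !is.na(d$logFC)
    n_pos <- sum(sig & d$logFC > 0)
    n_neg <- sum(sig & d$logFC < 0)
    label <- "unclassified"
    support <- 0L
    if (rule == "support") {
      if (n_pos >= min_support && n_neg == 0L) {
        label <- "tolerant"; support <- n_pos
      } else if (n_neg >= min_support && n_pos == 0L) {
        label <- "sensitive"; support <- n_neg
      }
    } else {
      mlf <- mean(d$logFC, na.rm = TRUE)
      if (sum(sig) >= min_support && n_pos * n_neg == 0L) {
        label <- if (mlf > 0) "tolerant" else "sensitive"
        support <- sum(sig)
      }
    }
    data.frame(strain = d$strain[1L], label = label,
               n_significant = n_pos + n_neg, support = support,
               mean_logFC = mean(d$logFC, na.rm = TRUE),
               sd_logFC = stats::sd(d$logFC, na.rm = TRUE),
               n_contrasts = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("tolerance_call", "data.frame")
  out
}

#' Hierarchically cluster a fitness matrix
#'
#' Agglomerative clustering of strains and of treatments with Euclidean
#' distance and Ward.D2 linkage (distances are not pre-squared; the squared
#' update happens inside the Lance-Williams recurrence), the standard recipe
#' for fitness-profile heatmaps. Missing values are imputed as 0 (neutral)
#' with a flag.
#'
#' @param fitness_matrix Strains-by-treatments matrix of log2 fold-changes.
#' @return A `fitness_clustering` list: `row_hclust`, `col_hclust`,
#'   `row_order`, `col_order`, the reordered `matrix`, and `imputed`.
#' @export
cluster_fitness <- function(fitness_matrix) {
  m <- as.matrix(fitness_matrix)
  if (nrow(m) < 2L) stop("clustering needs at least 2 rows")
  imputed <- any(is.na(m))
  m[is.na(m)] <- 0
  row_h <- stats::hclust(stats::dist(m), method = "ward.D2")
  col_h <- if (ncol(m) >= 2L) {
    stats::hclust(stats::dist(t(m)), method = "ward.D2")
  } else NULL
  structure(
    list(row_hclust = row_h, col_hclust = col_h,
         row_order = rownames(m)[row_h$order],
         col_order = if (is.null(col_h)) colnames(m) else
           colnames(m)[col_h$order],
         matrix = m[row_h$order,
                    if (is.null(col_h)) seq_len(ncol(m)) else col_h$order,
                    drop = FALSE],
         imputed = imputed),
    class = "fitness_clustering"
  )
}

#' @export
print.fitness_clustering <- function(x, ...) {
  cat("Ward.D2 fitness clustering:", nrow(x$matrix), "strains x",
      ncol(x$matrix), "treatments",
      if (x$imputed) "(missing values imputed as 0)" else "", "\n")
  invisible(x)
}

#' Write a clustered fitness matrix with leaf orders
#'
#' @param clustering A `fitness_clustering`.
#' @param path TSV output path.
#' @export
write_clustered_fitness <- function(clustering, path) {
  df <- data.frame(strain = rownames(clustering$matrix), clustering$matrix,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cross-batch correlation of reference fitness
#'
#' Spearman rank correlation of per-strain reference-condition fitness between
#' every pair of batches, computed over the strains the pair shares. Batches
#' sharing fewer than 3 strains get `NA` with a warning.
#'
#' @param reference_fitness_by_batch Either a named list of named numeric
#'   vectors (strain -> reference logFC per batch), or a named list of
#'   `barseq_fit` objects (their `"reference"` contrast is used).
#' @return Symmetric matrix of Spearman rho, batches as rows/columns.
#' @export
cross_batch_correlation <- function(reference_fitness_by_batch) {
  x <- lapply(reference_fitness_by_batch, function(b) {
    if (inherits(b, "barseq_fit")) {
      v <- stats::setNames(b$logFC[, "reference"], rownames(b$logFC))
      v[!is.na(v)]
    } else b
  })
  if (length(x) < 2L) stop("need at least 2 batches")
  if (is.null(names(x))) names(x) <- paste0("batch", seq_along(x))
  k <- length(x)
  rho <- matrix(NA_real_, k, k, dimnames = list(names(x), names(x)))
  diag(rho) <- 1
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      shared <- intersect(names(x[[i]]), names(x[[j]]))
      if (length(shared) < 3L) {
        warning("batches ", names(x)[i], " and ", names(x)[j], " share fewer ",
                "than 3 strains; correlation set to NA")
        next
      }
      rho[i, j] <- rho[j, i] <- stats::cor(x[[i]][shared], x[[j]][shared],
                                           method = "spearman")
    }
  }
  rho
}
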
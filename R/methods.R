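#' @export
print.barseq_fit <- function(x, ...) {
  cat("Bar-seq competitive fitness fit\n")
  cat("  ", nrow(x$counts), "strains x", ncol(x$counts), "samples;",
      "reference:", x$reference, "; contrast:", x$t_late, "vs", x$t_early, "\n")
  cat("  contrasts:", paste(colnames(x$logFC), collapse = ", "), "\n")
  cat("  common NB dispersion:", signif(x$dispersions$common, 3), "\n")
  invisible(x)
}

#' Extract log2 fold-changes
#'
#' @param object A `barseq_fit`.
#' @param ... Unused.
#' @return Strains-by-contrasts matrix of log2 fold-changes (the fitness
#'   estimates: `reference` is late-vs-early change in the reference medium,
#'   treatment columns are difference-in-differences against it).
#' @method coef barseq_fit
#' @export
coef.barseq_fit <- function(object, ...) object$logFC

#' @export
fitted.barseq_fit <- function(object, ...) object$glm$fitted

#' Residuals of the per-strain GLM fits
#'
#' @param object A `barseq_fit`.
#' @param type `"pearson"` (NB variance at the shrunk dispersion) or
#'   `"deviance"`-style raw residuals on the log scale.
#' @param ... Unused.
#' @return Strain-by-sample residual matrix.
#' @method residuals barseq_fit
#' @export
residuals.barseq_fit <- function(object, type = c("pearson", "raw"), ...) {
  type <- match.arg(type)
  y <- object$counts
  mu <- object$glm$fitted
  if (type == "raw") return(y - mu)
  phi <- object$dispersions$shrunk
  v <- mu * (1 + phi * mu)
  r <- (y - mu) / sqrt(v)
  r[v == 0] <- 0
  r
}

#' @method summary barseq_fit
#' @export
summary.barseq_fit <- function(object, fdr = object$fdr_threshold, ...) {
  sig <- object$fdr < fdr
  res <- data.frame(
    contrast = colnames(object$logFC),
    n_tested = colSums(!is.na(object$p_value)),
    n_flagged = colSums(object$flagged, na.rm = TRUE),
    n_significant = colSums(sig, na.rm = TRUE),
    n_up = colSums(sig & object$logFC > 0, na.rm = TRUE),
    n_down = colSums(sig & object$logFC < 0, na.rm = TRUE),
    row.names = NULL
  )
  structure(list(contrasts = res, fdr = fdr,
                 dispersion = object$dispersions,
                 dropped_samples = attr(object$counts, "dropped_samples"),
                 dropped_strains = attr(object$counts, "dropped_strains")),
            class = "summary.barseq_fit")
}

#' @export
print.summary.barseq_fit <- function(x, ...) {
  cat("Per-contrast results (FDR <", x$fdr, "):\n")
  print(x$contrasts, row.names = FALSE)
  print(x$dispersion)
  if (length(x$dropped_samples)) {
    cat("Filtered samples:", paste(x$dropped_samples, collapse = ", "), "\n")
  }
  if (length(x$dropped_strains)) {
    cat("Filtered strains:", paste(x$dropped_strains, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Long-format fitness result table
#'
#' One row per strain and contrast: log2 fold-change, moderated F statistic,
#' p-value, BH-adjusted FDR and the degenerate-strain flag — the shape used
#' for on-disk export of all pairwise comparisons.
#'
#' @param fit A `barseq_fit`.
#' @return A data frame.
#' @export
fitness_table <- function(fit) {
  stopifnot(inherits(fit, "barseq_fit"))
  fit$table
}

#' @rdname fitness_table
#' @param path TSV output path.
#' @export
write_fitness_table <- function(fit, path) {
  utils::write.table(fitness_table(fit), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Plot a fitness fit
#'
#' With two or more contrasts, draws a Ward.D2-clustered heatmap of the log2
#' fold-change matrix; with one contrast, a histogram of fold-changes.
#'
#' @param x A `barseq_fit`.
#' @param ... Passed to the underlying graphics call.
#' @method plot barseq_fit
#' @export
plot.barseq_fit <- function(x, ...) {
  lf <- x$logFC
  lf[is.na(lf)] <- 0
  if (ncol(lf) >= 2L && nrow(lf) >= 2L) {
    cl <- cluster_fitness(lf)
    stats::heatmap(lf, Rowv = stats::as.dendrogram(cl$row_hclust),
                   Colv = stats::as.dendrogram(cl$col_hclust),
                   scale = "none", xlab = "contrast", ylab = "strain", ...)
  } else {
    graphics::hist(lf[, 1L], breaks = 30,
                   main = colnames(lf)[1L], xlab = "log2 fold-change", ...)
  }
  invisible(x)
}
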
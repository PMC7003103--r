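## ---- per-strain GLM machinery -------------------------------------------
##
## Coefficients solve the quasi-Poisson score equations X'(y - mu) = 0 with a
## log link and known offsets. Under any saturated treatment:time encoding the
## fitted cell mean is the offset-adjusted arithmetic mean of the cell's
## counts, sum(y)/sum(exp(o)) — an estimator that does not depend on the
## dispersion, is identical across reparameterizations, and is exactly
## equivariant under per-strain scaling (the extraction-bias cancellation).
## The negative-binomial dispersion enters only the covariance and the
## quasi-likelihood F-test.

## Per-cell totals: sum(y) and sum(exp(offset)) for one strain.
cell_totals <- function(y, cells, eo) {
  list(y = rowsum(y, cells)[, 1L], eo = rowsum(eo, cells)[, 1L])
}

#' Fit per-strain GLMs under the cell-means design
#'
#' Fits a log-link GLM with known offsets to every strain (row) of a count
#' matrix. For the cell-means encoding the solution is closed-form (the
#' offset-adjusted cell mean); for other encodings iteratively reweighted
#' least squares is used. Returns coefficients on the natural-log scale plus
#' fitted means.
#'
#' @param counts Count matrix (strains x samples).
#' @param design A [build_design()] matrix.
#' @param offsets Per-sample offsets on the natural-log scale, normally
#'   `log(rle_size_factors(counts))`.
#' @return An `nb_glm_fit` list: `coefficients` (strains x coefficients),
#'   `fitted` (strains x samples mean matrix), `cell_log_means`, `cell_totals`
#'   and bookkeeping used by [test_contrast()].
#' @export
fit_nb_glm <- function(counts, design, offsets) {
  m <- .counts(counts)
  stopifnot(length(offsets) == ncol(m), all(is.finite(offsets)))
  cells <- attr(design, "cells")
  if (is.null(cells)) stop("design must come from build_design()")
  eo <- exp(offsets)
  cell_levels <- rownames(attr(design, "cell_rows"))
  n_cells <- length(cell_levels)

  tot_y <- rowsum(t(m), cells)                      # cells x strains
  tot_eo <- rowsum(eo, cells)[, 1L]
  tot_y <- t(tot_y[cell_levels, , drop = FALSE])    # strains x cells
  tot_eo <- tot_eo[cell_levels]
  clm <- log(sweep(tot_y, 2L, tot_eo, "/"))         # -Inf where cell total 0

  type <- attr(design, "type")
  if (identical(type, "cell_means")) {
    beta <- clm[, colnames(design), drop = FALSE]
  } else {
    beta <- matrix(NA_real_, nrow(m), ncol(design),
                   dimnames = list(rownames(m), colnames(design)))
    ctrl <- stats::glm.control(epsilon = 1e-12, maxit = 200L)
    for (i in seq_len(nrow(m))) {
      fit <- suppressWarnings(
        stats::glm.fit(design, m[i, ], offset = offsets,
                       family = stats::quasipoisson(), control = ctrl))
      beta[i, ] <- fit$coefficients
    }
  }
  ## fitted means from cell means (encoding-independent, exact)
  mu <- exp(clm)[, cells, drop = FALSE] * rep(eo, each = nrow(m))
  colnames(mu) <- colnames(m)
  structure(
    list(coefficients = beta, fitted = mu, cell_log_means = clm,
         cell_totals = tot_y, cell_eo = tot_eo, cells = cells,
         cell_rows = attr(design, "cell_rows"), counts = m,
         offsets = offsets, design = design,
         df_residual = ncol(m) - n_cells),
    class = "nb_glm_fit"
  )
}

## Pearson statistic for one strain at dispersion phi (terms with mu = 0
## contribute 0: there y = 0 and the cell is exactly fitted).
pearson_stat <- function(y, mu, phi) {
  ok <- mu > 0
  sum((y[ok] - mu[ok])^2 / (mu[ok] * (1 + phi * mu[ok])))
}

## Solve pearson_stat(phi) = target for phi >= 0 (monotone decreasing).
solve_phi <- function(y, mu, target) {
  if (target <= 0) return(0)
  if (pearson_stat(y, mu, 0) <= target) return(0)
  upper <- 1
  while (pearson_stat(y, mu, upper) > target && upper < 1e6) upper <- upper * 4
  stats::uniroot(function(p) pearson_stat(y, mu, p) - target,
                 c(0, upper), tol = 1e-10)$root
}

#' Estimate negative-binomial dispersions
#'
#' Method-of-moments dispersion estimation on the cell-means fit: the raw
#' per-strain dispersion solves `Pearson X^2(phi) = residual df`; a common
#' dispersion solves the pooled equation across strains; and per-strain values
#' are shrunk toward the common value by an empirical-Bayes weighted average
#' with `prior_df` prior degrees of freedom, so each shrunk value lies between
#' its raw estimate and the common one.
#'
#' @param counts Count matrix.
#' @param design A [build_design()] matrix.
#' @param offsets Per-sample log offsets.
#' @param prior_df Prior degrees of freedom for the shrinkage (default 10).
#' @param fit Optionally a precomputed [fit_nb_glm()] object.
#' @return A `dispersion_estimate` list: `common`, `raw`, `shrunk`,
#'   `prior_df`, `df_residual`.
#' @export
estimate_dispersions <- function(counts, design, offsets, prior_df = 10,
                                 fit = NULL) {
  stopifnot(prior_df > 0)
  if (is.null(fit)) fit <- fit_nb_glm(counts, design, offsets)
  m <- fit$counts
  mu <- fit$fitted
  df <- fit$df_residual
  if (df < 1L) {
    warning("zero residual degrees of freedom; per-strain dispersions set ",
            "to the common value")
  }
  usable <- rowSums(m) > 0
  raw <- rep(NA_real_, nrow(m))
  names(raw) <- rownames(m)
  for (i in which(usable)) {
    raw[i] <- if (df >= 1L) solve_phi(m[i, ], mu[i, ], df) else NA_real_
  }
  ## common value: pooled Pearson equation across usable strains
  pooled <- function(phi) {
    sum(vapply(which(usable), function(i) pearson_stat(m[i, ], mu[i, ], phi),
               numeric(1))) - df * sum(usable)
  }
  common <- if (df >= 1L && pooled(0) > 0) {
    upper <- 1
    while (pooled(upper) > 0 && upper < 1e6) upper <- upper * 4
    stats::uniroot(pooled, c(0, upper), tol = 1e-10)$root
  } else 0
  shrunk <- ifelse(is.na(raw) | df < 1L, common,
                   (prior_df * common + df * raw) / (prior_df + df))
  structure(list(common = common, raw = raw, shrunk = shrunk,
                 prior_df = prior_df, df_residual = df),
            class = "dispersion_estimate")
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat("NB dispersion: common =", signif(x$common, 4),
      "| shrunk per-strain median =",
      signif(stats::median(x$shrunk, na.rm = TRUE), 4),
      "| prior df =", x$prior_df,
      "| residual df =", x$df_residual, "\n")
  invisible(x)
}

#' Quasi-likelihood test of fitness contrasts
#'
#' For each strain and contrast: the estimate is the contrast of fitted cell
#' log-means; its variance comes from the negative-binomial variance function
#' at the shrunk dispersion (delta method on the offset-adjusted cell means);
#' a per-strain quasi-dispersion (Pearson statistic / residual df) is
#' empirical-Bayes squeezed across strains; and the moderated F statistic
#' `est^2 / (var * s2_post)` is referred to F(1, residual df + prior df),
#' two-sided. Strains with zero counts in every sample of a contrast cell are
#' flagged: their log fold-change is reported with a `prior_count` fallback
#' and their p-value is `NA` (excluded from the FDR denominator).
#'
#' @param fit An [fit_nb_glm()] object.
#' @param contrast Contrast vector in coefficient space, or a
#'   coefficients-by-contrasts matrix from [fitness_contrasts()].
#' @param dispersions An [estimate_dispersions()] object.
#' @param prior_count Pseudo-count for flagged strains' fold-changes.
#' @return A data frame per strain x contrast: `strain`, `contrast`, `logFC`
#'   (log2), `statistic`, `p_value`, `flagged`.
#' @export
test_contrast <- function(fit, contrast, dispersions, prior_count = 0.5) {
  stopifnot(inherits(fit, "nb_glm_fit"),
            inherits(dispersions, "dispersion_estimate"))
  if (is.null(dim(contrast))) {
    contrast <- matrix(contrast, ncol = 1L,
                       dimnames = list(NULL, "contrast"))
  }
  R <- fit$cell_rows
  if (nrow(contrast) != ncol(R)) {
    stop("contrast length ", nrow(contrast), " does not match the ",
         ncol(R), " design coefficients")
  }
  ## express each contrast as weights on cells: solve R' w = c
  W <- solve(t(R), contrast)                     # cells x contrasts
  rownames(W) <- rownames(R)

  m <- fit$counts
  df <- fit$df_residual
  phi <- dispersions$shrunk
  n_strain <- nrow(m)

  ## quasi-dispersions, squeezed across testable strains
  s2 <- rep(NA_real_, n_strain)
  usable <- rowSums(m) > 0 & df >= 1L
  for (i in which(usable)) {
    s2[i] <- pearson_stat(m[i, ], fit$fitted[i, ], phi[i]) / df
  }
  sq <- limma::squeezeVar(s2[usable], df = df)
  s2_post <- rep(NA_real_, n_strain)
  s2_post[usable] <- pmax(sq$var.post, 1e-8)
  df_total <- df + min(sq$df.prior, 1e6)

  out <- vector("list", ncol(W))
  for (k in seq_len(ncol(W))) {
    w <- W[, k]
    act <- abs(w) > 1e-12
    used_cells <- rownames(R)[act]
    est <- as.numeric(fit$cell_log_means[, used_cells, drop = FALSE] %*% w[act])
    flagged <- rowSums(fit$cell_totals[, used_cells, drop = FALSE] == 0) > 0
    if (any(flagged)) {
      fallback <- log(sweep(fit$cell_totals[flagged, used_cells, drop = FALSE] +
                              prior_count,
                            2L, fit$cell_eo[used_cells], "/")) %*% w[act]
      est[flagged] <- as.numeric(fallback)
    }
    ## delta-method variance on the active cells
    var_c <- rep(NA_real_, n_strain)
    for (i in which(!flagged & usable)) {
      v <- 0
      for (cl in used_cells) {
        in_cell <- fit$cells == cl
        mu_k <- fit$fitted[i, in_cell]
        v <- v + w[cl]^2 * sum(mu_k * (1 + phi[i] * mu_k)) / sum(mu_k)^2
      }
      var_c[i] <- v
    }
    Fstat <- est^2 / (var_c * s2_post)
    p <- stats::pf(Fstat, 1, df_total, lower.tail = FALSE)
    p[flagged | !usable] <- NA_real_
    Fstat[flagged | !usable] <- NA_real_
    out[[k]] <- data.frame(
      strain = rownames(m), contrast = colnames(W)[k],
      logFC = est / log(2), statistic = Fstat, p_value = p,
      flagged = flagged | !usable, row.names = NULL,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment applied over the non-`NA` entries; `NA` p-values (flagged
#' strains) stay `NA` and do not enter the denominator.
#'
#' @param p Numeric vector of p-values in `[0, 1]`, possibly with `NA`s.
#' @return Vector of adjusted values, same length as `p`.
#' @export
adjust_fdr <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Fit competitive fitness from a bar-seq count matrix
#'
#' The front door of the package: filters low-information samples and strains,
#' computes RLE size factors, fits the per-strain GLM under the
#' treatment-by-time design, estimates and shrinks dispersions, and tests the
#' reference-fitness contrast plus one treatment-fitness
#' (difference-in-differences) contrast per non-reference treatment.
#'
#' @param counts Strain-by-sample count matrix, `barseq_counts`, or
#'   `barseq_sim`.
#' @param samples Sample sheet (columns `sample`, `treatment`, `time`,
#'   optionally `replicate`, `batch`); for a `barseq_sim` input, defaults to
#'   its sheet.
#' @param reference Reference treatment label (for a `barseq_sim`, defaults to
#'   the design's reference).
#' @param t_early,t_late Time points contrasted (defaults `"T1"` / `"T3"`).
#' @param timepoints Time points retained in the analysis (default: just
#'   `t_early` and `t_late`; `NULL` keeps every sampled time point). Late,
#'   heavily selected passages contribute zeros and extreme composition shifts
#'   that degrade the normalization without informing the contrasts.
#' @param design_type `"cell_means"` (default) or `"intercept"`.
#' @param filter Apply [filter_counts()] first (default `TRUE`).
#' @param min_sample_reads,min_strain_reads Filter thresholds.
#' @param prior_df Prior degrees of freedom for dispersion shrinkage.
#' @param prior_count Pseudo-count for flagged strains' fold-changes.
#' @param fdr_threshold Threshold used by `summary()` when tallying
#'   significant strains (default 0.05).
#' @return A `barseq_fit` object; see [coef.barseq_fit()],
#'   [fitness_table()], [summary.barseq_fit()].
#' @examples
#' lib <- make_barcode_library(12, seed = 1)
#' pool <- strain_pool(lib, seed = 2)
#' des <- serial_batch_design(depth = 2e4, seed = 3)
#' fm <- fitness_grid(pool$strain_id, des$conditions, "treatment",
#'                    values = c(-0.1, 0, 0.1))
#' sim <- simulate_experiment(des, pool, fm)
#' fit <- barseq_fit(sim)
#' head(coef(fit))
#' @export
barseq_fit <- function(counts, samples = NULL, reference = NULL,
                       t_early = "T1", t_late = "T3",
                       timepoints = c(t_early, t_late),
                       design_type = c("cell_means", "intercept"),
                       filter = TRUE, min_sample_reads = 15L,
                       min_strain_reads = 3L, prior_df = 10,
                       prior_count = 0.5, fdr_threshold = 0.05) {
  design_type <- match.arg(design_type)
  if (inherits(counts, "barseq_sim")) {
    if (is.null(samples)) samples <- counts$samples
    if (is.null(reference)) reference <- counts$design$reference
  }
  m <- .counts(counts)
  if (is.null(samples)) stop("a sample sheet is required")
  if (is.null(reference)) stop("the reference treatment must be named")
  if (!all(samples$sample %in% colnames(m))) {
    stop("sample sheet rows missing from the count matrix: ",
         paste(setdiff(samples$sample, colnames(m)), collapse = ", "))
  }
  if (!is.null(timepoints)) {
    missing_tp <- setdiff(c(t_early, t_late), timepoints)
    if (length(missing_tp)) {
      stop("timepoints must include the contrasted points: ",
           paste(missing_tp, collapse = ", "))
    }
    samples <- samples[samples$time %in% timepoints, , drop = FALSE]
    if (nrow(samples) == 0L) stop("no samples left at the requested timepoints")
  }
  m <- m[, samples$sample, drop = FALSE]

  if (filter) {
    m <- filter_counts(m, min_sample_reads, min_strain_reads)
    samples <- samples[samples$sample %in% colnames(m), , drop = FALSE]
  }
  sf <- rle_size_factors(m, pseudo_reference = TRUE)
  offsets <- log(sf)
  design <- build_design(samples, type = design_type,
                         reference = if (design_type == "intercept") reference)
  contrasts <- fitness_contrasts(design, reference, t_early, t_late)
  glm_fit <- fit_nb_glm(m, design, offsets)
  disp <- estimate_dispersions(m, design, offsets, prior_df = prior_df,
                               fit = glm_fit)
  tab <- test_contrast(glm_fit, contrasts, disp, prior_count = prior_count)
  tab$fdr <- stats::ave(tab$p_value, tab$contrast, FUN = adjust_fdr)

  wide <- function(col) {
    out <- matrix(NA_real_, nrow(m), ncol(contrasts),
                  dimnames = list(rownames(m), colnames(contrasts)))
    out[cbind(tab$strain, tab$contrast)] <- tab[[col]]
    out
  }
  structure(
    list(counts = m, samples = samples, size_factors = sf, offsets = offsets,
         design = design, contrasts = contrasts, glm = glm_fit,
         dispersions = disp, table = tab,
         logFC = wide("logFC"), statistic = wide("statistic"),
         p_value = wide("p_value"), fdr = wide("fdr"),
         flagged = wide("flagged") > 0,
         reference = reference, t_early = t_early, t_late = t_late,
         fdr_threshold = fdr_threshold, call = match.call()),
    class = "barseq_fit"
  )
}
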
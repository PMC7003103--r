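#' Build the treatment-by-time design matrix
#'
#' Encodes the serial-batch design with one parameter per (treatment, time)
#' cell. `type = "cell_means"` uses the no-intercept parameterization
#' `~ 0 + treatment + treatment:time` (one coefficient per cell);
#' `type = "intercept"` uses `~ treatment + treatment:time` with the reference
#' condition as the intercept (the variant used when fresh juices serve as
#' reference). Both span the same column space, so fitted cell means — and
#' every contrast — are identical between them. Time is categorical: the
#' contrasts difference specific sampling points rather than fit a slope.
#'
#' @param samples Sample sheet: a data frame with columns `sample`,
#'   `treatment`, `time` (and usually `replicate`, `batch`).
#' @param type `"cell_means"` or `"intercept"`.
#' @param reference Reference treatment (required for `"intercept"`).
#' @return Design matrix (samples x coefficients) of class `barseq_design`
#'   with attributes `cells` (per-sample cell label `treatment:time`),
#'   `cell_rows` (one representative design row per cell) and `type`.
#' @export
build_design <- function(samples, type = c("cell_means", "intercept"),
                         reference = NULL) {
  type <- match.arg(type)
  req <- c("sample", "treatment", "time")
  if (!all(req %in% names(samples))) {
    stop("sample sheet needs columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(samples$sample)) stop("duplicate sample ids in sheet")
  treatment <- factor(samples$treatment)
  time <- factor(samples$time)
  cells <- paste(samples$treatment, samples$time, sep = ":")
  if (type == "cell_means") {
    lev <- unique(cells[order(treatment, time)])
    X <- 1 * outer(cells, lev, "==")
    colnames(X) <- lev
  } else {
    if (is.null(reference)) stop("intercept design requires `reference`")
    if (!reference %in% levels(treatment)) {
      stop("reference condition '", reference, "' not present in the sheet")
    }
    treatment <- stats::relevel(treatment, ref = reference)
    X <- stats::model.matrix(~ treatment + treatment:time,
                             data = data.frame(treatment, time))
    X <- X[, qr(X)$pivot[seq_len(qr(X)$rank)], drop = FALSE]  # drop aliased
  }
  rownames(X) <- samples$sample
  n_cells <- length(unique(cells))
  if (qr(X)$rank != n_cells || ncol(X) != n_cells) {
    stop("design is rank-deficient: rank ", qr(X)$rank, " for ", n_cells,
         " (treatment, time) cells")
  }
  cell_rows <- X[!duplicated(cells), , drop = FALSE]
  rownames(cell_rows) <- cells[!duplicated(cells)]
  structure(X, cells = cells, cell_rows = cell_rows, type = type,
            class = c("barseq_design", class(X)))
}

#' Fitness contrast vectors
#'
#' Builds the two contrasts the assay is designed around, as vectors in the
#' design's coefficient space: the *reference fitness* contrast
#' `(T_late, reference) - (T_early, reference)`, and per non-reference
#' treatment the *treatment fitness* difference-in-differences
#' `((T_late, t) - (T_early, t)) - ((T_late, ref) - (T_early, ref))`.
#'
#' @param design A `barseq_design`.
#' @param reference Reference treatment label.
#' @param t_early,t_late Early / late time-point labels (defaults `"T1"`,
#'   `"T3"`: two serial re-inoculations, about 16 generations apart).
#' @param treatments Treatments to contrast (default: all non-reference).
#' @return Coefficients-by-contrasts numeric matrix; first column
#'   `"reference"`, one further column per treatment.
#' @export
fitness_contrasts <- function(design, reference, t_early = "T1",
                              t_late = "T3", treatments = NULL) {
  R <- attr(design, "cell_rows")
  if (is.null(R)) stop("not a barseq_design: missing cell_rows attribute")
  cell <- function(tr, tm) {
    lab <- paste(tr, tm, sep = ":")
    if (!lab %in% rownames(R)) {
      stop("design has no samples in cell (", tr, ", ", tm, ")")
    }
    R[lab, ]
  }
  all_tr <- unique(sub(":[^:]*$", "", rownames(R)))
  if (!reference %in% all_tr) stop("reference '", reference, "' not in design")
  if (is.null(treatments)) treatments <- setdiff(all_tr, reference)
  ref_vec <- cell(reference, t_late) - cell(reference, t_early)
  out <- matrix(0, ncol(design), 1L + length(treatments),
                dimnames = list(colnames(design), c("reference", treatments)))
  out[, "reference"] <- ref_vec
  for (tr in treatments) {
    out[, tr] <- cell(tr, t_late) - cell(tr, t_early) - ref_vec
  }
  out
}
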
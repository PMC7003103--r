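#' Serial-batch experiment design
#'
#' Parameters of a pooled serial-batch competition: strains grow together
#' through `n_passages` growth phases of `gens_per_passage` doublings each,
#' sampled at the end of every phase (time points `T1`, `T2`, ...); between
#' phases a bottleneck of `bottleneck` cells is transferred into fresh medium.
#' With the defaults, two serial re-inoculations separate `T1` from `T3`
#' (about 16 generations of competitive growth).
#'
#' @param conditions Character vector of condition labels; the first (or
#'   `reference`) is the reference medium.
#' @param reference Which condition is the reference (default first).
#' @param n_passages Number of growth phases (default 4, sampled T1-T4).
#' @param gens_per_passage Doublings per growth phase (default 8; a 1:100
#'   transfer implies ~6.6 doublings, with residual growth absorbed here).
#' @param dilution Transfer dilution ratio in (0, 1) (default 0.01).
#' @param bottleneck Cells transferred at each passage; `Inf` disables drift.
#' @param replicates Replicate cultures per condition (default 3).
#' @param depth Expected sequencing reads per sample (default 3e4).
#' @param read_error_rate Per-base substitution probability in emitted reads.
#' @param inoculation `"reference_first"` (default): the first growth phase
#'   takes place in the reference medium for every flask, and condition-specific
#'   selection begins at the second passage — the serial scheme in which T1
#'   samples the shared starting culture. `"direct"`: strains are inoculated
#'   straight into each condition, so selection acts from the first phase (the
#'   fresh-juice variant).
#' @param seed Optional integer seed stored with the design.
#' @return A `serial_batch_design` list.
#' @export
serial_batch_design <- function(conditions = c("control", "treatment"),
                                reference = conditions[1L],
                                n_passages = 4L, gens_per_passage = 8,
                                dilution = 0.01, bottleneck = 1e7,
                                replicates = 3L, depth = 3e4,
                                read_error_rate = 0.001,
                                inoculation = c("reference_first", "direct"),
                                seed = NULL) {
  inoculation <- match.arg(inoculation)
  stopifnot(length(conditions) >= 1L, !anyDuplicated(conditions),
            reference %in% conditions,
            n_passages >= 1L, replicates >= 1L, depth >= 1)
  if (gens_per_passage < 0) stop("gens_per_passage must be non-negative")
  if (!(dilution > 0 && dilution < 1)) stop("dilution must lie in (0, 1)")
  if (!(bottleneck > 0)) stop("bottleneck must be positive (Inf allowed)")
  structure(
    list(conditions = conditions, reference = reference,
         n_passages = as.integer(n_passages),
         gens_per_passage = gens_per_passage, dilution = dilution,
         bottleneck = bottleneck, replicates = as.integer(replicates),
         depth = depth, read_error_rate = read_error_rate,
         inoculation = inoculation, seed = seed),
    class = "serial_batch_design"
  )
}

#' @export
print.serial_batch_design <- function(x, ...) {
  cat("Serial-batch design:", length(x$conditions), "conditions (reference:",
      x$reference, "),", x$n_passages, "passages x", x$gens_per_passage,
      "generations,", x$replicates, "replicates, depth", format(x$depth), "\n")
  invisible(x)
}

#' Strain-specific DNA-extraction bias factors
#'
#' Log-normal multipliers rescaled so the realized max/min ratio equals
#' `max_min_ratio` exactly (geometric mean 1). Extraction bias is a fixed
#' property of a strain's genetic background: the same factor applies to every
#' sample of an experiment, which is why it cancels from within-strain
#' temporal contrasts.
#'
#' @param n Number of strains.
#' @param max_min_ratio Target ratio of largest to smallest factor (default 22,
#'   the count spread observed for equal-abundance pools).
#' @param seed Optional integer seed.
#' @return Positive numeric vector of length `n`.
#' @export
extraction_bias_factors <- function(n, max_min_ratio = 22, seed = NULL) {
  stopifnot(n >= 1, max_min_ratio >= 1)
  if (n == 1L || max_min_ratio == 1) return(rep(1, n))
  with_seed(seed, {
    z <- stats::rnorm(n)
    z <- z - mean(z)
    z <- z * (log(max_min_ratio) / (max(z) - min(z)))
    exp(z - mean(z))
  })
}

#' Assemble a pool of barcoded strains
#'
#' @param library A `barcode_library`.
#' @param extraction_bias Positive multipliers, one per strain (default:
#'   [extraction_bias_factors()] with a 22-fold spread).
#' @param initial_fraction Starting proportions (default equal); must sum to 1.
#' @param bias_ratio Max/min extraction-bias ratio used when
#'   `extraction_bias` is not supplied.
#' @param seed Optional integer seed for the default bias draw.
#' @return A `strain_pool` data frame with columns `strain_id`, `barcode_up`,
#'   `barcode_dn`, `extraction_bias`, `initial_fraction`.
#' @export
strain_pool <- function(library, extraction_bias = NULL,
                        initial_fraction = NULL, bias_ratio = 22,
                        seed = NULL) {
  validate_barcode_library(library)
  n <- nrow(library)
  if (is.null(extraction_bias)) {
    extraction_bias <- extraction_bias_factors(n, bias_ratio, seed = seed)
  }
  if (is.null(initial_fraction)) initial_fraction <- rep(1 / n, n)
  stopifnot(length(extraction_bias) == n, length(initial_fraction) == n)
  if (any(extraction_bias <= 0)) stop("extraction_bias must be > 0")
  if (any(initial_fraction < 0) || abs(sum(initial_fraction) - 1) > 1e-9) {
    stop("initial fractions must be non-negative and sum to 1 (tol 1e-9)")
  }
  pool <- data.frame(
    strain_id = library$strain_id,
    barcode_up = library$barcode_up,
    barcode_dn = library$barcode_dn,
    extraction_bias = extraction_bias,
    initial_fraction = initial_fraction,
    stringsAsFactors = FALSE
  )
  class(pool) <- c("strain_pool", "data.frame")
  pool
}

#' Per-condition selection coefficients
#'
#' `s[i, c]` is strain `i`'s log2 per-generation growth-rate advantage in
#' condition `c`: its log2 abundance ratio to a neutral (s = 0) competitor
#' changes by `s * g` over `g` generations. `s = 0` encodes neutrality.
#'
#' @param strain_ids Character vector of strain ids.
#' @param conditions Character vector of condition labels.
#' @param s Either a single number, a vector of length `length(strain_ids)`
#'   (recycled across conditions), or a full strains-by-conditions matrix.
#' @return A numeric matrix with strain ids as rownames and conditions as
#'   colnames, class `fitness_map`.
#' @export
fitness_map <- function(strain_ids, conditions, s = 0) {
  n <- length(strain_ids); k <- length(conditions)
  if (is.matrix(s)) {
    stopifnot(nrow(s) == n, ncol(s) == k)
    m <- s
  } else if (length(s) %in% c(1L, n)) {
    m <- matrix(rep(s, length.out = n * k), n, k)
  } else {
    stop("s must be scalar, length n_strains, or an n_strains x n_conditions matrix")
  }
  if (any(!is.finite(m))) stop("selection coefficients must be finite")
  dimnames(m) <- list(strain_ids, conditions)
  class(m) <- c("fitness_map", "matrix")
  m
}

#' Selection-coefficient grid for recovery experiments
#'
#' Assigns the values in `values` cyclically across strains in one condition
#' and 0 in all others (including the reference), giving known ground truth
#' for parameter-recovery checks.
#'
#' @param strain_ids Strain ids.
#' @param conditions All condition labels.
#' @param condition The condition receiving the grid.
#' @param values Selection coefficients to cycle through.
#' @return A `fitness_map`.
#' @export
fitness_grid <- function(strain_ids, conditions, condition,
                         values = c(-0.2, -0.1, 0, 0.1, 0.2)) {
  stopifnot(condition %in% conditions)
  fm <- fitness_map(strain_ids, conditions, 0)
  fm[, condition] <- rep(values, length.out = length(strain_ids))
  fm
}

#' Simulate strain fractions through serial batch passages
#'
#' Within each growth phase every strain's abundance multiplies by
#' `2^((1 + s_i) * gens_per_passage)` and fractions renormalize; at each
#' transfer, `bottleneck` cells are drawn multinomially from the current
#' fractions (genetic drift). `bottleneck = Inf` gives the deterministic
#' limit. Fractions are recorded at the end of every growth phase
#' (time points `T1`, `T2`, ...). Under the default `"reference_first"`
#' inoculation scheme the first phase uses the reference condition's
#' selection coefficients in every flask (all flasks start from the same
#' reference-grown culture); `"direct"` applies each condition's coefficients
#' from the first phase. Extinct lineages (fraction exactly 0) are legal and
#' stay extinct.
#'
#' @param design A `serial_batch_design`.
#' @param pool A `strain_pool`.
#' @param fitness A `fitness_map` covering every design condition.
#' @param seed Optional integer seed (default: the design's seed).
#' @return A 4-d array `[strain, timepoint, replicate, condition]` of true
#'   cell fractions.
#' @export
simulate_serial_batch <- function(design, pool, fitness, seed = design$seed) {
  stopifnot(inherits(design, "serial_batch_design"))
  if (!all(design$conditions %in% colnames(fitness))) {
    stop("fitness map lacks conditions: ",
         paste(setdiff(design$conditions, colnames(fitness)), collapse = ", "))
  }
  if (!all(pool$strain_id %in% rownames(fitness))) {
    stop("fitness map lacks strains present in the pool")
  }
  n <- nrow(pool)
  tp <- paste0("T", seq_len(design$n_passages))
  reps <- paste0("r", seq_len(design$replicates))
  out <- array(
    NA_real_, dim = c(n, design$n_passages, design$replicates,
                      length(design$conditions)),
    dimnames = list(pool$strain_id, tp, reps, design$conditions)
  )
  growth <- function(f, s) {
    a <- f * 2^((1 + s) * design$gens_per_passage)
    a / sum(a)
  }
  with_seed(seed, {
    ref_first <- identical(design$inoculation, "reference_first")
    for (cond in design$conditions) {
      s <- fitness[pool$strain_id, cond]
      s1 <- if (ref_first) fitness[pool$strain_id, design$reference] else s
      for (r in seq_len(design$replicates)) {
        f <- pool$initial_fraction
        for (p in seq_len(design$n_passages)) {
          f <- growth(f, if (p == 1L) s1 else s)
          out[, p, r, cond] <- f
          if (p < design$n_passages && is.finite(design$bottleneck)) {
            draw <- stats::rmultinom(1L, size = design$bottleneck, prob = f)
            f <- as.numeric(draw) / design$bottleneck
          }
        }
      }
    }
  })
  out
}

#' Template proportions under extraction bias
#'
#' The proportion of amplifiable barcode templates contributed by each strain:
#' cell fractions reweighted by the strain-specific extraction-bias factors.
#'
#' @param fractions Cell fractions (sum to 1).
#' @param bias Positive extraction-bias multipliers.
#' @return Proportions summing to 1.
#' @export
template_proportions <- function(fractions, bias) {
  if (any(bias <= 0)) stop("extraction bias factors must be > 0")
  if (abs(sum(fractions) - 1) > 1e-6 || any(fractions < 0)) {
    stop("fractions must be non-negative and sum to 1")
  }
  p <- fractions * bias
  p / sum(p)
}

#' Observe barcode counts for one sample
#'
#' Applies the measurement model: template proportions are the cell fractions
#' distorted by extraction bias, and observed counts are a multinomial draw of
#' `depth` reads from those proportions.
#'
#' @param fractions True cell fractions (sum to 1).
#' @param bias Extraction-bias multipliers (one per strain, > 0).
#' @param depth Total reads drawn (>= 0).
#' @param seed Optional integer seed.
#' @return Integer count vector (named like `fractions` if it has names).
#' @export
apply_measurement_model <- function(fractions, bias, depth, seed = NULL) {
  stopifnot(depth >= 0)
  p <- template_proportions(fractions, bias)
  counts <- with_seed(seed, {
    if (depth == 0) rep(0L, length(p))
    else as.integer(stats::rmultinom(1L, size = depth, prob = p))
  })
  names(counts) <- names(fractions)
  counts
}

#' Simulate a full pooled competition experiment
#'
#' Runs [simulate_serial_batch()] and applies the measurement model to every
#' (condition, time point, replicate) sample, yielding a strain-by-sample
#' count matrix, a sample sheet, and the ground truth used to generate them.
#'
#' @param design A `serial_batch_design`.
#' @param pool A `strain_pool`.
#' @param fitness A `fitness_map`.
#' @param batch Batch label recorded in the sample sheet (default "B1").
#' @param seed Integer seed (default: the design's seed); the same seed
#'   reproduces the counts byte for byte.
#' @return A `barseq_sim` list: `counts` (integer matrix), `samples` (sample
#'   sheet with columns sample/treatment/time/replicate/batch), `fractions`
#'   (true-fraction array), `pool`, `fitness`, `design`.
#' @examples
#' lib <- make_barcode_library(8, seed = 1)
#' pool <- strain_pool(lib, seed = 2)
#' des <- serial_batch_design(depth = 5000, seed = 3)
#' fm <- fitness_grid(pool$strain_id, des$conditions, "treatment")
#' sim <- simulate_experiment(des, pool, fm)
#' dim(sim$counts)
#' @export
simulate_experiment <- function(design, pool, fitness, batch = "B1",
                                seed = design$seed) {
  with_seed(seed, {
    fr <- simulate_serial_batch(design, pool, fitness, seed = NULL)
    dn <- dimnames(fr)
    samples <- expand.grid(
      replicate = dn[[3L]], time = dn[[2L]], treatment = dn[[4L]],
      stringsAsFactors = FALSE
    )[, c("treatment", "time", "replicate")]
    samples$sample <- sprintf("%s_%s_%s", samples$treatment, samples$time,
                              samples$replicate)
    samples$batch <- batch
    counts <- matrix(0L, nrow(pool), nrow(samples),
                     dimnames = list(pool$strain_id, samples$sample))
    for (j in seq_len(nrow(samples))) {
      f <- fr[, samples$time[j], samples$replicate[j], samples$treatment[j]]
      counts[, j] <- apply_measurement_model(f, pool$extraction_bias,
                                             depth = design$depth, seed = NULL)
    }
    structure(
      list(counts = counts,
           samples = samples[, c("sample", "treatment", "time", "replicate", "batch")],
           fractions = fr, pool = pool, fitness = fitness, design = design),
      class = "barseq_sim"
    )
  })
}

#' @export
print.barseq_sim <- function(x, ...) {
  cat("Simulated bar-seq experiment:", nrow(x$counts), "strains x",
      ncol(x$counts), "samples (",
      length(x$design$conditions), "conditions,",
      x$design$n_passages, "time points,",
      x$design$replicates, "replicates )\n")
  invisible(x)
}

#' Write simulator outputs as plain-text files
#'
#' Emits the barcode library, sample sheet, count matrix and truth tables
#' (true fractions, selection coefficients, extraction-bias factors) as TSV.
#'
#' @param sim A `barseq_sim`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_sim_tables <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    library = file.path(dir, "barcode_library.tsv"),
    samples = file.path(dir, "sample_sheet.tsv"),
    counts = file.path(dir, "counts.tsv"),
    fractions = file.path(dir, "true_fractions.tsv"),
    fitness = file.path(dir, "true_fitness.tsv"),
    bias = file.path(dir, "extraction_bias.tsv")
  )
  utils::write.table(sim$pool[, c("strain_id", "barcode_up", "barcode_dn")],
                     paths["library"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$samples, paths["samples"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_count_matrix(sim$counts, paths["counts"])
  fr <- as.data.frame.table(sim$fractions, responseName = "fraction")
  names(fr)[1:4] <- c("strain_id", "time", "replicate", "treatment")
  utils::write.table(fr, paths["fractions"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  fm <- data.frame(strain_id = rownames(sim$fitness),
                   unclass(sim$fitness), check.names = FALSE)
  utils::write.table(fm, paths["fitness"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$pool[, c("strain_id", "extraction_bias")],
                     paths["bias"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
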
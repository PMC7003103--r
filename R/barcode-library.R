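#' Design a bipartite barcode library
#'
#' Generates a library of strain-identifying barcode pairs. Each strain is
#' tagged by an upstream and a downstream 12-nt barcode; strain identity is the
#' *pair*, so `k` upstream and `m` downstream codes tag up to `k * m` strains
#' (the combinatorial reuse that lets 20 primer-encoded codes tag 96 strains).
#' Distinct codes on the same side are kept at least `min_distance` Hamming
#' mismatches apart so that sequencing errors below the matching tolerance
#' cannot convert one strain into another.
#'
#' @param n_strains Number of strains to tag (>= 1).
#' @param min_distance Minimum Hamming distance between distinct codes on the
#'   same side (>= 1).
#' @param barcode_length Length of each barcode (default 12).
#' @param seed Optional integer; the same seed reproduces the same library.
#' @return A `barcode_library` data frame with columns `strain_id`,
#'   `barcode_up`, `barcode_dn` and attributes `min_dist_up` / `min_dist_dn`.
#' @examples
#' lib <- make_barcode_library(6, min_distance = 3, seed = 1)
#' attr(lib, "min_dist_up") >= 3
#' @export
make_barcode_library <- function(n_strains, min_distance = 3L,
                                 barcode_length = 12L, seed = NULL) {
  stopifnot(n_strains >= 1, min_distance >= 1, barcode_length >= 1)
  if (min_distance > barcode_length) {
    stop("infeasible library: min_distance (", min_distance,
         ") exceeds barcode length (", barcode_length, ")")
  }
  k_up <- ceiling(sqrt(n_strains))
  k_dn <- ceiling(n_strains / k_up)
  with_seed(seed, {
    up <- pick_codes(k_up, min_distance, barcode_length)
    dn <- pick_codes(k_dn, min_distance, barcode_length)
    idx <- seq_len(n_strains) - 1L
    lib <- data.frame(
      strain_id  = sprintf("S%03d", seq_len(n_strains)),
      barcode_up = up[idx %/% k_dn + 1L],
      barcode_dn = dn[idx %% k_dn + 1L],
      stringsAsFactors = FALSE
    )
    as_barcode_library(lib)
  })
}

## Rejection-sample `k` codes pairwise >= min_distance apart.
pick_codes <- function(k, min_distance, len, max_tries = 5000L * k) {
  codes <- character(0)
  mat <- matrix(0L, 0, len)
  tries <- 0L
  while (length(codes) < k) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("infeasible library: could not place ", k, " codes of length ", len,
           " at pairwise Hamming distance >= ", min_distance)
    }
    cand <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
    ci <- utf8ToInt(cand)
    if (nrow(mat) == 0L ||
        min(rowSums(mat != rep(ci, each = nrow(mat)))) >= min_distance) {
      codes <- c(codes, cand)
      mat <- rbind(mat, ci)
    }
  }
  codes
}

as_barcode_library <- function(df) {
  validate_barcode_library(df)
  attr(df, "min_dist_up") <- min_pairwise_distance(df$barcode_up)
  attr(df, "min_dist_dn") <- min_pairwise_distance(df$barcode_dn)
  class(df) <- c("barcode_library", "data.frame")
  df
}

validate_barcode_library <- function(df) {
  req <- c("strain_id", "barcode_up", "barcode_dn")
  if (!all(req %in% names(df))) {
    stop("barcode library needs columns: ", paste(req, collapse = ", "))
  }
  for (col in c("barcode_up", "barcode_dn")) {
    bad <- which(!grepl("^[ACGT]+$", df[[col]]))
    if (length(bad)) {
      stop("row ", bad[1L], ": ", col, " contains non-ACGT characters: ",
           df[[col]][bad[1L]])
    }
    lens <- nchar(df[[col]])
    if (length(unique(lens)) > 1L) {
      stop("row ", which(lens != lens[1L])[1L], ": ", col,
           " length differs from the rest of the library")
    }
  }
  if (anyDuplicated(df$strain_id)) {
    stop("row ", anyDuplicated(df$strain_id), ": duplicate strain_id '",
         df$strain_id[anyDuplicated(df$strain_id)], "'")
  }
  pair <- paste(df$barcode_up, df$barcode_dn)
  if (anyDuplicated(pair)) {
    stop("row ", anyDuplicated(pair), ": duplicate barcode pair (",
         pair[anyDuplicated(pair)], ")")
  }
  invisible(df)
}

#' Read a barcode library from a TSV file
#'
#' Expects three tab-separated columns (`strain_id`, `barcode_up`,
#' `barcode_dn`); a header line is detected and skipped automatically.
#' Validation failures report the offending file row. The minimum pairwise
#' Hamming distance among distinct up- and down-codes is recorded in the
#' attributes `min_dist_up` / `min_dist_dn` and shown by `print()`.
#'
#' @param path Path to the TSV file.
#' @return A `barcode_library` data frame.
#' @export
load_barcode_library <- function(path) {
  if (!file.exists(path)) stop("barcode library file not found: ", path)
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) != 3L) {
    stop("barcode library must have 3 columns, found ", ncol(raw))
  }
  offset <- 0L
  if (nrow(raw) > 0L &&
      !(grepl("^[ACGTacgt]+$", raw[1L, 2L]) && grepl("^[ACGTacgt]+$", raw[1L, 3L]))) {
    raw <- raw[-1L, , drop = FALSE]   # header line
    offset <- 1L
  }
  if (nrow(raw) == 0L) stop("barcode library file is empty: ", path)
  names(raw) <- c("strain_id", "barcode_up", "barcode_dn")
  raw$barcode_up <- toupper(raw$barcode_up)
  raw$barcode_dn <- toupper(raw$barcode_dn)
  rownames(raw) <- NULL
  lib <- tryCatch(as_barcode_library(raw), error = function(e) {
    ## translate data-frame row numbers into file row numbers
    msg <- sub("^row (\\d+)", "", conditionMessage(e))
    row <- suppressWarnings(as.integer(
      sub("^row (\\d+).*$", "\\1", conditionMessage(e))))
    if (!is.na(row)) stop("file row ", row + offset, msg, call. = FALSE)
    stop(e)
  })
  lib
}

#' Write a barcode library to TSV
#'
#' @param library A `barcode_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_barcode_library <- function(library, path) {
  validate_barcode_library(library)
  utils::write.table(as.data.frame(library)[, c("strain_id", "barcode_up", "barcode_dn")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.barcode_library <- function(x, ...) {
  cat("Bipartite barcode library:", nrow(x), "strains;",
      length(unique(x$barcode_up)), "up-codes x",
      length(unique(x$barcode_dn)), "dn-codes\n")
  cat("Min pairwise Hamming distance: up =", attr(x, "min_dist_up"),
      ", dn =", attr(x, "min_dist_dn"), "\n")
  NextMethod()
}
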
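#' Assign reads to strains by bipartite barcode matching
#'
#' Extracts the two barcode windows at the template-defined offsets,
#' concatenates them to a 24-nt tag and computes its Hamming distance to every
#' library pair. A read is assigned to the unique pair at minimum distance
#' `<= max_mismatch`; ties at the minimum are `"ambiguous"`; no pair within
#' tolerance (or a read too short to span the template) is `"unassigned"`.
#' Ambiguous reads are never fractionally assigned.
#'
#' For real data with ragged 5' ends, `offset_scan` additionally tries shifted
#' extraction windows (`-offset_scan .. +offset_scan`) and keeps the best.
#'
#' @param reads Character vector of read sequences.
#' @param library A `barcode_library`.
#' @param template An [amplicon_template()].
#' @param max_mismatch Maximum Hamming distance over the concatenated barcode
#'   (default 1; with library min distance >= 3 assignments stay unambiguous).
#' @param offset_scan Scan extraction offsets +/- this many nt (default 0).
#' @return Character vector: a strain id, `"ambiguous"`, or `"unassigned"` per
#'   read.
#' @export
match_reads <- function(reads, library, template = amplicon_template(),
                        max_mismatch = 1L, offset_scan = 0L) {
  validate_barcode_library(library)
  stopifnot(max_mismatch >= 0, offset_scan >= 0)
  n <- length(reads)
  out <- rep("unassigned", n)
  if (n == 0L) return(out)
  bl <- template$barcode_length
  L <- codes_to_int(paste0(library$barcode_up, library$barcode_dn))

  best_d <- matrix(NA_integer_, n, nrow(library))
  for (shift in seq.int(-offset_scan, offset_scan)) {
    up0 <- template$up_start + shift
    dn0 <- template$dn_start + shift
    ok <- nchar(reads) >= dn0 + bl - 1L & up0 >= 1L
    if (!any(ok)) next
    tags <- paste0(substr(reads[ok], up0, up0 + bl - 1L),
                   substr(reads[ok], dn0, dn0 + bl - 1L))
    D <- cross_hamming(codes_to_int(tags), L)
    cur <- best_d[ok, , drop = FALSE]
    take <- is.na(cur) | D < cur
    cur[take] <- D[take]
    best_d[ok, ] <- cur
  }
  spanned <- rowSums(!is.na(best_d)) > 0L
  if (any(spanned)) {
    D <- best_d[spanned, , drop = FALSE]
    dmin <- apply(D, 1L, min)
    nmin <- rowSums(D == dmin)
    hit <- max.col(-D, ties.method = "first")
    call <- ifelse(dmin > max_mismatch, "unassigned",
                   ifelse(nmin > 1L, "ambiguous", library$strain_id[hit]))
    out[spanned] <- call
  }
  out
}

#' @rdname match_reads
#' @param read A single read sequence.
#' @export
match_read <- function(read, library, template = amplicon_template(),
                       max_mismatch = 1L, offset_scan = 0L) {
  match_reads(read, library, template, max_mismatch, offset_scan)
}

#' Count barcoded reads into a strain-by-sample matrix
#'
#' Streams each sample's FASTQ through [match_reads()] and accumulates counts.
#' Input is either one FASTQ per sample (a character vector named by sample
#' id) or a single index-demultiplexed FASTQ whose headers carry the sample id
#' in the dual-index field (`demux = "header"`). Per-sample `assigned +
#' ambiguous + unassigned` always equals the number of reads processed, and
#' the result does not depend on read order.
#'
#' @param fastq_paths Character vector of FASTQ paths, named by sample id; or
#'   a single path with `demux = "header"`.
#' @param library A `barcode_library`.
#' @param template An [amplicon_template()].
#' @param max_mismatch,offset_scan Passed to [match_reads()].
#' @param demux `"files"` (one file per sample) or `"header"`.
#' @return A `barseq_counts` object: integer matrix `counts` (strains x
#'   samples) plus per-sample `unassigned` and `ambiguous` tallies.
#' @export
count_samples <- function(fastq_paths, library, template = amplicon_template(),
                          max_mismatch = 1L, offset_scan = 0L,
                          demux = c("files", "header")) {
  demux <- match.arg(demux)
  validate_barcode_library(library)
  missing <- fastq_paths[!file.exists(fastq_paths)]
  if (length(missing)) stop("FASTQ file not found: ", missing[1L])

  if (demux == "header") {
    if (length(fastq_paths) != 1L) {
      stop("demux = 'header' expects a single FASTQ path")
    }
    fq <- read_fastq(fastq_paths)
    sample_of <- parse_sample_from_header(fq$header)
    split_reads <- split(fq$seq, sample_of)
  } else {
    if (is.null(names(fastq_paths)) || any(names(fastq_paths) == "")) {
      stop("fastq_paths must be named by sample id")
    }
    if (anyDuplicated(names(fastq_paths))) stop("duplicate sample ids")
    split_reads <- lapply(fastq_paths, function(p) read_fastq(p)$seq)
  }

  samples <- names(split_reads)
  counts <- matrix(0L, nrow(library), length(samples),
                   dimnames = list(library$strain_id, samples))
  unassigned <- ambiguous <- stats::setNames(integer(length(samples)), samples)
  for (s in samples) {
    reads <- split_reads[[s]]
    if (length(reads) == 0L) {
      warning("sample '", s, "' has no reads; zero column emitted")
      next
    }
    calls <- match_reads(reads, library, template, max_mismatch, offset_scan)
    tab <- table(factor(calls, levels = c(library$strain_id,
                                          "unassigned", "ambiguous")))
    counts[, s] <- as.integer(tab[library$strain_id])
    unassigned[s] <- as.integer(tab[["unassigned"]])
    ambiguous[s] <- as.integer(tab[["ambiguous"]])
  }
  structure(list(counts = counts, unassigned = unassigned,
                 ambiguous = ambiguous),
            class = "barseq_counts")
}

#' @export
print.barseq_counts <- function(x, ...) {
  total <- colSums(x$counts) + x$unassigned + x$ambiguous
  cat("Barcode counts:", nrow(x$counts), "strains x", ncol(x$counts),
      "samples\n")
  cat(sprintf("Reads: %d total, %.1f%% assigned, %.1f%% ambiguous, %.1f%% unassigned\n",
              sum(total),
              100 * sum(x$counts) / max(1, sum(total)),
              100 * sum(x$ambiguous) / max(1, sum(total)),
              100 * sum(x$unassigned) / max(1, sum(total))))
  invisible(x)
}

#' @method as.matrix barseq_counts
#' @export
as.matrix.barseq_counts <- function(x, ...) x$counts

#' Write / read a count matrix as TSV
#'
#' The file has strains as rows and samples as columns; for a `barseq_counts`
#' object the unassigned and ambiguous tallies are stored as trailing
#' `__unassigned__` / `__ambiguous__` rows, which [read_count_matrix()] splits
#' back out.
#'
#' @param x A count matrix or `barseq_counts`.
#' @param path TSV path.
#' @return `path` (write) or a matrix / `barseq_counts` (read).
#' @export
write_count_matrix <- function(x, path) {
  if (inherits(x, "barseq_counts")) {
    m <- rbind(x$counts,
               `__unassigned__` = x$unassigned,
               `__ambiguous__` = x$ambiguous)
  } else {
    m <- .counts(x)
  }
  df <- data.frame(strain_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "integer"
  special <- c("__unassigned__", "__ambiguous__")
  if (all(special %in% rownames(m))) {
    keep <- setdiff(rownames(m), special)
    structure(list(counts = m[keep, , drop = FALSE],
                   unassigned = m["__unassigned__", ],
                   ambiguous = m["__ambiguous__", ]),
              class = "barseq_counts")
  } else {
    m
  }
}
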
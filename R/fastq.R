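#' Emit simulated FASTQ reads for one sample
#'
#' Writes `sum(counts)` single-end reads of fixed length. Each read is the
#' strain's amplicon template (`flank + barcode_up + spacer + barcode_dn` plus
#' padding) with i.i.d. base substitutions at `error_rate`. The sample
#' identity is carried in the read header's dual-index field, so reads can be
#' demultiplexed from the headers alone. Qualities are constant Phred 40.
#'
#' @param counts Named integer vector of reads per strain; names must exist in
#'   `library`.
#' @param library A `barcode_library`.
#' @param path Output FASTQ path (`.gz` suffix gives gzip output).
#' @param template An [amplicon_template()].
#' @param error_rate Per-base substitution probability.
#' @param sample Sample identifier written into headers.
#' @param seed Optional integer seed; same seed, same file bytes.
#' @return `path`, invisibly.
#' @export
emit_fastq <- function(counts, library, path, template = amplicon_template(),
                       error_rate = 0, sample = "S1", seed = NULL) {
  validate_barcode_library(library)
  stopifnot(error_rate >= 0, error_rate < 1)
  unknown <- setdiff(names(counts), library$strain_id)
  if (length(unknown)) {
    stop("counts reference strains absent from the library: ",
         paste(unknown, collapse = ", "))
  }
  if (is.null(names(counts))) stop("counts must be named by strain_id")
  counts <- counts[counts > 0]
  idx <- match(names(counts), library$strain_id)
  per_strain <- vapply(idx, function(i) {
    template_read(template, library$barcode_up[i], library$barcode_dn[i])
  }, character(1))
  seqs <- rep(per_strain, times = counts)
  n <- length(seqs)
  with_seed(seed, {
    if (n > 0 && error_rate > 0) {
      L <- template$read_length
      n_err <- stats::rbinom(n, L, error_rate)
      for (i in which(n_err > 0L)) {
        chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
        pos <- sample.int(L, n_err[i])
        chars[pos] <- vapply(chars[pos], function(b) {
          sample(setdiff(DNA_BASES, b), 1L)
        }, character(1), USE.NAMES = FALSE)
        seqs[i] <- paste(chars, collapse = "")
      }
    }
    headers <- if (n > 0) {
      sprintf("%s.%d 1:N:0:%s", sample, seq_len(n), sample)
    } else character(0)
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- headers
    q <- Biostrings::PhredQuality(rep(strrep("I", template$read_length), n))
    xq <- Biostrings::QualityScaledDNAStringSet(x, q)
    comp <- grepl("\\.gz$", path)
    Biostrings::writeQualityScaledXStringSet(xq, path, compress = comp)
  })
  invisible(path)
}

#' Write one FASTQ per sample of a simulated experiment
#'
#' @param sim A `barseq_sim` from [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @param template An [amplicon_template()].
#' @param error_rate Per-base substitution rate (default: the design's).
#' @param seed Optional integer seed.
#' @param gzip Compress output files.
#' @return Named character vector of FASTQ paths (names = sample ids).
#' @export
write_sim_fastq <- function(sim, dir, template = amplicon_template(),
                            error_rate = sim$design$read_error_rate,
                            seed = NULL, gzip = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lib <- as_barcode_library(sim$pool[, c("strain_id", "barcode_up", "barcode_dn")])
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  paths <- stats::setNames(
    file.path(dir, paste0(colnames(sim$counts), ext)), colnames(sim$counts))
  with_seed(seed, {
    for (s in colnames(sim$counts)) {
      emit_fastq(sim$counts[, s], lib, paths[[s]], template = template,
                 error_rate = error_rate, sample = s, seed = NULL)
    }
  })
  paths
}

## Read a FASTQ (plain or gzip) into sequences + header strings.
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  list(seq = as.character(unname(x)), header = names(x))
}

## Sample id from the dual-index field of an emitted header ("... 1:N:0:<id>").
parse_sample_from_header <- function(headers) {
  sub("^.* [0-9]+:[YN]:[0-9]+:", "", headers)
}
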
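## Fixed 92-nt spacer separating the two barcodes: the 34-nt loxP site left by
## Cre-mediated marker excision, embedded in fixed priming context. Any fixed
## 92-mer works; this one ships as the package default.
LOXP_SITE <- "ATAACTTCGTATAATGTATGCTATACGAAGTTAT"
BARSEQ_SPACER <- paste0(
  "GCTAGCCTGAAGGTCTTACCGTCAATCGA",   # 29 nt
  LOXP_SITE,                         # 34 nt
  "TCCAGGATCCAGTTCGAAGCTTGGATCAG"    # 29 nt
)

## Fixed downstream context used to pad reads out to the read length.
BARSEQ_PAD <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCACGTACGTAGGCATCTGA"

#' Amplicon layout for the bipartite barcode element
#'
#' Describes where the two barcodes sit in a single-end read:
#' `[flank_up][barcode_up][spacer][barcode_dn][padding]`, truncated or padded
#' to `read_length`. With the defaults (no upstream flank, 12-nt barcodes,
#' 92-nt spacer) the upstream barcode occupies positions 1-12, the spacer
#' 13-104 and the downstream barcode 105-116 of a 150-nt read.
#'
#' @param spacer Fixed inter-barcode sequence (default: the packaged 92-nt
#'   loxP-scar spacer).
#' @param flank_up Fixed sequence preceding the upstream barcode (default "").
#' @param barcode_length Barcode length on each side (default 12).
#' @param read_length Read length (default 150).
#' @param pad Fixed sequence recycled to fill the read after the downstream
#'   barcode.
#' @return An `amplicon_template` list with the computed 1-based offsets
#'   `up_start` and `dn_start`.
#' @examples
#' tpl <- amplicon_template()
#' tpl$dn_start  # 105
#' @export
amplicon_template <- function(spacer = BARSEQ_SPACER, flank_up = "",
                              barcode_length = 12L, read_length = 150L,
                              pad = BARSEQ_PAD) {
  stopifnot(grepl("^[ACGT]*$", spacer), grepl("^[ACGT]*$", flank_up),
            barcode_length >= 1, read_length >= 1)
  up_start <- nchar(flank_up) + 1L
  dn_start <- up_start + barcode_length + nchar(spacer)
  span <- dn_start + barcode_length - 1L
  if (span > read_length) {
    stop("template span (", span, " nt) exceeds read length (", read_length, ")")
  }
  structure(
    list(spacer = spacer, flank_up = flank_up, pad = pad,
         barcode_length = as.integer(barcode_length),
         read_length = as.integer(read_length),
         up_start = as.integer(up_start), dn_start = as.integer(dn_start),
         span = as.integer(span)),
    class = "amplicon_template"
  )
}

#' @export
print.amplicon_template <- function(x, ...) {
  cat("Amplicon template: read_length", x$read_length,
      "| barcode_up @", x$up_start, "-", x$up_start + x$barcode_length - 1L,
      "| spacer", nchar(x$spacer), "nt",
      "| barcode_dn @", x$dn_start, "-", x$dn_start + x$barcode_length - 1L, "\n")
  invisible(x)
}

## Full-length template read for one strain (no errors).
template_read <- function(template, barcode_up, barcode_dn) {
  body <- paste0(template$flank_up, barcode_up, template$spacer, barcode_dn)
  need <- template$read_length - nchar(body)
  if (need > 0L) {
    fill <- strrep(template$pad, ceiling(need / nchar(template$pad)))
    body <- paste0(body, substr(fill, 1L, need))
  }
  substr(body, 1L, template$read_length)
}
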
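#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

## Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is restored afterwards so seeded helpers compose deterministically.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Hamming distance between equal-length strings
#'
#' @param a,b Character vectors of equal-length strings (recycled pairwise).
#' @return Integer vector of mismatch counts.
#' @examples
#' hamming("ACGT", "ACCT")
#' @export
hamming <- function(a, b) {
  if (any(nchar(a) != nchar(b))) {
    stop("hamming(): strings must have equal length")
  }
  mapply(function(x, y) sum(utf8ToInt(x) != utf8ToInt(y)), a, b,
         USE.NAMES = FALSE)
}

## Character codes as an integer matrix (one row per string) for vectorized
## cross-distance computations.
codes_to_int <- function(codes) {
  n <- length(codes)
  if (n == 0L) return(matrix(integer(0), 0, 0))
  L <- nchar(codes[1L])
  m <- matrix(0L, n, L)
  for (i in seq_len(n)) m[i, ] <- utf8ToInt(codes[i])
  m
}

## All-pairs Hamming distances between rows of two integer code matrices.
cross_hamming <- function(A, B) {
  D <- matrix(0L, nrow(A), nrow(B))
  for (p in seq_len(ncol(A))) {
    D <- D + outer(A[, p], B[, p], "!=")
  }
  D
}

## Minimum pairwise Hamming distance among distinct codes (NA if < 2 distinct).
min_pairwise_distance <- function(codes) {
  u <- unique(codes)
  if (length(u) < 2L) return(NA_integer_)
  D <- cross_hamming(codes_to_int(u), codes_to_int(u))
  min(D[upper.tri(D)])
}

is_count_matrix <- function(x) {
  is.matrix(x) && is.numeric(x) && !is.null(rownames(x)) && !is.null(colnames(x))
}

## Accept either a plain matrix or a barseq_counts container.
.counts <- function(x) {
  if (inherits(x, "barseq_counts")) return(x$counts)
  if (inherits(x, "barseq_sim")) return(x$counts)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is_count_matrix(x)) {
    stop("expected a strain-by-sample count matrix with dimnames, ",
         "a 'barseq_counts' object, or a 'barseq_sim' object")
  }
  x
}
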
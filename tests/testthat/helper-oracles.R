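## Independent oracles used across the suite. These deliberately use naive
## loops / direct formulas so they share no code path with the package.

## Brute-force read matcher: per-read loop over every library pair.
brute_force_match <- function(reads, library, template, max_mismatch) {
  bl <- template$barcode_length
  pair <- paste0(library$barcode_up, library$barcode_dn)
  vapply(reads, function(rd) {
    if (nchar(rd) < template$dn_start + bl - 1L) return("unassigned")
    tag <- paste0(substr(rd, template$up_start, template$up_start + bl - 1L),
                  substr(rd, template$dn_start, template$dn_start + bl - 1L))
    d <- vapply(pair, function(p) {
      sum(strsplit(tag, "")[[1]] != strsplit(p, "")[[1]])
    }, numeric(1))
    dmin <- min(d)
    if (dmin > max_mismatch) "unassigned"
    else if (sum(d == dmin) > 1L) "ambiguous"
    else library$strain_id[which.min(d)]
  }, character(1), USE.NAMES = FALSE)
}

## Step-up BH by direct enumeration.
bh_enumerate <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (rank in seq_len(m)) {
    i <- o[rank]
    cand <- p[o[rank:m]] * m / seq(rank, m)
    adj[i] <- min(1, min(cand))
  }
  adj
}

## Ward.D2 agglomeration via the Lance-Williams recurrence on unsquared
## Euclidean distances; returns sorted merge heights.
ward_d2_heights <- function(mat) {
  d <- as.matrix(dist(mat))
  n <- nrow(d)
  active <- seq_len(n)
  size <- rep(1, n)
  heights <- numeric(0)
  while (length(active) > 1L) {
    best <- c(NA, NA); bd <- Inf
    for (a in seq_along(active)) {
      for (b in seq_along(active)) {
        if (a < b && d[active[a], active[b]] < bd) {
          bd <- d[active[a], active[b]]; best <- c(active[a], active[b])
        }
      }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, bd)
    for (k in setdiff(active, c(i, j))) {
      dk <- sqrt(((size[i] + size[k]) * d[i, k]^2 +
                  (size[j] + size[k]) * d[j, k]^2 -
                  size[k] * d[i, j]^2) / (size[i] + size[j] + size[k]))
      d[i, k] <- d[k, i] <- dk
    }
    size[i] <- size[i] + size[j]
    active <- setdiff(active, j)
  }
  sort(heights)
}

## Per-generation brute-force serial-batch iteration (one doubling at a time).
per_generation_fractions <- function(f0, s, gens_per_passage, n_passages) {
  f <- f0
  out <- matrix(NA_real_, length(f0), n_passages)
  for (p in seq_len(n_passages)) {
    for (g in seq_len(gens_per_passage)) {
      f <- f * 2^(1 + s)
      f <- f / sum(f)
    }
    out[, p] <- f
  }
  out
}

## Negative-binomial log-likelihood maximized by a generic optimizer.
nb_mle <- function(y, X, offsets, phi) {
  nll <- function(beta) {
    mu <- exp(as.numeric(X %*% beta) + offsets)
    -sum(dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
  }
  start <- rep(log(mean(y) + 0.5), ncol(X))
  optim(start, nll, method = "BFGS",
        control = list(reltol = 1e-15, maxit = 2000))$par
}

## Small fixed barcode library written through the TSV loader.
fixture_library <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("strain_id\tbarcode_up\tbarcode_dn", rows), path)
  load_barcode_library(path)
}

## Sample sheet for a full-factorial layout.
make_sheet <- function(treatments = c("control", "treatment"),
                       times = c("T1", "T3"), replicates = 3) {
  g <- expand.grid(replicate = paste0("r", seq_len(replicates)),
                   time = times, treatment = treatments,
                   stringsAsFactors = FALSE)
  data.frame(sample = sprintf("%s_%s_%s", g$treatment, g$time, g$replicate),
             treatment = g$treatment, time = g$time, replicate = g$replicate,
             batch = "B1", stringsAsFactors = FALSE)
}

## Simulated counts for a sheet: NB noise around exp(log2 cell means * log(2)).
## mean_log2 is a strains x cells matrix, cells named like "treatment:time".
nb_counts_for_sheet <- function(sheet, mean_log2, phi = 0.05, seed = 1) {
  set.seed(seed)
  cells <- paste(sheet$treatment, sheet$time, sep = ":")
  mu <- 2^mean_log2[, cells, drop = FALSE]
  colnames(mu) <- sheet$sample
  m <- mu
  for (j in seq_len(ncol(mu))) {
    m[, j] <- if (phi > 0) {
      rnbinom(nrow(mu), size = 1 / phi, mu = mu[, j])
    } else rpois(nrow(mu), mu[, j])
  }
  storage.mode(m) <- "integer"
  m
}
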
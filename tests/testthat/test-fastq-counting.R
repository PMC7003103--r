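tpl <- amplicon_template()
lib5 <- make_barcode_library(5, min_distance = 3, seed = 1)

test_that("error-free emission round-trips exactly through counting", {
  counts <- setNames(c(3L, 2L), lib5$strain_id[1:2])
  path <- tempfile(fileext = ".fastq")
  emit_fastq(counts, lib5, path, error_rate = 0, sample = "sampleA", seed = 2)
  lines <- readLines(path)
  expect_equal(length(lines), 4L * 5L)
  cts <- count_samples(c(sampleA = path), lib5, tpl, max_mismatch = 0)
  expect_equal(cts$counts[lib5$strain_id[1:2], "sampleA"], counts)
  expect_equal(sum(cts$counts), 5L)
  expect_equal(unname(cts$unassigned + cts$ambiguous), 0L)
})

test_that("reads carry the spacer at positions 13-104 and are read-length long", {
  counts <- setNames(rep(1L, 5), lib5$strain_id)
  path <- tempfile(fileext = ".fastq")
  emit_fastq(counts, lib5, path, error_rate = 0, seed = 3)
  seqs <- as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
  expect_true(all(nchar(seqs) == 150L))
  expect_true(all(substr(seqs, 13, 104) == BARSEQ_SPACER))
})

test_that("observed mismatch rate matches the requested error rate", {
  n <- 10000L
  counts <- setNames(n, lib5$strain_id[1])
  path <- tempfile(fileext = ".fastq")
  emit_fastq(counts, lib5, path, error_rate = 0.01, sample = "e", seed = 4)
  seqs <- as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
  tmpl <- barseqfit:::template_read(tpl, lib5$barcode_up[1], lib5$barcode_dn[1])
  mism <- sum(hamming(seqs, rep(tmpl, n)))
  total <- n * 150
  se <- sqrt(0.01 * 0.99 / total)
  expect_lt(abs(mism / total - 0.01), 3 * se)
})

test_that("single-read matching honors the mismatch tolerance boundary", {
  read <- barseqfit:::template_read(tpl, lib5$barcode_up[2], lib5$barcode_dn[2])
  expect_equal(match_read(read, lib5, tpl, max_mismatch = 0),
               lib5$strain_id[2])
  ## one substitution inside the upstream barcode
  mut <- read
  substr(mut, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(read, 5, 5))[1]
  expect_equal(match_read(mut, lib5, tpl, max_mismatch = 0), "unassigned")
  expect_equal(match_read(mut, lib5, tpl, max_mismatch = 1),
               lib5$strain_id[2])
  ## too-short reads are unassigned, not fatal
  expect_equal(match_read(substr(read, 1, 50), lib5, tpl), "unassigned")
})

test_that("equidistant reads are ambiguous (exhaustive-distance oracle)", {
  lib <- fixture_library(c("A\tAAAAAAAAAAAA\tCCCCCCCCCCCC",
                           "B\tAAAAAAAAAAAT\tCCCCCCCCCCCG"))
  ## up matches A exactly, dn matches B exactly: distance 1 to both pairs
  read <- barseqfit:::template_read(tpl, "AAAAAAAAAAAA", "CCCCCCCCCCCG")
  d_A <- hamming(paste0("AAAAAAAAAAAA", "CCCCCCCCCCCG"),
                 paste0(lib$barcode_up[1], lib$barcode_dn[1]))
  d_B <- hamming(paste0("AAAAAAAAAAAA", "CCCCCCCCCCCG"),
                 paste0(lib$barcode_up[2], lib$barcode_dn[2]))
  expect_equal(d_A, 1); expect_equal(d_B, 1)
  expect_equal(match_read(read, lib, tpl, max_mismatch = 1), "ambiguous")
  expect_equal(brute_force_match(read, lib, tpl, 1), "ambiguous")
})

test_that("mismatch-tolerant matching agrees read-for-read with brute force", {
  lib <- make_barcode_library(30, min_distance = 3, seed = 5)
  pool <- strain_pool(lib, seed = 6)
  counts <- setNames(rmultinom(1, 10000, pool$initial_fraction)[, 1],
                     lib$strain_id)
  path <- tempfile(fileext = ".fastq")
  emit_fastq(counts, lib, path, error_rate = 0.005, sample = "bf", seed = 7)
  reads <- as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
  fast <- match_reads(reads, lib, tpl, max_mismatch = 1)
  slow <- brute_force_match(reads, lib, tpl, max_mismatch = 1)
  expect_identical(fast, slow)
})

test_that("read accounting, order-invariance and additivity hold", {
  pool <- strain_pool(lib5, seed = 8)
  counts <- setNames(c(40L, 25L, 10L, 5L, 1L), lib5$strain_id)
  p1 <- tempfile(fileext = ".fastq"); p2 <- tempfile(fileext = ".fastq")
  emit_fastq(counts, lib5, p1, error_rate = 0.02, sample = "s1", seed = 9)
  emit_fastq(counts, lib5, p2, error_rate = 0.02, sample = "s1", seed = 10)
  cts1 <- count_samples(c(s1 = p1), lib5, tpl)
  tot1 <- colSums(cts1$counts) + cts1$unassigned + cts1$ambiguous
  expect_equal(unname(tot1), sum(counts))

  ## concatenation = sum of separate counts
  cts2 <- count_samples(c(s1 = p2), lib5, tpl)
  pc <- tempfile(fileext = ".fastq")
  writeLines(c(readLines(p1), readLines(p2)), pc)
  ctsc <- count_samples(c(s1 = pc), lib5, tpl)
  expect_equal(ctsc$counts, cts1$counts + cts2$counts)

  ## shuffling read order leaves the matrix unchanged
  rec <- matrix(readLines(p1), nrow = 4)
  set.seed(11)
  ps <- tempfile(fileext = ".fastq")
  writeLines(as.vector(rec[, sample.int(ncol(rec))]), ps)
  ctss <- count_samples(c(s1 = ps), lib5, tpl)
  expect_equal(ctss$counts, cts1$counts)
})

test_that("raising max_mismatch never decreases a strain's count", {
  pool <- strain_pool(lib5, seed = 12)
  counts <- setNames(rep(200L, 5), lib5$strain_id)
  path <- tempfile(fileext = ".fastq")
  emit_fastq(counts, lib5, path, error_rate = 0.03, sample = "m", seed = 13)
  prev <- count_samples(c(m = path), lib5, tpl, max_mismatch = 0)$counts
  for (mm in 1:3) {
    cur <- count_samples(c(m = path), lib5, tpl, max_mismatch = mm)$counts
    expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("header demultiplexing splits one FASTQ into sample columns", {
  counts_a <- setNames(c(5L, 3L), lib5$strain_id[1:2])
  counts_b <- setNames(c(2L, 7L), lib5$strain_id[c(3, 5)])
  pa <- tempfile(fileext = ".fastq"); pb <- tempfile(fileext = ".fastq")
  emit_fastq(counts_a, lib5, pa, sample = "A", seed = 14)
  emit_fastq(counts_b, lib5, pb, sample = "B", seed = 15)
  pooled <- tempfile(fileext = ".fastq")
  writeLines(c(readLines(pa), readLines(pb)), pooled)
  cts <- count_samples(pooled, lib5, tpl, demux = "header")
  expect_setequal(colnames(cts$counts), c("A", "B"))
  expect_equal(cts$counts[lib5$strain_id[1:2], "A"], counts_a)
  expect_equal(cts$counts[lib5$strain_id[c(3, 5)], "B"], counts_b)
})

test_that("missing files fail and gzip input is transparent", {
  expect_error(count_samples(c(x = tempfile()), lib5, tpl), "not found")
  counts <- setNames(c(4L, 6L), lib5$strain_id[1:2])
  pgz <- tempfile(fileext = ".fastq.gz")
  emit_fastq(counts, lib5, pgz, sample = "gz", seed = 16)
  cts <- count_samples(c(gz = pgz), lib5, tpl)
  expect_equal(cts$counts[lib5$strain_id[1:2], "gz"], counts)
})

test_that("offset-scan recovers assignments for shifted 5' ends", {
  read <- barseqfit:::template_read(tpl, lib5$barcode_up[1], lib5$barcode_dn[1])
  shifted <- paste0("GG", substr(read, 1, 148))
  expect_equal(match_read(shifted, lib5, tpl, max_mismatch = 1), "unassigned")
  expect_equal(match_read(shifted, lib5, tpl, max_mismatch = 1,
                          offset_scan = 2), lib5$strain_id[1])
})
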
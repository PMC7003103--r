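test_that("the cell-means design has one full-rank column per cell", {
  sheet <- make_sheet()                       # 2 treatments x 2 times x 3 reps
  X <- build_design(sheet)
  expect_equal(dim(X), c(12L, 4L))
  expect_equal(qr(X)$rank, 4L)
  expect_true(all(rowSums(X) == 1))           # each sample in exactly one cell

  Xi <- build_design(sheet, type = "intercept", reference = "control")
  expect_equal(dim(Xi), c(12L, 4L))
  expect_equal(qr(Xi)$rank, 4L)
  expect_true(all(Xi[, 1] == 1))              # reference baseline column
})

test_that("cell-means and intercept encodings give identical contrasts", {
  sheet <- make_sheet()
  mean_log2 <- cbind("control:T1" = rep(8, 30), "control:T3" = rep(8, 30),
                     "treatment:T1" = rep(8, 30),
                     "treatment:T3" = 8 + seq(-2, 2, length.out = 30))
  rownames(mean_log2) <- sprintf("g%02d", 1:30)
  m <- nb_counts_for_sheet(sheet, mean_log2, phi = 0.05, seed = 21)
  f1 <- barseq_fit(m, sheet, reference = "control", filter = FALSE)
  f2 <- barseq_fit(m, sheet, reference = "control", filter = FALSE,
                   design_type = "intercept")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
  expect_equal(fitted(f1), fitted(f2), tolerance = 1e-8)
})

test_that("a single cell with equal offsets fits the arithmetic mean", {
  sheet <- data.frame(sample = c("a", "b", "c"), treatment = "control",
                      time = "T1")
  X <- build_design(sheet)
  m <- matrix(c(10L, 20L, 30L), 1, 3, dimnames = list("g", sheet$sample))
  fit <- fit_nb_glm(m, X, offsets = c(0, 0, 0))
  expect_equal(unname(exp(fit$cell_log_means[1, ])), 20)
})

test_that("a two-cell contrast of normalized means 10 vs 40 gives logFC 2", {
  sheet <- make_sheet(treatments = "control", times = c("T1", "T3"))
  m <- matrix(rep(c(10L, 40L), each = 3), 1, 6,
              dimnames = list("g", sheet$sample))
  X <- build_design(sheet)
  ctr <- fitness_contrasts(X, "control", treatments = character(0))
  fit <- fit_nb_glm(m, X, offsets = rep(0, 6))
  disp <- estimate_dispersions(m, X, rep(0, 6), fit = fit)
  tab <- test_contrast(fit, ctr, disp)
  expect_equal(tab$logFC, 2)
})

test_that("GLM coefficients match direct NB likelihood maximization", {
  sheet <- make_sheet()                       # equal offsets within cells
  set.seed(31)
  X <- build_design(sheet)
  phi <- 0.1
  for (rep in 1:3) {
    mu <- 2^runif(4, 4, 9)
    y <- rnbinom(12, size = 1 / phi, mu = rep(mu, each = 3))
    m <- matrix(as.integer(y), 1, 12, dimnames = list("g", sheet$sample))
    fit <- fit_nb_glm(m, X, offsets = rep(0, 12))
    oracle <- nb_mle(y, X, rep(0, 12), phi)
    expect_equal(unname(fit$coefficients[1, ]), oracle, tolerance = 1e-6)
  }
})

test_that("Poisson data yields a near-zero common dispersion", {
  sheet <- make_sheet()
  set.seed(41)
  mean_log2 <- matrix(8, 80, 4,
                      dimnames = list(sprintf("g%02d", 1:80),
                                      c("control:T1", "control:T3",
                                        "treatment:T1", "treatment:T3")))
  m <- nb_counts_for_sheet(sheet, mean_log2, phi = 0, seed = 42)
  disp <- estimate_dispersions(m, build_design(sheet), rep(0, 12))
  expect_lte(disp$common, 0.01)
})

test_that("a known NB dispersion of 0.1 is recovered within 20%", {
  sheet <- data.frame(sample = sprintf("s%02d", 1:20), treatment = "c",
                      time = "T1")
  set.seed(43)
  m <- matrix(rnbinom(150 * 20, size = 10, mu = 300), 150, 20,
              dimnames = list(sprintf("g%03d", 1:150), sheet$sample))
  disp <- estimate_dispersions(m, build_design(sheet), rep(0, 20))
  expect_lt(abs(median(disp$shrunk) - 0.1), 0.02)
})

test_that("shrunk dispersions lie between raw and common", {
  sheet <- make_sheet()
  set.seed(44)
  mean_log2 <- matrix(8, 40, 4,
                      dimnames = list(sprintf("g%02d", 1:40),
                                      c("control:T1", "control:T3",
                                        "treatment:T1", "treatment:T3")))
  m <- nb_counts_for_sheet(sheet, mean_log2, phi = 0, seed = 45)
  ## one wildly overdispersed strain
  m[1, ] <- as.integer(rnbinom(12, size = 1.2, mu = 256))
  disp <- estimate_dispersions(m, build_design(sheet), rep(0, 12))
  expect_gt(disp$raw[1], disp$common)
  expect_gt(disp$shrunk[1], disp$common)
  expect_lt(disp$shrunk[1], disp$raw[1])
  lo <- pmin(disp$raw, disp$common) - 1e-12
  hi <- pmax(disp$raw, disp$common) + 1e-12
  expect_true(all(disp$shrunk >= lo & disp$shrunk <= hi))
})

test_that("null contrasts are zero: time-constant and jointly-scaled strains", {
  sheet <- make_sheet()
  ## strain 1: identical counts everywhere; strain 2: treatment and control
  ## scale identically over time -> treatment fitness cancels
  m <- rbind(g1 = rep(50L, 12),
             g2 = as.integer(c(20, 20, 20, 80, 80, 80, 20, 20, 20, 80, 80, 80)))
  colnames(m) <- sheet$sample
  X <- build_design(sheet)
  ctr <- fitness_contrasts(X, "control")
  fit <- fit_nb_glm(m, X, offsets = rep(0, 12))
  disp <- estimate_dispersions(m, X, rep(0, 12), fit = fit)
  tab <- test_contrast(fit, ctr, disp)
  ref_g1 <- tab[tab$strain == "g1" & tab$contrast == "reference", ]
  expect_equal(ref_g1$logFC, 0)
  expect_equal(ref_g1$statistic, 0)
  expect_equal(ref_g1$p_value, 1)
  expect_equal(tab$logFC[tab$strain == "g2" & tab$contrast == "treatment"], 0)
  expect_equal(tab$logFC[tab$strain == "g2" & tab$contrast == "reference"], 2)
})

test_that("a strong true effect is detected at depth 1e4 (power check)", {
  lib <- make_barcode_library(40, seed = 51)
  pool <- strain_pool(lib, seed = 52)
  des <- serial_batch_design(depth = 1e4, seed = 53)
  fm <- fitness_map(pool$strain_id, des$conditions, 0)
  fm[1, "treatment"] <- 0.15
  sim <- simulate_experiment(des, pool, fm)
  fit <- barseq_fit(sim)
  expect_lt(fit$p_value[pool$strain_id[1], "treatment"], 0.01)
})

test_that("BH adjustment matches hand values and enumeration", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  set.seed(61)
  p <- runif(100)
  expect_equal(adjust_fdr(p), bh_enumerate(p))
  ## NA p-values stay NA and do not enter the denominator
  p2 <- c(0.01, NA, 0.02, 0.03)
  expect_equal(adjust_fdr(p2), c(0.03, NA, 0.03, 0.03))
  expect_error(adjust_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("strains with an all-zero contrast cell are flagged, not tested", {
  sheet <- make_sheet()
  m <- rbind(g1 = rep(30L, 12), g2 = rep(30L, 12))
  colnames(m) <- sheet$sample
  m["g2", sheet$treatment == "treatment" & sheet$time == "T3"] <- 0L
  ## two-strain toy: the variance squeeze warns about near-zero residuals
  fit <- suppressWarnings(
    barseq_fit(m, sheet, reference = "control", filter = FALSE))
  expect_true(fit$flagged["g2", "treatment"])
  expect_true(is.na(fit$p_value["g2", "treatment"]))
  expect_true(is.finite(fit$logFC["g2", "treatment"]))
  expect_false(fit$flagged["g2", "reference"])
})

test_that("contrast log fold-changes agree with an independent GLM engine", {
  lib <- make_barcode_library(25, seed = 71)
  pool <- strain_pool(lib, seed = 72)
  des <- serial_batch_design(depth = 2e4, seed = 73)
  fm <- fitness_grid(pool$strain_id, des$conditions, "treatment",
                     values = c(-0.1, 0, 0.1))
  sim <- simulate_experiment(des, pool, fm)
  fit <- barseq_fit(sim, filter = FALSE)
  X <- build_design(fit$samples)
  suppressMessages(suppressWarnings({
    eg <- edgeR::glmFit(fit$counts, design = X,
                        offset = matrix(fit$offsets, nrow(fit$counts),
                                        ncol(fit$counts), byrow = TRUE),
                        dispersion = 0, prior.count = 0)
  }))
  ctr <- fitness_contrasts(X, "control")
  lfc_edger <- (eg$coefficients %*% ctr) / log(2)
  expect_equal(unname(coef(fit)), unname(lfc_edger), tolerance = 1e-4)
})

test_that("contrasts referencing missing cells fail with the cell named", {
  sheet <- make_sheet(times = c("T1", "T2"))
  X <- build_design(sheet)
  expect_error(fitness_contrasts(X, "control"), "T3")
})
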
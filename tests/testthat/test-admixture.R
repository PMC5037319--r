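test_that("the calibration smoother reproduces polynomial relationships", {
  # local quadratic regression reproduces a straight line exactly
  lin <- tibble::tibble(mapped_human_pct = seq(5, 95, by = 10),
                        true_human_pct = 0.8 * seq(5, 95, by = 10) + 3)
  fit <- fit_calibration(lin)
  est <- estimate_human_content(fit, lin$mapped_human_pct)
  expect_equal(est$est_human_pct, lin$true_human_pct, tolerance = 1e-6)
  expect_false(any(est$extrapolated))
})

test_that("the published mixing table is reproduced within rounding", {
  tab <- read_mixing_table()
  expect_equal(nrow(tab), 13L)
  fit <- fit_calibration(tab)
  est <- estimate_human_content(fit, tab$mapped_human_pct)$est_human_pct
  expect_lt(max(abs(est - tab$printed_estimate)), 0.5)
  # the spec'd worked rows
  expect_equal(estimate_human_content(fit, 83.14)$est_human_pct, 52.59,
               tolerance = 0.5)
  expect_equal(estimate_human_content(fit, 99.98)$est_human_pct, 98.70,
               tolerance = 0.5)
  expect_equal(estimate_human_content(fit, 62.44)$est_human_pct, 22.55,
               tolerance = 0.5)
  expect_equal(estimate_human_content(fit, 97.59)$est_human_pct, 90.97,
               tolerance = 0.5)
})

test_that("the fitted calibration is monotone and within the training hull", {
  tab <- read_mixing_table()
  fit <- fit_calibration(tab)
  grid <- seq(min(tab$mapped_human_pct), max(tab$mapped_human_pct),
              length.out = 300)
  est <- estimate_human_content(fit, grid)$est_human_pct
  # monotone up to sub-0.05-point numerical wiggle at the clipped bottom edge
  expect_true(all(diff(est) > -0.05))
  expect_true(all(est >= min(tab$true_human_pct) - 1e-9))
  expect_true(all(est <= max(tab$true_human_pct) + 1e-9))
})

test_that("extrapolation clamps to the nearest edge and is flagged", {
  tab <- read_mixing_table()
  fit <- fit_calibration(tab)
  out <- estimate_human_content(fit, c(-5, 101))
  expect_true(all(out$extrapolated))
  edge <- estimate_human_content(fit, range(tab$mapped_human_pct))
  expect_equal(out$est_human_pct, edge$est_human_pct)
  expect_error(fit_calibration(tab[1:4, ]), "at least 5")
})

test_that("calibration round-trips synthetic mixture series", {
  # identity bias, no noise: recovery is exact at training points
  ser0 <- simulate_calibration_series(bias_curve = identity, noise_sd = 0,
                                      seed = 3)
  fit0 <- fit_calibration(ser0)
  est0 <- estimate_human_content(fit0, ser0$mapped_human_pct)$est_human_pct
  expect_equal(est0, ser0$true_human_pct, tolerance = 1e-4)
  # default capture bias + noise: mean recovery within 3 points, worst
  # replicate within 5 (the steep top of the bias curve amplifies mapping
  # noise by about 4x)
  errs <- sapply(1:10, function(s) {
    ser <- simulate_calibration_series(noise_sd = 0.3, seed = s)
    fit <- fit_calibration(ser)
    est <- estimate_human_content(fit, ser$mapped_human_pct)$est_human_pct
    abs(est - ser$true_human_pct)
  })
  expect_lt(mean(errs), 3)
  expect_lt(max(errs), 5)
})

test_that("loss-region heterozygous SNPs are selected by genotype and segment", {
  segments <- tibble::tibble(chrom = c("chr1", "chr1"),
                             start = c(0L, 1000L), end = c(1000L, 2000L),
                             log_ratio = c(-0.5, 0))
  variants <- tibble::tibble(
    chrom = "chr1", pos = c(500L, 1500L, 600L),
    vaf = c(0.8, 0.8, 0.9),
    normal_genotype = c("het", "het", "hom_ref")
  )
  kept <- select_loss_het_snps(variants, segments)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$pos, 500L)
  expect_equal(kept$log_ratio, -0.5)
  # threshold is strict: log-ratio exactly -0.1 is not a loss
  seg_edge <- tibble::tibble(chrom = "chr1", start = 0L, end = 1000L,
                             log_ratio = -0.1)
  expect_equal(nrow(select_loss_het_snps(variants, seg_edge)), 0L)
  # tumor-only fallback uses the `genotype` column
  tum <- dplyr::rename(variants, genotype = normal_genotype)
  expect_equal(nrow(select_loss_het_snps(tum, segments)), 1L)
})

test_that("purity estimators handle the boundary cases exactly", {
  full <- estimate_purity(rep(1, 20))
  expect_equal(full$purity_paper, 1)
  expect_equal(full$purity_exact, 1)
  none <- estimate_purity(rep(0.5, 20))
  expect_equal(none$purity_paper, 0)
  expect_equal(none$purity_exact, 0)
  expect_error(estimate_purity(rep(0.8, 5)), "too few")
  expect_error(estimate_purity(c(rep(0.5, 10), 1.2)), "fractions")
})

test_that("purity estimation is invariant to allele labeling (VAF folding)", {
  withr::local_seed(41)
  v <- rbinom(400, 100, 1 / (2 - 0.6)) / 100
  flipped <- ifelse(runif(400) < 0.5, 1 - v, v)
  expect_equal(estimate_purity(v)$purity_exact,
               estimate_purity(flipped)$purity_exact, tolerance = 1e-12)
})

test_that("exact inversion recovers simulated purity; 2*VAF-1 is biased down", {
  ests <- purrr::map_dfr(1:10, function(s) {
    sim <- simulate_tumor(purity = 0.6, n_snps = 500, depth = 100, seed = s)
    snps <- select_loss_het_snps(sim$variants, sim$segments)
    estimate_purity(snps$vaf)
  })
  expect_lt(max(abs(ests$purity_exact - 0.6)), 0.05)
  expect_true(all(ests$purity_paper < ests$purity_exact))
  # analytic check of the downward bias: at the true density mode
  # 1/(2-p) the paper rule returns p/(2-p) < p for p in (0,1)
  p <- seq(0.1, 0.9, by = 0.2)
  expect_true(all(p / (2 - p) < p))
})

test_that("segment correction inverts the contamination mixing model", {
  segs <- tibble::tibble(log_ratio = c(0, log2(0.75), 0.3))
  # purity 1: untouched
  expect_equal(correct_segments(segs, 1)$log_ratio_corrected, segs$log_ratio)
  # diploid fixed point at any purity
  expect_equal(correct_segments(segs, 0.37)$log_ratio_corrected[1], 0)
  # worked example: p = 0.5, observed ratio 0.75 -> one copy, ratio 0.5
  expect_equal(correct_segments(segs, 0.5)$log_ratio_corrected[2], -1)
  expect_error(correct_segments(segs, 0), "purity")
  # round trip: forward-mix then correct is the identity above the floor
  p <- 0.4
  c_true <- c(0.1, 0.5, 1, 2, 3, 4.5)
  lr_obs <- log2((p * c_true + (1 - p) * 2) / 2)
  back <- correct_segments(tibble::tibble(log_ratio = lr_obs), p)
  expect_equal(back$log_ratio_corrected, log2(c_true / 2), tolerance = 1e-12)
})

test_that("CNA calls partition the log-ratio line at the four cutpoints", {
  calls <- call_cna(tibble::tibble(
    log_ratio = c(-3, -1.2, -1, -0.7, -0.4, -0.39, 0, 0.24, 0.25, 0.5,
                  0.74, 0.75, 2)), "log_ratio")$call
  expect_equal(as.character(calls),
               c("HOMD", "HOMD", "HETD", "HETD", "HETD", "NEUT", "NEUT",
                 "NEUT", "GAIN", "GAIN", "GAIN", "AMP", "AMP"))
  # every finite value receives exactly one call
  withr::local_seed(51)
  l <- runif(200, -4, 4)
  out <- call_cna(tibble::tibble(log_ratio = l), "log_ratio")
  expect_true(all(!is.na(out$call)))
  expect_equal(levels(out$call), c("HOMD", "HETD", "NEUT", "GAIN", "AMP"))
})
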
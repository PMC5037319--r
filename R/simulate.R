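#' Synthetic-data generators
#'
#' Each generator draws from its own named substream (a fixed offset added
#' to the user seed) so that adding a generator never perturbs the output
#' of another, and reruns with the same seed are bit-identical.
#' @name simulate
#' @keywords internal
NULL

.seed_offsets <- c(plate = 101L, combination = 211L, tumor = 307L,
                   calibration = 401L, clusters = 503L)

local_stream <- function(seed, stream, envir = parent.frame()) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
  withr::local_seed(as.integer(seed) + .seed_offsets[[stream]], .local_envir = envir)
}

hill_fraction <- function(d, ec50, hill, emax, e0) {
  ifelse(d <= 0, e0, e0 + (emax - e0) * d^hill / (d^hill + ec50^hill))
}

#' Simulate a single-agent screening plate
#'
#' Forward model: a Hill dose-response
#' `f(d) = e0 + (emax - e0) * d^h / (d^h + ec50^h)` (kill fraction),
#' read out as well intensities through the plate-control scale, with
#' Gaussian well noise and a shared plate effect on the percent scale.
#' Defaults mirror the screening design: a 5-point tenfold dilution
#' ladder, 3 technical replicates, 5% well noise.
#'
#' @param ec50 Dose of half-maximal effect (µM).
#' @param hill Hill slope (>= 0).
#' @param emax,e0 Maximal/baseline kill fractions (`e0 <= emax`).
#' @param doses Dose ladder (µM), strictly increasing.
#' @param n_replicates Technical replicates.
#' @param noise_sd Well noise SD, percent-response units.
#' @param plate_sd SD of the shared plate effect, percent units.
#' @param pos_ctrl,neg_ctrl Control intensities.
#' @param model_id,passage_id,drug_id,assay,plate_id,date Identifiers
#'   stamped on the output rows.
#' @param seed Integer seed; same seed, same table.
#' @return List: `data` (long plate tibble including control wells, ready
#'   for [normalize_plate()]) and `truth` (generating parameters, the
#'   noiseless response curve and its AUC).
#' @export
simulate_plate <- function(ec50 = 0.1, hill = 1, emax = 1, e0 = 0,
                           doses = 10^seq(-3, 1, length.out = 5),
                           n_replicates = 3L, noise_sd = 5, plate_sd = 2,
                           pos_ctrl = 1000, neg_ctrl = 100,
                           model_id = "SIM1", passage_id = "P1",
                           drug_id = "DRUG1", assay = "CTG",
                           plate_id = "plate1", date = "2016-01-01",
                           seed = 1L) {
  stopifnot(e0 <= emax, hill >= 0)
  local_stream(seed, "plate")
  r_true <- 100 * hill_fraction(doses, ec50, hill, emax, e0)
  plate_effect <- rnorm(1L, 0, plate_sd)
  rows <- purrr::map_dfr(seq_len(n_replicates), function(k) {
    r_obs <- r_true + plate_effect + rnorm(length(doses), 0, noise_sd)
    tibble(dose_uM = doses, replicate = k,
           intensity = neg_ctrl + (1 - r_obs / 100) * (pos_ctrl - neg_ctrl),
           well_role = "sample")
  })
  controls <- tibble(
    dose_uM = NA_real_, replicate = NA_integer_,
    intensity = rep(c(pos_ctrl, neg_ctrl), each = 8L),
    well_role = rep(c("pos_ctrl", "neg_ctrl"), each = 8L)
  )
  data <- bind_rows(rows, controls) %>%
    mutate(model_id = model_id, passage_id = passage_id, drug_id = drug_id,
           assay = assay, plate_id = plate_id, date = date)
  truth <- list(
    ec50 = ec50, hill = hill, emax = emax, e0 = e0, doses = doses,
    response_true = r_true,
    auc_true = auc_response(fit_isotonic(doses, r_true))
  )
  list(data = data, truth = truth)
}

#' Block synergy kernel
#'
#' Convenience constructor for the injected-interaction grid: a constant
#' `value` over the top-right `block x block` corner (the highest doses of
#' both drugs), zero elsewhere.
#'
#' @param nx,ny Grid dimensions.
#' @param value Signed kill-fraction shift (positive = synergy).
#' @param block Edge length of the square block (default 2).
#' @return `nx x ny` matrix.
#' @export
synergy_kernel_block <- function(nx = 5L, ny = 5L, value = 0.15, block = 2L) {
  k <- matrix(0, nx, ny)
  k[(nx - block + 1L):nx, (ny - block + 1L):ny] <- value
  k
}

#' Simulate a two-drug combination grid
#'
#' Observed kill fractions are
#' `clip(bliss_expected(fx(i), fy(j)) + kernel[i, j] + noise, 0, 1)`:
#' independence plus an additive interaction kernel. A zero kernel
#' generates a true-independence grid. The default dose ladders start at 0
#' so the grid carries its own single-agent margins, and the default
#' `emax` of 0.5 keeps an injected +/-0.15 kernel clear of the \[0, 1\]
#' clipping bounds.
#'
#' @param params_x,params_y Hill parameter lists
#'   (`ec50`, `hill`, `emax`, `e0`) for the two drugs.
#' @param doses_x,doses_y Dose ladders; leading 0 = single-agent margin.
#' @param kernel Interaction matrix matching the grid (default all zero).
#' @param noise_sd Well noise SD on the fraction scale (default 0.02).
#' @param seed Integer seed.
#' @return List: `observed`, `doses_x`, `doses_y`, `truth` (margin
#'   fractions, expected surface, kernel).
#' @export
simulate_combination <- function(params_x = list(ec50 = 0.1, hill = 1, emax = 0.5, e0 = 0),
                                 params_y = list(ec50 = 0.1, hill = 1, emax = 0.5, e0 = 0),
                                 doses_x = c(0, 0.01, 0.1, 1, 10),
                                 doses_y = c(0, 0.01, 0.1, 1, 10),
                                 kernel = NULL, noise_sd = 0.02, seed = 1L) {
  if (is.null(kernel)) kernel <- matrix(0, length(doses_x), length(doses_y))
  if (!all(dim(kernel) == c(length(doses_x), length(doses_y)))) {
    abort("`kernel` shape must match the dose grid.")
  }
  local_stream(seed, "combination")
  fx <- do.call(hill_fraction, c(list(d = doses_x), params_x))
  fy <- do.call(hill_fraction, c(list(d = doses_y), params_y))
  expected_true <- outer(fx, fy, bliss_expected)
  noise <- matrix(rnorm(length(expected_true), 0, noise_sd),
                  nrow = length(doses_x))
  observed <- pmin(pmax(expected_true + kernel + noise, 0), 1)
  list(observed = observed, doses_x = doses_x, doses_y = doses_y,
       truth = list(fx = fx, fy = fy, expected = expected_true, kernel = kernel))
}

#' Simulate a tumor sample for purity estimation and CNA calling
#'
#' Generates a variant table and segment table with known purity `p`:
#' one-copy-loss segments carry the log-ratio of the mixing model
#' `log2((p * 1 + (1 - p) * 2) / 2)` and heterozygous SNPs whose alternate
#' read counts are Binomial(depth, 1 / (2 - p)); allele labels are swapped
#' at random (VAF -> 1 - VAF) to exercise the fold-invariance of the
#' estimator. Diploid background segments carry SNPs at Binomial(depth,
#' 0.5) and log-ratio 0.
#'
#' @param purity Tumor cell fraction in \[0, 1\].
#' @param n_snps Heterozygous SNPs in loss regions.
#' @param depth Sequencing depth per SNP.
#' @param n_background Diploid-region SNPs (default 200).
#' @param seed Integer seed.
#' @return List: `variants` (tibble with chrom, pos, gq, dp, fs, vaf,
#'   normal_genotype), `segments` (chrom, start, end, log_ratio), `truth`
#'   (purity, expected loss log-ratio, expected loss VAF).
#' @export
simulate_tumor <- function(purity = 0.6, n_snps = 500L, depth = 100L,
                           n_background = 200L, seed = 1L) {
  if (purity < 0 || purity > 1) abort("`purity` must be in [0, 1].")
  local_stream(seed, "tumor")
  loss_lr <- log2((purity * 1 + (1 - purity) * 2) / 2)
  segments <- tibble(
    chrom = c("chr1", "chr2"),
    start = c(0L, 0L),
    end = c(200e6, 200e6),
    log_ratio = c(loss_lr, 0)
  )
  vaf_loss_true <- 1 / (2 - purity)
  alt <- rbinom(n_snps, depth, vaf_loss_true)
  vaf <- alt / depth
  flip <- runif(n_snps) < 0.5
  vaf[flip] <- 1 - vaf[flip]
  loss_snps <- tibble(
    chrom = "chr1",
    pos = sort(sample.int(199e6, n_snps)),
    gq = 99, dp = depth, fs = 0,
    vaf = vaf, normal_genotype = "het"
  )
  bg_snps <- tibble(
    chrom = "chr2",
    pos = sort(sample.int(199e6, n_background)),
    gq = 99, dp = depth, fs = 0,
    vaf = rbinom(n_background, depth, 0.5) / depth,
    normal_genotype = "het"
  )
  list(
    variants = bind_rows(loss_snps, bg_snps),
    segments = segments,
    truth = list(purity = purity, loss_log_ratio = loss_lr,
                 vaf_loss = vaf_loss_true)
  )
}

#' Default capture-bias curve for calibration simulations
#'
#' Monotone (Hyman-filtered) spline through the replicate means of the
#' packaged mixing table, emulating the capture-step bias that maps true
#' human DNA content to the percentage of reads mapped to the human
#' genome.
#'
#' @return Function of true human percent -> mapped human percent.
#' @export
default_bias_curve <- function() {
  means <- read_mixing_table() %>%
    group_by(.data$true_human_pct) %>%
    summarise(m = mean(.data$mapped_human_pct), .groups = "drop")
  splinefun(means$true_human_pct, means$m, method = "hyman")
}

#' Simulate a human/mouse calibration mixture series
#'
#' `mapped = bias_curve(true) + noise`, clipped to \[0, 100\]. The default
#' bias curve interpolates the packaged mixing-table means; any monotone
#' curve on \[0, 100\] may be supplied.
#'
#' @param fractions True human DNA percentages of the series.
#' @param n_replicates Replicates per fraction.
#' @param bias_curve Monotone function percent -> percent
#'   (default [default_bias_curve()]).
#' @param noise_sd Mapping noise SD in percentage points (default 0.3).
#' @param seed Integer seed.
#' @return Tibble (`sample_id`, `true_human_pct`, `replicate`,
#'   `mapped_human_pct`, `mapped_mouse_pct`), suitable for
#'   [fit_calibration()].
#' @export
simulate_calibration_series <- function(fractions = c(0, 25, 50, 90, 100),
                                        n_replicates = 3L,
                                        bias_curve = NULL, noise_sd = 0.3,
                                        seed = 1L) {
  if (is.null(bias_curve)) bias_curve <- default_bias_curve()
  grid <- seq(0, 100, by = 1)
  if (is.unsorted(bias_curve(grid))) {
    abort("`bias_curve` must be monotone non-decreasing on [0, 100].")
  }
  local_stream(seed, "calibration")
  tidyr::expand_grid(true_human_pct = fractions,
                     replicate = seq_len(n_replicates)) %>%
    mutate(
      mapped_human_pct = pmin(pmax(
        bias_curve(.data$true_human_pct) +
          rnorm(dplyr::n(), 0, noise_sd), 0), 100),
      mapped_mouse_pct = 100 - .data$mapped_human_pct,
      sample_id = sprintf("%s_R%d", .data$true_human_pct, .data$replicate)
    ) %>%
    select("sample_id", "true_human_pct", "replicate",
           "mapped_human_pct", "mapped_mouse_pct")
}

#' Simulate cluster cellular prevalences with credible intervals
#'
#' Fixtures for the credible-interval shift rule: each cluster has a base
#' prevalence; in truly shifting clusters one sample is displaced by
#' `shift`. Intervals are `center +/- ci_width / 2` around jittered
#' centers, clipped to \[0, 1\].
#'
#' @param n_clusters,n_samples Grid size.
#' @param shifted_clusters Indices of clusters that truly shift
#'   (default 1; use `integer(0)` for all-stable).
#' @param shift Displacement of the shifted sample (prevalence units).
#' @param ci_width Width of each credible interval.
#' @param center_jitter SD of the jitter on interval centers
#'   (default 0.02).
#' @param seed Integer seed.
#' @return List: `clusters` tibble (`cluster_id`, `sample_id`, `ci_lo`,
#'   `ci_hi`), `truth` (logical vector of true shift flags).
#' @export
simulate_cluster_prevalences <- function(n_clusters = 5L, n_samples = 4L,
                                         shifted_clusters = 1L, shift = 0.5,
                                         ci_width = 0.1, center_jitter = 0.02,
                                         seed = 1L) {
  local_stream(seed, "clusters")
  base <- runif(n_clusters, 0.2, 0.8)
  rows <- purrr::map_dfr(seq_len(n_clusters), function(cl) {
    centers <- base[cl] + rnorm(n_samples, 0, center_jitter)
    if (cl %in% shifted_clusters) {
      shifted_sample <- sample.int(n_samples, 1L)
      centers[shifted_sample] <- centers[shifted_sample] +
        if (base[cl] > 0.5) -shift else shift
    }
    centers <- pmin(pmax(centers, 0), 1)
    tibble(
      cluster_id = cl, sample_id = paste0("S", seq_len(n_samples)),
      ci_lo = pmax(centers - ci_width / 2, 0),
      ci_hi = pmin(centers + ci_width / 2, 1)
    )
  })
  list(clusters = rows,
       truth = seq_len(n_clusters) %in% shifted_clusters)
}
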
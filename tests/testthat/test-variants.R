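toy_qc_expectations <- function() {
  list(
    fail = c(v02 = "low_gq", v04 = "low_dp", v06 = "high_fs",
             v07 = "high_fs", v09 = "low_gq;low_dp;high_fs",
             v10 = "missing_field", v11 = "homopolymer", v13 = "homopolymer"),
    pass = sprintf("v%02d", c(1, 3, 5, 8, 12, 14:20)),
    clonality_excluded = c("v04", "v09", "v15", "v16", "v17")
  )
}

test_that("QC thresholds annotate the toy table exactly as constructed", {
  toy <- read_variant_toy()
  out <- filter_variants(toy)
  per_variant <- out |>
    dplyr::distinct(variant_id, qc_pass, fail_reasons)
  exp <- toy_qc_expectations()
  expect_setequal(per_variant$variant_id[per_variant$qc_pass], exp$pass)
  got_reasons <- setNames(per_variant$fail_reasons, per_variant$variant_id)
  for (v in names(exp$fail)) expect_equal(unname(got_reasons[v]), exp$fail[[v]])
})

test_that("threshold boundaries sit exactly where printed", {
  rec <- function(gq, dp, fs) tibble::tibble(gq = gq, dp = dp, fs = fs)
  expect_false(suppressWarnings(filter_variants(rec(19, 50, 0)))$qc_pass)
  expect_true(suppressWarnings(filter_variants(rec(20, 50, 0)))$qc_pass)
  expect_false(suppressWarnings(filter_variants(rec(99, 4, 0)))$qc_pass)
  expect_true(suppressWarnings(filter_variants(rec(99, 5, 0)))$qc_pass)
  expect_false(suppressWarnings(filter_variants(rec(99, 50, 40)))$qc_pass)
  expect_true(suppressWarnings(filter_variants(rec(99, 50, 39.9)))$qc_pass)
  expect_warning(filter_variants(rec(99, 50, 0)), "homopolymer filter skipped")
})

test_that("homopolymer detection respects run length and window", {
  hp <- function(ctx) {
    filter_variants(tibble::tibble(gq = 99, dp = 50, fs = 0,
                                   context = ctx))$fail_reasons
  }
  expect_equal(hp("ACGTACGTAAAAAGTACGTAC"), "homopolymer")  # run 5 at center
  expect_equal(hp("ACGTACGTAAAAGTACGTACG"), "")             # run 4
  expect_equal(hp("CAAAAACGTACGTACGTACGT"), "homopolymer")  # run ends at edge
  expect_equal(hp("AAAAACGTACGTACGTACGTA"), "")             # run outside window
})

test_that("germline labeling and the segdup recurrence rule annotate correctly", {
  v <- tibble::tibble(
    variant_id = c("a", "a", "a", "b", "c", "c", "c", "c"),
    sample_id = c("s1", "s2", "s3", "s1", "s1", "s2", "s3", "s4"),
    gq = 99, dp = 50, fs = 0,
    in_1000g = c(rep(FALSE, 4), rep(TRUE, 4)),
    in_normal = FALSE,
    is_insertion = c(rep(TRUE, 4), rep(FALSE, 4)),
    in_segdup = c(rep(TRUE, 4), rep(FALSE, 4))
  )
  out <- suppressWarnings(filter_variants(v))
  # "a" is a segdup insertion seen in 3 samples: recurrent, kept
  expect_false(any(out$segdup_excluded[out$variant_id == "a"]))
  # "b" is a singleton segdup insertion: excluded
  expect_true(all(out$segdup_excluded[out$variant_id == "b"]))
  # "c" is in the population database: germline, not somatic
  expect_true(all(out$germline[out$variant_id == "c"]))
  expect_false(any(out$somatic[out$variant_id == "c"]))
  expect_true(all(out$somatic[out$variant_id == "a"]))
})

test_that("MATH matches hand arithmetic and basic distribution shape", {
  expect_equal(math_score(rep(0.4, 10)), 0)
  expect_equal(math_score(c(0.4, 0.5, 0.6)), 29.652)
  expect_error(math_score(c(0.4, 0.5)), "at least 3")
  expect_warning(res <- math_score(c(0, 0, 0)), "undefined")
  expect_true(is.na(res))
  # scale-free in the VAFs
  withr::local_seed(61)
  v <- runif(40, 0.1, 0.9)
  expect_equal(math_score(v), math_score(0.37 * v), tolerance = 1e-12)
  # bimodal VAFs score higher than a tight unimodal set of the same size
  bimodal <- c(rep(0.1, 50), rep(0.5, 50))
  unimodal <- pmin(pmax(rnorm(100, 0.3, 0.02), 0), 1)
  expect_gt(math_score(bimodal), math_score(unimodal))
})

test_that("MATH grows with clone separation in two-clone mixtures", {
  withr::local_seed(62)
  seps <- c(0.05, 0.15, 0.25, 0.35)
  scores <- sapply(seps, function(d) {
    v <- c(rnorm(100, 0.45 - d / 2, 0.01), rnorm(100, 0.45 + d / 2, 0.01))
    math_score(v)
  })
  expect_true(all(diff(scores) > 0))
})

test_that("clonality input filters match the toy construction", {
  toy <- read_variant_toy()
  out <- prepare_clonality_input(toy |> dplyr::rename(depth = dp))
  exp <- toy_qc_expectations()
  expect_setequal(unique(out$mutation_id),
                  setdiff(sprintf("v%02d", 1:20), exp$clonality_excluded))
  expect_named(out, c("mutation_id", "sample_id", "ref_counts", "var_counts",
                      "normal_cn", "minor_cn", "major_cn", "tumour_content"))
  expect_true(all(out$tumour_content == 1))
  expect_true(all(out$ref_counts + out$var_counts > 0))
})

test_that("the top-k rule caps output at 300 by median depth with genomic ties", {
  withr::local_seed(63)
  n <- 350
  d <- tibble::tibble(
    variant_id = rep(sprintf("m%03d", 1:n), each = 2),
    chrom = "chr1",
    pos = rep(1:n, each = 2),
    sample_id = rep(c("s1", "s2"), n),
    depth = rep(sample(50:500, n, replace = TRUE), each = 2),
    vaf = 0.4
  )
  out <- prepare_clonality_input(d)
  kept <- unique(out$mutation_id)
  expect_equal(length(kept), 300L)
  med <- d |> dplyr::group_by(variant_id) |>
    dplyr::summarise(md = median(depth))
  thresh <- sort(med$md, decreasing = TRUE)[300]
  expect_true(all(med$md[med$variant_id %in% kept] >= thresh))
  # filters are set-semantic: permuting rows gives the same kept set
  out2 <- prepare_clonality_input(d[sample(nrow(d)), ])
  expect_setequal(unique(out2$mutation_id), kept)
})

test_that("spec'd clonality exclusions hold on minimal cases", {
  base <- tibble::tibble(
    variant_id = "v", sample_id = c("s1", "s2", "s3"),
    depth = c(60, 60, 10), vaf = 0.4
  )
  expect_warning(out <- prepare_clonality_input(base), "no variants")
  expect_equal(nrow(out), 0L)
  lowvaf <- tibble::tibble(variant_id = "v", sample_id = c("s1", "s2"),
                           depth = 100, vaf = c(0.05, 0.08))
  expect_warning(out2 <- prepare_clonality_input(lowvaf), "no variants")
  expect_equal(nrow(out2), 0L)
})

test_that("cluster-shift flagging implements CI disjointness per sample", {
  same <- tibble::tibble(cluster_id = 1, sample_id = c("a", "b", "c"),
                         ci_lo = 0.4, ci_hi = 0.6)
  expect_equal(flag_significant_clusters(same)$status, "stable")
  shifted <- tibble::tibble(cluster_id = 1, sample_id = c("a", "b", "c"),
                            ci_lo = c(0.8, 0.1, 0.15),
                            ci_hi = c(0.9, 0.2, 0.25))
  expect_equal(flag_significant_clusters(shifted)$status, "significant")
  overlap <- tibble::tibble(cluster_id = 1, sample_id = c("a", "b"),
                            ci_lo = c(0.1, 0.4), ci_hi = c(0.5, 0.8))
  expect_equal(flag_significant_clusters(overlap)$status, "stable")
  # touching endpoints count as overlapping
  touch <- tibble::tibble(cluster_id = 1, sample_id = c("a", "b"),
                          ci_lo = c(0.1, 0.5), ci_hi = c(0.5, 0.9))
  expect_equal(flag_significant_clusters(touch)$status, "stable")
  single <- tibble::tibble(cluster_id = 1, sample_id = "a",
                           ci_lo = 0.2, ci_hi = 0.4)
  expect_equal(flag_significant_clusters(single)$status, "not_assessable")
})

test_that("flagging equals a brute-force all-pairs disjointness oracle", {
  brute <- function(lo, hi) {
    any(sapply(seq_along(lo), function(s) {
      all(sapply(seq_along(lo)[-s], function(t) hi[s] < lo[t] || lo[s] > hi[t]))
    }))
  }
  withr::local_seed(71)
  for (k in 1:50) {
    n <- sample(2:6, 1)
    lo <- runif(n)
    hi <- lo + runif(n, 0, 0.4)
    df <- tibble::tibble(cluster_id = 1, sample_id = paste0("s", 1:n),
                         ci_lo = lo, ci_hi = pmin(hi, 1))
    expect_equal(flag_significant_clusters(df)$flagged,
                 brute(df$ci_lo, df$ci_hi))
  }
})

test_that("promoter methylation averages covered CpGs in the TSS window", {
  tss <- tibble::tibble(chrom = "chr1", tss = 10000L, gene = "G1")
  cpg <- tibble::tibble(
    chrom = "chr1",
    pos = c(10000L, 8000L, 12000L, 12001L, 7999L, 10500L),
    meth_reads = c(10, 5, 0, 10, 10, 2),
    total_reads = c(10, 10, 10, 10, 10, 4)
  )
  out <- promoter_methylation(cpg, tss)
  # qualifying: pos 10000 (beta 1), 8000 (0.5), 12000 (0); 12001/7999 out of
  # window, 10500 under-covered
  expect_equal(out$n_cpgs, 3L)
  expect_equal(out$promoter_meth, 0.5)
  # fully methylated promoter scores 1
  full <- promoter_methylation(
    tibble::tibble(chrom = "chr1", pos = 10000L, meth_reads = 8,
                   total_reads = 8), tss)
  expect_equal(full$promoter_meth, 1)
  # no qualifying CpG: NA score, zero count
  empty <- promoter_methylation(
    tibble::tibble(chrom = "chr1", pos = 50000L, meth_reads = 5,
                   total_reads = 10), tss)
  expect_true(is.na(empty$promoter_meth))
  expect_equal(empty$n_cpgs, 0L)
})

test_that("BED6 TSS input resolves strand-aware start sites", {
  bed <- tibble::tibble(chrom = "chr1", start = 999L, end = 2000L,
                        name = c("Gplus", "Gminus"), score = 0,
                        strand = c("+", "-"))
  cpg <- tibble::tibble(chrom = "chr1", pos = c(1000L, 2000L),
                        meth_reads = c(10, 0), total_reads = 10)
  out <- promoter_methylation(cpg, bed, window = 100L)
  # + gene TSS = start + 1 = 1000 -> only the methylated CpG in window
  expect_equal(out$promoter_meth[out$gene == "Gplus"], 1)
  # - gene TSS = end = 2000 -> only the unmethylated CpG
  expect_equal(out$promoter_meth[out$gene == "Gminus"], 0)
})
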
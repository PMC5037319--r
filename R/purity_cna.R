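#' Select heterozygous SNPs in copy-loss regions
#'
#' Picks the variants that inform the tumor-purity estimate: heterozygous
#' SNPs (in the matched normal when available, otherwise heterozygous in
#' the tumor) lying inside segments with segmented log2 ratio below the
#' loss threshold. In such loss-of-heterozygosity regions a pure tumor
#' shows VAF 0 or 1; residual mouse/normal contamination pulls the VAF
#' toward 0.5.
#'
#' @param variants Tibble with `chrom`, `pos` (1-based) and a genotype
#'   column: `normal_genotype` when a matched normal exists, else
#'   `genotype` (values `"hom_ref"`, `"het"`, `"hom_alt"`, `"unknown"`).
#' @param segments Tibble with `chrom`, `start`, `end` (0-based half-open)
#'   and `log_ratio`.
#' @param loss_threshold Segments with `log_ratio` strictly below this are
#'   loss regions (default -0.1).
#' @return The qualifying variant rows with the segment `log_ratio`
#'   appended; zero rows when nothing qualifies.
#' @export
select_loss_het_snps <- function(variants, segments, loss_threshold = -0.1) {
  variants <- as_tibble(variants)
  segments <- as_tibble(segments)
  geno_col <- if ("normal_genotype" %in% names(variants)) "normal_genotype"
              else if ("genotype" %in% names(variants)) "genotype"
              else abort("`variants` needs a `normal_genotype` or `genotype` column.")
  loss <- filter(segments, .data$log_ratio < loss_threshold) %>%
    select("chrom", "start", "end", "log_ratio")
  variants %>%
    filter(.data[[geno_col]] == "het") %>%
    mutate(.pos0 = .data$pos - 1L) %>%  # 1-based position -> 0-based point
    inner_join(loss, by = join_by("chrom", ".pos0" >= "start", ".pos0" < "end")) %>%
    select(-".pos0", -"start", -"end")
}

#' Estimate tumor purity from loss-region VAFs
#'
#' VAFs of heterozygous SNPs in one-copy-loss regions concentrate at
#' `1 / (2 - p)` for tumor purity `p` (the retained allele is carried by
#' all tumor cells plus half the contaminating normal cells). VAFs are
#' folded to \[0.5, 1\] (`v -> max(v, 1 - v)`) so that the estimate does
#' not depend on which allele was lost, and the mode of a Gaussian kernel
#' density (Silverman bandwidth, 512-point grid on \[0.5, 1\]) is taken as
#' the consensus VAF. Two estimates are returned: `purity_paper`, the
#' `2 * VAF - 1` rule (a downward-biased estimate for partial purity), and
#' `purity_exact`, the exact inversion `2 - 1 / VAF` of the expected-VAF
#' model, which is the recommended estimator.
#'
#' @param vafs Variant allele fractions in \[0, 1\] of loss-region
#'   heterozygous SNPs.
#' @param min_snps Minimum number of SNPs required (default 10).
#' @return One-row tibble: `n_snps`, `vaf_mode`, `purity_paper`,
#'   `purity_exact`.
#' @examples
#' estimate_purity(rep(1, 20))  # pure tumor, both estimators 1
#' @export
estimate_purity <- function(vafs, min_snps = 10L) {
  vafs <- as.numeric(vafs)
  if (any(!is.finite(vafs)) || any(vafs < 0 | vafs > 1)) {
    abort("`vafs` must be fractions in [0, 1].")
  }
  if (length(vafs) < min_snps) {
    abort(sprintf("too few loss-region SNPs: %d (minimum %d).",
                  length(vafs), min_snps))
  }
  folded <- pmax(vafs, 1 - vafs)
  if (diff(range(folded)) < .Machine$double.eps^0.5) {
    mode <- folded[1L]
  } else {
    dens <- density(folded, bw = "nrd0", n = 512L, from = 0.5, to = 1)
    mode <- dens$x[which.max(dens$y)]
  }
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  tibble(
    n_snps = length(vafs),
    vaf_mode = mode,
    purity_paper = clip01(2 * mode - 1),
    purity_exact = clip01(2 - 1 / mode)
  )
}

#' Correct segmented log-ratios for normal contamination
#'
#' Inverts the mixing model `observed copies = p * c + (1 - p) * 2`:
#' the tumor copy number is `c = (2^l - (1 - p)) * 2 / p`, floored at
#' `min_copies` to keep the log defined, and the corrected log ratio is
#' `log2(c / 2)`. Purity 1 leaves the input unchanged; a diploid segment
#' (`l = 0`) is a fixed point at any purity.
#'
#' @param segments Tibble with a `log_ratio` column.
#' @param purity Tumor cell fraction in (0, 1].
#' @param min_copies Floor on the inferred copy number (default 0.01).
#' @return `segments` with `log_ratio_corrected` appended.
#' @export
correct_segments <- function(segments, purity, min_copies = 0.01) {
  if (!is.finite(purity) || purity <= 0 || purity > 1) {
    abort("`purity` must be in (0, 1]; purity 0 means no tumor signal to correct.")
  }
  segments <- as_tibble(segments)
  if (any(!is.finite(segments$log_ratio))) abort("`log_ratio` must be finite.")
  mutate(segments,
    log_ratio_corrected = log2(pmax(
      (2^.data$log_ratio - (1 - purity)) * 2 / purity, min_copies) / 2)
  )
}

#' Five-state copy-number calls from corrected log-ratios
#'
#' Thresholds the (purity-corrected) segmented log2 ratio at the four
#' cutpoints -1, -0.4, 0.25, 0.75:
#' HOMD (homozygous deletion) `l < -1`; HETD (heterozygous deletion)
#' `-1 <= l <= -0.4`; NEUT (neutral) `-0.4 < l < 0.25`; GAIN (single-copy
#' gain) `0.25 <= l < 0.75`; AMP (high-level amplification) `l >= 0.75`.
#' The boundaries are assigned so that an exact single-copy loss
#' (`l = -1` at purity 1) is HETD and an exact two-fold gain (`l = 1`) is
#' AMP; every finite value receives exactly one call.
#'
#' @param segments Tibble with the log-ratio column.
#' @param ratio_col Column to threshold (default `log_ratio_corrected`,
#'   falling back to `log_ratio` when absent).
#' @return `segments` with an ordered factor column `call` appended.
#' @export
call_cna <- function(segments, ratio_col = NULL) {
  segments <- as_tibble(segments)
  if (is.null(ratio_col)) {
    ratio_col <- if ("log_ratio_corrected" %in% names(segments))
      "log_ratio_corrected" else "log_ratio"
  }
  l <- segments[[ratio_col]]
  if (is.null(l) || any(!is.finite(l))) abort("log-ratio column must be finite.")
  call <- dplyr::case_when(
    l < -1 ~ "HOMD",
    l <= -0.4 ~ "HETD",
    l < 0.25 ~ "NEUT",
    l < 0.75 ~ "GAIN",
    TRUE ~ "AMP"
  )
  mutate(segments,
         call = factor(call, levels = c("HOMD", "HETD", "NEUT", "GAIN", "AMP"),
                       ordered = TRUE))
}
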
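#' Annotate variants with QC filters
#'
#' Applies the variant quality filters: genotype quality `gq >= 20`, depth
#' `dp >= 5`, Phred-scale strand bias `fs < 40`, and absence of a
#' homopolymer run (length >= `homopolymer_len`) within
#' `+/- homopolymer_flank` bases of the site. Every failing filter is
#' recorded, so a record can carry several reasons; nothing is dropped.
#' Germline labeling (membership in a population-variant list or presence
#' in any normal sample) and the segmental-duplication insertion rule
#' (excluded unless seen in >= 3 samples or >= 3/4 of the model's samples)
#' are annotated when the corresponding columns are present.
#'
#' Expected columns: `gq`, `dp`, `fs`; optional `context` (reference
#' sequence centered on the variant; without it the homopolymer filter is
#' skipped with a warning), `in_1000g`, `in_normal`, `is_insertion`,
#' `in_segdup`, and `variant_id` + `sample_id` (for the recurrence rule).
#'
#' @param variants Tibble of variant records.
#' @param gq_min,dp_min,fs_max QC thresholds (defaults 20, 5, 40).
#' @param homopolymer_len Minimum run length that triggers the homopolymer
#'   filter (default 5).
#' @param homopolymer_flank Window around the site, in bases (default 5).
#' @return `variants` with `qc_pass`, `fail_reasons` (`";"`-joined, `""`
#'   when clean), `germline`, `segdup_excluded`, `somatic` appended.
#' @export
filter_variants <- function(variants, gq_min = 20, dp_min = 5, fs_max = 40,
                            homopolymer_len = 5L, homopolymer_flank = 5L) {
  variants <- as_tibble(variants)
  need <- c("gq", "dp", "fs")
  if (!all(need %in% names(variants))) {
    abort("`variants` needs `gq`, `dp` and `fs` columns.")
  }
  n <- nrow(variants)
  reasons <- vector("list", n)
  add <- function(idx, reason) {
    for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], reason)
  }
  missing_field <- is.na(variants$gq) | is.na(variants$dp) | is.na(variants$fs)
  add(missing_field, "missing_field")
  ok <- !missing_field
  add(ok & variants$gq < gq_min, "low_gq")
  add(ok & variants$dp < dp_min, "low_dp")
  add(ok & variants$fs >= fs_max, "high_fs")
  if ("context" %in% names(variants)) {
    homopol <- vapply(variants$context, has_homopolymer, logical(1),
                      min_run = homopolymer_len, flank = homopolymer_flank)
    add(!is.na(homopol) & homopol, "homopolymer")
  } else {
    warn("no `context` column: homopolymer filter skipped.")
  }
  germline <- rep(FALSE, n)
  if ("in_1000g" %in% names(variants)) germline <- germline | isTRUE_vec(variants$in_1000g)
  if ("in_normal" %in% names(variants)) germline <- germline | isTRUE_vec(variants$in_normal)
  segdup_excluded <- rep(FALSE, n)
  if (all(c("is_insertion", "in_segdup") %in% names(variants))) {
    flagged <- isTRUE_vec(variants$is_insertion) & isTRUE_vec(variants$in_segdup)
    if (all(c("variant_id", "sample_id") %in% names(variants))) {
      n_samples <- n_distinct(variants$sample_id)
      counts <- variants %>%
        distinct(.data$variant_id, .data$sample_id) %>%
        dplyr::count(.data$variant_id, name = ".n_seen")
      seen <- counts$.n_seen[match(variants$variant_id, counts$variant_id)]
      recurrent <- seen >= 3L | seen >= ceiling(0.75 * n_samples)
      segdup_excluded <- flagged & !recurrent
    } else {
      segdup_excluded <- flagged
    }
  }
  variants %>%
    mutate(
      fail_reasons = vapply(reasons, function(r)
        paste(r, collapse = ";"), character(1)),
      qc_pass = .data$fail_reasons == "",
      germline = germline,
      segdup_excluded = segdup_excluded,
      somatic = .data$qc_pass & !germline & !segdup_excluded
    )
}

# TRUE where x is TRUE, FALSE elsewhere (NA-safe)
isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

# homopolymer run >= min_run overlapping +/- flank of the center base
has_homopolymer <- function(context, min_run = 5L, flank = 5L) {
  if (is.na(context) || !nzchar(context)) return(NA)
  bases <- strsplit(toupper(context), "")[[1]]
  center <- ceiling(length(bases) / 2)
  runs <- rle(bases)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  any(runs$lengths >= min_run &
        starts <= center + flank & ends >= center - flank)
}

#' MATH intra-tumor heterogeneity score
#'
#' Mutant-allele tumor heterogeneity: the width of the center of the VAF
#' distribution relative to its center, `100 * MAD / median`, with the
#' median absolute deviation scaled by the Gaussian consistency constant
#' 1.4826. Higher scores mean a broader VAF spread, i.e. more subclonal
#' structure.
#'
#' @param vafs Somatic variant allele fractions (>= 3 values).
#' @return The MATH score; `NA` when the median VAF is 0.
#' @examples
#' math_score(c(0.4, 0.5, 0.6))  # 29.652
#' @export
math_score <- function(vafs) {
  vafs <- as.numeric(vafs)
  if (length(vafs) < 3L) abort("MATH needs at least 3 VAFs.")
  if (any(!is.finite(vafs))) abort("`vafs` must be finite.")
  med <- median(vafs)
  if (med == 0) {
    warn("median VAF is 0: MATH undefined.")
    return(NA_real_)
  }
  100 * mad(vafs) / med
}

#' Prepare variant input for clonal-inference tools
#'
#' Applies the clonality input filters to a model's variant-by-sample
#' table: keep variants with median depth >= 50 across the model's
#' samples, depth >= 15 in every sample, and VAF >= 0.1 in at least one
#' sample; if more than `max_variants` remain, keep the `max_variants`
#' with the highest median depth (ties broken by genomic order). Emits the
#' per-sample count table expected by clonal-inference tools.
#'
#' @param data Long tibble: `variant_id`, `sample_id`, `depth`, and `vaf`
#'   or `alt_count`; optional `chrom` + `pos` for the genomic tie-break.
#' @param purity Per-sample tumor content: named vector or tibble
#'   (`sample_id`, `purity`); a single unnamed value is recycled.
#'   Default 1 (explant samples have no human normal contamination).
#' @param min_median_depth,min_depth,min_max_vaf,max_variants Filter
#'   thresholds (defaults 50, 15, 0.1, 300).
#' @return Tibble: `mutation_id`, `sample_id`, `ref_counts`, `var_counts`,
#'   `normal_cn`, `minor_cn`, `major_cn`, `tumour_content`.
#' @export
prepare_clonality_input <- function(data, purity = 1,
                                    min_median_depth = 50, min_depth = 15,
                                    min_max_vaf = 0.1, max_variants = 300L) {
  data <- as_tibble(data)
  need <- c("variant_id", "sample_id", "depth")
  if (!all(need %in% names(data))) {
    abort("`data` needs `variant_id`, `sample_id` and `depth` columns.")
  }
  if (!"alt_count" %in% names(data)) {
    if (!"vaf" %in% names(data)) abort("`data` needs `vaf` or `alt_count`.")
    data <- mutate(data, alt_count = round(.data$vaf * .data$depth))
  }
  if (!"vaf" %in% names(data)) {
    data <- mutate(data, vaf = ifelse(.data$depth > 0, .data$alt_count / .data$depth, 0))
  }
  stats_tbl <- data %>%
    group_by(.data$variant_id) %>%
    summarise(
      .med_depth = median(.data$depth),
      .min_depth = min(.data$depth),
      .max_vaf = max(.data$vaf),
      .chrom = if ("chrom" %in% names(data)) dplyr::first(.data$chrom) else NA_character_,
      .pos = if ("pos" %in% names(data)) dplyr::first(.data$pos) else NA_real_,
      .groups = "drop"
    ) %>%
    filter(.data$.med_depth >= min_median_depth,
           .data$.min_depth >= min_depth,
           .data$.max_vaf >= min_max_vaf) %>%
    arrange(desc(.data$.med_depth), .data$.chrom, .data$.pos, .data$variant_id) %>%
    slice_head(n = max_variants)
  if (!nrow(stats_tbl)) {
    warn("no variants survive the clonality input filters.")
  }
  purity_tbl <- if (is.data.frame(purity)) {
    as_tibble(purity)
  } else if (!is.null(names(purity))) {
    tibble(sample_id = names(purity), purity = unname(purity))
  } else {
    tibble(sample_id = unique(data$sample_id), purity = purity)
  }
  data %>%
    semi_join(stats_tbl, by = "variant_id") %>%
    left_join(purity_tbl, by = "sample_id") %>%
    mutate(
      mutation_id = .data$variant_id,
      ref_counts = .data$depth - .data$alt_count,
      var_counts = .data$alt_count,
      normal_cn = 2L, minor_cn = 0L, major_cn = 2L,
      tumour_content = .data$purity
    ) %>%
    select("mutation_id", "sample_id", "ref_counts", "var_counts",
           "normal_cn", "minor_cn", "major_cn", "tumour_content")
}

#' Flag clusters whose prevalence shifts between samples
#'
#' A mutation cluster is called significant when some sample's 90%
#' credible interval for its cellular prevalence is disjoint from the
#' interval of every other sample of that cluster. Intervals are closed;
#' touching endpoints count as overlapping. Clusters observed in a single
#' sample cannot be assessed and get their own status.
#'
#' @param clusters Tibble: `cluster_id`, `sample_id`, `ci_lo`, `ci_hi`.
#' @return Tibble per cluster: `cluster_id`, `n_samples`, `flagged`
#'   (`NA` when not assessable), `status` (`"significant"`, `"stable"`,
#'   `"not_assessable"`).
#' @export
flag_significant_clusters <- function(clusters) {
  clusters <- as_tibble(clusters)
  need <- c("cluster_id", "sample_id", "ci_lo", "ci_hi")
  if (!all(need %in% names(clusters))) {
    abort("`clusters` needs cluster_id, sample_id, ci_lo, ci_hi.")
  }
  if (any(clusters$ci_lo > clusters$ci_hi)) abort("ci_lo must be <= ci_hi.")
  any_disjoint_sample <- function(lo, hi) {
    if (length(lo) < 2L) return(NA)
    any(vapply(seq_along(lo), function(s) {
      all(hi[s] < lo[-s] | lo[s] > hi[-s])
    }, logical(1)))
  }
  clusters %>%
    group_by(.data$cluster_id) %>%
    summarise(
      n_samples = n(),
      flagged = any_disjoint_sample(.data$ci_lo, .data$ci_hi),
      .groups = "drop"
    ) %>%
    mutate(status = case_when(
      is.na(.data$flagged) ~ "not_assessable",
      .data$flagged ~ "significant",
      TRUE ~ "stable"
    ))
}

#' Promoter methylation scores from CpG counts
#'
#' Per-gene promoter methylation: the mean methylation proportion (beta)
#' over CpG sites with at least `min_reads` total reads lying within
#' `+/- window` bases of the transcription start site (inclusive window,
#' strand-agnostic). Genes with no qualifying CpG get `NA`.
#'
#' @param cpg Tibble: `chrom`, `pos`, `meth_reads`, `total_reads`.
#' @param tss Tibble: `chrom`, `tss`, `gene` (one row per gene/TSS); or
#'   BED6-style columns `chrom`, `start`, `end`, `name`, `score`, `strand`
#'   (TSS = `start + 1` on `+`, `end` on `-`).
#' @param min_reads Minimum CpG coverage (default 5).
#' @param window Half-width of the promoter window in bases (default 2000).
#' @return Tibble per gene: `gene`, `n_cpgs`, `promoter_meth`.
#' @export
promoter_methylation <- function(cpg, tss, min_reads = 5L, window = 2000L) {
  cpg <- as_tibble(cpg)
  tss <- as_tibble(tss)
  if (!all(c("chrom", "pos", "meth_reads", "total_reads") %in% names(cpg))) {
    abort("`cpg` needs chrom, pos, meth_reads, total_reads.")
  }
  if (any(cpg$meth_reads > cpg$total_reads)) {
    abort("`meth_reads` cannot exceed `total_reads`.")
  }
  if (!"tss" %in% names(tss)) {
    if (all(c("start", "end", "strand", "name") %in% names(tss))) {
      tss <- tss %>%
        mutate(gene = .data$name,
               tss = ifelse(.data$strand == "-", .data$end, .data$start + 1L))
    } else {
      abort("`tss` needs (chrom, tss, gene) or BED6 columns.")
    }
  }
  if (!"gene" %in% names(tss)) abort("`tss` needs a `gene` column.")
  covered <- filter(cpg, .data$total_reads >= min_reads) %>%
    mutate(beta = .data$meth_reads / .data$total_reads)
  windows <- tss %>%
    mutate(.lo = .data$tss - window, .hi = .data$tss + window) %>%
    select("gene", "chrom", "tss", ".lo", ".hi")
  hits <- inner_join(windows, covered,
                     by = join_by("chrom", ".lo" <= "pos", ".hi" >= "pos"))
  scores <- hits %>%
    group_by(.data$gene) %>%
    summarise(n_cpgs = n(), promoter_meth = mean(.data$beta), .groups = "drop")
  windows %>%
    distinct(.data$gene) %>%
    left_join(scores, by = "gene") %>%
    mutate(n_cpgs = ifelse(is.na(.data$n_cpgs), 0L, .data$n_cpgs))
}

#' Constructed 20-variant QC toy table
#'
#' A small synthetic variant table packaged for worked examples and filter
#' checks: 20 variants x 3 samples with genotype quality, depth, strand
#' bias, VAF and reference context chosen to exercise every QC threshold
#' (including both sides of each boundary) and every clonality input
#' filter.
#'
#' @return Tibble with columns `variant_id`, `chrom`, `pos`, `sample_id`,
#'   `gq`, `dp`, `fs`, `vaf`, `context`.
#' @export
read_variant_toy <- function() {
  path <- system.file("extdata", "variant_qc_toy.csv", package = "pdxscreen",
                      mustWork = TRUE)
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
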
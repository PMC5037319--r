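# pdxscreen

Analysis toolkit for ex vivo drug screens on patient-derived tumor
xenograft (PDTX) explant cultures, and for the genomics bookkeeping that
xenograft samples need: mouse/human admixture calibration, tumor-purity
estimation, copy-number calling and intra-tumor-heterogeneity scores.

It is aimed at groups running plate-based viability screens on short-term
cultures from xenografted tumors, where three mixture problems recur:

1. **Wells** mix signal and background — raw intensities are normalized to
   percent-of-cells-dead against each plate's positive/negative controls,
   `r = 100 − 100·(I − C⁻)/(C⁺ − C⁻)`.
2. **Drugs** mix effects — single-agent responses are fitted by isotonic
   (monotone) regression with trapezoid AUC, smoothing-spline IC50 (with
   explicit censoring), percent-dose IC50 and replicate error bars, and
   classified against eight canonical response patterns; two-drug dose
   matrices are scored against the Bliss independence surface
   `rx + ry − rx·ry` using an exact bivariate isotonic (bimonotone) fit,
   with the 95th percentile of the signed residuals as the synergy
   summary.
3. **Genomes** mix species and cell types — a loess calibration maps the
   fraction of reads aligning to the human side of a combined human–mouse
   genome to true human DNA content; purity is estimated from VAFs of
   heterozygous SNPs in copy-loss regions (mode of the folded-VAF density;
   exact inversion `2 − 1/VAF` alongside the classical `2·VAF − 1`);
   segmented log2 ratios are purity-corrected and called
   HOMD/HETD/NEUT/GAIN/AMP at cutpoints (−1, −0.4, 0.25, 0.75). Variant QC
   filters, the MATH score (100·MAD/median of VAFs), clonality-input
   preparation, credible-interval cluster flags and promoter methylation
   scores round out the tool set.

A synthetic-data module generates every input type with known ground truth
(Hill-curve plates, combination grids with injected synergy, binomial
VAF sampling at known purity, calibration mixture series), so the whole
pipeline is testable without any external data. Everything is data-frame
in, tibble out; fitted objects have `tidy()`, `glance()` and `autoplot()`
methods.

## Worked example

```r
library(pdxscreen)

# a simulated 5-dose, 3-replicate screen with EC50 at the middle dose
sim <- simulate_plate(ec50 = 0.1, seed = 7)
responses <- normalize_plate(sim$data)
fit_dose_response(responses)
#>   model_id passage_id drug_id n_doses n_replicates   auc auc_sd ic50_uM
#> 1 SIM1     P1         DRUG1         5            3 0.498 0.0164   0.104
#>   ic50_censor ic50_pct ic50_sd ic50_censored_reps pattern_id pattern_distance
#> 1 estimated       1.03  0.0278                  0          5             504.
```

The drug kills half the cells over the ladder (`auc` 0.50), crosses 50%
kill at 0.104 µM — recovering the generating EC50 of 0.1 within replicate
noise (`ic50_sd` 0.028) — at 1% of the tested dose range, and the curve
shape matches template 5, the graded full-response pattern.

```r
# a 5x5 combination grid with +0.15 synergy injected in the top-right block
combo <- simulate_combination(kernel = synergy_kernel_block(value = 0.15), seed = 7)
glance(fit_bliss(combo$observed, combo$doses_x, combo$doses_y))
#>   p95_residual_pct mean_residual_pct min_residual_pct max_residual_pct argmax_dose_x argmax_dose_y
#> 1             14.8              2.20            -2.36             15.0            10             1

# human DNA content from mapped-read percentages, via the packaged mixing table
cal <- fit_calibration(read_mixing_table())
estimate_human_content(cal, c(62.44, 97.59))
#>   mapped_human_pct est_human_pct extrapolated
#> 1             62.4          22.5 FALSE
#> 2             97.6          91.0 FALSE

# purity from loss-region het SNP VAFs (truth: 0.6)
tum <- simulate_tumor(purity = 0.6, seed = 7)
snps <- select_loss_het_snps(tum$variants, tum$segments)
estimate_purity(snps$vaf)
#>   n_snps vaf_mode purity_paper purity_exact
#> 1    500    0.717        0.434        0.606
```

The Bliss residual map recovers the injected ~15% synergy at the highest
dose pair; the calibration turns 62.4% mapped reads into 22.5% human DNA
(capture bias makes mapped % overshoot true content); the exact-inversion
purity estimate lands on the simulated truth while the classical
`2·VAF − 1` rule shows its expected downward bias.

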
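---
title: "Models and methods behind pdxscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pdxscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdxscreen)
```

pdxscreen analyses pharmacogenomic screens run on cells derived from
patient-derived tumor xenografts (PDTXs) and the genomic bookkeeping those
samples require: because the tumor grows in a mouse, every readout is a
mixture — of drug-treated and control wells on a plate, of human tumor and
mouse stroma in the DNA, of tumor and normal cells in the variant calls.
This vignette describes each model, its assumptions, the tunable parameters
and their defaults, and the choices made where the methods were genuinely
open.

## Plate normalization

Raw well intensities are converted to percent-of-cells-dead against the
plate's own controls,

$$r = 100 - 100\,\frac{I - C^-}{C^+ - C^-},$$

with $C^+$ the untreated (maximal-viability) control and $C^-$ the
cell-free control. Noise pushes some wells outside $[0, 100]$; those values
are *flagged but kept*, because the isotonic fit averages replicate noise
correctly only on the unclipped scale. Clipping happens exactly twice
downstream: inside the AUC (responses) and inside the Bliss model (kill
fractions). `control_qc()` is purely descriptive — per-plate control means,
SDs and a signal-window statistic $(C^+ - C^-)/\text{pooled SD}$ — since no
quantitative plate-rejection rule is part of the analysis contract.

## Monotone dose-response fitting

Cell kill is assumed non-decreasing in dose. The fit is the least-squares
projection of all replicate points onto the monotone cone
(pool-adjacent-violators, `pava()`); pooling weights every technical
replicate point equally, which is equivalent to weighted PAVA on the
per-dose means. PAVA is implemented in the package (rather than wrapping
`stats::isoreg`) because the pooled fits and the bivariate projection below
need case weights; tests cross-check it against `stats::isoreg` and a
brute-force partition oracle. Decreasing trends are flattened, not
mirrored: a drug that appears to *increase* viability with dose fits as a
constant.

Summaries per curve:

* **AUC** — trapezoid rule on fitted responses clipped to $[0,100]$ and
  scaled to $[0,1]$. The abscissa maps doses to equally spaced rank
  positions by default, so AUC is comparable across drugs screened over
  different ranges (five tenfold dilutions here, other ladders elsewhere);
  `axis = "dose"` gives the raw-dose alternative.
* **IC50** — a GCV smoothing spline through the isotonic fit on the log10
  dose scale (doses are serial dilutions), first crossing of 50% located by
  a 512-point grid plus root refinement. Censoring is explicit: curves at
  or above 50% at the lowest dose are `below_min`, curves that never reach
  50% are `above_max`. With fewer than four distinct fitted values the GCV
  spline is ill-posed and a monotone piecewise-linear interpolant is used;
  because a smoothing spline reproduces straight lines exactly, a log-linear
  curve yields the geometric dose midpoint either way.
* **Percent-dose IC50** — $100 (IC_{50} - d_{\min})/(d_{\max} - d_{\min})$
  on the raw dose scale.
* **Dispersion** — each replicate refitted alone; SDs of per-replicate AUC
  and IC50 are the error bars. Censored replicate IC50s are excluded and
  counted; a single replicate reports `NA`, never a misleading 0.

Each fitted curve is classified against eight canonical five-point response
templates (flat resistance through full toxicity) by minimum squared
distance, interpolated linearly for other ladder lengths. Ties resolve to
the lowest template index so output is deterministic; a genuine tie such as
(0,0,0,0,25) — equidistant from the flat template and the
top-dose-only template — goes to the former.

## Bliss independence for drug combinations

For kill fractions $r_X(i)$ and $r_Y(j)$ the independence expectation is
$r_X + r_Y - r_X r_Y$. The expected surface is built from isotonic fits of
the combination's own dose-0 margins (or externally supplied curves). The
observed grid is denoised by projection onto the *bimonotone* cone —
non-decreasing along both dose axes — computed by Dykstra's alternating
projections between the row- and column-monotone cones (each step a
per-line PAVA) to tolerance $10^{-8}$. Exact cone projection was chosen
over penalized bivariate isotonic fitting because it has no free penalty
parameter and is verifiable against an independent quadratic-program
oracle (the tests solve the projection dual by Lawson–Hanson NNLS and
require agreement to $10^{-6}$).

Residuals are fit − expected by default (observed − expected is also
emitted, and both per-cell maps are in `tidy()` output, since either view
of the heatmap is defensible); positive = more killing than independence =
synergy. The summary is the 95th percentile of residuals over dose pairs
(linear-interpolation order statistic, `quantile` type 7, i.e. rank
$0.95(n-1)+1$), plus mean and extremes with the argmax dose pair. These are
descriptive markers only; no inference is attached to them.

## Human/mouse admixture calibration

Reads from a xenograft are aligned to a combined human–mouse genome;
reads mapping equally well to both are discarded (an upstream contract —
the package consumes the resulting mapped percentages). Human-specific
exome capture biases the mapped-to-human percentage $m$ away from the true
human DNA content $h$, so the package ships the published mixing-series
table (13 rows: 0/25/50/90/100% human with replicates) and fits a
locally weighted quadratic regression (loess, tricube kernel, exact
surface) of $h$ on $m$. The default span 1.07 was identified by matching
the published estimated-content column: it reproduces those values to
within 0.04 percentage points, while conventional spans (0.5–1.0) miss by
up to 2.3. With 13 points a span just above 1 makes the fit an
almost-global quadratic with mild locality. `estimate_human_content()`
clamps queries outside the training range to the nearest edge (flagged
`extrapolated`) and clips estimates to $[0,100]$.

Two properties of the published calibration carry over and are worth
knowing: the curve estimates pure-human mixtures at about 98.7%, not 100%
(smoothing bias at the boundary), and the top of the bias curve is steep —
$dh/dm \approx 4$ near $m = 98$ — so mapping noise there is amplified
about four-fold in the content estimate. In round-trip simulations with
0.3-point mapping noise the mean recovery error is well under 3 points but
a worst single replicate can reach about 3.5.

## Tumor purity, segment correction and CNA calls

Heterozygous SNPs falling in copy-loss segments (segmented log2 ratio
below −0.1) have lost one allele in the tumor; with purity $p$ the
retained allele's expected VAF is $1/(2-p)$, and only contamination keeps
it below 1. VAFs are folded to $[0.5, 1]$ ($v \mapsto \max(v, 1-v)$)
because the retained allele may be recorded as REF or ALT — folding makes
the estimator allele-label invariant — and the consensus VAF is the mode
of a Gaussian KDE (Silverman bandwidth, 512 grid points on $[0.5,1]$).
Two estimates are reported: the `2·VAF − 1` rule (`purity_paper`), which
is downward-biased for partial purity since the mode sits at $1/(2-p)$ and
$2/(2-p) - 1 = p/(2-p) < p$, and the exact inversion `2 − 1/VAF`
(`purity_exact`), which is recommended and is the one held to the
recovery budget in the tests. The minimum SNP count defaults to 10.
Near-boundary purities interact with the fold: at $p = 0.2$ the true VAF
(0.556) is close enough to 0.5 that reflected mass skews the KDE mode
slightly downward, which is why recovery error is quoted pooled across the
purity grid rather than only at its easiest points.

Segment correction inverts the same mixing model for copy number:
$c = (2^{\ell} - (1-p))\cdot 2/p$, floored at 0.01 copies to keep the log
defined, and $\ell' = \log_2(c/2)$. Five-state calls threshold $\ell'$ at
−1, −0.4, 0.25 and 0.75. The boundaries are assigned HOMD $< -1 \le$
HETD $\le -0.4 <$ NEUT $< 0.25 \le$ GAIN $< 0.75 \le$ AMP: the cutpoint
−1 belongs to HETD because an exact clean single-copy loss sits exactly at
$\ell' = -1$ and must not be called homozygous, while 0.75 belongs to AMP.
Every finite value receives exactly one call.

## Variant QC, MATH, clonality input and cluster flags

QC thresholds: genotype quality ≥ 20, depth ≥ 5, strand-bias Phred score
< 40, and no homopolymer near the site. The homopolymer rule is
quantified here — a single-base run of ≥ 5 overlapping ±5 bp of the
variant, both configurable — because only the qualitative filter is part
of the method description; it needs a reference-context string and is
skipped with a warning without one. All failing filters are recorded per
record. Germline labels (population database or any normal sample) and the
segmental-duplication insertion rule (excluded unless present in ≥ 3
samples or ≥ ¾ of the model's samples) are annotations, not exceptions.
Gene-region annotation (intergenic/intronic discards) is accepted as a
precomputed column upstream; annotation databases are out of scope.

**MATH** is $100 \cdot \text{MAD}/\text{median}$ of the somatic VAFs, MAD
scaled by 1.4826 for Gaussian consistency; it is scale-free and grows with
clone separation in two-clone mixtures.

**Clonality input preparation** keeps variants with median depth ≥ 50
across the model's samples, depth ≥ 15 in every sample and VAF ≥ 0.1 in at
least one sample ("low VAF across all samples" is read as *no* sample
reaching 0.1), then caps at the 300 highest-median-depth variants with
genomic order as the deterministic tie-break, and emits the standard
count-table columns (ref/var counts, copy-number placeholders, per-sample
tumour content; explant samples default to content 1).

**Cluster flags**: a cluster's prevalence shift is significant when some
sample's 90% credible interval is disjoint from *every* other sample's
interval of that cluster. Intervals are closed and touching endpoints
overlap; single-sample clusters are `not_assessable` rather than silently
stable.

**Promoter methylation** averages beta values of CpGs with ≥ 5 reads
within ±2000 bp (inclusive, strand-agnostic window) of the TSS; BED6 input
resolves the TSS strand-aware. Genes without qualifying CpGs are `NA`,
distinguishing "unmethylated" from "unmeasured".

## The synthetic-data generators

The generators produce every input type with known ground truth; they are
the package's test bed and parameter-recovery harness, and their defaults
*are* the study conditions used by the tests and the acceptance script:

* `simulate_plate()` — Hill curve $e_0 + (e_{\max}-e_0)\,d^h/(d^h +
  EC_{50}^h)$ on a 5-point tenfold ladder, 3 technical replicates, 5%
  well noise and a 2-point shared plate effect, read out as intensities
  through configurable controls. Five points and tenfold steps match the
  screen design the response templates assume.
* `simulate_combination()` — independence surface plus an additive signed
  kernel plus 2% noise, clipped to $[0,1]$. Dose ladders start at 0 so
  grids carry their own margins; the default $e_{\max} = 0.5$ keeps a
  ±0.15 kernel away from the clipping bounds so the injected effect
  survives intact.
* `simulate_tumor()` — one-copy-loss segments at the forward-model
  log-ratio with Binomial(depth, $1/(2-p)$) allele counts and random
  allele labels (exercising VAF folding), plus diploid background;
  defaults 500 SNPs at depth 100.
* `simulate_calibration_series()` — a monotone capture-bias curve
  (default: Hyman spline through the packaged table's replicate means)
  plus 0.3-point mapping noise.
* `simulate_cluster_prevalences()` — stable or shifted prevalences with
  configurable interval width.

Each generator draws from its own named substream (a fixed offset added to
the seed), so adding a generator never changes another's output, and equal
seeds give bit-identical tables.

What the generators deliberately do *not* emulate: plate-position
artifacts and edge effects, non-Gaussian readout noise, subclonal copy
number and multi-state segments, mapping-rate dependence on fragment
length, or correlated noise between combination wells. Passing the
recovery suites therefore shows the estimators invert their own forward
models at realistic sizes — not that those forward models capture
everything in real screens.

## Numerical choices and problem sizes

Dykstra iterations stop when the sup-norm change and residual
monotonicity violation fall below $10^{-8}$ (oracle agreement in tests:
$10^{-6}$). The IC50 grid has 512 points with `uniroot` refinement to
$10^{-10}$; the KDE grid has 512 points. Ties in pattern classification
and clonality ranking break deterministically (lowest index, genomic
order). The test and acceptance studies use 200 random instances per
oracle check, 100 seeds for the Bliss null and detection studies, 50
seeds per purity level, and 10–40 seeds for the lighter unit-level
recovery checks; the full suite runs in well under a minute.

## Known limitations

* The calibration is specific to the capture chemistry behind the mixing
  table; other enrichment designs need their own series (the span is a
  tuning argument).
* The purity estimator assumes one-copy losses; whole-genome-doubled
  tumors violate $E[\text{VAF}] = 1/(2-p)$.
* Isotonic fitting cannot represent genuinely non-monotone responses
  (e.g. proliferative low-dose effects); they flatten.
* Growth-rate-corrected sensitivity metrics, multi-parameter logistic
  fits, Loewe/HSA/ZIP synergy frameworks, and running the clonal-inference
  MCMC itself are out of scope.
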
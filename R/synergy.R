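#' Bliss independence expected response
#'
#' Expected fraction of cells dead when two independently acting drugs are
#' combined: `rx + ry - rx * ry`, equivalently `1 - (1 - rx) * (1 - ry)`.
#' Inputs are kill fractions in \[0, 1\]; out-of-range normalized values
#' are clipped here (this is the one place clipping is applied before
#' summary).
#'
#' @param rx,ry Single-agent kill fractions (vectorized).
#' @return Expected combined kill fraction.
#' @examples
#' bliss_expected(0.5, 0.5)  # 0.75
#' @export
bliss_expected <- function(rx, ry) {
  if (any(!is.finite(rx)) || any(!is.finite(ry))) abort("inputs must be finite.")
  rx <- pmin(pmax(rx, 0), 1)
  ry <- pmin(pmax(ry, 0), 1)
  rx + ry - rx * ry
}

#' Expected combination surface from single-agent curves
#'
#' `expected[i, j] = bliss_expected(fx[i], fy[j])` where `fx`, `fy` are the
#' isotonic single-agent fits; the surface is monotone in both indices by
#' construction.
#'
#' @param curve_x,curve_y `monotone_curve` objects (kill fractions) fitted
#'   on the combination's own dose ladders.
#' @return Matrix `length(curve_x$doses) x length(curve_y$doses)`.
#' @export
expected_surface <- function(curve_x, curve_y) {
  stopifnot(inherits(curve_x, "monotone_curve"), inherits(curve_y, "monotone_curve"))
  outer(curve_x$fitted, curve_y$fitted, bliss_expected)
}

#' Percentile of Bliss residuals
#'
#' Linear-interpolation order statistic (the order statistic at rank
#' `p * (n - 1) + 1`, i.e. [stats::quantile()] type 7).
#' @noRd
residual_quantile <- function(res, p = 0.95) {
  unname(quantile(res, probs = p, type = 7))
}

#' Fit the Bliss synergy model to a combination grid
#'
#' Full two-drug analysis: single-agent isotonic fits on the grid's own
#' dose-0 margins (or supplied curves), the Bliss expected surface, a
#' bivariate isotonic (bimonotone) fit of the observed grid, and signed
#' residual maps. Residuals are `fit - expected` by default (the
#' bimonotone fit denoises the observed surface); `residual_on =
#' "observed"` gives raw `observed - expected` residuals. Positive
#' residuals = more killing than independence = synergy. Residual summaries
#' (95th percentile, mean, extremes) are reported on the percent scale and
#' are descriptive markers only; no inference is attached.
#'
#' @param observed `nx x ny` matrix of kill fractions in \[0, 1\], rows
#'   indexed by `doses_x`, columns by `doses_y`.
#' @param doses_x,doses_y Strictly increasing dose ladders; a leading 0
#'   denotes the single-agent margin.
#' @param curve_x,curve_y Optional externally fitted single-agent
#'   `monotone_curve`s (kill fractions) on the same ladders. Required when
#'   the grid lacks dose-0 margins.
#' @param residual_on `"fitted"` (default) or `"observed"`.
#' @return Object of class `bliss_fit` with [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @examples
#' sim <- simulate_combination(seed = 3)
#' fit <- fit_bliss(sim$observed, sim$doses_x, sim$doses_y)
#' glance(fit)
#' @export
fit_bliss <- function(observed, doses_x, doses_y,
                      curve_x = NULL, curve_y = NULL,
                      residual_on = c("fitted", "observed")) {
  residual_on <- match.arg(residual_on)
  observed <- as.matrix(observed)
  if (nrow(observed) != length(doses_x) || ncol(observed) != length(doses_y)) {
    abort("`observed` must be length(doses_x) x length(doses_y).")
  }
  if (any(!is.finite(observed))) abort("`observed` must be complete and finite.")
  if (is.null(curve_x) || is.null(curve_y)) {
    if (doses_x[1L] != 0 || doses_y[1L] != 0) {
      abort("grid has no dose-0 margins; supply `curve_x` and `curve_y`.")
    }
    curve_x <- fit_isotonic(doses_x, observed[, 1L])
    curve_y <- fit_isotonic(doses_y, observed[1L, ])
  } else {
    if (!isTRUE(all.equal(curve_x$doses, doses_x)) ||
        !isTRUE(all.equal(curve_y$doses, doses_y))) {
      abort("single-agent curve doses do not match the grid doses.")
    }
  }
  expected <- expected_surface(curve_x, curve_y)
  fitted <- fit_bivariate_isotonic(observed)
  res_fit <- fitted - expected
  res_obs <- observed - expected
  res <- if (residual_on == "fitted") res_fit else res_obs
  imax <- arrayInd(which.max(res), dim(res))
  structure(
    list(
      doses_x = doses_x, doses_y = doses_y,
      observed = observed, fitted = fitted, expected = expected,
      residuals_fitted = res_fit, residuals_observed = res_obs,
      residual_on = residual_on,
      summary = tibble(
        p95_residual_pct = 100 * residual_quantile(res, 0.95),
        mean_residual_pct = 100 * mean(res),
        min_residual_pct = 100 * min(res),
        max_residual_pct = 100 * max(res),
        argmax_dose_x = doses_x[imax[1L]],
        argmax_dose_y = doses_y[imax[2L]]
      )
    ),
    class = "bliss_fit"
  )
}

#' @export
print.bliss_fit <- function(x, ...) {
  cat("<bliss_fit> ", nrow(x$observed), "x", ncol(x$observed),
      " grid, residuals on ", x$residual_on, " surface\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname fit_bliss
#' @param x,object A `bliss_fit`.
#' @param ... Unused.
#' @method tidy bliss_fit
#' @export
tidy.bliss_fit <- function(x, ...) {
  grid <- tidyr::expand_grid(dose_x = x$doses_x, dose_y = x$doses_y)
  # expand_grid varies dose_y fastest == row-major traversal of the matrices
  grid %>%
    mutate(
      observed = as.vector(t(x$observed)),
      fitted = as.vector(t(x$fitted)),
      expected = as.vector(t(x$expected)),
      residual_fitted = as.vector(t(x$residuals_fitted)),
      residual_observed = as.vector(t(x$residuals_observed))
    )
}

#' @rdname fit_bliss
#' @method glance bliss_fit
#' @export
glance.bliss_fit <- function(x, ...) x$summary

#' @rdname fit_bliss
#' @method autoplot bliss_fit
#' @export
autoplot.bliss_fit <- function(object, ...) {
  df <- tidy(object) %>%
    mutate(residual_pct = 100 * (if (object$residual_on == "fitted")
      .data$residual_fitted else .data$residual_observed))
  ggplot(df, aes(x = factor(.data$dose_y), y = factor(.data$dose_x),
                 fill = .data$residual_pct)) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick",
                         midpoint = 0, name = "residual (%)") +
    labs(x = "dose Y (µM)", y = "dose X (µM)",
         title = sprintf("Bliss residuals (p95 = %.1f%%)",
                         object$summary$p95_residual_pct))
}

#' Concordance between combination-margin and single-screen AUCs
#'
#' Each combination screen carries its own single-agent margins; this joins
#' margin-derived AUCs to the single-drug screen AUCs for the same
#' (model, drug) pairs and reports the Pearson correlation.
#'
#' @param margin_aucs,single_aucs Tibbles with columns `model_id`,
#'   `drug_id`, `auc`.
#' @return List: `pairs` (joined tibble with `auc_margin`, `auc_single`),
#'   `pearson_r` (`NA` with fewer than 3 shared pairs), `n_pairs`.
#' @export
single_agent_concordance <- function(margin_aucs, single_aucs) {
  pairs <- inner_join(
    rename(as_tibble(margin_aucs), auc_margin = "auc"),
    rename(as_tibble(single_aucs), auc_single = "auc"),
    by = intersect(c("model_id", "drug_id"),
                   intersect(names(margin_aucs), names(single_aucs)))
  )
  r <- if (nrow(pairs) >= 3L) cor(pairs$auc_margin, pairs$auc_single) else NA_real_
  list(pairs = pairs, pearson_r = r, n_pairs = nrow(pairs))
}
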
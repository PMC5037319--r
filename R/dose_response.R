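#' Area under a monotone dose-response curve
#'
#' Trapezoid-rule AUC of the fitted curve, normalized to \[0, 1\]:
#' responses are clipped to \[0, 100\] and divided by 100, and the dose axis
#' is mapped to \[0, 1\]. The default abscissa places the doses at equally
#' spaced rank positions, making AUCs comparable across drugs screened over
#' different concentration ranges; `axis = "dose"` uses the raw dose scale
#' instead. 0 = no effect at any dose, 1 = complete kill at every dose.
#'
#' @param curve A `monotone_curve` from [fit_isotonic()], or a numeric
#'   vector of fitted responses (then assumed rank-spaced).
#' @param axis `"rank"` (default) or `"dose"`.
#' @return AUC in \[0, 1\].
#' @examples
#' auc_response(fit_isotonic(1:5, c(0, 0, 0, 0, 100)))  # 0.125
#' @export
auc_response <- function(curve, axis = c("rank", "dose")) {
  axis <- match.arg(axis)
  if (inherits(curve, "monotone_curve")) {
    y <- curve$fitted
    d <- curve$doses
  } else {
    y <- as.numeric(curve)
    d <- seq_along(y)
  }
  n <- length(y)
  if (n < 2L) abort("AUC needs at least 2 dose points.")
  y <- pmin(pmax(y, 0), 100) / 100
  x <- switch(axis,
    rank = seq(0, 1, length.out = n),
    dose = (d - d[1L]) / (d[n] - d[1L])
  )
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

#' IC50 from a monotone dose-response curve
#'
#' Fits a cubic smoothing spline (GCV-selected stiffness) through the
#' isotonic fit on the log10-dose scale and reports the smallest dose where
#' the spline crosses 50% response, located by dense-grid bracketing and
#' root refinement. If the fitted response at the lowest dose is already
#' >= 50 the IC50 is censored `below_min`; if the spline never reaches 50
#' it is censored `above_max`. With fewer than four distinct fitted values
#' the GCV spline is ill-posed and a monotone piecewise-linear interpolant
#' of the isotonic fit is used instead.
#'
#' @param curve A `monotone_curve`.
#' @param dose_scale `"log"` (default; doses are serial dilutions) or
#'   `"linear"`.
#' @param n_grid Grid size for bracketing the first crossing.
#' @return List with `dose` (numeric, `NA` when censored) and `status`
#'   (`"estimated"`, `"below_min"`, `"above_max"`).
#' @export
ic50 <- function(curve, dose_scale = c("log", "linear"), n_grid = 512L) {
  stopifnot(inherits(curve, "monotone_curve"))
  dose_scale <- match.arg(dose_scale)
  d <- curve$doses
  y <- curve$fitted
  if (length(d) < 2L) abort("IC50 needs at least 2 dose points.")
  if (dose_scale == "log" && any(d <= 0)) {
    abort("log dose scale requires strictly positive doses.")
  }
  x <- if (dose_scale == "log") log10(d) else d
  if (y[1L] >= 50) {
    return(list(dose = NA_real_, status = "below_min"))
  }
  f <- NULL
  if (length(unique(y)) >= 4L && length(x) >= 4L) {
    sm <- tryCatch(smooth.spline(x, y), error = function(e) NULL)
    if (!is.null(sm)) f <- function(z) predict(sm, z)$y
  }
  if (is.null(f)) f <- approxfun(x, y, rule = 2)
  grid <- seq(x[1L], x[length(x)], length.out = n_grid)
  vals <- f(grid)
  hit <- which(vals >= 50)
  if (!length(hit)) {
    return(list(dose = NA_real_, status = "above_max"))
  }
  i <- hit[1L]
  root <- if (i == 1L) grid[1L] else {
    uniroot(function(z) f(z) - 50, lower = grid[i - 1L], upper = grid[i],
            tol = 1e-10)$root
  }
  dose <- if (dose_scale == "log") 10^root else root
  list(dose = dose, status = "estimated")
}

#' IC50 as percent of the tested dose range
#'
#' `100 * (IC50 - min dose) / (max dose - min dose)` on the raw dose scale,
#' making IC50s comparable across drugs screened over different ranges.
#'
#' @param ic50_dose IC50 in dose units (`NA` propagates).
#' @param doses The tested dose ladder.
#' @return Percent of dose range in \[0, 100\] (`NA` if censored).
#' @export
ic50_percent <- function(ic50_dose, doses) {
  if (length(doses) < 2L) abort("need at least 2 doses.")
  d_min <- min(doses)
  d_max <- max(doses)
  100 * (ic50_dose - d_min) / (d_max - d_min)
}

#' The eight canonical dose-response patterns
#'
#' Template curves of percent-cells-dead at five dose points covering
#' increasingly sensitive responses, from flat resistance to full toxicity:
#' (0,0,0,0,0); (0,0,0,0,50); (0,0,0,50,90); (0,0,30,50,90);
#' (0,25,50,75,100); (0,50,60,80,100); (60,60,60,60,60);
#' (100,100,100,100,100). For ladders with a different number of doses the
#' templates are linearly interpolated over equally spaced abscissae.
#'
#' @param n_doses Number of dose points (>= 2), default 5.
#' @return 8 x `n_doses` matrix, rows named `pattern_1` .. `pattern_8`.
#' @export
theoretical_curves <- function(n_doses = 5L) {
  if (n_doses < 2L) abort("`n_doses` must be >= 2.")
  templates <- rbind(
    c(0, 0, 0, 0, 0),
    c(0, 0, 0, 0, 50),
    c(0, 0, 0, 50, 90),
    c(0, 0, 30, 50, 90),
    c(0, 25, 50, 75, 100),
    c(0, 50, 60, 80, 100),
    c(60, 60, 60, 60, 60),
    c(100, 100, 100, 100, 100)
  )
  rownames(templates) <- paste0("pattern_", 1:8)
  if (n_doses == 5L) return(templates)
  x5 <- seq(0, 1, length.out = 5L)
  xn <- seq(0, 1, length.out = n_doses)
  out <- t(apply(templates, 1L, function(r) approx(x5, r, xout = xn)$y))
  rownames(out) <- rownames(templates)
  out
}

#' Classify a fitted curve into the eight canonical patterns
#'
#' Minimum-squares assignment: the pattern minimising the squared distance
#' `sum((fitted - template)^2)` wins; ties resolve deterministically to the
#' lowest template index.
#'
#' @param curve A `monotone_curve` or numeric vector of fitted responses.
#' @return List with `pattern_id` (1-8) and `pattern_distance` (squared
#'   error to the assigned template).
#' @export
classify_pattern <- function(curve) {
  y <- if (inherits(curve, "monotone_curve")) curve$fitted else as.numeric(curve)
  templates <- theoretical_curves(length(y))
  d2 <- rowSums(sweep(templates, 2L, y)^2)
  id <- which.min(d2)  # which.min returns the first (lowest-index) minimum
  list(pattern_id = unname(id), pattern_distance = unname(d2[id]))
}

#' Replicate dispersion of AUC and IC50
#'
#' Fits an isotonic curve to each technical replicate individually, computes
#' per-replicate AUC and IC50, and reports their sample standard deviations
#' (the error bars around the pooled estimates). Censored per-replicate
#' IC50s are excluded from `ic50_sd` and counted. With a single replicate
#' the SDs are `NA`, not zero.
#'
#' @param doses Dose ladder.
#' @param responses Matrix (replicates x doses) or list of response vectors.
#' @inheritParams ic50
#' @inheritParams auc_response
#' @return List: `auc_sd`, `ic50_sd`, `ic50_censored` (count),
#'   `per_replicate` tibble (replicate, auc, ic50, ic50_status).
#' @export
replicate_dispersion <- function(doses, responses, axis = c("rank", "dose"),
                                 dose_scale = c("log", "linear")) {
  axis <- match.arg(axis)
  dose_scale <- match.arg(dose_scale)
  if (is.list(responses)) responses <- do.call(rbind, responses)
  if (is.null(dim(responses))) responses <- matrix(responses, nrow = 1L)
  per <- purrr::map_dfr(seq_len(nrow(responses)), function(k) {
    cv <- fit_isotonic(doses, responses[k, ], source = paste0("replicate:", k))
    ick <- ic50(cv, dose_scale = dose_scale)
    tibble(replicate = k,
           auc = auc_response(cv, axis = axis),
           ic50 = ick$dose, ic50_status = ick$status)
  })
  est <- per$ic50[per$ic50_status == "estimated"]
  list(
    auc_sd = if (nrow(per) >= 2L) sd(per$auc) else NA_real_,
    ic50_sd = if (length(est) >= 2L) sd(est) else NA_real_,
    ic50_censored = sum(per$ic50_status != "estimated"),
    per_replicate = per
  )
}

#' Fit one dose-response experiment
#'
#' Full single-experiment analysis: pooled isotonic fit, AUC, IC50 (with
#' censoring), percent-dose IC50, pattern classification and replicate
#' dispersion. Returns a fitted object with [tidy()], [glance()] and
#' [autoplot()] methods.
#'
#' @inheritParams replicate_dispersion
#' @inheritParams auc_response
#' @inheritParams ic50
#' @return Object of class `dose_response_fit`.
#' @examples
#' sim <- simulate_plate(seed = 7)
#' resp <- normalize_plate(sim$data)
#' fit <- dose_response(sort(unique(resp$dose_uM)),
#'                      matrix(resp$response_pct[order(resp$replicate, resp$dose_uM)],
#'                             nrow = 3, byrow = TRUE))
#' glance(fit)
#' @export
dose_response <- function(doses, responses, axis = c("rank", "dose"),
                          dose_scale = c("log", "linear")) {
  axis <- match.arg(axis)
  dose_scale <- match.arg(dose_scale)
  if (is.list(responses)) responses <- do.call(rbind, responses)
  if (is.null(dim(responses))) responses <- matrix(responses, nrow = 1L)
  curve <- fit_isotonic(doses, responses)
  ic <- ic50(curve, dose_scale = dose_scale)
  disp <- replicate_dispersion(doses, responses, axis = axis, dose_scale = dose_scale)
  cls <- classify_pattern(curve)
  structure(
    list(curve = curve, responses = responses,
         auc = auc_response(curve, axis = axis),
         ic50 = ic$dose, ic50_status = ic$status,
         ic50_pct = if (ic$status == "estimated") ic50_percent(ic$dose, doses) else NA_real_,
         pattern_id = cls$pattern_id, pattern_distance = cls$pattern_distance,
         dispersion = disp, axis = axis, dose_scale = dose_scale),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("<dose_response_fit>\n")
  print(glance(x))
  invisible(x)
}

#' @rdname dose_response
#' @param x A `dose_response_fit`.
#' @param ... Unused.
#' @method tidy dose_response_fit
#' @export
tidy.dose_response_fit <- function(x, ...) {
  tibble(
    dose_uM = x$curve$doses,
    response_mean = colMeans(x$responses),
    fitted = x$curve$fitted
  )
}

#' @rdname dose_response
#' @method glance dose_response_fit
#' @export
glance.dose_response_fit <- function(x, ...) {
  tibble(
    n_doses = length(x$curve$doses),
    n_replicates = nrow(x$responses),
    auc = x$auc, auc_sd = x$dispersion$auc_sd,
    ic50_uM = x$ic50, ic50_censor = x$ic50_status,
    ic50_pct = x$ic50_pct, ic50_sd = x$dispersion$ic50_sd,
    ic50_censored_reps = x$dispersion$ic50_censored,
    pattern_id = x$pattern_id, pattern_distance = x$pattern_distance
  )
}

#' @rdname dose_response
#' @param object A `dose_response_fit`.
#' @method autoplot dose_response_fit
#' @export
autoplot.dose_response_fit <- function(object, ...) {
  pts <- tidyr::pivot_longer(
    as_tibble(object$responses, .name_repair = ~ as.character(object$curve$doses)),
    cols = dplyr::everything(), names_to = "dose_uM", values_to = "response_pct"
  ) %>%
    mutate(dose_uM = as.numeric(.data$dose_uM))
  fit <- tidy(object)
  ggplot(pts, aes(x = .data$dose_uM, y = .data$response_pct)) +
    geom_point(alpha = 0.6) +
    geom_line(data = fit, aes(y = .data$fitted), colour = "firebrick", linewidth = 1) +
    scale_x_log10() +
    labs(x = "dose (µM)", y = "response (% dead)",
         title = sprintf("AUC %.2f, pattern %d", object$auc, object$pattern_id))
}

#' Summarise a normalized screen table
#'
#' Pipeline front end: groups a normalized long table by
#' (`model_id`, `passage_id`, `drug_id`) and runs [dose_response()] on each
#' experiment, returning one summary row per experiment.
#'
#' @param data Long table with `dose_uM`, `replicate`, `response_pct` and
#'   the identifier columns.
#' @inheritParams auc_response
#' @inheritParams ic50
#' @return Tibble, one row per experiment, with the [glance()] columns.
#' @export
fit_dose_response <- function(data, axis = c("rank", "dose"),
                              dose_scale = c("log", "linear")) {
  axis <- match.arg(axis)
  dose_scale <- match.arg(dose_scale)
  data <- as_tibble(data)
  id_cols <- intersect(c("model_id", "passage_id", "drug_id"), names(data))
  data %>%
    group_by(across(all_of(id_cols))) %>%
    group_modify(function(df, key) {
      wide <- df %>%
        select("replicate", "dose_uM", "response_pct") %>%
        arrange(.data$replicate, .data$dose_uM) %>%
        tidyr::pivot_wider(names_from = "dose_uM", values_from = "response_pct")
      doses <- as.numeric(setdiff(names(wide), "replicate"))
      mat <- as.matrix(wide[, as.character(doses), drop = FALSE])
      if (any(is.na(mat))) abort("replicates have mismatched dose ladders.")
      glance(dose_response(doses, mat, axis = axis, dose_scale = dose_scale))
    }) %>%
    ungroup()
}
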
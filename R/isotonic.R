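#' Weighted pool-adjacent-violators projection
#'
#' Least-squares projection of a numeric vector onto the cone of
#' non-decreasing vectors, with optional case weights. This is the monotone
#' regression primitive behind every curve and surface fit in the package;
#' it is written out (rather than wrapping [stats::isoreg()]) because the
#' pooled replicate fits and the bivariate projection both need weights.
#'
#' @param y Numeric vector.
#' @param w Positive weights, recycled to `length(y)`. Default all 1.
#' @return Numeric vector of the same length, non-decreasing, minimising
#'   `sum(w * (y - fit)^2)` over all non-decreasing vectors.
#' @examples
#' pava(c(10, 0, 20))        # c(5, 5, 20)
#' pava(c(1, 2, 3))          # unchanged
#' @export
pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  stopifnot(n >= 1, all(is.finite(y)))
  w <- rep_len(w, n)
  if (any(!is.finite(w)) || any(w <= 0)) {
    abort("`w` must be positive and finite.")
  }
  if (n == 1L) return(y)
  # blocks stored as (value, weight, size) stacks
  val <- numeric(n); wt <- numeric(n); sz <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    val[top] <- y[i]; wt[top] <- w[i]; sz[top] <- 1L
    while (top > 1L && val[top - 1L] > val[top]) {
      wsum <- wt[top - 1L] + wt[top]
      val[top - 1L] <- (wt[top - 1L] * val[top - 1L] + wt[top] * val[top]) / wsum
      wt[top - 1L] <- wsum
      sz[top - 1L] <- sz[top - 1L] + sz[top]
      top <- top - 1L
    }
  }
  rep.int(val[seq_len(top)], sz[seq_len(top)])
}

#' Fit a monotone (isotonic) dose-response curve
#'
#' Projects observed responses onto the cone of curves that are
#' non-decreasing in dose, pooling technical replicates so that every
#' replicate point enters the least-squares criterion with equal weight
#' (one curve fitted to the whole set of replicate points).
#'
#' @param doses Strictly increasing dose ladder (micromolar), length >= 2
#'   for downstream summaries (a single dose is accepted for the bare fit).
#' @param responses Percent-dead responses: a numeric vector aligned to
#'   `doses`, a matrix with one row per replicate and one column per dose,
#'   or a list of such vectors.
#' @param source Label recorded on the fit, e.g. `"pooled"` or
#'   `"replicate:1"`.
#' @return An object of class `monotone_curve`: list with `doses`, `fitted`
#'   (non-decreasing), `n_replicates`, `source`.
#' @examples
#' fit_isotonic(c(0.1, 1, 10), c(10, 0, 20))$fitted  # 5 5 20
#' @export
fit_isotonic <- function(doses, responses, source = "pooled") {
  doses <- as.numeric(doses)
  if (length(doses) < 1L || any(!is.finite(doses))) {
    abort("`doses` must be finite.")
  }
  if (is.unsorted(doses, strictly = TRUE)) {
    abort("`doses` must be strictly increasing.")
  }
  if (is.list(responses)) responses <- do.call(rbind, responses)
  if (is.null(dim(responses))) responses <- matrix(responses, nrow = 1L)
  if (ncol(responses) != length(doses)) {
    abort("each replicate must have exactly one response per dose.")
  }
  if (any(!is.finite(responses))) abort("responses must be finite.")
  # pooled projection == weighted PAVA on per-dose means, weight = n points
  ybar <- colMeans(responses)
  fit <- pava(ybar, w = rep(nrow(responses), length(ybar)))
  structure(
    list(doses = doses, fitted = fit,
         n_replicates = nrow(responses), source = source),
    class = "monotone_curve"
  )
}

#' @export
print.monotone_curve <- function(x, ...) {
  cat("<monotone_curve> ", x$source, ", ", length(x$doses), " doses, ",
      x$n_replicates, " replicate(s)\n", sep = "")
  print(tibble(dose = x$doses, fitted = x$fitted))
  invisible(x)
}

#' Bivariate isotonic (bimonotone) projection of a dose-combination grid
#'
#' Least-squares projection of an `nx x ny` response matrix onto the cone of
#' matrices non-decreasing along both rows and columns (doses increasing
#' along each axis). Computed by Dykstra's alternating projections between
#' the row-monotone and column-monotone cones, each projection being a
#' per-line pool-adjacent-violators pass; for an intersection of convex
#' cones this converges to the exact Euclidean projection.
#'
#' @param observed Numeric matrix; rows ordered by increasing dose of drug X,
#'   columns by increasing dose of drug Y.
#' @param tol Convergence tolerance on the sup-norm change per cycle and on
#'   residual monotonicity violations.
#' @param max_iter Maximum Dykstra cycles.
#' @return Matrix of the same shape, non-decreasing along both axes, with
#'   attributes `iterations` and `max_violation`.
#' @export
fit_bivariate_isotonic <- function(observed, tol = 1e-8, max_iter = 10000L) {
  x <- as.matrix(observed)
  if (any(!is.finite(x))) abort("`observed` must be finite and complete.")
  if (nrow(x) == 1L && ncol(x) == 1L) return(x)
  p_row <- matrix(0, nrow(x), ncol(x))  # Dykstra increments
  p_col <- matrix(0, nrow(x), ncol(x))
  cur <- x
  for (it in seq_len(max_iter)) {
    prev <- cur
    z <- cur + p_row
    cur <- t(apply(z, 1L, pava))
    if (ncol(x) == 1L) cur <- matrix(cur, ncol = 1L)  # apply() drops shape
    p_row <- z - cur
    z <- cur + p_col
    cur <- apply(z, 2L, pava)
    if (nrow(x) == 1L) cur <- matrix(cur, nrow = 1L)
    p_col <- z - cur
    viol_col <- if (nrow(x) > 1L) max(0, -min(diff(cur))) else 0
    viol_row <- if (ncol(x) > 1L) max(0, -min(apply(cur, 1L, diff))) else 0
    viol <- max(viol_col, viol_row)
    if (max(abs(cur - prev)) < tol && viol < tol) {
      attr(cur, "iterations") <- it
      attr(cur, "max_violation") <- viol
      dimnames(cur) <- dimnames(x)
      return(cur)
    }
  }
  abort(sprintf(
    "bivariate isotonic projection did not converge in %d iterations (last change %.3g)",
    max_iter, max(abs(cur - prev))
  ))
}
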
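# Independent oracles for the monotone-projection tests.
#
# 1-D: exhaustive search over block partitions. The isotonic projection is
# piecewise constant with non-decreasing block means, so enumerating all
# 2^(n-1) partitions and keeping the feasible one with least weighted SSE
# is an exact brute-force solution for small n.
iso_oracle_1d <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (n == 1L) return(y)
  best <- NULL
  best_sse <- Inf
  for (mask in 0:(2^(n - 1L) - 1L)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2L))) > 0)
    bounds <- c(0L, cuts, n)
    fit <- numeric(n)
    means <- numeric(length(bounds) - 1L)
    for (b in seq_len(length(bounds) - 1L)) {
      idx <- (bounds[b] + 1L):bounds[b + 1L]
      means[b] <- sum(w[idx] * y[idx]) / sum(w[idx])
      fit[idx] <- means[b]
    }
    if (is.unsorted(means)) next
    sse <- sum(w * (y - fit)^2)
    if (sse < best_sse) {
      best_sse <- sse
      best <- fit
    }
  }
  best
}

# Lawson-Hanson non-negative least squares: min ||X b - y||^2 s.t. b >= 0.
# Finite active-set algorithm, exact at termination.
nnls_lh <- function(X, y, tol = 1e-12) {
  m <- ncol(X)
  beta <- numeric(m)
  passive <- rep(FALSE, m)
  repeat {
    wgrad <- drop(crossprod(X, y - X %*% beta))
    cand <- which(!passive & wgrad > tol)
    if (!length(cand)) return(beta)
    passive[cand[which.max(wgrad[cand])]] <- TRUE
    repeat {
      s <- numeric(m)
      P <- which(passive)
      s[P] <- qr.solve(X[, P, drop = FALSE], y)
      if (all(s[P] > tol)) {
        beta <- s
        break
      }
      neg <- P[s[P] <= tol]
      alpha <- min(beta[neg] / (beta[neg] - s[neg]))
      beta <- beta + alpha * (s - beta)
      passive[beta <= tol] <- FALSE
      beta[!passive] <- 0
    }
  }
}

# Difference (monotonicity) constraint matrix A with Ax >= 0 for a grid
# stored column-major as vec(nx x ny): non-decreasing down each column
# (increasing dose of drug X) and along each row (drug Y).
bimonotone_constraints <- function(nx, ny) {
  idx <- function(i, j) (j - 1L) * nx + i
  rows <- list()
  for (j in seq_len(ny)) for (i in seq_len(nx - 1L)) {
    a <- numeric(nx * ny)
    a[idx(i + 1L, j)] <- 1
    a[idx(i, j)] <- -1
    rows[[length(rows) + 1L]] <- a
  }
  for (i in seq_len(nx)) for (j in seq_len(ny - 1L)) {
    a <- numeric(nx * ny)
    a[idx(i, j + 1L)] <- 1
    a[idx(i, j)] <- -1
    rows[[length(rows) + 1L]] <- a
  }
  do.call(rbind, rows)
}

# Exact Euclidean projection onto {x : Ax >= 0} via the dual:
# lambda* = argmin_{l >= 0} ||y + A'l||^2, x* = y + A'lambda*.
cone_project_oracle <- function(y, A) {
  lambda <- nnls_lh(t(A), -y)
  as.numeric(y + crossprod(A, lambda))
}

bimonotone_oracle <- function(mat) {
  A <- bimonotone_constraints(nrow(mat), ncol(mat))
  matrix(cone_project_oracle(as.vector(mat), A), nrow(mat), ncol(mat))
}
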
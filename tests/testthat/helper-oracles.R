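# Independent oracles used across the suite. Each is a deliberately naive
# reference computation, coded without reuse of the package's internals.

# Cox-de Boor recursion for a single B-spline basis function B_{i,k}(x)
# (zero-based order recursion; k = order = degree + 1).
deboor_basis <- function(x, knots, i, k) {
  if (k == 1L) {
    # half-open support, closed at the global right boundary
    last <- max(knots)
    as.numeric(knots[i] <= x & (x < knots[i + 1] | (x == last & knots[i + 1] == last)))
  } else {
    d1 <- knots[i + k - 1] - knots[i]
    d2 <- knots[i + k] - knots[i + 1]
    t1 <- if (d1 > 0) (x - knots[i]) / d1 * deboor_basis(x, knots, i, k - 1L) else 0
    t2 <- if (d2 > 0) (knots[i + k] - x) / d2 * deboor_basis(x, knots, i + 1L, k - 1L) else 0
    t1 + t2
  }
}

# Full de Boor basis matrix at points x.
deboor_matrix <- function(x, knots, degree) {
  k <- degree + 1L
  nb <- length(knots) - k
  vapply(seq_len(nb), function(i) deboor_basis(x, knots, i, k),
         numeric(length(x)))
}

# Newton-Raphson logistic MLE from the explicit score and information,
# independent of the package's IRLS code path.
newton_logistic <- function(y, X, tol = 1e-12, maxit = 50L) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    p <- 1 / (1 + exp(-drop(X %*% beta)))
    score <- drop(t(X) %*% (y - p))
    info <- t(X) %*% (X * (p * (1 - p)))
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# Tricube-weighted local linear fit at each data point over its r nearest
# neighbors (r = floor(span * n), the classical lowess window).
tricube_wls <- function(x, y, span) {
  n <- length(x)
  r <- floor(span * n)
  sapply(seq_len(n), function(i) {
    d <- abs(x - x[i])
    h <- sort(d)[r]
    w <- pmax(1 - (d / max(h, 1e-300))^3, 0)^3
    X <- cbind(1, x - x[i])
    b <- solve(t(X) %*% (X * w), t(X) %*% (w * y))
    b[1]
  })
}

# Hand rank-average quantile normalization for equal-length panels without
# ties: sort each panel, average order statistics, map back through ranks.
rank_average_oracle <- function(panels) {
  ref <- rowMeans(sapply(panels, sort))
  lapply(panels, function(p) ref[rank(p)])
}

# Small cohort for structural tests (fast).
small_cohort <- function(n = 400, seed = 11, ...) {
  generate_cohort(cohort_config(n_subjects = n, ...), seed = seed)
}
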
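test_that("the B-spline basis is a partition of unity and matches de Boor recursion", {
  set.seed(31)
  x <- sort(runif(60, 0, 10))
  for (dm in c(5L, 8L, 12L)) {
    bs <- spline_basis(x, dim = dm)
    expect_equal(rowSums(bs$B), rep(1, length(x)))
    expect_identical(ncol(bs$B), dm)
  }
  bs <- spline_basis(x, dim = 9, degree = 3)
  expect_equal(unname(bs$B), unname(deboor_matrix(x, bs$knots, 3)),
               tolerance = 1e-10)
  # second differences of a linear coefficient sequence are unpenalized
  gam_lin <- 2 + 3 * seq_len(9)
  expect_equal(drop(t(gam_lin) %*% bs$P %*% gam_lin), 0)
  expect_error(spline_basis(rep(1, 10)), "constant")
  expect_error(spline_basis(x, dim = 3), ">= 4")
})

test_that("an infinite penalty collapses the smooth to the OLS line", {
  set.seed(32)
  n <- 300
  x <- runif(n, 0, 10)
  z <- rnorm(n)
  y <- 1 + 0.5 * x - 0.3 * z + rnorm(n, 0, 0.4)
  fit <- fit_pgam(y, x, X = cbind(z = z), lambda = 1e12)
  ols <- lm(y ~ z + x)
  expect_equal(unname(fit$fitted), unname(fitted(ols)), tolerance = 1e-4)
  # edf shrinks to the penalty null space (intercept + z + linear-in-x)
  expect_equal(fit$edf, 3, tolerance = 1e-3)
})

test_that("a zero penalty reproduces unpenalized least squares on the full basis", {
  set.seed(33)
  n <- 200
  x <- runif(n, 0, 6)
  y <- sin(x) + rnorm(n, 0, 0.3)
  fit <- fit_pgam(y, x, lambda = 0, basis_dim = 8)
  # normal-equations oracle on the same design
  bs <- fit$basis
  M <- cbind(1, bs$B %*% fit$constraint)
  beta <- solve(crossprod(M), crossprod(M, y))
  expect_equal(unname(fit$fitted), unname(drop(M %*% beta)), tolerance = 1e-8)
  expect_equal(fit$edf, ncol(M), tolerance = 1e-8)
})

test_that("responses linear in x are fitted exactly for any penalty", {
  x <- seq(0, 10, length.out = 120)
  y <- 2 - 0.7 * x
  for (lam in c(0, 1, 1e6)) {
    fit <- fit_pgam(y, x, lambda = lam)
    expect_lt(fit$rss, 1e-16 * sum(y^2) + 1e-12)
  }
})

test_that("effective degrees of freedom agree between trace and leverage sums", {
  set.seed(34)
  n <- 250
  x <- runif(n)
  y <- cos(6 * x) + rnorm(n, 0, 0.2)
  fit <- fit_pgam(y, x, lambda = 5)
  M <- cbind(1, fit$basis$B %*% fit$constraint)
  P <- matrix(0, ncol(M), ncol(M))
  P[-1, -1] <- t(fit$constraint) %*% fit$basis$P %*% fit$constraint
  Ainv <- solve(crossprod(M) + fit$lambda * P)
  leverage <- rowSums((M %*% Ainv) * M)  # diag of the influence matrix
  expect_equal(fit$edf, sum(leverage), tolerance = 1e-8)
})

test_that("fitted values reproduce the observed mean when the model has an intercept", {
  set.seed(35)
  x <- runif(150, 0, 5)
  y <- exp(-x) + rnorm(150, 0, 0.1)
  fit <- fit_pgam(y, x)
  expect_equal(mean(fit$fitted), mean(y), tolerance = 1e-10)
  expect_true(is.finite(fit$aic))
  expect_gte(fit$edf, 2)
  expect_lte(fit$edf, 10 + 1)
})

test_that("the GCV smooth tracks an independent GAM implementation", {
  skip_if_not_installed("mgcv")
  set.seed(36)
  n <- 500
  x <- runif(n, 0, 10)
  y <- sin(x) + 0.1 * x + rnorm(n, 0, 0.3)
  ours <- fit_pgam(y, x, basis_dim = 10)
  ref <- mgcv::gam(y ~ s(x, k = 10, bs = "ps"), method = "GCV.Cp")
  expect_lt(sqrt(mean((ours$fitted - fitted(ref))^2)), 0.05)
})

test_that("degenerate designs are rejected with informative errors", {
  set.seed(37)
  x <- runif(50)
  y <- rnorm(50)
  z <- rnorm(50)
  expect_error(fit_pgam(y, x, X = cbind(a = z, b = 2 * z)), "rank-deficient")
  expect_error(fit_pgam(y, x, lambda = -1), "lambda")
})

test_that("the candidate grid has exact 0.2 spacing and the scan validates inputs", {
  expect_length(seq(5, 20, by = 0.2), 76)
  co <- small_cohort(n = 1500, seed = 41)
  sc <- suppressWarnings(threshold_scan(co, adjust = "none", grid_low = 5,
                                        grid_high = 20, log_uacr = TRUE))
  expect_identical(nrow(sc$table), 76L)
  expect_equal(unique(round(diff(sc$table$tau), 10)), 0.2)
  expect_true(sc$tau %in% sc$table$tau)
  expect_equal(sc$aic_min, min(sc$table$aic))
  expect_error(threshold_scan(co, grid_low = -50, grid_high = 20), "support")
  expect_error(threshold_scan(co, grid_low = 10, grid_high = 11), "candidates")
})

test_that("the scan's incremental fits equal full least-squares refits", {
  co <- small_cohort(n = 800, seed = 42)
  sc <- suppressWarnings(threshold_scan(co, adjust = "demo", grid_low = 6,
                                        grid_high = 12, log_uacr = TRUE))
  y <- log(co$uacr)
  mm <- model.matrix(~ age + sex + season, data = co)
  for (i in c(1L, 10L, nrow(sc$table))) {
    tau <- sc$table$tau[i]
    full <- lm(y ~ mm - 1 + serum_25ohd + pmax(tau - serum_25ohd, 0),
               data = co)
    rss <- sum(residuals(full)^2)
    p <- length(coef(full))
    expect_equal(sc$table$aic[i], nrow(co) * log(rss / nrow(co)) + 2 * (p + 1),
                 tolerance = 1e-8)
    expect_equal(sc$table$delta[i], unname(coef(full)[p]), tolerance = 1e-8)
  }
})

test_that("the scan recovers change-points across a range of true values", {
  for (tau_true in c(6, 10)) {
    taus <- sapply(1:5, function(s) {
      co <- generate_cohort(
        cohort_config(n_subjects = 15000, true_threshold = tau_true), seed = s)
      suppressWarnings(threshold_scan(co, adjust = "none", grid_low = 4,
                                      grid_high = 20, log_uacr = TRUE))$tau
    })
    expect_lte(abs(median(taus) - tau_true), 0.2)
  }
})

test_that("data without a change-point report no threshold", {
  found <- sapply(1:5, function(s) {
    co <- generate_cohort(
      cohort_config(n_subjects = 10000, below_threshold_slope = 0), seed = s)
    suppressWarnings(threshold_scan(co, adjust = "none", grid_low = 4,
                                    grid_high = 20, log_uacr = TRUE))$threshold_found
  })
  expect_lte(sum(found), 1)
  # while a strong change-point is always reported
  co <- generate_cohort(cohort_config(n_subjects = 10000), seed = 1)
  sc <- suppressWarnings(threshold_scan(co, adjust = "none", grid_low = 4,
                                        grid_high = 20, log_uacr = TRUE))
  expect_true(sc$threshold_found)
  expect_gt(sc$aic_margin, 50)
})

test_that("threshold figure writes one panel per adjustment set and the smooth is continuous", {
  co <- small_cohort(n = 1200, seed = 43)
  sc1 <- suppressWarnings(threshold_scan(co, adjust = "none", grid_low = 6,
                                         grid_high = 14, log_uacr = TRUE))
  sc2 <- suppressWarnings(threshold_scan(co, adjust = "demo", grid_low = 6,
                                         grid_high = 14, log_uacr = TRUE))
  f <- tempfile(fileext = ".png")
  fits <- plot_threshold_gam(list(sc1, sc2), co, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
  expect_length(fits, 2)
  # bands contain the estimate everywhere; curve continuous across tau
  cv <- fits[[1]]$curve(seq(6, 14, by = 0.05))
  expect_true(all(cv$lower <= cv$fit & cv$fit <= cv$upper))
  eps <- 1e-4
  jump <- abs(fits[[1]]$curve(sc1$tau + eps)$fit -
              fits[[1]]$curve(sc1$tau - eps)$fit)
  expect_lt(jump, 1e-2)
  unlink(f)
})
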
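test_that("IRLS matches a Newton-Raphson oracle and glm on random designs", {
  set.seed(51)
  for (rep in 1:4) {
    n <- 200
    X <- cbind(1, matrix(rnorm(n * 3), n, 3))
    y <- rbinom(n, 1, plogis(drop(X %*% c(-0.5, 0.8, -0.4, 0.2))))
    fit <- fit_logistic(y, X)
    expect_lt(max(abs(coef(fit) - newton_logistic(y, X))), 1e-6)
    ref <- glm.fit(X, y, family = binomial())
    expect_lt(max(abs(coef(fit) - coef(ref))), 1e-6)
  }
})

test_that("the intercept-only fit equals the logit of the event fraction", {
  # event counts of the study cohort: 2,424 high-normal of 14,594
  y <- c(rep(1, 2424), rep(0, 14594 - 2424))
  fit <- fit_logistic(y, matrix(1, length(y)))
  expect_equal(unname(coef(fit)), log(2424 / (14594 - 2424)), tolerance = 1e-9)
  expect_equal(round(unname(coef(fit)), 3), -1.614)
})

test_that("a single binary predictor reproduces the 2x2 cross-product ratio", {
  # diabetes x UAE-group counts: 1,001/12,170 with diabetes among normal UAE,
  # 348/2,424 among high-normal UAE
  y <- c(rep(1, 2424), rep(0, 12170))
  x <- c(rep(1, 348), rep(0, 2424 - 348), rep(1, 1001), rep(0, 12170 - 1001))
  fit <- fit_logistic(y, cbind(1, diabetes = x))
  or_closed <- (348 * (12170 - 1001)) / (1001 * (2424 - 348))
  expect_equal(unname(exp(coef(fit)["diabetes"])), or_closed, tolerance = 1e-9)
  expect_equal(round(or_closed, 2), 1.87)
  # Wald CI contains the OR and reproduces exp(b +/- 1.96 se)
  se <- sqrt(diag(vcov(fit)))["diabetes"]
  ci <- exp(coef(fit)["diabetes"] + c(-1.96, 1.96) * se)
  expect_true(ci[1] < or_closed && or_closed < ci[2])
})

test_that("degenerate outcomes and separation are errors, not estimates", {
  expect_error(fit_logistic(rep(0, 20), matrix(1, 20)), "no events|degenerate")
  x <- c(rep(0, 20), rep(1, 20))
  expect_error(fit_logistic(x, cbind(1, x)), "separation")
  expect_error(fit_logistic(c(0, 1, 2), matrix(1, 3)), "binary")
})

test_that("category odds ratios rise in the lowest vitamin-D category under a true link", {
  co <- generate_cohort(cohort_config(n_subjects = 20000), seed = 52)
  keep <- apply_exclusions(co)$cohort
  ors <- category_or(keep, scheme = "quartile", adjust = "none")
  expect_s3_class(ors, "or_result")
  expect_identical(nrow(ors), 4L)
  ref_row <- ors[ors$level == ors$reference[1], ]
  expect_equal(ref_row$or, 1)
  expect_true(is.na(ref_row$ci_lo))
  q1 <- ors[ors$level == "Q1", ]
  expect_gt(q1$or, 1)
  expect_gt(q1$ci_lo, 1)  # significant at this effect size and n
  # non-increasing toward the reference within simulation tolerance
  expect_gt(q1$or, ors[ors$level == "Q2", "or"] - 0.05)
  expect_gt(ors[ors$level == "Q2", "or"], ors[ors$level == "Q3", "or"] - 0.1)
  # CI always contains the OR
  ok <- !is.na(ors$ci_lo)
  expect_true(all(ors$ci_lo[ok] < ors$or[ok] & ors$or[ok] < ors$ci_hi[ok]))
})

test_that("with no true effect the category CIs cover 1 at the nominal rate", {
  cover <- matrix(NA, 20, 3)
  for (s in 1:20) {
    co <- generate_cohort(
      cohort_config(n_subjects = 3000, below_threshold_slope = 0), seed = s)
    keep <- apply_exclusions(co)$cohort
    ors <- category_or(keep, scheme = "quartile", adjust = "none")
    ors <- ors[ors$level != ors$reference, ]
    cover[s, ] <- ors$ci_lo <= 1 & 1 <= ors$ci_hi
  }
  # each non-reference category's 95% CI covers 1 in at least 90% of runs
  expect_true(all(colMeans(cover) >= 0.9))
})

test_that("diabetes-stratified models drop the constant indicator and keep the pattern", {
  co <- generate_cohort(cohort_config(n_subjects = 20000), seed = 53)
  keep <- apply_exclusions(co)$cohort
  ors <- category_or(keep, scheme = "clinical", adjust = "full",
                     stratify_by_diabetes = TRUE)
  expect_setequal(unique(ors$stratum), c("diabetes", "no-diabetes"))
  expect_identical(nrow(ors), 6L)
  nd <- ors[ors$stratum == "no-diabetes" & ors$level == "deficiency", ]
  expect_gt(nd$or, 1)
})

test_that("lowess reproduces linear and constant data exactly and matches per-point WLS", {
  set.seed(54)
  x <- sort(runif(50, 0, 10))
  y_lin <- 2 + 0.5 * x
  sm <- lowess_smooth(x, y_lin, span = 0.4)
  expect_equal(sm$y, y_lin[order(x)], tolerance = 1e-9)
  sm_const <- lowess_smooth(x, rep(3, 50))
  expect_equal(sm_const$y, rep(3, 50))
  # tricube local-linear oracle, no robustness iterations
  y <- sin(x) + rnorm(50, 0, 0.2)
  sm2 <- lowess_smooth(x, y, span = 0.5, iter = 0)
  expect_equal(sm2$y, tricube_wls(x, y, 0.5), tolerance = 1e-8)
  expect_error(lowess_smooth(x[1:5], y[1:5]), "at least 10")
  expect_error(lowess_smooth(x, y, span = 0.02), "fewer than 3")
})

test_that("the predicted-probability curve falls below the change-point and flattens above", {
  co <- generate_cohort(cohort_config(n_subjects = 12000), seed = 55)
  keep <- apply_exclusions(co)$cohort
  pc <- predicted_probability_curve(keep, adjust = "none", n_boot = 30,
                                    seed = 2)
  expect_true(all(pc$fit > 0 & pc$fit < 1))
  expect_true(all(pc$lower <= pc$fit & pc$fit <= pc$upper))
  tau <- 8
  below <- pc$grid < tau - 2 & pc$grid > min(pc$grid) + 1
  above <- pc$grid > tau + 2 & pc$grid < 30
  slope_below <- mean(diff(pc$fit[below]) / diff(pc$grid[below]))
  slope_above <- mean(diff(pc$fit[above]) / diff(pc$grid[above]))
  expect_lt(slope_below, 0)
  expect_lt(abs(slope_above), abs(slope_below) / 2)
})

test_that("bootstrap band width shrinks with sample size", {
  widths <- sapply(c(2000, 20000), function(n) {
    co <- generate_cohort(cohort_config(n_subjects = n), seed = 56)
    keep <- apply_exclusions(co)$cohort
    pc <- predicted_probability_curve(keep, adjust = "none", n_boot = 40,
                                      seed = 3)
    mid <- pc$grid > 10 & pc$grid < 30
    mean(pc$upper[mid] - pc$lower[mid])
  })
  expect_lt(widths[2], widths[1])
})
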
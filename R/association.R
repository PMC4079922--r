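#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit with an explicit convergence rule:
#' iteration stops when the maximum absolute coefficient change falls below
#' `1e-8`, and fails after 100 iterations. The Wald covariance is the
#' inverse of the final weighted information matrix `X' W X`. Complete (or
#' quasi-complete) separation is detected from diverging coefficients with
#' near-degenerate fitted probabilities and raised as an error rather than
#' reported as a spurious fit.
#'
#' @param y Binary response vector (0/1 or logical).
#' @param X Design matrix including the intercept column.
#' @return Object of class `logistic_fit`: `coefficients`, `vcov`,
#'   `fitted`, `deviance`, `iter`, `converged`.
#' @export
#' @examples
#' x <- c(rep(0, 50), rep(1, 50))
#' y <- rbinom(100, 1, plogis(-1 + x))
#' fit <- fit_logistic(y, cbind(1, x))
#' coef(fit)
fit_logistic <- function(y, X) {
  y <- as.numeric(y)
  if (any(is.na(y)) || !all(y %in% c(0, 1)))
    stop("`y` must be binary (0/1)")
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("dimensions of `y` and `X` disagree")
  if (sum(y) == 0 || sum(y) == length(y))
    stop("degenerate outcome: no events (or no non-events); ",
         "the likelihood has no interior maximum")
  if (qr(X)$rank < ncol(X)) stop("`X` is not full rank")

  beta <- rep(0, ncol(X))
  dev <- Inf
  for (it in seq_len(100L)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    XtW <- t(X * w)
    beta_new <- tryCatch(
      solve(XtW %*% X, XtW %*% z),
      error = function(e) stop("IRLS step failed: ", conditionMessage(e)))
    delta <- max(abs(beta_new - beta))
    beta <- drop(beta_new)
    dev <- -2 * sum(y * log(pmax(plogis(drop(X %*% beta)), 1e-300)) +
                    (1 - y) * log(pmax(1 - plogis(drop(X %*% beta)), 1e-300)))
    if (max(abs(beta)) > 30 &&
        all(abs(plogis(drop(X %*% beta)) - y) < 1e-6))
      stop("complete separation detected: a linear combination of ",
           "covariates perfectly predicts the outcome")
    if (delta < 1e-8) {
      p <- plogis(drop(X %*% beta))
      w <- pmax(p * (1 - p), 1e-10)
      info <- t(X * w) %*% X
      return(structure(list(coefficients = setNames(beta, colnames(X)),
                            vcov = solve(info), fitted = p, deviance = dev,
                            iter = it, converged = TRUE),
                       class = "logistic_fit"))
    }
  }
  stop(sprintf("IRLS failed to converge in 100 iterations (last deviance %.4f)",
               dev))
}

#' @export
coef.logistic_fit <- function(object, ...) object$coefficients

#' @export
vcov.logistic_fit <- function(object, ...) object$vcov

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit (IRLS, %d iterations), deviance %.2f\n",
              x$iter, x$deviance))
  se <- sqrt(diag(x$vcov))
  print(data.frame(estimate = x$coefficients, se = se,
                   or = exp(x$coefficients)))
  invisible(x)
}

#' Odds ratios for high-normal albuminuria across vitamin-D categories
#'
#' Fits one logistic model per categorization scheme with indicator
#' contrasts against the reference (highest) category: the 4th quartile, the
#' 50-100th percentile bin, or vitamin-D sufficiency. The outcome is
#' high-normal UAE (UACR 10-29 mg/g) versus normal UAE (< 10 mg/g).
#' Adjusted models include age, sex, season, BMI, hemoglobin, eGFR,
#' hypertension, diabetes, vitamin-D supplement use, RAS blockers, serum
#' albumin, calcium, phosphorus, HDL cholesterol, triglyceride and hs-CRP.
#' With `stratify_by_diabetes = TRUE`, separate models are fitted within
#' diabetes strata, dropping the (constant) diabetes indicator from the
#' adjustment set. Confidence intervals are Wald intervals on the log-odds
#' scale, `exp(b +/- 1.96 se)`.
#'
#' @param cohort A retained (normoalbuminuric) cohort `data.frame`.
#' @param scheme Categorization scheme for [classify_vitd()].
#' @param adjust `"none"` or `"full"`.
#' @param stratify_by_diabetes Fit separate models by diabetes status.
#' @return A `data.frame` of class `or_result`, one row per category level
#'   and stratum: odds ratio, 95% CI (NA for the reference level and for
#'   levels with zero events, the latter flagged in `note`), cell counts.
#' @export
category_or <- function(cohort, scheme = c("quartile", "percentile", "clinical"),
                        adjust = c("full", "none"),
                        stratify_by_diabetes = FALSE) {
  scheme <- match.arg(scheme)
  adjust <- match.arg(adjust)
  cat_all <- classify_vitd(cohort$serum_25ohd, scheme = scheme)
  ref <- attr(cat_all, "reference")
  y_all <- as.integer(classify_uae(cohort$uacr) == "high_normal")

  strata <- if (stratify_by_diabetes) {
    list(diabetes = which(cohort$diabetes),
         `no-diabetes` = which(!cohort$diabetes))
  } else list(all = seq_len(nrow(cohort)))

  rows <- lapply(names(strata), function(sn) {
    idx <- strata[[sn]]
    cat_s <- factor(cat_all[idx], levels = levels(cat_all))
    y <- y_all[idx]
    cat_rel <- stats::relevel(cat_s, ref = ref)
    Xcat <- model.matrix(~ cat_rel)
    covmat <- if (adjust == "full") {
      vars <- setdiff(.adjust_vars("full"),
                      if (stratify_by_diabetes) "diabetes" else character(0))
      mm <- model.matrix(~ ., data = cohort[idx, vars, drop = FALSE])
      mm[, -1, drop = FALSE]
    } else NULL
    n_events <- tapply(y, cat_s, sum)
    n_cell <- table(cat_s)
    keep_ok <- n_events > 0 & !is.na(n_events)

    fit <- fit_logistic(y, cbind(Xcat, covmat))
    b <- coef(fit); se <- sqrt(diag(vcov(fit)))
    lev <- levels(cat_s)
    out <- lapply(lev, function(lv) {
      if (lv == ref)
        return(data.frame(scheme = scheme, level = lv, reference = ref,
                          or = 1, ci_lo = NA_real_, ci_hi = NA_real_,
                          n = as.integer(n_cell[lv]),
                          n_events = as.integer(n_events[lv]),
                          stratum = sn, adjusted = adjust, note = "reference",
                          stringsAsFactors = FALSE))
      if (!keep_ok[lv])
        return(data.frame(scheme = scheme, level = lv, reference = ref,
                          or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                          n = as.integer(n_cell[lv]),
                          n_events = as.integer(n_events[lv]),
                          stratum = sn, adjusted = adjust,
                          note = "zero events: OR omitted",
                          stringsAsFactors = FALSE))
      nm <- paste0("cat_rel", lv)
      data.frame(scheme = scheme, level = lv, reference = ref,
                 or = exp(b[nm]),
                 ci_lo = exp(b[nm] - 1.96 * se[nm]),
                 ci_hi = exp(b[nm] + 1.96 * se[nm]),
                 n = as.integer(n_cell[lv]),
                 n_events = as.integer(n_events[lv]),
                 stratum = sn, adjusted = adjust, note = "",
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("or_result", "data.frame")
  out
}

#' Locally weighted scatterplot smoothing (lowess)
#'
#' Local linear regression with tricube weights over the span-nearest
#' neighbors of each point, with optional bisquare robustness iterations.
#' Defaults (span 2/3, 3 robustness iterations) are the conventional lowess
#' defaults.
#'
#' @param x,y Numeric vectors (at least 10 points).
#' @param span Fraction of points in each local window, in `(0, 1]`; the
#'   window must contain at least 3 points.
#' @param iter Number of robustness (bisquare reweighting) iterations.
#' @return A list with sorted `x` and smoothed `y`.
#' @export
lowess_smooth <- function(x, y, span = 2 / 3, iter = 3L) {
  if (length(x) < 10L) stop("lowess needs at least 10 points")
  if (length(x) != length(y)) stop("`x` and `y` lengths differ")
  if (span <= 0 || span > 1) stop("`span` must be in (0, 1]")
  if (floor(span * length(x)) < 3L)
    stop("`span` too small: local windows contain fewer than 3 points")
  stats::lowess(x, y, f = span, iter = iter, delta = 0)
}

#' Predicted-probability curve for high-normal albuminuria
#'
#' Fits the multivariate logistic model for high-normal UAE, computes each
#' subject's predicted probability at their observed covariates
#' (population-averaged, not at covariate means), smooths the probabilities
#' against 25(OH)D with lowess, and attaches pointwise 95% bands from a
#' seeded bootstrap over subjects (model refitted and re-smoothed in each
#' resample). Serum 25(OH)D enters the model through an unpenalized
#' B-spline basis (`d_form = "spline"`, the default) so the curve can bend
#' around a change-point; `d_form = "linear"` gives the plain linear-logit
#' term.
#'
#' @param cohort A retained cohort `data.frame`.
#' @param adjust `"full"` or `"none"` (intercept + 25(OH)D only).
#' @param n_boot Number of bootstrap resamples for the band.
#' @param seed Seed for the bootstrap.
#' @param span Lowess span.
#' @param grid_length Number of evaluation points across the 25(OH)D range.
#' @param d_form How 25(OH)D enters the logit: `"spline"` (6-dimensional
#'   B-spline) or `"linear"`.
#' @return Object of class `probability_curve`: `grid`, `fit`, `lower`,
#'   `upper`, and the underlying `logistic_fit`.
#' @export
predicted_probability_curve <- function(cohort, adjust = c("full", "none"),
                                        n_boot = 200L, seed = 1L,
                                        span = 2 / 3, grid_length = 100L,
                                        d_form = c("spline", "linear")) {
  adjust <- match.arg(adjust)
  d_form <- match.arg(d_form)
  y <- as.integer(classify_uae(cohort$uacr) == "high_normal")
  D <- cohort$serum_25ohd
  Dmat <- if (d_form == "spline") {
    B <- spline_basis(D, dim = 6L)$B[, -1, drop = FALSE]  # drop one column:
    colnames(B) <- paste0("d_bs", seq_len(ncol(B)))       # basis sums to 1
    B
  } else matrix(D, dimnames = list(NULL, "serum_25ohd"))
  build_X <- function(rows) {
    cov <- if (adjust == "full") .adjust_matrix(cohort[rows, , drop = FALSE],
                                                "full") else NULL
    cbind(`(Intercept)` = 1, Dmat[rows, , drop = FALSE], cov)
  }
  all_rows <- seq_len(nrow(cohort))
  fit <- fit_logistic(y, build_X(all_rows))
  grid <- seq(min(D), max(D), length.out = grid_length)
  smooth_to_grid <- function(d, p) {
    s <- lowess_smooth(d, p, span = span, iter = 0L)
    approx(s$x, s$y, xout = grid, rule = 2, ties = mean)$y
  }
  est <- smooth_to_grid(D, fit$fitted)

  set.seed(as.integer(seed))
  boot <- matrix(NA_real_, n_boot, grid_length)
  for (b in seq_len(n_boot)) {
    rows <- sample(all_rows, replace = TRUE)
    bf <- tryCatch(fit_logistic(y[rows], build_X(rows)),
                   error = function(e) NULL)
    if (is.null(bf)) next
    boot[b, ] <- smooth_to_grid(D[rows], bf$fitted)
  }
  qs <- apply(boot, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  structure(list(grid = grid, fit = pmin(pmax(est, 0), 1),
                 lower = pmin(pmax(pmin(qs[1, ], est), 0), 1),
                 upper = pmin(pmax(pmax(qs[2, ], est), 0), 1),
                 model = fit, adjust = adjust, n_boot = n_boot, seed = seed),
            class = "probability_curve")
}

#' @export
print.probability_curve <- function(x, ...) {
  cat(sprintf("Predicted-probability curve (%s adjustment, %d bootstrap resamples)\n",
              x$adjust, x$n_boot))
  cat(sprintf("  25(OH)D grid: [%.1f, %.1f] ng/mL; probability range %.3f-%.3f\n",
              min(x$grid), max(x$grid), min(x$fit), max(x$fit)))
  invisible(x)
}

#' @export
plot.probability_curve <- function(x, ...) {
  graphics::plot(x$grid, x$fit, type = "l", lwd = 2,
                 ylim = range(x$lower, x$upper),
                 xlab = "serum 25(OH)D (ng/mL)",
                 ylab = "predicted probability of high-normal UAE", ...)
  graphics::lines(x$grid, x$lower, lty = 2)
  graphics::lines(x$grid, x$upper, lty = 2)
  invisible(x)
}
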
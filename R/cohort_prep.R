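#' Apply the study's inclusion and exclusion rules
#'
#' Retains subjects aged >= 20 years with serum 25(OH)D <= 125 ng/mL and
#' UACR < 30 mg/g (normoalbuminuria). Records missing any of the three
#' required fields are rejected with reason code `"missing"` and counted
#' separately. The log reports the overlap-aware union count, so
#' `n_retained = n_input - n_excluded_union` always holds even when a record
#' triggers several rules at once.
#'
#' @param cohort A cohort `data.frame` with columns `age`, `serum_25ohd`,
#'   `uacr`.
#' @return A list with components `cohort` (retained records) and `log` (an
#'   `exclusion_log`: counts per reason, the union count, and per-record
#'   reason codes for excluded records).
#' @export
#' @examples
#' fx <- generate_exclusion_fixture(seed = 1)
#' res <- apply_exclusions(fx)
#' res$log$n_retained  # 14594
apply_exclusions <- function(cohort) {
  need <- c("age", "serum_25ohd", "uacr")
  miss_col <- setdiff(need, names(cohort))
  if (length(miss_col) > 0L)
    stop("cohort lacks required column(s): ", paste(miss_col, collapse = ", "))
  n <- nrow(cohort)
  missing <- !complete.cases(cohort[, need, drop = FALSE])
  young <- !missing & cohort$age < 20
  vitd_out <- !missing & cohort$serum_25ohd > 125
  uacr_out <- !missing & cohort$uacr >= 30
  excl <- missing | young | vitd_out | uacr_out

  reasons <- character(0)
  if (any(excl)) {
    idx <- which(excl)
    reasons <- vapply(idx, function(i) {
      r <- c(if (missing[i]) "missing",
             if (young[i]) "age_lt_20",
             if (vitd_out[i]) "vitd_outlier",
             if (uacr_out[i]) "uacr_ge_30")
      paste(r, collapse = "+")
    }, character(1))
    names(reasons) <- if (!is.null(cohort$subject_id)) cohort$subject_id[idx] else idx
  }

  log <- structure(list(
    n_input = n,
    n_excluded_missing = sum(missing),
    n_excluded_age = sum(young),
    n_excluded_vitd_outlier = sum(vitd_out),
    n_excluded_uacr = sum(uacr_out),
    n_excluded_union = sum(excl),
    n_retained = n - sum(excl),
    reasons = reasons), class = "exclusion_log")
  list(cohort = cohort[!excl, , drop = FALSE], log = log)
}

#' @export
print.exclusion_log <- function(x, ...) {
  cat("Exclusion log\n")
  cat(sprintf("  input: %d\n", x$n_input))
  cat(sprintf("  excluded (union): %d\n", x$n_excluded_union))
  cat(sprintf("    25(OH)D > 125 ng/mL: %d\n", x$n_excluded_vitd_outlier))
  cat(sprintf("    UACR >= 30 mg/g:     %d\n", x$n_excluded_uacr))
  cat(sprintf("    age < 20 years:      %d\n", x$n_excluded_age))
  cat(sprintf("    missing fields:      %d\n", x$n_excluded_missing))
  cat(sprintf("  retained: %d\n", x$n_retained))
  invisible(x)
}

#' Classify urinary albumin excretion status
#'
#' Normal UAE is UACR < 10 mg/g; high-normal UAE is UACR 10-29 mg/g.
#' Values >= 30 mg/g (or negative/missing) are outside the study population
#' and must be excluded upstream; passing one is an error, not a silent NA.
#'
#' @param uacr Numeric vector of UACR values (mg/g), each in `[0, 30)`.
#' @return Factor with levels `normal`, `high_normal`.
#' @export
#' @examples
#' classify_uae(c(0, 9.99, 10, 29.9))
classify_uae <- function(uacr) {
  if (any(is.na(uacr)))
    stop("UACR contains missing values; exclude them upstream")
  if (any(uacr < 0 | uacr >= 30))
    stop("UACR outside [0, 30): records with UACR >= 30 mg/g must be ",
         "excluded before classification")
  factor(ifelse(uacr < 10, "normal", "high_normal"),
         levels = c("normal", "high_normal"))
}

#' Categorize serum 25(OH)D levels
#'
#' Three categorization schemes, each with the highest category as the
#' reference level:
#' \describe{
#'   \item{`quartile`}{cohort quartiles Q1 (lowest) to Q4 (reference); cut
#'     points are the cohort's 25th/50th/75th percentiles (type-7 quantiles),
#'     boundary values assigned to the upper bin.}
#'   \item{`percentile`}{bins at the cohort's 5th/25th/50th percentiles:
#'     `<5`, `5-24.9`, `25-49.9`, `50-100` (reference). The lowest bin covers
#'     everything below the 5th percentile.}
#'   \item{`clinical`}{deficiency `< 15.0`, insufficiency `15.0-29.9`,
#'     sufficiency `>= 30.0` ng/mL (reference).}
#' }
#'
#' @param serum_25ohd Numeric vector of 25(OH)D values (ng/mL).
#' @param scheme One of `"quartile"`, `"percentile"`, `"clinical"`.
#' @param cohort_values Values from which cohort quantiles are computed
#'   (default: `serum_25ohd` itself). Pass the retained cohort's values when
#'   classifying a subset.
#' @return Factor with the scheme's levels (lowest first); the reference
#'   level (the highest category) is stored in attribute `reference` and the
#'   scheme in attribute `scheme`.
#' @export
#' @examples
#' classify_vitd(c(10, 14.9, 15, 29.9, 30), scheme = "clinical")
classify_vitd <- function(serum_25ohd,
                          scheme = c("quartile", "percentile", "clinical"),
                          cohort_values = serum_25ohd) {
  scheme <- match.arg(scheme)
  if (any(is.na(serum_25ohd))) stop("serum_25ohd contains missing values")
  br_lab <- switch(scheme,
    quartile = {
      q <- quantile(cohort_values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      if (any(duplicated(q))) stop("degenerate quartile cut points")
      list(breaks = c(-Inf, q, Inf), labels = c("Q1", "Q2", "Q3", "Q4"))
    },
    percentile = {
      q <- quantile(cohort_values, c(0.05, 0.25, 0.50), type = 7, names = FALSE)
      if (any(duplicated(q))) stop("degenerate percentile cut points")
      list(breaks = c(-Inf, q, Inf),
           labels = c("<5.0th", "5.0-24.9th", "25.0-49.9th", "50.0-100.0th"))
    },
    clinical = list(breaks = c(-Inf, 15, 30, Inf),
                    labels = c("deficiency", "insufficiency", "sufficiency")))
  out <- cut(serum_25ohd, breaks = br_lab$breaks, labels = br_lab$labels,
             right = FALSE)
  attr(out, "scheme") <- scheme
  attr(out, "reference") <- br_lab$labels[length(br_lab$labels)]
  out
}

#' Estimated GFR by the four-variable MDRD equation
#'
#' `eGFR = 175 * creatinine^-1.154 * age^-0.203 * (0.742 if female)` in
#' mL/min/1.73 m^2. The race coefficient is omitted (East Asian cohort).
#'
#' @param serum_creatinine Serum creatinine (mg/dL), > 0.
#' @param age Age in years, > 0.
#' @param sex Character/factor vector with values `"male"`/`"female"`.
#' @return Numeric vector of eGFR values.
#' @export
#' @examples
#' compute_egfr(1.0, 50, "male")    # ~79.1
#' compute_egfr(1.0, 50, "female")  # ~58.7
compute_egfr <- function(serum_creatinine, age, sex) {
  if (any(is.na(serum_creatinine)) || any(serum_creatinine <= 0))
    stop("serum_creatinine must be positive")
  if (any(is.na(age)) || any(age <= 0)) stop("age must be positive")
  sex <- as.character(sex)
  if (!all(sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  175 * serum_creatinine^(-1.154) * age^(-0.203) *
    ifelse(sex == "female", 0.742, 1)
}

#' Map examination month to season
#'
#' Spring is March-May, summer June-August, autumn September-November,
#' winter December-February.
#'
#' @param exam_month Integer vector of months, 1-12.
#' @return Factor with levels `spring`, `summer`, `autumn`, `winter`.
#' @export
#' @examples
#' assign_season(c(3, 12))
assign_season <- function(exam_month) {
  if (any(is.na(exam_month)) || any(exam_month < 1 | exam_month > 12) ||
      any(exam_month != round(exam_month)))
    stop("exam_month must be an integer in 1-12")
  season <- c("winter", "winter", "spring", "spring", "spring",
              "summer", "summer", "summer", "autumn", "autumn", "autumn",
              "winter")[exam_month]
  factor(season, levels = c("spring", "summer", "autumn", "winter"))
}

# Table-1 presentation conventions: which variables are summarized as
# median (IQR) with a rank test rather than mean +/- SD with a t-test.
.skewed_vars <- c("uacr", "hs_crp")

#' Two-group descriptive table with significance tests
#'
#' Summarizes cohort variables by a two-level grouping: approximately normal
#' continuous variables as mean +/- SD compared by Student's t-test, skewed
#' variables (UACR, hs-CRP) as median (IQR) compared by the Mann-Whitney
#' U-test, and categorical/logical variables as N (%) compared by the
#' chi-squared test. All p-values are two-sided. Groups with fewer than two
#' observations get summaries but no test (flagged in the `test` column).
#'
#' @param cohort A cohort `data.frame`.
#' @param group A factor with exactly two levels (one entry per row of
#'   `cohort`), or the name of a two-level column in `cohort`.
#' @param variables Variables to summarize; defaults to the standard
#'   clinical set present in `cohort`.
#' @return A `data.frame` of class `descriptive_table` with one row per
#'   variable: formatted per-group summaries, the test used, and the
#'   p-value.
#' @export
descriptive_table <- function(cohort, group, variables = NULL) {
  if (is.character(group) && length(group) == 1L) {
    if (!group %in% names(cohort)) stop("no column named '", group, "'")
    group <- cohort[[group]]
  }
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("`group` must have exactly 2 levels")
  if (length(group) != nrow(cohort))
    stop("`group` length must match the cohort")
  if (is.null(variables)) {
    std <- c("age", "sex", "season", "bmi", "serum_25ohd", "uacr",
             "hemoglobin", "serum_albumin", "serum_calcium",
             "serum_phosphorus", "hs_crp", "total_chol", "ldl_chol",
             "hdl_chol", "triglyceride", "egfr", "diabetes", "hypertension",
             "ras_blocker", "vitd_supplement")
    variables <- intersect(std, names(cohort))
  }
  g1 <- levels(group)[1]; g2 <- levels(group)[2]
  small <- min(table(group)) < 2L

  rows <- lapply(variables, function(v) {
    x <- cohort[[v]]
    by_g <- split(x, group)
    if (is.numeric(x) && !(v %in% .skewed_vars)) {
      fmt <- vapply(by_g, function(z)
        sprintf("%.1f ± %.1f", mean(z), sd(z)), character(1))
      test <- "t"
      p <- if (small) NA_real_ else t.test(x ~ group)$p.value
    } else if (is.numeric(x)) {
      fmt <- vapply(by_g, function(z) {
        q <- quantile(z, c(0.25, 0.5, 0.75), names = FALSE)
        sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3])
      }, character(1))
      test <- "mann-whitney"
      p <- if (small) NA_real_ else
        suppressWarnings(wilcox.test(x ~ group)$p.value)
    } else {
      xf <- if (is.logical(x)) factor(x, levels = c(FALSE, TRUE)) else as.factor(x)
      fmt <- vapply(by_g, function(z) {
        zf <- if (is.logical(z)) factor(z, levels = c(FALSE, TRUE)) else
          factor(z, levels = levels(xf))
        if (is.logical(x) || nlevels(xf) == 2L) {
          k <- sum(zf == levels(xf)[nlevels(xf)])
          sprintf("%d/%.1f%%", k, 100 * k / length(z))
        } else {
          paste(sprintf("%s: %.1f%%", levels(zf), 100 * prop.table(table(zf))),
                collapse = "; ")
        }
      }, character(1))
      test <- "chi-squared"
      p <- if (small) NA_real_ else
        suppressWarnings(chisq.test(table(x, group))$p.value)
    }
    data.frame(variable = v, group1 = fmt[[g1]], group2 = fmt[[g2]],
               test = if (small) paste0(test, " (suppressed: group < 2)") else test,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:3] <- c(g1, g2)
  class(out) <- c("descriptive_table", "data.frame")
  out
}
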
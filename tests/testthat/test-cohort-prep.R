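test_that("exclusion rules retain the normoalbuminuric adult cohort", {
  co <- data.frame(subject_id = 1:6,
                   age = c(25, 19, 40, 50, 60, NA),
                   serum_25ohd = c(20, 20, 130, 20, 126, 20),
                   uacr = c(5, 5, 35, 30, 10, 5))
  res <- apply_exclusions(co)
  expect_identical(res$log$n_retained, 1L)
  expect_identical(res$cohort$subject_id, 1L)
  expect_identical(res$log$n_excluded_union, 5L)
  expect_identical(res$log$n_excluded_missing, 1L)
  expect_identical(res$log$n_excluded_age, 1L)
  # a record failing both rules counts once in the union, with both flags
  one <- apply_exclusions(data.frame(age = 30, serum_25ohd = 130, uacr = 35))
  expect_identical(one$log$n_excluded_union, 1L)
  expect_identical(one$log$n_excluded_vitd_outlier, 1L)
  expect_identical(one$log$n_excluded_uacr, 1L)
  expect_match(one$log$reasons[[1]], "vitd_outlier\\+uacr_ge_30")

  empty <- apply_exclusions(data.frame(age = numeric(0),
                                       serum_25ohd = numeric(0),
                                       uacr = numeric(0)))
  expect_identical(empty$log$n_retained, 0L)
  expect_identical(empty$log$n_excluded_union, 0L)
})

test_that("applying exclusions twice changes nothing", {
  fx <- generate_exclusion_fixture(seed = 4)
  once <- apply_exclusions(fx)
  twice <- apply_exclusions(once$cohort)
  expect_identical(twice$log$n_excluded_union, 0L)
  expect_equal(twice$cohort$uacr, once$cohort$uacr)
})

test_that("UAE classification uses the 10 mg/g boundary exactly", {
  expect_identical(as.character(classify_uae(c(0, 9.99, 10, 29.9))),
                   c("normal", "normal", "high_normal", "high_normal"))
  expect_error(classify_uae(30), "excluded")
  expect_error(classify_uae(-1), "UACR")
})

test_that("vitamin D categories partition the cohort with the highest level as reference", {
  set.seed(21)
  d <- runif(1000, 1, 50)
  for (scheme in c("quartile", "percentile", "clinical")) {
    cat_ <- classify_vitd(d, scheme = scheme)
    expect_false(any(is.na(cat_)))                 # exhaustive partition
    expect_identical(sum(table(cat_)), 1000L)
    expect_identical(attr(cat_, "reference"),
                     levels(cat_)[nlevels(cat_)])  # highest category
  }
  # quartile bins are balanced (continuous data, no ties)
  q <- table(classify_vitd(d, "quartile"))
  expect_lte(max(q) - min(q), 1)
  # clinical boundaries
  expect_identical(as.character(classify_vitd(c(14.9, 15, 29.9, 30), "clinical")),
                   c("deficiency", "insufficiency", "insufficiency", "sufficiency"))
  # the cohort median belongs to the reference percentile bin
  pc <- classify_vitd(median(d), "percentile", cohort_values = d)
  expect_identical(as.character(pc), "50.0-100.0th")
})

test_that("MDRD eGFR matches direct evaluation of the published formula", {
  expect_equal(compute_egfr(1.0, 50, "male"),
               175 * 50^(-0.203), tolerance = 1e-12)
  expect_equal(round(compute_egfr(1.0, 50, "male"), 1), 79.1)
  expect_equal(compute_egfr(1.0, 50, "female"),
               compute_egfr(1.0, 50, "male") * 0.742)
  expect_equal(round(compute_egfr(1.0, 50, "female"), 1), 58.7)
  # spreadsheet-style recomputation on random records
  set.seed(30)
  scr <- runif(20, 0.5, 2); age <- runif(20, 25, 80)
  sex <- sample(c("male", "female"), 20, replace = TRUE)
  manual <- 175 * scr^(-1.154) * age^(-0.203) * ifelse(sex == "female", 0.742, 1)
  expect_equal(compute_egfr(scr, age, sex), manual)
  # monotone decreasing in creatinine
  expect_true(all(compute_egfr(2 * scr, age, sex) < compute_egfr(scr, age, sex)))
  expect_error(compute_egfr(0, 50, "male"), "positive")
})

test_that("months map onto the four seasons as defined", {
  expect_identical(as.character(assign_season(3)), "spring")
  expect_identical(as.character(assign_season(12)), "winter")
  all12 <- assign_season(1:12)
  expect_false(any(is.na(all12)))
  expect_identical(as.vector(table(all12)), rep(3L, 4))
  expect_error(assign_season(13), "1-12")
})

test_that("descriptive table applies the test convention of the study", {
  co <- small_cohort(n = 600, seed = 14)
  keep <- apply_exclusions(co)$cohort
  tab <- descriptive_table(keep, classify_uae(keep$uacr))
  expect_s3_class(tab, "descriptive_table")
  expect_identical(tab$test[tab$variable == "uacr"], "mann-whitney")
  expect_identical(tab$test[tab$variable == "hs_crp"], "mann-whitney")
  expect_identical(tab$test[tab$variable == "age"], "t")
  expect_identical(tab$test[tab$variable == "diabetes"], "chi-squared")
  expect_true(all(is.na(tab$p_value) | (tab$p_value >= 0 & tab$p_value <= 1)))
})

test_that("two identical groups give t = 0, p = 1; tiny groups suppress tests", {
  x <- data.frame(age = rep(c(30, 40, 50), 2), uacr = rep(c(2, 4, 8), 2))
  g <- factor(rep(c("a", "b"), each = 3))
  tab <- descriptive_table(x, g, variables = "age")
  expect_equal(tab$p_value, 1)
  tiny <- descriptive_table(data.frame(age = c(30, 40, 50)),
                            factor(c("a", "a", "b")), variables = "age")
  expect_true(is.na(tiny$p_value))
  expect_match(tiny$test, "suppressed")
})

test_that("Mann-Whitney on fully separated pairs gives U = 0 and exact p = 1/3", {
  # brute force over all choose(4,2) = 6 rank arrangements: P(U <= 0) = 1/6,
  # two-sided p = 1/3
  w <- wilcox.test(c(1, 2), c(3, 4))
  expect_equal(unname(w$statistic), 0)
  expect_equal(w$p.value, 1 / 3)
  df <- data.frame(uacr = c(1, 2, 3, 4))
  tab <- descriptive_table(df, factor(c("x", "x", "y", "y")), variables = "uacr")
  expect_equal(tab$p_value, 1 / 3)
})
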
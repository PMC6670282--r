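test_that("BMI and WHR derivation: arithmetic, missingness, validation", {
  expect_equal(derive_bmi(1.60, 64), 25.0)
  expect_true(is.na(derive_bmi(NA, 64)))
  expect_true(is.na(derive_bmi(1.60, NA)))
  expect_error(derive_bmi(0, 64), "positive")
  expect_error(derive_bmi(1.6, -2), "positive")

  expect_equal(derive_whr(91, 100), 0.91)
  expect_true(is.na(derive_whr(NA, 100)))
  expect_error(derive_whr(91, 0), "positive")
  expect_warning(z <- derive_whr(0, 100), "zero waist")
  expect_equal(z, 0)

  # the default cohort's derived indices track the published means
  co <- generate_cohort(cohort_profile(n_subjects = 3000,
                                       missing_rates = numeric(0)), seed = 6)
  expect_equal(mean(derive_bmi(co$height, co$weight)), 25.25,
               tolerance = 0.01)
  expect_equal(mean(derive_whr(co$waist_girth, co$hip_girth)), 0.91,
               tolerance = 0.01)
})

test_that("missingness filter keeps records with at most 6 of 18 missing", {
  co <- derive_indices(generate_cohort(cohort_profile(n_subjects = 10,
                                                      missing_rates = numeric(0)),
                                       seed = 1))
  attrs <- analysis_attribute_names()
  co[1, attrs[1:7]] <- NA   # 7 missing -> removed
  co[2, attrs[1:6]] <- NA   # 6 missing -> kept (boundary)
  out <- filter_incomplete(co)
  expect_equal(nrow(out), 9)
  expect_equal(attr(out, "n_removed"), 1)
  expect_true(anyNA(out[1, attrs]))   # the 6-missing boundary record stays
  # order preserved, complete records untouched
  expect_equal(out[-1, ], co[3:10, ], ignore_attr = TRUE)
})

test_that("imputation fills means, modes and flags provenance", {
  df <- data.frame(x = c(2, NA, 4), gender = c(1, 1, NA), oa = c(1, 2, 1))
  out <- impute_missing(df)
  expect_equal(out$x[2], 3)
  expect_equal(out$gender[3], 1)
  expect_false(anyNA(out))
  expect_equal(which(attr(out, "imputed")), c(2L, 6L))

  # mode ties break toward the lower state
  df2 <- data.frame(education = c(1, 1, 2, 2, NA), oa = 1)
  expect_equal(impute_missing(df2)$education[5], 1)

  # identity on complete data
  df3 <- data.frame(x = 1:3, oa = c(1, 2, 1))
  expect_equal(impute_missing(df3)[, ], df3, ignore_attr = TRUE)

  expect_error(impute_missing(data.frame(x = c(NA_real_, NA_real_))), "'x'")
})

test_that("1-D k-means cutpoints are exact", {
  expect_equal(as.numeric(learn_cutpoint_kmeans(c(1, 2, 9, 10))), 5.5)
  expect_equal(as.numeric(learn_cutpoint_kmeans(c(-3, 3))), 0)
  expect_error(learn_cutpoint_kmeans(rep(5, 4)), "distinct")

  # brute-force oracle: best contiguous split of the sorted values
  brute_cut <- function(x) {
    x <- sort(x)
    n <- length(x)
    best <- NULL
    for (s in 1:(n - 1)) {
      a <- x[1:s]; b <- x[(s + 1):n]
      wcss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
      if (is.null(best) || wcss < best$wcss - 1e-12) {
        best <- list(wcss = wcss, cut = (mean(a) + mean(b)) / 2)
      }
    }
    best$cut
  }
  set.seed(99)
  for (i in 1:50) {
    x <- round(stats::runif(sample(3:12, 1), 0, 20), 2)
    if (length(unique(x)) < 2) next
    expect_equal(as.numeric(learn_cutpoint_kmeans(x)), brute_cut(x),
                 tolerance = 1e-12)
  }
  # k = 3 beats or matches every exhaustive double-split on a small vector
  x <- c(1, 1.5, 6, 7, 14, 15, 15.5)
  cuts <- learn_cutpoint_kmeans(x, k = 3)
  expect_equal(length(cuts), 2)
  expect_true(all(diff(cuts) > 0))
})

test_that("the packaged scheme reproduces the printed boundary conventions", {
  sch <- table3_scheme()
  expect_equal(discretize_values(c(8.9, 8.91, 0), sch$tug), c(1L, 2L, 1L))
  expect_equal(discretize_values(c(24.9, 25.0), sch$bmi), c(1L, 2L))
  expect_equal(discretize_values(c(70, 70.1), sch$age), c(1L, 2L))
  expect_equal(discretize_values(c(0.91, 0.911), sch$whr), c(1L, 2L))
  expect_equal(discretize_values(c(0.763, 0.764), sch$sebt_anterior),
               c(1L, 2L))
  expect_error(discretize_values(-1, sch$tug), "support")
  expect_error(discretize_values(2.5, sch$sebt_medial, "sebt_medial"),
               "support")
})

test_that("discretize maps records to valid states and keeps NA", {
  rec <- make_analysis_records(seed = 11)
  rec$msr[3] <- NA
  dd <- discretize(rec, table3_scheme())
  expect_s3_class(dd, "discrete_dataset")
  expect_true(is.na(dd$data[3, "msr"]))
  expect_true(all(dd$data[, "education"] %in% 1:3, na.rm = TRUE))
  expect_equal(unname(dd$levels["oa"]), "disease")
  expect_equal(unname(dd$levels["sebt_medial"]), "predictor")

  # idempotent in effect: bin representatives map back to their own state
  sch <- table3_scheme()
  for (v in c("tug", "bmi", "slsb")) {
    cut <- sch[[v]]$cutpoints
    reps <- c(cut / 2, cut + 1)
    expect_equal(discretize_values(reps, sch[[v]]), c(1L, 2L))
  }
})

test_that("learned schemes cover the attributes and use k-means cutpoints", {
  rec <- make_analysis_records(seed = 21)
  bal <- smote_oversample(rec, seed = 3)
  sch <- learn_scheme(bal)
  expect_setequal(names(sch), names(rec))
  expect_equal(as.numeric(sch$tug$cutpoints),
               as.numeric(learn_cutpoint_kmeans(bal$tug)))
  dd <- discretize(bal, sch)
  expect_false(anyNA(dd$data))
})

test_that("filter -> impute -> discretize leaves no missing states", {
  raw <- generate_cohort(cohort_profile(), seed = 31)
  rec <- impute_missing(filter_incomplete(derive_indices(raw)))
  dd <- discretize(rec, table3_scheme())
  expect_false(anyNA(dd$data))
  for (v in colnames(dd$data)) {
    expect_true(all(dd$data[, v] %in% seq_along(dd$states[[v]])))
  }
})
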
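test_that("stratified folds are balanced, exhaustive and deterministic", {
  lab <- rep(1:2, each = 55)
  folds <- stratified_kfold(lab, k = 5, seed = 1)
  expect_equal(sort(unlist(folds)), 1:110)
  for (f in folds) {
    expect_equal(length(f), 22)
    expect_equal(sum(lab[f] == 2), 11)
  }
  expect_identical(stratified_kfold(lab, k = 5, seed = 2),
                   stratified_kfold(lab, k = 5, seed = 2))

  lab157 <- rep(1:2, times = c(78, 79))
  sizes <- sort(lengths(stratified_kfold(lab157, k = 5, seed = 3)),
                decreasing = TRUE)
  expect_equal(sizes, c(32, 32, 31, 31, 31))
  # per-fold class share within one record of the global share
  for (f in stratified_kfold(lab157, k = 5, seed = 3)) {
    expect_lt(abs(sum(lab157[f] == 2) - length(f) * 79 / 157), 1)
  }
  expect_error(stratified_kfold(rep(1:2, c(100, 3)), k = 5), "smaller k")
})

test_that("the 30/70 split is stratified and disjoint", {
  lab <- rep(1:2, times = c(78, 79))
  sp <- stratified_split(lab, fraction = 0.3, seed = 9)
  expect_equal(sort(c(sp$first, sp$second)), seq_along(lab))
  expect_equal(length(intersect(sp$first, sp$second)), 0)
  expect_equal(sum(lab[sp$first] == 2), round(79 * 0.3))
})

test_that("confusion counting follows the ties-positive rule", {
  perfect <- confusion(c(0.9, 0.8, 0.1, 0.2), c(2, 2, 1, 1))
  expect_equal(perfect$fp + perfect$fn, 0)

  ties <- confusion(rep(0.5, 4), rep(1, 4))
  expect_equal(ties$fp, 4)

  scores <- c(.9, .8, .7, .6, .55, .45, .4, .3, .2, .1)
  labels <- c(2, 2, 1, 2, 1, 2, 1, 1, 2, 1)
  cm <- confusion(scores, labels)
  expect_equal(c(cm$tp, cm$fp, cm$tn, cm$fn), c(3, 2, 3, 2))
  expect_error(confusion(0.5, 3), "coded 1")
})

test_that("accuracy, sensitivity and specificity mirror the SHBN row", {
  cm <- structure(list(tp = 73, fn = 27, tn = 78, fp = 22),
                  class = "confusion_counts")
  expect_equal(sensitivity(cm), 0.73)
  expect_equal(specificity(cm), 0.78)
  expect_equal(accuracy(cm), 0.755)

  all_good <- structure(list(tp = 5, fn = 0, tn = 5, fp = 0),
                        class = "confusion_counts")
  expect_equal(c(accuracy(all_good), sensitivity(all_good),
                 specificity(all_good)), c(1, 1, 1))

  no_pos <- structure(list(tp = 0, fn = 0, tn = 5, fp = 1),
                      class = "confusion_counts")
  expect_error(sensitivity(no_pos), "undefined")
})

test_that("AUC is the Mann-Whitney statistic with half-weight ties", {
  expect_equal(auc(c(.9, .8, .2, .1), c(2, 2, 1, 1)), 1.0)
  expect_equal(auc(rep(0.4, 6), rep(1:2, 3)), 0.5)

  brute_auc <- function(s, l) {
    pos <- s[l == 2]; neg <- s[l == 1]
    tot <- 0
    for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  set.seed(31)
  for (i in 1:25) {
    n <- sample(6:20, 1)
    s <- round(stats::runif(n), 1)  # coarse grid forces ties
    l <- sample(1:2, n, replace = TRUE)
    if (length(unique(l)) < 2) next
    expect_equal(auc(s, l), brute_auc(s, l), tolerance = 1e-12)
  }
  expect_error(auc(c(.1, .2), c(1, 1)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(37)
  s <- stats::runif(60)
  l <- sample(1:2, 60, replace = TRUE)
  expect_equal(auc(s, l),
               as.numeric(pROC::auc(pROC::roc(l, s, levels = c(1, 2),
                                              direction = "<", quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("predictive values reproduce the published tables cell by cell", {
  # headline cells
  expect_equal(round(ppv_at_prevalence(.73, .78, .20), 2), 0.45)
  expect_equal(round(ppv_at_prevalence(.73, .78, .01), 2), 0.03)
  expect_equal(round(npv_at_prevalence(.73, .78, .20), 2), 0.92)
  expect_equal(round(npv_at_prevalence(.69, .73, .20), 2), 0.90)
  expect_equal(ppv_at_prevalence(0.4, 1.0, 0.3), 1.0)
  expect_equal(npv_at_prevalence(1.0, 0.4, 0.3), 1.0)

  # all 48 cells of the two reference predictive-value tables
  tab <- predictive_value_table()
  published_ppv <- rbind(
    shbn = c(.03, .27, .45), hbn = c(.03, .22, .39),
    decision_tree = c(.02, .22, .39), discriminant_analysis = c(.03, .22, .39),
    logistic_regression = c(.03, .26, .44), svm = c(.03, .22, .39),
    knn = c(.02, .21, .37), ensemble = c(.03, .28, .46))
  published_npv <- rbind(
    shbn = c(1.00, .96, .92), hbn = c(1.00, .95, .90),
    decision_tree = c(1.00, .97, .93), discriminant_analysis = c(1.00, .95, .90),
    logistic_regression = c(1.00, .96, .91), svm = c(1.00, .95, .90),
    knn = c(1.00, .96, .92), ensemble = c(1.00, .97, .93))
  for (i in seq_len(nrow(tab))) {
    m <- tab$model[i]
    expect_equal(unname(unlist(tab[i, c("ppv_1", "ppv_10", "ppv_20")])),
                 unname(published_ppv[m, ]), label = paste("PPV", m))
    expect_equal(unname(unlist(tab[i, c("npv_1", "npv_10", "npv_20")])),
                 unname(published_npv[m, ]), label = paste("NPV", m))
  }
})

test_that("PPV rises and NPV falls with prevalence; limits are 1", {
  grid <- expand.grid(se = c(.6, .73, .9), sp = c(.6, .78, .9))
  for (i in seq_len(nrow(grid))) {
    p <- seq(0.05, 0.95, by = 0.05)
    ppv <- vapply(p, function(q) {
      ppv_at_prevalence(grid$se[i], grid$sp[i], q)
    }, numeric(1))
    npv <- vapply(p, function(q) {
      npv_at_prevalence(grid$se[i], grid$sp[i], q)
    }, numeric(1))
    expect_true(all(diff(ppv) > 0))
    expect_true(all(diff(npv) < 0))
  }
  expect_equal(npv_at_prevalence(.73, .78, 1e-9), 1, tolerance = 1e-6)
  expect_equal(ppv_at_prevalence(.73, .78, 1 - 1e-9), 1, tolerance = 1e-6)
})

test_that("percent gains match the published improvement arithmetic", {
  expect_equal(round(percent_gain(.709, .754), 1), 6.3)
  expect_equal(round(percent_gain(.75, .78), 1), 4.0)
  expect_equal(round(percent_gain(.73, .78), 1), 6.8)
  expect_equal(round(percent_gain(.69, .73), 1), 5.8)
  expect_equal(round(percent_gain(.39, .45), 1), 15.4)
  expect_equal(round(percent_gain(.90, .92), 1), 2.2)
  expect_equal(round(percent_gain(.682, .754), 1), 10.6)
  expect_equal(round(percent_gain(.67, .78), 1), 16.4)
  expect_equal(round(percent_gain(.60, .78), 1), 30.0)
  expect_equal(percent_gain(0.4, 0.4), 0)
  expect_error(percent_gain(0, 0.5), "nonpositive")
})

test_that("the evaluation protocol pools folds coherently", {
  raw <- generate_cohort(cohort_profile(), seed = 41)
  rec <- smote_oversample(impute_missing(filter_incomplete(derive_indices(raw))),
                          seed = 41)
  dd <- discretize(rec, table3_scheme())
  rep_shbn <- evaluate_pipeline(dd, "shbn", seed = 41,
                                search_args = list(n_restarts = 0))
  expect_s3_class(rep_shbn, "metrics_report")
  expect_equal(rep_shbn$n_structure + rep_shbn$n_eval, 157)
  # pooled accuracy equals the record-weighted mean of fold accuracies
  expect_equal(rep_shbn$accuracy,
               sum(rep_shbn$folds$accuracy * rep_shbn$folds$n) /
                 sum(rep_shbn$folds$n), tolerance = 1e-12)
  expect_true(all(c(rep_shbn$accuracy, rep_shbn$auc, rep_shbn$sensitivity,
                    rep_shbn$specificity) >= 0))
  expect_equal(names(rep_shbn$ppv), c("1%", "10%", "20%"))
  # determinism
  rep2 <- evaluate_pipeline(dd, "shbn", seed = 41,
                            search_args = list(n_restarts = 0))
  expect_equal(rep_shbn$accuracy, rep2$accuracy)

  bg <- evaluate_pipeline(dd, "shbn", feature_mode = "background_only",
                          seed = 41)
  expect_equal(ncol(bg$structure$edges), 2)
  expect_false(any(grepl("sebt|tug|slsb", bg$structure$nodes)))
})
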
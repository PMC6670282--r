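#' Stratified k-fold assignment
#'
#' Partitions record indices into k folds while keeping every class's
#' share per fold within one record of its global share. Class remainders
#' are dealt to the currently least-loaded folds, so total fold sizes are
#' as even as possible (e.g. 157 records split 5 ways gives sizes
#' 32, 32, 31, 31, 31). Deterministic under the seed.
#'
#' @param labels class label per record (any atomic vector).
#' @param k number of folds (default 5); every class must have at least k
#'   members.
#' @param seed RNG seed for the within-class shuffles.
#' @return list of k integer index vectors partitioning
#'   \code{seq_along(labels)}.
#' @export
stratified_kfold <- function(labels, k = 5, seed = 1L) {
  classes <- sort(unique(labels))
  counts <- table(labels)
  if (any(counts < k)) {
    stop("every class must have at least k = ", k, " records (smallest has ",
         min(counts), "); use a smaller k")
  }
  set.seed(seed)
  folds <- vector("list", k)
  load <- integer(k)
  for (cl in classes) {
    idx <- sample(which(labels == cl))
    n_c <- length(idx)
    base <- n_c %/% k
    extra <- n_c %% k
    take <- rep(base, k)
    if (extra > 0) {
      recipients <- order(load, seq_len(k))[seq_len(extra)]
      take[recipients] <- take[recipients] + 1L
    }
    pos <- 1L
    for (f in seq_len(k)) {
      if (take[f] > 0) {
        folds[[f]] <- c(folds[[f]], idx[pos:(pos + take[f] - 1L)])
        pos <- pos + take[f]
      }
    }
    load <- load + take
  }
  lapply(folds, sort)
}

#' Stratified two-way split
#'
#' Seeded, label-stratified split into disjoint structure-training and
#' evaluation subsets (default 30/70).
#'
#' @param labels class label per record.
#' @param fraction share assigned to the first subset (default 0.3).
#' @param seed RNG seed.
#' @return list with integer index vectors \code{first} and \code{second}.
#' @export
stratified_split <- function(labels, fraction = 0.3, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  set.seed(seed)
  first <- integer(0)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    n_take <- round(length(idx) * fraction)
    first <- c(first, sample(idx, n_take))
  }
  first <- sort(first)
  list(first = first, second = setdiff(seq_along(labels), first))
}

#' Confusion counts at a decision threshold
#'
#' @param scores numeric positive-class scores in \[0, 1\].
#' @param labels class labels coded 1 (negative) / 2 (positive).
#' @param threshold decision threshold; scores at the threshold are called
#'   positive (ties go positive, as in [classify()]).
#' @return list of class \code{confusion_counts} with TP, FP, TN, FN.
#' @export
confusion <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(1L, 2L))) {
    stop("labels must be coded 1 (negative) / 2 (positive); found: ",
         paste(setdiff(unique(labels), 1:2), collapse = ", "))
  }
  pred_pos <- scores >= threshold
  structure(list(
    tp = sum(pred_pos & labels == 2L),
    fp = sum(pred_pos & labels == 1L),
    tn = sum(!pred_pos & labels == 1L),
    fn = sum(!pred_pos & labels == 2L)
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' @rdname classification_metrics
#' @export
accuracy <- function(counts) {
  n <- counts$tp + counts$fp + counts$tn + counts$fn
  if (n == 0) stop("accuracy undefined: no records")
  (counts$tp + counts$tn) / n
}

#' Classification metrics from confusion counts
#'
#' Sensitivity is the true-positive rate (sick subjects correctly called
#' positive), specificity the true-negative rate (healthy subjects
#' correctly called negative). A zero denominator raises an error rather
#' than returning \code{NaN}.
#'
#' @param counts a [confusion()] result.
#' @return proportion in \[0, 1\].
#' @name classification_metrics
#' @export
sensitivity <- function(counts) {
  if (counts$tp + counts$fn == 0) {
    stop("sensitivity undefined: no positive records")
  }
  counts$tp / (counts$tp + counts$fn)
}

#' @rdname classification_metrics
#' @export
specificity <- function(counts) {
  if (counts$tn + counts$fp == 0) {
    stop("specificity undefined: no negative records")
  }
  counts$tn / (counts$tn + counts$fp)
}

#' Area under the ROC curve
#'
#' Mann-Whitney rank statistic: the probability that a random positive
#' outranks a random negative, ties counted one half. Equivalent to
#' trapezoidal integration of the ROC curve.
#'
#' @param scores numeric positive-class scores.
#' @param labels class labels coded 1 (negative) / 2 (positive); both
#'   classes must be present.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 2L)
  n_neg <- sum(labels == 1L)
  if (n_pos == 0 || n_neg == 0) stop("AUC undefined: both classes required")
  r <- rank(scores)
  (sum(r[labels == 2L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Prevalence-adjusted predictive values
#'
#' Bayes' theorem applied to test characteristics: the probability of
#' disease given a positive call (PPV) or of health given a negative call
#' (NPV) when the classifier with the given sensitivity and specificity is
#' deployed in a population with the given disease prevalence,
#' \deqn{PPV = \frac{se \cdot p}{se \cdot p + (1 - sp)(1 - p)}, \qquad
#'       NPV = \frac{sp (1 - p)}{sp (1 - p) + (1 - se) p}.}
#' For fixed sensitivity and specificity PPV increases and NPV decreases
#' with prevalence.
#'
#' @param sensitivity,specificity test characteristics in (0, 1\].
#' @param prevalence assumed population disease proportion, strictly in
#'   (0, 1).
#' @return proportion in \[0, 1\].
#' @export
ppv_at_prevalence <- function(sensitivity, specificity, prevalence) {
  stopifnot(prevalence > 0, prevalence < 1,
            sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  num <- sensitivity * prevalence
  den <- num + (1 - specificity) * (1 - prevalence)
  if (den == 0) stop("PPV undefined: the model never calls positive")
  num / den
}

#' @rdname ppv_at_prevalence
#' @export
npv_at_prevalence <- function(sensitivity, specificity, prevalence) {
  stopifnot(prevalence > 0, prevalence < 1,
            sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  num <- specificity * (1 - prevalence)
  den <- num + (1 - sensitivity) * prevalence
  if (den == 0) stop("NPV undefined: the model never calls negative")
  num / den
}

#' Relative percent gain between two metric values
#'
#' \code{100 * (new - old) / old}; reports round it to one decimal.
#'
#' @param old reference value (> 0).
#' @param new comparison value.
#' @return percent gain (positive = improvement).
#' @export
percent_gain <- function(old, new) {
  if (old <= 0) stop("percent gain undefined for a nonpositive reference")
  100 * (new - old) / old
}

#' Published comparator performance
#'
#' The reference evaluation table for the original N=157 cohort:
#' accuracy, AUC, specificity and sensitivity of the semihandcrafted
#' (SHBN) and handcrafted (HBN) Bayesian networks, six standard
#' classifiers, their mean, and the background-characteristics-only
#' ablations. These are ingested constants for report rendering and
#' arithmetic cross-checks; the comparator classifiers themselves are not
#' re-implemented.
#'
#' @return data.frame with columns \code{model}, \code{accuracy},
#'   \code{auc}, \code{specificity}, \code{sensitivity}.
#' @export
reference_performance <- function() {
  data.frame(
    model = c("shbn", "hbn", "decision_tree", "discriminant_analysis",
              "logistic_regression", "svm", "knn", "ensemble", "mean",
              "shbn_background_only", "logistic_regression_background_only"),
    accuracy = c(.754, .709, .736, .709, .736, .709, .727, .773, .732,
                 .682, .709),
    auc = c(.78, .75, .77, .75, .81, .77, .78, .81, .78, .67, .74),
    specificity = c(.78, .73, .69, .73, .78, .73, .67, .78, .73, .60, .73),
    sensitivity = c(.73, .69, .78, .69, .69, .69, .78, .76, .73, .76, .69),
    stringsAsFactors = FALSE
  )
}

#' Predictive-value table from test characteristics
#'
#' Expands sensitivity/specificity rows into PPV and NPV at a set of
#' prevalences, as used for the model-comparison tables.
#'
#' @param performance data.frame with columns \code{model},
#'   \code{sensitivity}, \code{specificity} (default
#'   [reference_performance()] without the mean/ablation rows).
#' @param prevalences numeric vector of prevalences (default 1%, 10%, 20%).
#' @param digits rounding applied to the reported values (default 2, as in
#'   the comparison tables); \code{NULL} for full precision.
#' @return data.frame with one row per model and one \code{ppv_*} /
#'   \code{npv_*} column per prevalence.
#' @export
predictive_value_table <- function(performance = NULL,
                                   prevalences = c(0.01, 0.10, 0.20),
                                   digits = 2) {
  if (is.null(performance)) {
    performance <- reference_performance()
    performance <- performance[!grepl("mean|background", performance$model), ]
  }
  out <- data.frame(model = performance$model, stringsAsFactors = FALSE)
  for (p in prevalences) {
    ppv <- mapply(ppv_at_prevalence, performance$sensitivity,
                  performance$specificity, p)
    npv <- mapply(npv_at_prevalence, performance$sensitivity,
                  performance$specificity, p)
    if (!is.null(digits)) {
      ppv <- round(ppv, digits)
      npv <- round(npv, digits)
    }
    out[[sprintf("ppv_%g", 100 * p)]] <- ppv
    out[[sprintf("npv_%g", 100 * p)]] <- npv
  }
  out
}

#' Run the full evaluation protocol on a discrete dataset
#'
#' Implements the two-stage design: a stratified 30/70 split reserves 30%
#' of the records for structure training; the chosen structure (base
#' handcrafted star for \code{"hbn"}, refined by [bayesian_search()] for
#' \code{"shbn"}) is then assessed by stratified k-fold cross-validation
#' on the remaining 70%, fitting CPTs on each training fold and scoring
#' the held-out fold. Fold confusions are pooled (micro-averaged) for
#' accuracy/sensitivity/specificity and out-of-fold scores are pooled for
#' the AUC; per-fold detail is retained. PPV/NPV are reported at the given
#' prevalences. \code{feature_mode = "background_only"} drops all
#' predictor attributes before structure building (the ablation
#' quantifying what the physical-fitness tests add).
#'
#' @param data a [discrete_dataset()] with level tags and a binary disease
#'   attribute.
#' @param structure_mode \code{"shbn"} (search-refined) or \code{"hbn"}
#'   (handcrafted base).
#' @param feature_mode \code{"full"} or \code{"background_only"}.
#' @param k evaluation folds (default 5).
#' @param seed seed controlling the split, the search and the folds.
#' @param split_fraction share reserved for structure training
#'   (default 0.3).
#' @param prevalences prevalences for PPV/NPV (default 1%, 10%, 20%).
#' @param alpha CPT pseudo-count (default 1).
#' @param search_args list of extra arguments for [bayesian_search()].
#' @param pool \code{"micro"} (default; pool fold confusions) or
#'   \code{"macro"} (average fold metrics).
#' @return object of class \code{metrics_report}: accuracy, auc,
#'   sensitivity, specificity, \code{ppv}/\code{npv} named by prevalence,
#'   per-fold detail, the fitted structure and the model tag.
#' @export
evaluate_pipeline <- function(data,
                              structure_mode = c("shbn", "hbn"),
                              feature_mode = c("full", "background_only"),
                              k = 5, seed = 1L, split_fraction = 0.3,
                              prevalences = c(0.01, 0.10, 0.20),
                              alpha = 1, search_args = list(),
                              pool = c("micro", "macro")) {
  structure_mode <- match.arg(structure_mode)
  feature_mode <- match.arg(feature_mode)
  pool <- match.arg(pool)
  stopifnot(inherits(data, "discrete_dataset"))
  keep <- if (feature_mode == "background_only") {
    names(data$levels)[data$levels %in% c("background", "disease")]
  } else {
    colnames(data$data)
  }
  X <- data$data[, keep, drop = FALSE]
  states <- data$states[keep]
  lv <- data$levels[keep]
  attrs <- data.frame(name = keep, level = unname(lv),
                      n_states = unname(lengths(states)),
                      stringsAsFactors = FALSE)
  base <- build_base_structure(attrs, states = states)
  d <- disease_node(base)

  split <- stratified_split(X[, d], fraction = split_fraction, seed = seed)
  X_struct <- X[split$first, , drop = FALSE]
  X_eval <- X[split$second, , drop = FALSE]

  search <- NULL
  structure <- base
  if (structure_mode == "shbn" &&
      sum(lv == "predictor", na.rm = TRUE) >= 2) {
    search <- do.call(bayesian_search,
                      c(list(base = base, data = X_struct, seed = seed,
                             alpha = alpha), search_args))
    structure <- search$structure
  }

  folds <- stratified_kfold(X_eval[, d], k = k, seed = seed + 1L)
  fold_detail <- data.frame()
  all_scores <- numeric(nrow(X_eval))
  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    train <- X_eval[-test_idx, , drop = FALSE]
    test <- X_eval[test_idx, , drop = FALSE]
    net <- if (anyNA(train)) {
      em_fit(structure, train, em_config(alpha = alpha))
    } else {
      fit_cpts(structure, train, alpha = alpha)
    }
    scores <- if (anyNA(test)) {
      vapply(seq_len(nrow(test)), function(i) {
        ev <- test[i, setdiff(colnames(test), d)]
        classify(net, ev[!is.na(ev)])$score
      }, numeric(1))
    } else {
      disease_scores_complete(net, test)
    }
    all_scores[test_idx] <- scores
    cm <- confusion(scores, test[, d])
    fold_detail <- rbind(fold_detail, data.frame(
      fold = f, n = nrow(test), tp = cm$tp, fp = cm$fp, tn = cm$tn,
      fn = cm$fn, accuracy = accuracy(cm)))
  }
  pooled <- structure(list(tp = sum(fold_detail$tp), fp = sum(fold_detail$fp),
                           tn = sum(fold_detail$tn), fn = sum(fold_detail$fn)),
                      class = "confusion_counts")
  if (pool == "micro") {
    acc <- accuracy(pooled)
    sens <- sensitivity(pooled)
    spec <- specificity(pooled)
  } else {
    acc <- mean(fold_detail$accuracy)
    sens <- mean((fold_detail$tp) / (fold_detail$tp + fold_detail$fn))
    spec <- mean((fold_detail$tn) / (fold_detail$tn + fold_detail$fp))
  }
  auc_val <- auc(all_scores, X_eval[, d])
  ppv <- vapply(prevalences, function(p) {
    ppv_at_prevalence(sens, spec, p)
  }, numeric(1))
  npv <- vapply(prevalences, function(p) {
    npv_at_prevalence(sens, spec, p)
  }, numeric(1))
  names(ppv) <- names(npv) <- sprintf("%g%%", 100 * prevalences)
  structure(list(
    model = paste0(structure_mode,
                   if (feature_mode == "background_only") "_background_only" else ""),
    accuracy = acc, auc = auc_val, sensitivity = sens, specificity = spec,
    ppv = ppv, npv = npv, confusion = pooled, folds = fold_detail,
    scores = all_scores, labels = X_eval[, d],
    structure = structure, search = search,
    n_structure = nrow(X_struct), n_eval = nrow(X_eval), seed = seed
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Model:", x$model, sprintf("(structure n=%d, evaluation n=%d)\n",
                                 x$n_structure, x$n_eval))
  cat(sprintf("  accuracy %.3f  AUC %.2f  specificity %.2f  sensitivity %.2f\n",
              x$accuracy, x$auc, x$specificity, x$sensitivity))
  cat("  PPV:", paste(sprintf("%s %.2f", names(x$ppv), x$ppv), collapse = "  "), "\n")
  cat("  NPV:", paste(sprintf("%s %.2f", names(x$npv), x$npv), collapse = "  "), "\n")
  invisible(x)
}
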
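test_that("the base structure is the 18-edge three-level star", {
  base <- build_base_structure()
  expect_equal(nrow(base$edges), 18)
  expect_equal(sum(base$edges[, 2] == "oa"), 5)   # background -> disease
  expect_equal(sum(base$edges[, 1] == "oa"), 13)  # disease -> predictors
  expect_false(is.null(topological_order(base$parents)))

  tiny <- data.frame(name = c("b", "d", "p"),
                     level = c("background", "disease", "predictor"),
                     n_states = 2)
  star <- build_base_structure(tiny)
  expect_equal(edge_key(star$edges), c("b->d", "d->p"))

  two <- data.frame(name = c("d1", "d2"), level = "disease", n_states = 2)
  expect_error(build_base_structure(two), "exactly one")
})

test_that("the wrapper CV score behaves on degenerate structures", {
  set.seed(1)
  n <- 200
  lab <- rep(1:2, each = n / 2)
  # disease disconnected from an uninformative predictor: chance-level score
  attrs <- data.frame(name = c("d", "p"), level = c("disease", "predictor"),
                      n_states = 2)
  disc <- bayes_net(states = list(d = c("1", "2"), p = c("1", "2")),
                    levels = c(d = "disease", p = "predictor"))
  X <- cbind(d = sample(lab), p = sample(1:2, n, TRUE))
  s <- cv_accuracy_score(disc, X, seed = 1)
  expect_lt(abs(s - 0.5), 0.12)

  # deterministic predictor: perfect score
  star <- build_base_structure(attrs)
  X2 <- cbind(d = lab, p = lab)
  expect_equal(cv_accuracy_score(star, X2, seed = 1), 1.0)

  # determinism under the seed
  expect_identical(cv_accuracy_score(star, X, seed = 4),
                   cv_accuracy_score(star, X, seed = 4))
})

test_that("the fast complete-evidence scorer agrees with posterior()", {
  truth <- ground_truth_shbn()
  X <- sample_from_network(truth, 30, seed = 13)$data
  fast <- disease_scores_complete(truth, X)
  slow <- vapply(seq_len(nrow(X)), function(i) {
    ev <- X[i, setdiff(colnames(X), "oa")]
    unname(posterior(truth, ev, "oa")["positive"])
  }, numeric(1))
  expect_lt(max(abs(fast - slow)), 1e-10)
})

test_that("hill climbing respects constraints, identity and monotonicity", {
  truth <- ground_truth_shbn()
  data <- sample_from_network(truth, 400, seed = 17)
  base <- build_base_structure()

  frozen <- bayesian_search(base, data, max_iter = 0, n_restarts = 0,
                            seed = 1)
  expect_equal(edge_key(frozen$structure$edges), edge_key(base$edges))

  res <- bayesian_search(base, data, seed = 1)
  con <- structure_constraints(base)
  expect_null(check_constraints(res$structure, con))
  expect_gte(res$score, res$base_score)
  # accepted-move scores are non-decreasing within each climb
  starts <- which(res$trace$move == "start")
  bounds <- c(starts, nrow(res$trace) + 1)
  for (i in seq_along(starts)) {
    seg <- res$trace[bounds[i]:(bounds[i + 1] - 1), ]
    acc <- seg$score[seg$accepted]
    expect_true(all(diff(acc) >= -1e-12))
  }
  # only predictor-predictor edges may differ from the base
  extra <- setdiff(edge_key(res$structure$edges), edge_key(base$edges))
  if (length(extra) > 0) {
    lv <- base$levels
    for (e in strsplit(extra, "->", fixed = TRUE)) {
      expect_equal(unname(lv[e]), c("predictor", "predictor"))
    }
  }
})

test_that("incremental search scoring agrees with cv_accuracy_score", {
  # small 5-node model so every candidate structure can be re-scored
  # independently through the public scorer
  attrs <- data.frame(name = c("b", "d", "p1", "p2", "p3"),
                      level = c("background", "disease", rep("predictor", 3)),
                      n_states = 2)
  base <- build_base_structure(attrs)
  truth <- structure_with_edges(base, rbind(c("p1", "p2")))
  truth$cpts <- list(
    b = c(0.5, 0.5),
    d = array(c(0.7, 0.3, 0.4, 0.6), c(2, 2)),
    p1 = array(c(0.7, 0.3, 0.3, 0.7), c(2, 2)),
    p2 = array(c(0.78, 0.22, 0.22, 0.78, 0.22, 0.78, 0.78, 0.22),
               c(2, 2, 2)),
    p3 = array(c(0.6, 0.4, 0.45, 0.55), c(2, 2)))
  expect_true(validate_network(truth)$ok)
  X <- sample_from_network(truth, 300, seed = 29)$data

  res <- bayesian_search(base, X, max_iter = 1, n_restarts = 0, seed = 3)
  cand <- res$trace[!grepl("^(start|accept)", res$trace$move), ]
  # every evaluated candidate's cached score equals the public scorer's
  for (i in seq_len(nrow(cand))) {
    mv <- strsplit(cand$move[i], " ", fixed = TRUE)[[1]]
    extra <- switch(mv[1],
                    add = rbind(c(mv[2], mv[4])),
                    delete = matrix(character(0), ncol = 2),
                    reverse = rbind(c(mv[4], mv[2])))
    s_pub <- cv_accuracy_score(structure_with_edges(base, extra), X,
                               seed = 3)
    expect_equal(cand$score[i], s_pub, tolerance = 1e-12)
  }
  # the accepted move (if any) is the candidate argmax
  accepted <- res$trace$move[res$trace$accepted][-1]
  if (length(accepted) > 0) {
    expect_equal(sub("^accept ", "", accepted[1]),
                 cand$move[which.max(cand$score)])
  }
})

test_that("injected SEBT-SEBT edges are recovered from sampled cohorts", {
  hits <- vapply(1:3, function(s) {
    structure_recovery_run(n = 2000, seed = s)$recovered
  }, numeric(1))
  expect_gte(mean(hits), 2)
})

test_that("a constraint-violating base is rejected before searching", {
  base <- build_base_structure()
  con <- structure_constraints(base)
  # a background -> predictor edge is outside the mutable class
  bad <- structure_with_edges(base, rbind(c("gender", "tug")))
  X <- sample_from_network(ground_truth_shbn(), 100, seed = 1)
  expect_error(bayesian_search(bad, X, constraints = con), "constraints")
})
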
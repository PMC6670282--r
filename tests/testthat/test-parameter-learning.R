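test_that("expected counts equal contingency counts on complete data", {
  net <- rand_net(4, seed = 1, max_parents = 2, cards = 2)
  X <- sample_from_network(net, 300, seed = 2)$data
  ec <- expected_counts(net, X)
  hc <- hard_counts(net, X)
  for (v in net$nodes) {
    expect_equal(as.numeric(ec$counts[[v]]), as.numeric(hc[[v]]),
                 tolerance = 1e-12)
  }
})

test_that("a missing cell splits its count by the exact posterior", {
  # single binary node at P = 0.5: a missing cell adds 0.5 to each state
  net <- bayes_net(states = list(A = c("1", "2")), cpts = list(A = c(0.5, 0.5)))
  X <- matrix(c(1L, 2L, NA, NA), ncol = 1, dimnames = list(NULL, "A"))
  ec <- expected_counts(net, X)
  expect_equal(as.numeric(ec$counts$A), c(2, 2))

  # two-node net with one hidden parent cell: hand-computed weighting
  net2 <- bayes_net(
    states = list(A = c("1", "2"), B = c("1", "2")),
    edges = matrix(c("A", "B"), ncol = 2),
    cpts = list(A = c(0.6, 0.4), B = array(c(0.9, 0.1, 0.2, 0.8), c(2, 2))))
  X2 <- matrix(c(NA, 2L), ncol = 2, dimnames = list(NULL, c("A", "B")))
  ec2 <- expected_counts(net2, X2)
  # P(A | B = 2) = (0.6*0.1, 0.4*0.8) / 0.38
  pa <- c(0.06, 0.32) / 0.38
  expect_equal(as.numeric(ec2$counts$A), pa, tolerance = 1e-12)
  expect_equal(as.numeric(ec2$counts$B), c(0, pa[1], 0, pa[2]),
               tolerance = 1e-12)
  expect_equal(ec2$loglik, log(0.38), tolerance = 1e-12)

  # observed configuration impossible under the current CPTs
  net3 <- net2
  net3$cpts$B <- array(c(1, 0, 1, 0), c(2, 2))
  expect_error(expected_counts(net3, X2), "impossible")
})

test_that("EM on complete data equals the smoothed frequency estimator", {
  net <- rand_net(5, seed = 3, max_parents = 2, cards = 2)
  X <- sample_from_network(net, 400, seed = 4)$data
  for (a in c(0, 1)) {
    fitted <- em_fit(net, X, em_config(alpha = a))
    direct <- fit_cpts(net, X, alpha = a)
    expect_equal(attr(fitted, "iterations"), 1L)
    for (v in net$nodes) {
      expect_equal(as.numeric(fitted$cpts[[v]]),
                   as.numeric(direct$cpts[[v]]), tolerance = 1e-12)
    }
  }
  # alpha = 0 gives exact relative frequencies
  mle <- em_fit(net, X, em_config(alpha = 0))
  root <- net$nodes[vapply(net$parents, length, integer(1)) == 0][1]
  expect_equal(as.numeric(mle$cpts[[root]]),
               as.numeric(table(factor(X[, root], levels = 1:2)) / nrow(X)))
})

test_that("empty data with a unit pseudo-count yields uniform CPTs", {
  net <- rand_net(3, seed = 5, cards = 2)
  X <- matrix(integer(0), nrow = 0, ncol = 3,
              dimnames = list(NULL, net$nodes))
  fitted <- em_fit(net, X, em_config(alpha = 1))
  for (v in net$nodes) {
    expect_true(all(abs(fitted$cpts[[v]] - 0.5) < 1e-12))
  }
})

test_that("observed-data log-likelihood is monotone under unsmoothed EM", {
  for (seed in 1:20) {
    net <- rand_net(sample(3:4, 1), seed = seed, cards = 2, min_p = 0.2)
    X <- sample_from_network(net, 120, seed = seed + 100)$data
    X <- dd_matrix(inject_missingness(as.data.frame(X),
                                      stats::setNames(rep(0.25, ncol(X)),
                                                      colnames(X)),
                                      seed = seed, label_col = ""))
    fitted <- em_fit(net, X, em_config(alpha = 0, tol = 1e-6))
    trace <- attr(fitted, "loglik_trace")
    expect_gte(length(trace), 2)
    expect_true(all(diff(trace) >= -1e-9))
  }
})

test_that("EM recovers generating CPTs from data with 10% MCAR missingness", {
  net <- rand_net(4, seed = 7, max_parents = 2, cards = 2, min_p = 0.15)
  X <- sample_from_network(net, 5000, seed = 8)$data
  X <- dd_matrix(inject_missingness(as.data.frame(X),
                                    stats::setNames(rep(0.1, 4), colnames(X)),
                                    seed = 9, label_col = ""))
  fitted <- em_fit(net, X, em_config(alpha = 0.5, tol = 1e-6))
  for (v in net$nodes) {
    est <- matrix(as.numeric(fitted$cpts[[v]]), nrow = 2)
    truth <- matrix(as.numeric(net$cpts[[v]]), nrow = 2)
    tv <- apply(abs(est - truth), 2, sum) / 2
    expect_lt(max(tv), 0.05)
  }
})

test_that("recovered CPTs improve with sample size", {
  net <- rand_net(3, seed = 11, max_parents = 1, cards = 2, min_p = 0.2)
  tv_at <- function(n) {
    errs <- vapply(1:5, function(s) {
      X <- sample_from_network(net, n, seed = s)$data
      X <- dd_matrix(inject_missingness(as.data.frame(X),
                                        stats::setNames(rep(0.1, 3),
                                                        colnames(X)),
                                        seed = s + 50, label_col = ""))
      fitted <- em_fit(net, X, em_config(alpha = 0.5, tol = 1e-6))
      max(vapply(net$nodes, function(v) {
        est <- matrix(as.numeric(fitted$cpts[[v]]), nrow = 2)
        truth <- matrix(as.numeric(net$cpts[[v]]), nrow = 2)
        max(apply(abs(est - truth), 2, sum) / 2)
      }, numeric(1)))
    }, numeric(1))
    mean(errs)
  }
  errs <- vapply(c(100, 1000, 8000), tv_at, numeric(1))
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.05)
})
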
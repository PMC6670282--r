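# Random networks and small fixtures shared across test files.

# Random DAG over n_nodes with CPT entries bounded away from zero.
rand_net <- function(n_nodes, seed, max_parents = 2, cards = 2:3,
                     min_p = 0.05) {
  set.seed(seed)
  nodes <- paste0("n", seq_len(n_nodes))
  card <- if (length(cards) == 1) rep(cards, n_nodes) else {
    sample(cards, n_nodes, replace = TRUE)
  }
  states <- stats::setNames(lapply(card, function(k) as.character(seq_len(k))),
                            nodes)
  edges <- NULL
  for (i in seq_len(n_nodes)[-1]) {
    k <- sample(0:min(max_parents, i - 1), 1)
    if (k > 0) {
      for (p in sample(nodes[seq_len(i - 1)], k)) {
        edges <- rbind(edges, c(p, nodes[i]))
      }
    }
  }
  net <- bayes_net(states, edges)
  net$cpts <- lapply(nodes, function(v) {
    dims <- c(length(states[[v]]),
              unname(lengths(states[net$parents[[v]]])))
    m <- matrix(stats::runif(prod(dims), min_p, 1), nrow = dims[1])
    array(sweep(m, 2, colSums(m), "/"), dim = dims)
  })
  names(net$cpts) <- nodes
  net
}

# Disease -> test net used for hand-checked Bayes arithmetic.
disease_testnet <- function(prior = 0.5) {
  bayes_net(
    states = list(D = c("negative", "positive"), T = c("negative", "positive")),
    edges = matrix(c("D", "T"), ncol = 2),
    cpts = list(D = c(1 - prior, prior),
                T = array(c(0.78, 0.22, 0.27, 0.73), dim = c(2, 2))),
    levels = c(D = "disease", T = "predictor")
  )
}

# Random evidence on a subset of nodes (never the query).
rand_evidence <- function(net, query, p_obs = 0.5) {
  ev <- integer(0)
  for (v in setdiff(net$nodes, query)) {
    if (stats::runif(1) < p_obs) {
      ev[v] <- sample(length(net$states[[v]]), 1)
    }
  }
  ev
}

# Complete synthetic analysis table ready for discretization.
make_analysis_records <- function(n = 131, seed = 1) {
  raw <- generate_cohort(cohort_profile(n_subjects = n), seed = seed)
  imputed <- impute_missing(filter_incomplete(derive_indices(raw)))
  imputed
}
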
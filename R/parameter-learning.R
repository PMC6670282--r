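#' EM configuration
#'
#' @param tol convergence tolerance on the change in observed-data
#'   log-likelihood between iterations (default \code{1e-4}).
#' @param max_iter maximum EM iterations (default 200).
#' @param alpha Dirichlet pseudo-count added to every CPT cell (Laplace
#'   smoothing, default 1). At cohort-scale sample sizes many parent
#'   configurations are unobserved and unsmoothed estimates produce zeros
#'   that poison inference.
#' @param init \code{"uniform"} (deterministic, default) or \code{"random"}.
#' @param seed RNG seed for random initialization.
#' @return list of class \code{em_config}.
#' @export
em_config <- function(tol = 1e-4, max_iter = 200, alpha = 1,
                      init = c("uniform", "random"), seed = 1L) {
  stopifnot(tol > 0, max_iter >= 1, alpha >= 0)
  structure(list(tol = tol, max_iter = max_iter, alpha = alpha,
                 init = match.arg(init), seed = as.integer(seed)),
            class = "em_config")
}

cpt_dims <- function(net, v) {
  c(node_card(net, v), unname(lengths(net$states[net$parents[[v]]])))
}

# Normalize count arrays (plus pseudo-counts) into CPTs.
counts_to_cpts <- function(net, counts, alpha) {
  cpts <- vector("list", length(net$nodes))
  names(cpts) <- net$nodes
  for (v in net$nodes) {
    dims <- cpt_dims(net, v)
    m <- matrix(as.numeric(counts[[v]]) + alpha, nrow = dims[1])
    tot <- colSums(m)
    if (any(tot <= 0)) {
      stop("node '", v, "': zero total count for a parent configuration; ",
           "increase the pseudo-count")
    }
    m <- sweep(m, 2, tot, "/")
    cpts[[v]] <- array(m, dim = dims)
  }
  cpts
}

# Hard counts from complete data (vectorized linear indexing per family).
hard_counts <- function(net, X) {
  counts <- vector("list", length(net$nodes))
  names(counts) <- net$nodes
  for (v in net$nodes) {
    fam <- c(v, net$parents[[v]])
    dims <- cpt_dims(net, v)
    lin <- X[, fam[1]] - 1L
    mult <- dims[1]
    for (i in seq_along(net$parents[[v]])) {
      lin <- lin + (X[, fam[i + 1]] - 1L) * mult
      mult <- mult * dims[i + 1]
    }
    counts[[v]] <- array(tabulate(lin + 1L, nbins = prod(dims)), dim = dims)
  }
  counts
}

#' Closed-form CPT estimation from complete data
#'
#' Relative frequencies with Dirichlet smoothing; the fixed point that
#' [em_fit()] reduces to when no cell is missing.
#'
#' @param structure a [bayes_net()] (CPTs ignored if present).
#' @param data a [discrete_dataset()] or complete integer matrix whose
#'   columns cover the network's nodes.
#' @param alpha pseudo-count per CPT cell (default 1).
#' @return the network with fitted CPTs.
#' @export
fit_cpts <- function(structure, data, alpha = 1) {
  X <- dd_matrix(data)[, structure$nodes, drop = FALSE]
  if (anyNA(X)) stop("data contains missing cells; use em_fit()")
  structure$cpts <- counts_to_cpts(structure, hard_counts(structure, X), alpha)
  structure
}

#' Expected sufficient statistics under a current network (E-step)
#'
#' For every node/parent configuration, sums over records the exact
#' posterior probability of that family configuration given the record's
#' observed cells. Complete records contribute hard counts. Records are
#' grouped by their unique (observed values, missingness pattern) before
#' the exact computation, which enumerates completions of the missing
#' cells and weights them by their joint probability.
#'
#' @param net a parameterized [bayes_net()].
#' @param data a [discrete_dataset()] or integer matrix with \code{NA}s.
#' @return list with \code{counts} (named list of arrays) and
#'   \code{loglik}, the observed-data log-likelihood of \code{data} under
#'   \code{net}.
#' @export
expected_counts <- function(net, data) {
  X <- dd_matrix(data)[, net$nodes, drop = FALSE]
  counts <- lapply(net$nodes, function(v) array(0, dim = cpt_dims(net, v)))
  names(counts) <- net$nodes
  loglik <- 0

  key <- apply(X, 1, paste, collapse = ",")
  first <- !duplicated(key)
  weight <- as.numeric(table(key)[key[first]])
  U <- X[first, , drop = FALSE]

  complete <- !apply(U, 1, anyNA)
  if (any(complete)) {
    Xc <- U[complete, , drop = FALSE]
    wc <- weight[complete]
    # weighted hard counts + likelihood
    for (v in net$nodes) {
      fam <- c(v, net$parents[[v]])
      dims <- cpt_dims(net, v)
      lin <- Xc[, fam[1]] - 1L
      mult <- dims[1]
      for (i in seq_along(net$parents[[v]])) {
        lin <- lin + (Xc[, fam[i + 1]] - 1L) * mult
        mult <- mult * dims[i + 1]
      }
      cnt <- vapply(split(wc, lin + 1L), sum, numeric(1))
      idx <- as.integer(names(cnt))
      counts[[v]][idx] <- counts[[v]][idx] + cnt
      p <- as.numeric(net$cpts[[v]])[lin + 1L]
      if (any(p <= 0)) {
        stop("record with impossible observed combination under current CPTs ",
             "(node '", v, "')")
      }
      loglik <- loglik + sum(wc * log(p))
    }
  }

  for (r in which(!complete)) {
    obs <- U[r, ]
    miss <- names(obs)[is.na(obs)]
    grid <- as.matrix(expand.grid(lapply(net$states[miss], seq_along)))
    w <- numeric(nrow(grid))
    full <- obs
    for (g in seq_len(nrow(grid))) {
      full[miss] <- grid[g, ]
      w[g] <- joint_probability(net, full)
    }
    z <- sum(w)
    if (z <= 0) {
      stop("record with impossible observed combination under current CPTs ",
           "(record pattern: ", paste(obs, collapse = ","), ")")
    }
    loglik <- loglik + weight[r] * log(z)
    w <- w / z * weight[r]
    for (g in seq_len(nrow(grid))) {
      full[miss] <- grid[g, ]
      for (v in net$nodes) {
        fam <- c(v, net$parents[[v]])
        dims <- cpt_dims(net, v)
        lin <- full[fam[1]] - 1L
        mult <- dims[1]
        for (i in seq_along(net$parents[[v]])) {
          lin <- lin + (full[fam[i + 1]] - 1L) * mult
          mult <- mult * dims[i + 1]
        }
        counts[[v]][lin + 1L] <- counts[[v]][lin + 1L] + w[g]
      }
    }
  }
  list(counts = counts, loglik = loglik)
}

#' Fit CPTs by expectation-maximization
#'
#' Alternates [expected_counts()] (E) with smoothed re-normalization (M)
#' until the observed-data log-likelihood improves by less than
#' \code{config$tol} or \code{config$max_iter} is reached. With complete
#' data this reduces in one step to the smoothed frequency estimator of
#' [fit_cpts()]. With \code{alpha = 0} the observed-data log-likelihood
#' trace is non-decreasing (the classical EM guarantee); with smoothing the
#' maximized objective is the posterior density, and the trace reported is
#' still the observed-data log-likelihood.
#'
#' @param structure a [bayes_net()] structure (CPTs ignored).
#' @param data a [discrete_dataset()] or integer matrix with \code{NA}s;
#'   every attribute must have at least one observed value.
#' @param config an [em_config()].
#' @return the fitted network, with attributes \code{loglik_trace}
#'   (observed-data log-likelihood after each E-step) and \code{iterations}.
#' @export
em_fit <- function(structure, data, config = em_config()) {
  X <- dd_matrix(data)[, structure$nodes, drop = FALSE]
  all_missing <- colnames(X)[colSums(!is.na(X)) == 0 & nrow(X) > 0]
  if (length(all_missing) > 0) {
    stop("attribute(s) with no observed values: ",
         paste(all_missing, collapse = ", "))
  }
  net <- structure
  if (nrow(X) == 0) {
    if (config$alpha <= 0) stop("empty data requires a positive pseudo-count")
    zero <- lapply(net$nodes, function(v) array(0, dim = cpt_dims(net, v)))
    names(zero) <- net$nodes
    net$cpts <- counts_to_cpts(net, zero, config$alpha)
    attr(net, "loglik_trace") <- numeric(0)
    attr(net, "iterations") <- 0L
    return(net)
  }
  if (!anyNA(X)) {
    net <- fit_cpts(net, X, alpha = config$alpha)
    ll <- expected_counts(net, X)$loglik
    attr(net, "loglik_trace") <- ll
    attr(net, "iterations") <- 1L
    return(net)
  }
  # initialization
  init_counts <- lapply(net$nodes, function(v) array(0, dim = cpt_dims(net, v)))
  names(init_counts) <- net$nodes
  if (config$init == "random") {
    set.seed(config$seed)
    init_counts <- lapply(init_counts, function(a) {
      array(stats::runif(length(a)), dim = dim(a))
    })
    net$cpts <- counts_to_cpts(net, init_counts, alpha = 0)
  } else {
    net$cpts <- counts_to_cpts(net, init_counts, alpha = 1)
  }
  trace <- numeric(0)
  for (it in seq_len(config$max_iter)) {
    es <- expected_counts(net, X)
    if (!is.finite(es$loglik)) {
      stop("non-finite log-likelihood; increase the pseudo-count")
    }
    trace <- c(trace, es$loglik)
    net$cpts <- counts_to_cpts(net, es$counts, config$alpha)
    if (it > 1 && abs(trace[it] - trace[it - 1]) < config$tol) break
  }
  attr(net, "loglik_trace") <- trace
  attr(net, "iterations") <- length(trace)
  net
}
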
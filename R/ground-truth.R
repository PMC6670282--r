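#' Ancestral sampling from a Bayesian network
#'
#' Samples records in topological order, each node drawn from its CPT row
#' given the already-sampled parents (vectorized over records).
#' Deterministic under the seed; the empirical joint converges to the
#' network's exact joint as n grows.
#'
#' @param net a parameterized [bayes_net()].
#' @param n number of records.
#' @param seed RNG seed.
#' @return a [discrete_dataset()] with the network's states and level
#'   tags.
#' @export
sample_from_network <- function(net, n, seed = 1L) {
  if (is.null(net$cpts)) stop("network has no CPTs")
  ord <- topological_order(net$parents)
  if (is.null(ord)) stop("cannot sample: structure is cyclic")
  diag <- validate_network(net)
  if (!diag$ok) stop("invalid network: ", paste(diag$problems, collapse = "; "))
  set.seed(seed)
  X <- matrix(NA_integer_, n, length(net$nodes),
              dimnames = list(NULL, net$nodes))
  for (v in ord) {
    pa <- net$parents[[v]]
    dims <- cpt_dims(net, v)
    cpt <- matrix(as.numeric(net$cpts[[v]]), nrow = dims[1])
    cfg <- rep(1L, n)
    mult <- 1L
    for (i in seq_along(pa)) {
      cfg <- cfg + (X[, pa[i]] - 1L) * mult
      mult <- mult * dims[i + 1]
    }
    cum <- matrix(apply(cpt, 2, cumsum), nrow = dims[1])
    u <- stats::runif(n)
    X[, v] <- rowSums(u > t(cum[, cfg, drop = FALSE])) + 1L
  }
  lv <- net$levels[!is.na(net$levels)]
  discrete_dataset(X, states = net$states,
                   levels = if (length(lv) > 0) lv else NULL)
}

#' Ground-truth network for recovery experiments
#'
#' The handcrafted base structure plus a known set of injected
#' predictor-predictor edges (by default three SEBT-SEBT edges), with
#' CPTs chosen so the injected edges matter for disease classification:
#' each child of an injected edge is, given OA status alone, uninformative
#' (its marginal is identical in both classes), but strongly informative
#' once its SEBT parent is modeled -- the disease effect flips direction
#' with the parent's state. Sampling cohorts from this network and
#' checking that [bayesian_search()] rediscovers the injected edges is
#' the package's structure-recovery harness.
#'
#' @param injected two-column matrix of injected edges; default
#'   anterior->anterolateral, lateral->posterolateral,
#'   posterior->posteromedial.
#' @param disease_effect P(high | OA positive) for ordinary predictors
#'   (default 0.70, with 0.30 for negatives).
#' @param interaction_effect P(high | parent and OA agree) for injected
#'   children (default 0.78).
#' @return a parameterized [bayes_net()] with attribute
#'   \code{"injected_edges"}.
#' @export
ground_truth_shbn <- function(injected = NULL, disease_effect = 0.70,
                              interaction_effect = 0.78) {
  if (is.null(injected)) {
    injected <- cbind(paste0("sebt_", c("anterior", "lateral", "posterior")),
                      paste0("sebt_", c("anterolateral", "posterolateral",
                                        "posteromedial")))
  }
  base <- build_base_structure()
  net <- structure_with_edges(base, injected)
  d <- disease_node(net)
  cpts <- list()
  cpts$gender <- c(0.344, 0.656)
  cpts$age <- c(0.55, 0.45)
  cpts$bmi <- c(0.50, 0.50)
  cpts$whr <- c(0.55, 0.45)
  cpts$education <- c(0.30, 0.38, 0.32)
  # disease given the 5 backgrounds, additive on the log-odds scale
  bg <- net$parents[[d]]
  grid <- expand.grid(lapply(net$states[bg], seq_along))
  beta <- c(gender = 0.3, age = 0.5, bmi = 0.6, whr = 0.5, education = -0.2)
  logit <- -0.45 +
    rowSums(mapply(function(v) beta[[v]] * (grid[[v]] - 1), bg))
  p_pos <- 1 / (1 + exp(-logit))
  cpts[[d]] <- array(rbind(1 - p_pos, p_pos),
                     dim = c(2, unname(lengths(net$states[bg]))))
  children <- injected[, 2]
  for (v in names(net$levels)[net$levels == "predictor"]) {
    if (v %in% children) {
      u_cfg <- expand.grid(oa = 1:2, parent = 1:2)
      p_hi <- ifelse(u_cfg$oa == u_cfg$parent, interaction_effect,
                     1 - interaction_effect)
      cpts[[v]] <- array(rbind(1 - p_hi, p_hi), dim = c(2, 2, 2))
    } else {
      p_hi <- c(1 - disease_effect, disease_effect)
      cpts[[v]] <- array(rbind(1 - p_hi, p_hi), dim = c(2, 2))
    }
  }
  net$cpts <- cpts[net$nodes]
  diag <- validate_network(net)
  stopifnot(diag$ok)
  attr(net, "injected_edges") <- injected
  net
}

#' Structure-recovery experiment against a known generator
#'
#' Samples a cohort from [ground_truth_shbn()], runs [bayesian_search()]
#' from the base structure, and counts how many injected edges are
#' recovered in the skeleton (direction ignored).
#'
#' @param n cohort size (default 2000).
#' @param seed seed for sampling and search.
#' @param truth ground-truth network (default [ground_truth_shbn()]).
#' @param ... passed to [bayesian_search()].
#' @return list with \code{recovered} (count), \code{n_injected},
#'   \code{structure} and the search result.
#' @export
structure_recovery_run <- function(n = 2000, seed = 1L,
                                   truth = ground_truth_shbn(), ...) {
  data <- sample_from_network(truth, n = n, seed = seed)
  base <- build_base_structure()
  res <- bayesian_search(base, data, seed = seed, ...)
  found <- edge_key(res$structure$edges)
  injected <- attr(truth, "injected_edges")
  hit <- vapply(seq_len(nrow(injected)), function(i) {
    paste0(injected[i, 1], "->", injected[i, 2]) %in% found ||
      paste0(injected[i, 2], "->", injected[i, 1]) %in% found
  }, logical(1))
  list(recovered = sum(hit), n_injected = nrow(injected),
       structure = res$structure, search = res)
}
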
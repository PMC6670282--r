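#' Build the handcrafted three-level base structure
#'
#' Every background node points at the disease node and the disease node
#' points at every predictor: with 5 background and 13 predictor
#' attributes this is the 18-edge star that domain knowledge fixes before
#' any search. Acyclic by construction.
#'
#' @param attributes data.frame with columns \code{name}, \code{level}
#'   (exactly one \code{"disease"}) and \code{n_states}, as from
#'   [oa_attributes()].
#' @param states optional named list of state labels (defaults to
#'   \code{1..n_states}, with clinical labels for the canonical set).
#' @return an unparameterized [bayes_net()] structure with level tags.
#' @export
build_base_structure <- function(attributes = oa_attributes(), states = NULL) {
  stopifnot(all(c("name", "level", "n_states") %in% names(attributes)))
  if (!all(attributes$level %in% c("background", "disease", "predictor"))) {
    stop("every attribute needs a level tag in {background, disease, predictor}")
  }
  d <- attributes$name[attributes$level == "disease"]
  if (length(d) != 1) {
    stop("exactly one attribute must be tagged 'disease' (found ",
         length(d), ")")
  }
  if (is.null(states)) {
    states <- if (identical(sort(attributes$name), sort(oa_attributes()$name))) {
      oa_state_labels(attributes)
    } else {
      stats::setNames(lapply(attributes$n_states, function(k) {
        as.character(seq_len(k))
      }), attributes$name)
    }
  }
  bg <- attributes$name[attributes$level == "background"]
  pred <- attributes$name[attributes$level == "predictor"]
  edges <- rbind(
    if (length(bg) > 0) cbind(bg, d),
    if (length(pred) > 0) cbind(d, pred)
  )
  bayes_net(states = states[attributes$name], edges = edges,
            levels = stats::setNames(attributes$level, attributes$name))
}

#' Constraints for the structure search
#'
#' The search never touches the required base edges; by default only
#' predictor-predictor edges may be added, deleted or reversed (the edge
#' class where hidden correlations between fitness tests, notably the
#' SEBT directions, are expected), with a parent-count cap guarding CPT
#' size at cohort-scale sample sizes.
#'
#' @param base the base [bayes_net()] structure (its edges become required).
#' @param max_parents maximum number of parents per node (default 4).
#' @param mutable \code{"predictor-predictor"} (default) or \code{"all"}
#'   (any non-required edge not entering a background node or leaving the
#'   disease node toward a background node).
#' @return list of class \code{structure_constraints}.
#' @export
structure_constraints <- function(base, max_parents = 4,
                                  mutable = c("predictor-predictor", "all")) {
  mutable <- match.arg(mutable)
  # required edges are exempt from the cap: each node may keep its base
  # parents even where (as for the disease node) they already exceed it
  base_parents <- vapply(base$parents, length, integer(1))
  cap <- stats::setNames(pmax(as.integer(max_parents), base_parents),
                         names(base_parents))
  structure(list(required = base$edges, levels = base$levels,
                 max_parents = cap, mutable = mutable),
            class = "structure_constraints")
}

edge_key <- function(edges) {
  if (NROW(edges) == 0) return(character(0))
  sort(paste(edges[, 1], edges[, 2], sep = "->"))
}

# Is (u, v) an edge the search may modify?
edge_mutable <- function(constraints, u, v) {
  req <- constraints$required
  if (NROW(req) > 0 &&
      any((req[, 1] == u & req[, 2] == v) | (req[, 1] == v & req[, 2] == u))) {
    return(FALSE)
  }
  lu <- constraints$levels[[u]]
  lv <- constraints$levels[[v]]
  if (constraints$mutable == "predictor-predictor") {
    identical(lu, "predictor") && identical(lv, "predictor")
  } else {
    # never into background, never predictor -> disease
    !identical(lv, "background") &&
      !(identical(lu, "predictor") && identical(lv, "disease"))
  }
}

structure_with_edges <- function(base, extra_edges) {
  edges <- rbind(base$edges, extra_edges)
  bayes_net(states = base$states, edges = edges, levels = base$levels)
}

check_constraints <- function(structure, constraints) {
  key <- edge_key(structure$edges)
  req <- edge_key(constraints$required)
  if (!all(req %in% key)) return("missing required base edge(s)")
  n_par <- vapply(structure$parents, length, integer(1))
  if (any(n_par > constraints$max_parents[names(n_par)])) {
    return("parent-count cap exceeded")
  }
  extra <- setdiff(key, req)
  for (e in extra) {
    uv <- strsplit(e, "->", fixed = TRUE)[[1]]
    if (!edge_mutable(constraints, uv[1], uv[2])) {
      return(paste0("edge outside the mutable class: ", e))
    }
  }
  if (is.null(topological_order(structure$parents))) return("cyclic structure")
  NULL
}

# ---- wrapper score -------------------------------------------------------

binary_disease_node <- function(net) {
  d <- disease_node(net)
  if (node_card(net, d) != 2) stop("wrapper scoring requires a binary disease node")
  d
}

# Per-node log-CPT contribution to log P(x_{-d}, d = s) for both disease
# states, over the complete rows of X. Returns an n x 2 matrix.
node_loglik_contrib <- function(net, v, X, d) {
  fam <- c(v, net$parents[[v]])
  dims <- cpt_dims(net, v)
  logp <- log(as.numeric(net$cpts[[v]]))
  out <- matrix(0, nrow(X), 2)
  for (s in 1:2) {
    lin <- (if (fam[1] == d) rep.int(s, nrow(X)) else X[, fam[1]]) - 1L
    mult <- dims[1]
    for (i in seq_along(net$parents[[v]])) {
      pv <- fam[i + 1]
      lin <- lin + ((if (pv == d) rep.int(s, nrow(X)) else X[, pv]) - 1L) * mult
      mult <- mult * dims[i + 1]
    }
    out[, s] <- logp[lin + 1L]
    if (!(d %in% fam)) {
      out[, 2] <- out[, 1]
      break
    }
  }
  out
}

# Posterior positive-class scores for complete evidence rows (fast path;
# equals posterior() with all non-disease attributes as evidence).
disease_scores_complete <- function(net, X) {
  d <- binary_disease_node(net)
  total <- matrix(0, nrow(X), 2)
  for (v in net$nodes) total <- total + node_loglik_contrib(net, v, X, d)
  1 / (1 + exp(total[, 1] - total[, 2]))
}

fold_accuracy <- function(scores, labels, threshold = 0.5) {
  pred <- ifelse(scores >= threshold, 2L, 1L)
  mean(pred == labels)
}

#' Cross-validated classification accuracy of a structure
#'
#' The wrapper score used by the structure search: mean accuracy of the
#' disease classifier over k stratified folds, with CPTs re-fit on each
#' training fold (closed form when the fold is complete, EM otherwise)
#' and every non-disease attribute supplied as evidence.
#'
#' @param structure an unparameterized [bayes_net()] with a binary disease
#'   node.
#' @param data a [discrete_dataset()] or integer matrix covering the
#'   structure's nodes.
#' @param k number of folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @param alpha CPT pseudo-count used when fitting folds (default 1).
#' @return mean fold accuracy in \[0, 1\].
#' @export
cv_accuracy_score <- function(structure, data, k = 5, seed = 1L, alpha = 1) {
  X <- dd_matrix(data)[, structure$nodes, drop = FALSE]
  d <- binary_disease_node(structure)
  folds <- stratified_kfold(X[, d], k = k, seed = seed)
  mean(vapply(folds, function(test_idx) {
    train <- X[-test_idx, , drop = FALSE]
    test <- X[test_idx, , drop = FALSE]
    net <- if (anyNA(train)) {
      em_fit(structure, train, em_config(alpha = alpha))
    } else {
      fit_cpts(structure, train, alpha = alpha)
    }
    if (anyNA(test)) {
      scores <- vapply(seq_len(nrow(test)), function(i) {
        ev <- test[i, setdiff(colnames(test), d)]
        ev <- ev[!is.na(ev)]
        classify(net, ev)$score
      }, numeric(1))
    } else {
      scores <- disease_scores_complete(net, test)
    }
    fold_accuracy(scores, test[, d])
  }, numeric(1)))
}

# ---- hill climbing with incremental fold cache ---------------------------

# Fit one node's CPT on the training rows, given an explicit parent set.
fit_node_cpt <- function(states, v, pa, train, alpha) {
  dims <- c(length(states[[v]]), unname(lengths(states[pa])))
  lin <- train[, v] - 1L
  mult <- dims[1]
  for (i in seq_along(pa)) {
    lin <- lin + (train[, pa[i]] - 1L) * mult
    mult <- mult * dims[i + 1]
  }
  cnt <- tabulate(lin + 1L, nbins = prod(dims))
  m <- matrix(cnt + alpha, nrow = dims[1])
  array(sweep(m, 2, colSums(m), "/"), dim = dims)
}

contrib_for <- function(states, v, pa, cpt, X, d) {
  fam <- c(v, pa)
  dims <- c(length(states[[v]]), unname(lengths(states[pa])))
  logp <- log(as.numeric(cpt))
  out <- matrix(0, nrow(X), 2)
  for (s in 1:2) {
    lin <- (if (fam[1] == d) rep.int(s, nrow(X)) else X[, fam[1]]) - 1L
    mult <- dims[1]
    for (i in seq_along(pa)) {
      pv <- pa[i]
      lin <- lin + ((if (pv == d) rep.int(s, nrow(X)) else X[, pv]) - 1L) * mult
      mult <- mult * dims[i + 1]
    }
    out[, s] <- logp[lin + 1L]
    if (!(d %in% fam)) {
      out[, 2] <- out[, 1]
      break
    }
  }
  out
}

# Build the per-fold score cache for a parent map.
make_fold_cache <- function(states, parents, d, X, folds, alpha) {
  lapply(folds, function(test_idx) {
    train <- X[-test_idx, , drop = FALSE]
    test <- X[test_idx, , drop = FALSE]
    contribs <- lapply(names(parents), function(v) {
      cpt <- fit_node_cpt(states, v, parents[[v]], train, alpha)
      contrib_for(states, v, parents[[v]], cpt, test, d)
    })
    names(contribs) <- names(parents)
    total <- Reduce(`+`, contribs)
    list(train = train, test = test, labels = test[, d],
         contribs = contribs, total = total)
  })
}

cache_score <- function(cache) {
  mean(vapply(cache, function(f) {
    scores <- 1 / (1 + exp(f$total[, 1] - f$total[, 2]))
    fold_accuracy(scores, f$labels)
  }, numeric(1)))
}

# Score a candidate parent change for nodes `changed` without rebuilding.
cache_eval_move <- function(cache, states, parents_new, changed, d, alpha) {
  mean(vapply(cache, function(f) {
    total <- f$total
    for (v in changed) {
      cpt <- fit_node_cpt(states, v, parents_new[[v]], f$train, alpha)
      total <- total - f$contribs[[v]] +
        contrib_for(states, v, parents_new[[v]], cpt, f$test, d)
    }
    scores <- 1 / (1 + exp(total[, 1] - total[, 2]))
    fold_accuracy(scores, f$labels)
  }, numeric(1)))
}

cache_apply_move <- function(cache, states, parents_new, changed, d, alpha) {
  lapply(cache, function(f) {
    for (v in changed) {
      new_c <- contrib_for(states, v, parents_new[[v]],
                           fit_node_cpt(states, v, parents_new[[v]], f$train, alpha),
                           f$test, d)
      f$total <- f$total - f$contribs[[v]] + new_c
      f$contribs[[v]] <- new_c
    }
    f
  })
}

candidate_moves <- function(extra, mutable_nodes, parents, constraints) {
  moves <- list()
  present <- if (NROW(extra) > 0) paste(extra[, 1], extra[, 2]) else character(0)
  for (u in mutable_nodes) {
    for (v in mutable_nodes) {
      if (u == v) next
      if (paste(u, v) %in% present || paste(v, u) %in% present) next
      if (!edge_mutable(constraints, u, v)) next
      if (length(parents[[v]]) >= constraints$max_parents[[v]]) next
      moves[[length(moves) + 1]] <- list(op = "add", u = u, v = v)
    }
  }
  if (NROW(extra) > 0) {
    for (i in seq_len(nrow(extra))) {
      u <- extra[i, 1]; v <- extra[i, 2]
      moves[[length(moves) + 1]] <- list(op = "delete", u = u, v = v)
      if (edge_mutable(constraints, v, u) &&
          length(parents[[u]]) < constraints$max_parents[[u]]) {
        moves[[length(moves) + 1]] <- list(op = "reverse", u = u, v = v)
      }
    }
  }
  moves
}

apply_move_edges <- function(extra, move) {
  if (move$op == "add") {
    rbind(extra, c(move$u, move$v))
  } else if (move$op == "delete") {
    extra[!(extra[, 1] == move$u & extra[, 2] == move$v), , drop = FALSE]
  } else {
    rbind(extra[!(extra[, 1] == move$u & extra[, 2] == move$v), , drop = FALSE],
          c(move$v, move$u))
  }
}

parents_from_edges <- function(nodes, base_edges, extra) {
  edges <- rbind(base_edges, extra)
  pa <- lapply(nodes, function(v) edges[edges[, 2] == v, 1])
  names(pa) <- nodes
  pa
}

#' Refine a base structure by constrained greedy hill climbing
#'
#' The search that turns the handcrafted structure into the
#' semihandcrafted one: add/delete/reverse moves restricted to the
#' constraints' mutable edge class, each candidate scored by
#' [cv_accuracy_score()] on a fixed fold assignment, accepting the best
#' strictly improving move (ties resolved toward fewer edges, then the
#' lexicographically smaller edge set, so reruns are deterministic).
#' Optional random restarts perturb the starting point; the best-scoring
#' climb is returned and is never worse than the base structure's score.
#'
#' @param base the base structure; must satisfy \code{constraints}.
#' @param data complete [discrete_dataset()] or integer matrix (typically
#'   the structure-training split).
#' @param constraints a [structure_constraints()] (default: base edges
#'   required, predictor-predictor edges mutable, 4-parent cap).
#' @param k folds for the wrapper score (default 5).
#' @param max_iter maximum accepted moves per climb (default 100).
#' @param n_restarts random restarts (default 2).
#' @param seed seed controlling folds and restarts.
#' @param alpha CPT pseudo-count for fold fitting.
#' @return list with \code{structure} (the refined [bayes_net()]),
#'   \code{score}, \code{base_score} and \code{trace} (data.frame of
#'   evaluated moves: move, score, accepted).
#' @export
bayesian_search <- function(base, data, constraints = NULL, k = 5,
                            max_iter = 100, n_restarts = 2, seed = 1L,
                            alpha = 1) {
  if (is.null(constraints)) constraints <- structure_constraints(base)
  bad <- check_constraints(base, constraints)
  if (!is.null(bad)) stop("base structure violates constraints: ", bad)
  X <- dd_matrix(data)[, base$nodes, drop = FALSE]
  if (anyNA(X)) stop("structure search requires complete (imputed) data")
  d <- binary_disease_node(base)
  folds <- stratified_kfold(X[, d], k = k, seed = seed)
  states <- base$states
  mutable_nodes <- if (constraints$mutable == "predictor-predictor") {
    names(constraints$levels)[constraints$levels == "predictor"]
  } else {
    base$nodes
  }
  no_extra <- matrix(character(0), ncol = 2)

  trace <- list()
  note <- function(move, score, accepted) {
    trace[[length(trace) + 1]] <<- data.frame(
      move = move, score = score, accepted = accepted,
      stringsAsFactors = FALSE)
  }

  climb <- function(extra) {
    parents <- parents_from_edges(base$nodes, base$edges, extra)
    cache <- make_fold_cache(states, parents, d, X, folds, alpha)
    score <- cache_score(cache)
    note("start", score, TRUE)
    for (iter in seq_len(max_iter)) {
      moves <- candidate_moves(extra, mutable_nodes, parents, constraints)
      best <- NULL
      for (mv in moves) {
        extra2 <- apply_move_edges(extra, mv)
        parents2 <- parents_from_edges(base$nodes, base$edges, extra2)
        if (is.null(topological_order(parents2))) next
        np2 <- vapply(parents2, length, integer(1))
        if (any(np2 > constraints$max_parents[names(np2)])) next
        changed <- if (mv$op == "reverse") c(mv$u, mv$v) else mv$v
        s <- cache_eval_move(cache, states, parents2, changed, d, alpha)
        mv_desc <- paste(mv$op, mv$u, "->", mv$v)
        note(mv_desc, s, FALSE)
        cand <- list(move = mv, desc = mv_desc, score = s, extra = extra2,
                     parents = parents2, changed = changed,
                     n_edges = NROW(extra2),
                     key = paste(edge_key(extra2), collapse = ";"))
        if (is.null(best) || s > best$score + 1e-12 ||
            (abs(s - best$score) <= 1e-12 &&
             (cand$n_edges < best$n_edges ||
              (cand$n_edges == best$n_edges && cand$key < best$key)))) {
          best <- cand
        }
      }
      improved <- !is.null(best) &&
        (best$score > score + 1e-12 ||
         (abs(best$score - score) <= 1e-12 && best$n_edges < NROW(extra)))
      if (!improved) break
      extra <- best$extra
      parents <- best$parents
      cache <- cache_apply_move(cache, states, parents, best$changed, d, alpha)
      score <- cache_score(cache)
      note(paste("accept", best$desc), score, TRUE)
    }
    list(extra = extra, score = score)
  }

  base_run <- climb(no_extra)
  runs <- list(base_run)
  if (n_restarts > 0 && max_iter > 0) {
    set.seed(seed + 1L)
    for (r in seq_len(n_restarts)) {
      extra <- no_extra
      parents <- parents_from_edges(base$nodes, base$edges, extra)
      adds <- Filter(function(m) m$op == "add",
                     candidate_moves(extra, mutable_nodes, parents, constraints))
      n_seed_edges <- min(2L, length(adds))
      for (mv in sample(adds, n_seed_edges)) {
        extra2 <- apply_move_edges(extra, mv)
        parents2 <- parents_from_edges(base$nodes, base$edges, extra2)
        if (!is.null(topological_order(parents2))) extra <- extra2
      }
      runs[[length(runs) + 1]] <- climb(extra)
    }
  }
  scores <- vapply(runs, `[[`, numeric(1), "score")
  sizes <- vapply(runs, function(r) NROW(r$extra), integer(1))
  keys <- vapply(runs, function(r) paste(edge_key(r$extra), collapse = ";"),
                 character(1))
  ord <- order(-scores, sizes, keys)
  win <- runs[[ord[1]]]
  result <- structure_with_edges(base, win$extra)
  stopifnot(is.null(check_constraints(result, constraints)))
  list(structure = result, score = win$score, base_score = base_run$score,
       trace = do.call(rbind, trace), seed = seed)
}
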
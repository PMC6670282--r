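#' Construct a discrete Bayesian network
#'
#' A \code{bayes_net} is a directed acyclic graph over discrete variables
#' with one conditional probability table (CPT) per node. Nodes carry an
#' optional level tag (\code{"background"}, \code{"disease"} or
#' \code{"predictor"}) used by the three-level clinical models; generic
#' networks may leave the tags \code{NA}.
#'
#' CPTs are stored as arrays whose first dimension indexes the node's own
#' states and whose remaining dimensions index the parents in the order of
#' \code{parents[[node]]}. Each "row" (the distribution over node states for
#' one parent configuration) must sum to 1 within \code{1e-12}. States are
#' indexed from 1 in all user-facing input and output.
#'
#' @param states named list; one character vector of state labels per node.
#' @param edges two-column character matrix (or data.frame) of directed
#'   edges \code{from -> to}; may have zero rows.
#' @param cpts named list of CPT arrays, or \code{NULL} for an
#'   unparameterized structure (as consumed by the learning functions).
#' @param levels optional named character vector of level tags.
#' @param check if \code{TRUE} (default) the network is validated and
#'   construction fails on a cycle or malformed CPT.
#' @return an object of class \code{bayes_net}.
#' @seealso [validate_network()], [posterior()], [joint_probability()]
#' @examples
#' net <- bayes_net(
#'   states = list(D = c("neg", "pos"), T = c("neg", "pos")),
#'   edges = matrix(c("D", "T"), ncol = 2),
#'   cpts = list(
#'     D = matrix(c(0.5, 0.5), 2, 1),
#'     T = array(c(0.78, 0.22, 0.27, 0.73), dim = c(2, 2))
#'   ),
#'   levels = c(D = "disease", T = "predictor")
#' )
#' posterior(net, evidence = c(T = 2), query = "D")
#' @export
bayes_net <- function(states, edges = NULL, cpts = NULL, levels = NULL,
                      check = TRUE) {
  stopifnot(is.list(states), length(states) > 0, !is.null(names(states)))
  nodes <- names(states)
  states <- lapply(states, as.character)
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- matrix(character(0), ncol = 2)
  } else {
    edges <- as.matrix(edges)
    storage.mode(edges) <- "character"
    if (ncol(edges) != 2) stop("`edges` must have two columns (from, to)")
  }
  colnames(edges) <- c("from", "to")
  unknown <- setdiff(c(edges), nodes)
  if (length(unknown) > 0) {
    stop("edge refers to unknown node(s): ", paste(unknown, collapse = ", "))
  }
  parents <- lapply(nodes, function(v) edges[edges[, 2] == v, 1])
  names(parents) <- nodes
  lv <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  if (!is.null(levels)) lv[names(levels)] <- as.character(levels)
  net <- structure(
    list(nodes = nodes, states = states, parents = parents,
         edges = edges, cpts = cpts, levels = lv),
    class = "bayes_net"
  )
  if (check) {
    diag <- validate_network(net)
    if (!diag$ok) stop("invalid network: ", paste(diag$problems, collapse = "; "))
  }
  net
}

node_card <- function(net, v) lengths(net$states[v])

#' @export
print.bayes_net <- function(x, ...) {
  cat("Discrete Bayesian network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges,",
      if (is.null(x$cpts)) "no CPTs (structure only)" else "with CPTs", "\n")
  tags <- x$levels[!is.na(x$levels)]
  if (length(tags) > 0) {
    for (lev in c("background", "disease", "predictor")) {
      nn <- names(tags)[tags == lev]
      if (length(nn) > 0) cat(sprintf("  %-10s %s\n", lev, paste(nn, collapse = " ")))
    }
  }
  invisible(x)
}

# Topological order of the node set, or NULL if the edge set is cyclic.
topological_order <- function(parents) {
  nodes <- names(parents)
  indeg <- vapply(parents, length, integer(1))
  order <- character(0)
  avail <- nodes[indeg == 0]
  parents_left <- parents
  while (length(avail) > 0) {
    v <- avail[1]
    avail <- avail[-1]
    order <- c(order, v)
    for (w in nodes) {
      if (v %in% parents_left[[w]]) {
        parents_left[[w]] <- setdiff(parents_left[[w]], v)
        if (length(parents_left[[w]]) == 0 && !(w %in% order) && !(w %in% avail)) {
          avail <- c(avail, w)
        }
      }
    }
  }
  if (length(order) < length(nodes)) NULL else order
}

#' Diagnose structural and numerical problems in a network
#'
#' Checks acyclicity, CPT presence/dimensions and row normalization
#' (each conditional distribution must sum to 1 within \code{1e-12}).
#' Returns diagnostics rather than throwing, so it can be used to vet
#' hand-built or deserialized networks.
#'
#' @param net a [bayes_net()].
#' @return list with elements \code{ok} (logical), \code{acyclic},
#'   \code{cpts_ok} and \code{problems} (character vector of messages).
#' @export
validate_network <- function(net) {
  problems <- character(0)
  acyclic <- !is.null(topological_order(net$parents))
  if (!acyclic) problems <- c(problems, "edge set contains a directed cycle")
  cpts_ok <- TRUE
  if (!is.null(net$cpts)) {
    for (v in net$nodes) {
      cpt <- net$cpts[[v]]
      if (is.null(cpt)) {
        cpts_ok <- FALSE
        problems <- c(problems, paste0("node '", v, "' has no CPT"))
        next
      }
      expect_dim <- c(node_card(net, v), unname(lengths(net$states[net$parents[[v]]])))
      have_dim <- if (is.null(dim(cpt))) length(cpt) else dim(cpt)
      if (length(have_dim) != length(expect_dim) || any(have_dim != expect_dim)) {
        # accept vector/matrix shorthand for root / single-parent nodes
        if (prod(have_dim) != prod(expect_dim)) {
          cpts_ok <- FALSE
          problems <- c(problems, paste0("node '", v, "' CPT has wrong dimensions"))
          next
        }
      }
      m <- matrix(as.numeric(cpt), nrow = node_card(net, v))
      sums <- colSums(m)
      if (any(abs(sums - 1) > 1e-12) || any(m < 0)) {
        cpts_ok <- FALSE
        problems <- c(problems,
                      paste0("node '", v, "' has a CPT row not summing to 1 ",
                             "(max deviation ", format(max(abs(sums - 1))), ")"))
      }
    }
  }
  list(ok = acyclic && cpts_ok, acyclic = acyclic, cpts_ok = cpts_ok,
       problems = problems)
}

# Normalize user evidence / assignments to 1-based integer state indices.
as_state_index <- function(net, assignment) {
  if (length(assignment) == 0) return(stats::setNames(integer(0), character(0)))
  nm <- names(assignment)
  if (is.null(nm) || any(nm == "")) stop("assignment must be named by node")
  unknown <- setdiff(nm, net$nodes)
  if (length(unknown) > 0) stop("unknown node(s): ", paste(unknown, collapse = ", "))
  out <- integer(length(nm))
  for (i in seq_along(nm)) {
    v <- nm[i]
    val <- assignment[[i]]
    if (is.character(val)) {
      j <- match(val, net$states[[v]])
      if (is.na(j)) {
        stop("node '", v, "': unknown state '", val, "'; valid states: ",
             paste(net$states[[v]], collapse = ", "))
      }
      out[i] <- j
    } else {
      j <- as.integer(val)
      if (is.na(j) || j < 1 || j > node_card(net, v)) {
        stop("node '", v, "': state index ", val, " out of range 1..",
             node_card(net, v))
      }
      out[i] <- j
    }
  }
  stats::setNames(out, nm)
}

cpt_entry <- function(net, v, assignment) {
  pa <- net$parents[[v]]
  cpt <- net$cpts[[v]]
  idx <- assignment[v]
  if (length(pa) > 0) {
    cards <- c(node_card(net, v), unname(lengths(net$states[pa])))
    mult <- cumprod(cards)
    lin <- idx - 1
    for (i in seq_along(pa)) lin <- lin + (assignment[pa[i]] - 1) * mult[i]
    as.numeric(cpt)[lin + 1]
  } else {
    as.numeric(cpt)[idx]
  }
}

#' Joint probability of a complete assignment
#'
#' Chain-rule factorization: the product over nodes of
#' \eqn{P(x_v \mid x_{pa(v)})}.
#'
#' @param net a parameterized [bayes_net()].
#' @param assignment named vector/list covering every node, states given as
#'   1-based indices or state labels.
#' @return probability in \[0, 1\].
#' @export
joint_probability <- function(net, assignment) {
  if (is.null(net$cpts)) stop("network has no CPTs")
  a <- as_state_index(net, assignment)
  missing_nodes <- setdiff(net$nodes, names(a))
  if (length(missing_nodes) > 0) {
    stop("assignment must cover every node; missing: ",
         paste(missing_nodes, collapse = ", "))
  }
  p <- 1
  for (v in net$nodes) p <- p * cpt_entry(net, v, a)
  p
}

node_factor <- function(net, v) {
  pa <- net$parents[[v]]
  vars <- c(v, pa)
  card <- unname(lengths(net$states[vars]))
  new_factor(vars, card, as.numeric(net$cpts[[v]]))
}

#' Exact posterior distribution of a query node
#'
#' Computes \eqn{P(\mathrm{query} \mid \mathrm{evidence})} exactly by
#' variable elimination with a min-fill ordering. With empty evidence this
#' is the marginal distribution. Agreement with the brute-force
#' [enumerate_posterior()] oracle within \code{1e-10} is part of the
#' package's test contract.
#'
#' @param net a parameterized [bayes_net()].
#' @param evidence named vector/list of observed states (may be empty).
#' @param query name of the query node; must not appear in the evidence.
#' @return object of class \code{bn_posterior}: named probability vector
#'   over the query node's states (sums to 1), with the query name as an
#'   attribute.
#' @export
posterior <- function(net, evidence = NULL, query) {
  if (is.null(net$cpts)) stop("network has no CPTs")
  stopifnot(length(query) == 1, query %in% net$nodes)
  ev <- as_state_index(net, if (is.null(evidence)) list() else evidence)
  if (query %in% names(ev)) stop("query node '", query, "' cannot be evidence")
  factors <- lapply(net$nodes, function(v) node_factor(net, v))
  for (i in seq_along(factors)) {
    for (v in intersect(names(ev), factors[[i]]$vars)) {
      factors[[i]] <- factor_reduce(factors[[i]], v, ev[[v]])
    }
  }
  elim <- setdiff(net$nodes, c(query, names(ev)))
  ord <- min_fill_order(lapply(factors, `[[`, "vars"), elim)
  for (v in c(ord, setdiff(elim, ord))) {
    involved <- vapply(factors, function(f) v %in% f$vars, logical(1))
    if (!any(involved)) next
    prod_f <- Reduce(factor_product, factors[involved])
    factors <- c(factors[!involved], list(factor_marginalize(prod_f, v)))
  }
  res <- Reduce(factor_product, factors)
  if (length(res$vars) != 1 || res$vars != query) {
    # only constant factors plus the query factor remain; product handles it
    res <- Reduce(factor_product, factors)
  }
  z <- sum(res$vals)
  if (!is.finite(z) || z <= 0) {
    stop("impossible evidence: observed configuration has probability 0")
  }
  p <- res$vals / z
  structure(stats::setNames(p, net$states[[query]]),
            query = query, class = "bn_posterior")
}

#' @export
print.bn_posterior <- function(x, ...) {
  cat("Posterior P(", attr(x, "query"), " | evidence):\n", sep = "")
  print(round(unclass(x), 6))
  invisible(x)
}

# Full joint table over all nodes as a single factor, built by vectorized
# indexing (independent of the elimination engine).
full_joint_factor <- function(net) {
  vars <- net$nodes
  card <- unname(lengths(net$states[vars]))
  if (prod(card) > 1e7) {
    stop("state space exceeds 1e7 configurations; use posterior() instead")
  }
  vals <- rep(1, prod(card))
  for (v in vars) {
    f <- node_factor(net, v)
    vals <- vals * f$vals[config_index(vars, card, f$vars, f$card)]
  }
  new_factor(vars, card, vals)
}

#' Brute-force posterior by full enumeration
#'
#' Reference oracle for [posterior()]: materializes the full joint table and
#' conditions on the evidence by direct summation. Only feasible for state
#' spaces up to \code{1e7} configurations.
#'
#' @inheritParams posterior
#' @return as [posterior()].
#' @export
enumerate_posterior <- function(net, evidence = NULL, query) {
  if (is.null(net$cpts)) stop("network has no CPTs")
  stopifnot(length(query) == 1, query %in% net$nodes)
  ev <- as_state_index(net, if (is.null(evidence)) list() else evidence)
  if (query %in% names(ev)) stop("query node '", query, "' cannot be evidence")
  f <- full_joint_factor(net)
  for (v in names(ev)) f <- factor_reduce(f, v, ev[[v]])
  for (v in setdiff(f$vars, query)) f <- factor_marginalize(f, v)
  z <- sum(f$vals)
  if (!is.finite(z) || z <= 0) {
    stop("impossible evidence: observed configuration has probability 0")
  }
  structure(stats::setNames(f$vals / z, net$states[[query]]),
            query = query, class = "bn_posterior")
}

disease_node <- function(net) {
  d <- names(net$levels)[!is.na(net$levels) & net$levels == "disease"]
  if (length(d) != 1) stop("network must have exactly one node tagged 'disease'")
  d
}

#' Classify the disease state from partial evidence
#'
#' Score is \eqn{P(\mathrm{disease} = \mathrm{positive} \mid \mathrm{evidence})};
#' the label is positive when the score reaches the threshold (ties are
#' called positive: for a prescreening tool the costlier mistake is the
#' missed case). Any subset of the non-disease attributes may be supplied
#' as evidence, so prediction degrades gracefully when tests are missing.
#'
#' @param net a parameterized [bayes_net()] with one node tagged
#'   \code{"disease"}.
#' @param evidence named vector/list of observed states (may be empty).
#' @param threshold decision threshold on the positive-state posterior,
#'   default 0.5.
#' @param positive positive state of the disease node (index or label);
#'   default the second state, matching the negative/positive coding.
#' @return list with \code{label} (state label), \code{state} (index),
#'   \code{score} and the full \code{posterior}.
#' @export
classify <- function(net, evidence = NULL, threshold = 0.5, positive = 2L) {
  d <- disease_node(net)
  if (!is.null(evidence) && d %in% names(evidence)) {
    stop("disease node '", d, "' cannot be evidence")
  }
  pos <- as_state_index(net, stats::setNames(list(positive), d))[[d]]
  post <- posterior(net, evidence, query = d)
  score <- unname(post[pos])
  lab_idx <- if (score >= threshold) pos else {
    neg <- which.max(unclass(post)[-pos])
    setdiff(seq_along(post), pos)[neg]
  }
  list(label = net$states[[d]][lab_idx], state = lab_idx, score = score,
       posterior = post)
}
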
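# Discrete factor algebra used by the exact inference engines.
#
# A factor is a list(vars, card, vals): `vars` a character vector of variable
# names, `card` their cardinalities, and `vals` a numeric vector of length
# prod(card) laid out with the FIRST variable varying fastest (column-major,
# as in base R arrays).

new_factor <- function(vars, card, vals) {
  stopifnot(length(vars) == length(card), length(vals) == prod(card))
  list(vars = as.character(vars), card = as.integer(card), vals = as.numeric(vals))
}

# Linear indices (1-based) into a factor over `vars_sub` for every
# configuration of the joint space over (vars_all, card_all).
config_index <- function(vars_all, card_all, vars_sub, card_sub) {
  n <- prod(card_all)
  lin <- 0:(n - 1)
  stride <- cumprod(c(1, card_all))[seq_along(card_all)]
  idx <- rep(0, n)
  mult <- 1
  for (i in seq_along(vars_sub)) {
    j <- match(vars_sub[i], vars_all)
    val <- (lin %/% stride[j]) %% card_all[j]
    idx <- idx + val * mult
    mult <- mult * card_sub[i]
  }
  as.integer(idx + 1)
}

factor_product <- function(f, g) {
  if (is.null(f)) return(g)
  if (is.null(g)) return(f)
  vars <- union(f$vars, g$vars)
  card <- integer(length(vars))
  names(card) <- vars
  card[f$vars] <- f$card
  card[g$vars] <- g$card
  fi <- config_index(vars, card, f$vars, f$card)
  gi <- config_index(vars, card, g$vars, g$card)
  new_factor(vars, card, f$vals[fi] * g$vals[gi])
}

factor_marginalize <- function(f, var) {
  j <- match(var, f$vars)
  if (is.na(j)) return(f)
  if (length(f$vars) == 1L) {
    return(new_factor(character(0), integer(0), sum(f$vals)))
  }
  a <- array(f$vals, dim = f$card)
  keep <- setdiff(seq_along(f$vars), j)
  vals <- apply(a, keep, sum)
  new_factor(f$vars[keep], f$card[keep], as.numeric(vals))
}

factor_reduce <- function(f, var, state) {
  j <- match(var, f$vars)
  if (is.na(j)) return(f)
  a <- array(f$vals, dim = f$card)
  ix <- rep(list(quote(expr = )), length(f$card))
  ix[[j]] <- state
  sub <- do.call(`[`, c(list(a), ix, list(drop = FALSE)))
  keep <- setdiff(seq_along(f$vars), j)
  if (length(keep) == 0L) {
    return(new_factor(character(0), integer(0), as.numeric(sub)))
  }
  new_factor(f$vars[keep], f$card[keep], as.numeric(sub))
}

# Min-fill elimination ordering over the interaction graph induced by the
# factor scopes; deterministic (ties broken by variable name).
min_fill_order <- function(scopes, elim_vars) {
  vars <- sort(unique(unlist(scopes)))
  adj <- stats::setNames(vector("list", length(vars)), vars)
  for (sc in scopes) {
    for (v in sc) adj[[v]] <- union(adj[[v]], setdiff(sc, v))
  }
  order <- character(0)
  remaining <- sort(intersect(elim_vars, vars))
  while (length(remaining) > 0) {
    fill <- vapply(remaining, function(v) {
      nb <- intersect(adj[[v]], names(adj))
      if (length(nb) < 2) return(0L)
      cnt <- 0L
      for (i in seq_len(length(nb) - 1)) {
        for (j in (i + 1):length(nb)) {
          if (!(nb[j] %in% adj[[nb[i]]])) cnt <- cnt + 1L
        }
      }
      cnt
    }, integer(1))
    v <- remaining[which.min(fill)]
    nb <- intersect(adj[[v]], names(adj))
    for (a in nb) adj[[a]] <- union(setdiff(adj[[a]], v), setdiff(nb, a))
    adj[[v]] <- NULL
    order <- c(order, v)
    remaining <- setdiff(remaining, v)
  }
  order
}
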
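# ---- XMLBIF 0.3 ----------------------------------------------------------

# Table entry order: the node's own states vary fastest, then the GIVEN
# parents from last to first (the usual XMLBIF reading order). Level tags
# ride along as <PROPERTY>level = ...</PROPERTY>, since the format has no
# native slot for them.

#' Write / read a network in XMLBIF 0.3
#'
#' @param net a parameterized [bayes_net()].
#' @param path file path.
#' @param name network name for the file header.
#' @return \code{read_xmlbif} returns a [bayes_net()].
#' @export
write_xmlbif <- function(net, path, name = "oaknet") {
  if (is.null(net$cpts)) stop("network has no CPTs")
  doc <- xml2::xml_new_root("BIF", VERSION = "0.3")
  nw <- xml2::xml_add_child(doc, "NETWORK")
  xml2::xml_add_child(nw, "NAME", name)
  for (v in net$nodes) {
    var <- xml2::xml_add_child(nw, "VARIABLE", TYPE = "nature")
    xml2::xml_add_child(var, "NAME", v)
    for (s in net$states[[v]]) xml2::xml_add_child(var, "OUTCOME", s)
    if (!is.na(net$levels[[v]])) {
      xml2::xml_add_child(var, "PROPERTY",
                          paste0("level = ", net$levels[[v]]))
    }
  }
  for (v in net$nodes) {
    def <- xml2::xml_add_child(nw, "DEFINITION")
    xml2::xml_add_child(def, "FOR", v)
    for (p in net$parents[[v]]) xml2::xml_add_child(def, "GIVEN", p)
    pa <- net$parents[[v]]
    a <- array(as.numeric(net$cpts[[v]]),
               dim = c(node_card(net, v), unname(lengths(net$states[pa]))))
    # reorder so that earlier parents vary slower than later ones
    if (length(pa) > 1) {
      a <- aperm(a, c(1, rev(seq_along(pa)) + 1))
    }
    xml2::xml_add_child(def, "TABLE",
                        paste(format(as.numeric(a), digits = 17,
                                     scientific = FALSE, trim = TRUE),
                              collapse = " "))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_xmlbif
#' @export
read_xmlbif <- function(path) {
  doc <- xml2::read_xml(path)
  vars <- xml2::xml_find_all(doc, ".//VARIABLE")
  states <- list()
  levels <- character(0)
  for (var in vars) {
    nm <- xml2::xml_text(xml2::xml_find_first(var, "./NAME"))
    states[[nm]] <- xml2::xml_text(xml2::xml_find_all(var, "./OUTCOME"))
    props <- xml2::xml_text(xml2::xml_find_all(var, "./PROPERTY"))
    lev <- sub("^level\\s*=\\s*", "", props[grepl("^level\\s*=", props)])
    if (length(lev) == 1) levels[nm] <- lev
  }
  defs <- xml2::xml_find_all(doc, ".//DEFINITION")
  edges <- NULL
  cpts <- list()
  for (def in defs) {
    v <- xml2::xml_text(xml2::xml_find_first(def, "./FOR"))
    pa <- xml2::xml_text(xml2::xml_find_all(def, "./GIVEN"))
    vals <- as.numeric(strsplit(trimws(xml2::xml_text(
      xml2::xml_find_first(def, "./TABLE"))), "\\s+")[[1]])
    dims <- c(length(states[[v]]), unname(lengths(states[pa])))
    if (length(pa) > 1) {
      a <- array(vals, dim = c(dims[1], rev(dims[-1])))
      a <- aperm(a, c(1, rev(seq_along(pa)) + 1))
    } else {
      a <- array(vals, dim = dims)
    }
    cpts[[v]] <- a
    for (p in pa) edges <- rbind(edges, c(p, v))
  }
  bayes_net(states = states, edges = edges, cpts = cpts[names(states)],
            levels = if (length(levels) > 0) levels else NULL)
}

# ---- JSON dialect --------------------------------------------------------

#' Write / read a network as JSON
#'
#' A JSON dialect that, unlike XMLBIF, carries the level tags natively:
#' per node its states, level, parents and flattened CPT (own states
#' varying fastest, then parents in listed order).
#'
#' @param net a [bayes_net()].
#' @param path file path.
#' @return \code{read_bn_json} returns a [bayes_net()].
#' @export
write_bn_json <- function(net, path) {
  nodes <- lapply(net$nodes, function(v) {
    list(name = v, states = net$states[[v]],
         level = if (is.na(net$levels[[v]])) NULL else net$levels[[v]],
         parents = net$parents[[v]],
         cpt = if (is.null(net$cpts)) NULL else as.numeric(net$cpts[[v]]))
  })
  jsonlite::write_json(list(nodes = nodes), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_bn_json
#' @export
read_bn_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  states <- list()
  levels <- character(0)
  edges <- NULL
  cpts <- list()
  has_cpts <- TRUE
  for (nd in obj$nodes) {
    states[[nd$name]] <- unlist(nd$states)
    if (!is.null(nd$level)) levels[nd$name] <- nd$level
    for (p in nd$parents) edges <- rbind(edges, c(p, nd$name))
    if (is.null(nd$cpt)) has_cpts <- FALSE else {
      pa <- unlist(nd$parents)
      cpts[[nd$name]] <- array(unlist(nd$cpt))
    }
  }
  net <- bayes_net(states = states, edges = edges, cpts = NULL,
                   levels = if (length(levels) > 0) levels else NULL)
  if (has_cpts) {
    net$cpts <- lapply(net$nodes, function(v) {
      array(as.numeric(cpts[[v]]), dim = cpt_dims(net, v))
    })
    names(net$cpts) <- net$nodes
    diag <- validate_network(net)
    if (!diag$ok) stop("invalid network in ", path, ": ",
                       paste(diag$problems, collapse = "; "))
  }
  net
}

# ---- discretization scheme ----------------------------------------------

#' Write / read a discretization scheme as JSON
#'
#' @param scheme a [discretization_scheme()].
#' @param path file path.
#' @return \code{read_scheme_json} returns a [discretization_scheme()].
#' @export
write_scheme_json <- function(scheme, path) {
  jsonlite::write_json(lapply(unclass(scheme), function(a) {
    a$support <- if (!is.null(a$support)) {
      ifelse(is.finite(a$support), a$support, c("-Inf", "Inf"))
    }
    a
  }), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_scheme_json
#' @export
read_scheme_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  obj <- lapply(obj, function(a) {
    if (!is.null(a$cutpoints)) a$cutpoints <- as.numeric(unlist(a$cutpoints))
    if (!is.null(a$support)) a$support <- as.numeric(unlist(a$support))
    if (!is.null(a$labels)) a$labels <- as.character(unlist(a$labels))
    a
  })
  discretization_scheme(obj)
}
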
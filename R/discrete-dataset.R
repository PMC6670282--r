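#' Construct a discrete dataset
#'
#' The unit consumed by all learning functions: an n-by-p matrix of 1-based
#' state indices with \code{NA} marking missing cells, per-attribute state
#' labels, level tags (background / disease / predictor) and per-row
#' provenance (\code{"observed"} or \code{"synthetic"} for SMOTE rows).
#'
#' @param data integer matrix with named columns; \code{NA} = missing.
#' @param states named list of state-label character vectors, one per column.
#' @param levels named character vector of level tags per column.
#' @param provenance character vector of row provenance flags, recycled.
#' @return object of class \code{discrete_dataset}.
#' @export
discrete_dataset <- function(data, states, levels = NULL,
                             provenance = "observed") {
  data <- as.matrix(data)
  storage.mode(data) <- "integer"
  if (is.null(colnames(data))) stop("`data` must have column names")
  if (!setequal(colnames(data), names(states))) {
    stop("`states` must name exactly the columns of `data`")
  }
  states <- lapply(states[colnames(data)], as.character)
  for (v in colnames(data)) {
    x <- data[, v]
    bad <- !is.na(x) & (x < 1 | x > length(states[[v]]))
    if (any(bad)) {
      stop("attribute '", v, "': state index out of range in ",
           sum(bad), " cell(s)")
    }
  }
  lv <- stats::setNames(rep(NA_character_, ncol(data)), colnames(data))
  if (!is.null(levels)) lv[names(levels)] <- as.character(levels)
  if (sum(lv == "disease", na.rm = TRUE) > 1) {
    stop("at most one attribute may be tagged 'disease'")
  }
  structure(
    list(data = data, states = states, levels = lv,
         provenance = rep_len(as.character(provenance), nrow(data))),
    class = "discrete_dataset"
  )
}

#' @export
print.discrete_dataset <- function(x, ...) {
  cat("Discrete dataset:", nrow(x$data), "records x", ncol(x$data),
      "attributes;", sum(is.na(x$data)), "missing cell(s);",
      sum(x$provenance != "observed"), "synthetic row(s)\n")
  invisible(x)
}

# Accept either a discrete_dataset or a bare integer matrix.
dd_matrix <- function(data) {
  if (inherits(data, "discrete_dataset")) data$data else {
    m <- as.matrix(data)
    storage.mode(m) <- "integer"
    m
  }
}

dd_states <- function(data, net = NULL) {
  if (inherits(data, "discrete_dataset")) return(data$states)
  if (!is.null(net)) return(net$states[colnames(dd_matrix(data))])
  m <- dd_matrix(data)
  lapply(stats::setNames(as.list(colnames(m)), colnames(m)), function(v) {
    as.character(seq_len(max(m[, v], na.rm = TRUE)))
  })
}
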
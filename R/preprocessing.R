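# Names of the 18 analysis attributes (after BMI/WHR derivation), label
# excluded, and the raw anthropometric columns they replace.
analysis_attribute_names <- function() {
  setdiff(oa_attributes()$name, "oa")
}

raw_anthropometric_names <- function() {
  c("height", "weight", "waist_girth", "hip_girth")
}

#' Derive body mass index
#'
#' \code{weight / height^2}; missing if either input is missing. Used in
#' place of the raw height and weight columns.
#'
#' @param height metres (> 0).
#' @param weight kilograms (> 0).
#' @return BMI in kg/m^2 (vectorized; \code{NA} propagates).
#' @export
derive_bmi <- function(height, weight) {
  bad <- (!is.na(height) & height <= 0) | (!is.na(weight) & weight <= 0)
  if (any(bad)) stop("derive_bmi: height and weight must be positive")
  weight / height^2
}

#' Derive waist-to-hip ratio
#'
#' \code{waist / hip}; missing if either input is missing. A zero waist
#' girth yields 0 with a warning.
#'
#' @param waist,hip girths in cm; hip must be positive.
#' @return unitless ratio (vectorized; \code{NA} propagates).
#' @export
derive_whr <- function(waist, hip) {
  if (any(!is.na(hip) & hip <= 0)) stop("derive_whr: hip girth must be positive")
  if (any(!is.na(waist) & waist < 0)) stop("derive_whr: waist girth must be nonnegative")
  if (any(!is.na(waist) & waist == 0)) {
    warning("derive_whr: zero waist girth")
  }
  waist / hip
}

#' Replace raw anthropometrics by BMI and WHR
#'
#' Applies [derive_bmi()] and [derive_whr()] to a raw record table and
#' drops the height, weight and girth columns, yielding the 18 analysis
#' attributes plus label.
#'
#' @param records data.frame with columns \code{height}, \code{weight},
#'   \code{waist_girth}, \code{hip_girth} (as from [generate_cohort()]).
#' @return data.frame with \code{bmi} and \code{whr} in their place.
#' @export
derive_indices <- function(records) {
  records$bmi <- derive_bmi(records$height, records$weight)
  records$whr <- derive_whr(records$waist_girth, records$hip_girth)
  records[, setdiff(names(records), raw_anthropometric_names()), drop = FALSE]
}

#' Drop records with too many missing attributes
#'
#' A record is kept iff at most \code{max_missing} of the 18 analysis
#' attributes (label excluded, BMI/WHR already derived) are missing --
#' records missing more than a third of their attributes carry too little
#' information to impute. Order is preserved and the removal count is
#' attached as an attribute.
#'
#' @param records data.frame of subject records (post [derive_indices]).
#' @param max_missing largest tolerated number of missing analysis
#'   attributes (default 6 of 18).
#' @param attributes the attribute names counted (default the 18 analysis
#'   attributes present in \code{records}).
#' @return the retained records, with attribute \code{n_removed}.
#' @export
filter_incomplete <- function(records, max_missing = 6, attributes = NULL) {
  if (is.null(attributes)) {
    attributes <- intersect(analysis_attribute_names(), names(records))
  }
  n_miss <- rowSums(is.na(records[, attributes, drop = FALSE]))
  keep <- n_miss <= max_missing
  out <- records[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Mean/mode imputation
#'
#' Continuous missing cells are replaced by the column mean of the
#' observed values; categorical cells by the column mode (ties broken
#' toward the lower state). Imputed cells are flagged in the
#' \code{"imputed"} attribute (a logical matrix) so provenance survives
#' the pipeline.
#'
#' @param records data.frame; columns may contain \code{NA}.
#' @param categorical names of categorical columns (default gender,
#'   education and the disease label when present).
#' @return data.frame with no missing cells.
#' @export
impute_missing <- function(records, categorical = NULL) {
  if (is.null(categorical)) {
    categorical <- intersect(c("gender", "education", "oa"), names(records))
  }
  imputed <- is.na(as.matrix(records))
  for (v in names(records)) {
    x <- records[[v]]
    if (!anyNA(x)) next
    obs <- x[!is.na(x)]
    if (length(obs) == 0) stop("attribute '", v, "' has no observed values")
    fill <- if (v %in% categorical) {
      tab <- table(obs)
      as.numeric(names(tab)[which.max(tab)])  # which.max takes the first max
    } else {
      mean(obs)
    }
    x[is.na(x)] <- fill
    records[[v]] <- x
  }
  attr(records, "imputed") <- imputed
  records
}

#' Exact one-dimensional k-means cutpoints
#'
#' Optimal k-means clustering in one dimension is a contiguous partition
#' of the sorted values, so the global within-cluster sum-of-squares
#' minimum is found exactly by dynamic programming over split positions
#' (no random initialization, deterministic). Cutpoints are the midpoints
#' between adjacent cluster means -- the boundary at which a new value
#' would switch nearest cluster.
#'
#' @param values numeric vector with at least \code{k} distinct values.
#' @param k number of clusters (default 2, giving one cutpoint).
#' @return numeric vector of \code{k - 1} increasing cutpoints, with the
#'   cluster means in attribute \code{"centers"}.
#' @export
learn_cutpoint_kmeans <- function(values, k = 2) {
  values <- values[!is.na(values)]
  if (length(unique(values)) < k) {
    stop("need at least k = ", k, " distinct values (have ",
         length(unique(values)), ")")
  }
  x <- sort(values)
  n <- length(x)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  sse <- function(i, j) {
    # within-cluster SS of x[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  cost <- matrix(Inf, k, n)
  back <- matrix(0L, k, n)
  for (j in 1:n) cost[1, j] <- sse(1, j)
  if (k > 1) {
    for (m in 2:k) {
      for (j in m:n) {
        for (i in m:j) {
          c_try <- cost[m - 1, i - 1] + sse(i, j)
          if (c_try < cost[m, j] - 1e-12) {
            cost[m, j] <- c_try
            back[m, j] <- i
          }
        }
      }
    }
  }
  bounds <- integer(0)
  j <- n
  for (m in k:2) {
    i <- back[m, j]
    bounds <- c(i, bounds)
    j <- i - 1L
  }
  starts <- c(1L, bounds)
  ends <- c(bounds - 1L, n)
  centers <- (cs[ends] - ifelse(starts > 1, cs[starts - 1], 0)) /
    (ends - starts + 1)
  cuts <- (centers[-k] + centers[-1]) / 2
  attr(cuts, "centers") <- centers
  cuts
}

#' Construct a discretization scheme
#'
#' Per-attribute cutpoints with an explicit boundary convention:
#' \code{closed = "lower"} assigns a value equal to a cutpoint to the
#' lower state (interval form \code{[.. to c]; (c to ..)}), while
#' \code{closed = "upper"} assigns it to the upper state
#' (\code{[.. to c); [c to ..)}). The packaged reference scheme uses
#' \code{"lower"} everywhere except BMI, reproducing the published
#' interval notation literally. Attributes with \code{cutpoints = NULL}
#' are treated as already discrete.
#'
#' @param attributes named list; each element a list with fields
#'   \code{cutpoints} (numeric or NULL), \code{closed}
#'   (\code{"lower"}/\code{"upper"}), \code{labels} (state labels),
#'   \code{support} (length-2 numeric, allowed value range).
#' @return object of class \code{discretization_scheme}.
#' @export
discretization_scheme <- function(attributes) {
  for (v in names(attributes)) {
    a <- attributes[[v]]
    if (!is.null(a$cutpoints)) {
      if (is.unsorted(a$cutpoints, strictly = TRUE)) {
        stop("attribute '", v, "': cutpoints must be strictly increasing")
      }
      n_states <- length(a$cutpoints) + 1L
      if (is.null(a$labels)) a$labels <- as.character(seq_len(n_states))
      if (length(a$labels) != n_states) {
        stop("attribute '", v, "': need ", n_states, " state labels")
      }
      if (is.null(a$closed)) a$closed <- "lower"
      if (!a$closed %in% c("lower", "upper")) {
        stop("attribute '", v, "': closed must be 'lower' or 'upper'")
      }
      if (is.null(a$support)) a$support <- c(0, Inf)
    } else {
      if (is.null(a$labels)) stop("attribute '", v, "': discrete attributes need labels")
    }
    attributes[[v]] <- a
  }
  structure(attributes, class = "discretization_scheme")
}

#' @export
print.discretization_scheme <- function(x, ...) {
  for (v in names(x)) {
    a <- x[[v]]
    if (is.null(a$cutpoints)) {
      cat(sprintf("%-20s discrete: %s\n", v, paste(a$labels, collapse = ", ")))
    } else {
      cat(sprintf("%-20s cut at %s (%s closed)\n", v,
                  paste(signif(a$cutpoints, 4), collapse = ", "), a$closed))
    }
  }
  invisible(x)
}

#' The packaged reference discretization scheme
#'
#' The published cutpoints for the final N=157 dataset, verbatim: age 70,
#' BMI 25, WHR 0.91 for the background level; SLSB 73.6 s, BRT 0.63 s,
#' MSR 24.3 cm, LEP 281 W, TUG 8.9 s and the eight SEBT cutpoints
#' 0.763, 0.833, 0.812, 0.749, 0.658, 0.607, 0.490, 0.682 for the
#' predictors. The cutpoint value itself belongs to state 1 for every
#' attribute except BMI, where 25 opens state 2 -- the conventions are
#' intentionally carried as printed, inconsistency included. SEBT values
#' are supported on (0, 2] (normalized reach), the remaining continuous
#' attributes on \[0, Inf).
#'
#' @return a [discretization_scheme()] covering all 19 attributes.
#' @export
table3_scheme <- function() {
  cont <- function(cut, closed = "lower", support = c(0, Inf)) {
    list(cutpoints = cut, closed = closed, labels = c("1", "2"),
         support = support)
  }
  sebt_cuts <- c(anterior = 0.763, anterolateral = 0.833, lateral = 0.812,
                 posterolateral = 0.749, posterior = 0.658,
                 posteromedial = 0.607, medial = 0.490, anteromedial = 0.682)
  attrs <- list(
    gender = list(labels = c("male", "female")),
    age = cont(70),
    bmi = cont(25, closed = "upper"),
    whr = cont(0.91),
    education = list(labels = c("junior_and_below", "junior_high",
                                "senior_high_and_above")),
    oa = list(labels = c("negative", "positive")),
    slsb = cont(73.6),
    brt = cont(0.63),
    msr = cont(24.3),
    lep = cont(281),
    tug = cont(8.9)
  )
  for (nm in names(sebt_cuts)) {
    attrs[[paste0("sebt_", nm)]] <- cont(unname(sebt_cuts[nm]),
                                         support = c(0, 2))
  }
  discretization_scheme(attrs)
}

#' Learn a discretization scheme from data
#'
#' Applies exact 1-D k-means ([learn_cutpoint_kmeans()]) to every
#' continuous attribute of the (typically final, balanced) dataset;
#' gender, education and the disease label are treated as already
#' discrete. Learned schemes use the \code{"lower"} boundary convention.
#'
#' @param records complete data.frame of analysis attributes plus label.
#' @param k states per continuous attribute (default 2).
#' @return a [discretization_scheme()].
#' @export
learn_scheme <- function(records, k = 2) {
  ref <- table3_scheme()
  attrs <- list()
  for (v in names(ref)) {
    if (!v %in% names(records)) next
    a <- ref[[v]]
    if (is.null(a$cutpoints)) {
      attrs[[v]] <- a
    } else {
      cuts <- as.numeric(learn_cutpoint_kmeans(records[[v]], k = k))
      attrs[[v]] <- list(cutpoints = cuts, closed = "lower",
                         labels = as.character(seq_len(k)),
                         support = a$support)
    }
  }
  discretization_scheme(attrs)
}

# Map one attribute's values to states under the scheme's convention.
discretize_values <- function(x, spec, name = "attribute") {
  if (is.null(spec$cutpoints)) {
    s <- as.integer(x)
    bad <- !is.na(s) & (s < 1 | s > length(spec$labels))
    if (any(bad)) {
      stop("attribute '", name, "': state outside 1..", length(spec$labels))
    }
    return(s)
  }
  out_of_support <- !is.na(x) &
    (x < spec$support[1] | x > spec$support[2])
  if (any(out_of_support)) {
    stop("attribute '", name, "': value outside declared support [",
         spec$support[1], ", ", spec$support[2], "]")
  }
  # "lower": value == cutpoint -> lower state; "upper": -> upper state
  right <- spec$closed == "lower"
  s <- findInterval(x, spec$cutpoints, left.open = right,
                    rightmost.closed = FALSE) + 1L
  s[is.na(x)] <- NA_integer_
  as.integer(s)
}

#' Discretize subject records under a scheme
#'
#' Maps every attribute to its 1-based state per the scheme's boundary
#' convention; missing cells stay missing. Values outside an attribute's
#' declared support (negative times, SEBT ratios above 2) raise an error.
#'
#' @param records data.frame of analysis attributes (and label).
#' @param scheme a [discretization_scheme()] covering every column.
#' @param provenance row provenance flags passed to the result (default
#'   taken from a \code{"provenance"} attribute on \code{records}, else
#'   \code{"observed"}).
#' @return a [discrete_dataset()] with level tags from [oa_attributes()]
#'   where the names match.
#' @export
discretize <- function(records, scheme = table3_scheme(), provenance = NULL) {
  missing_cols <- setdiff(names(records), names(scheme))
  if (length(missing_cols) > 0) {
    stop("scheme does not cover attribute(s): ",
         paste(missing_cols, collapse = ", "))
  }
  cols <- names(records)
  m <- matrix(NA_integer_, nrow(records), length(cols),
              dimnames = list(NULL, cols))
  for (v in cols) {
    m[, v] <- discretize_values(records[[v]], scheme[[v]], name = v)
  }
  states <- lapply(scheme[cols], `[[`, "labels")
  canon <- oa_attributes()
  lv <- stats::setNames(canon$level[match(cols, canon$name)], cols)
  if (is.null(provenance)) {
    provenance <- attr(records, "provenance")
    if (is.null(provenance)) provenance <- "observed"
  }
  discrete_dataset(m, states = states, levels = lv[!is.na(lv)],
                   provenance = provenance)
}
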
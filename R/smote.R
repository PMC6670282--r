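#' SMOTE oversampling of the minority class
#'
#' Synthetic-minority oversampling on continuous-scale records (after
#' imputation, before discretization): each synthetic record is
#' \eqn{x + \lambda (x_{nn} - x)} for a seed point \eqn{x} drawn from the
#' minority class, one of its \code{k_neighbors} nearest minority
#' neighbors \eqn{x_{nn}} (Euclidean distance on standardized continuous
#' attributes; categorical attributes are excluded from the distance and
#' copied from the seed point), and \eqn{\lambda \sim U[0,1]}. Majority
#' rows pass through untouched. The default synthetic count of 26 is the
#' bookkeeping of the reference cohort: 53 positive + 26 synthetic
#' against 78 negative gives the 157-record, 50.3%-positive final
#' dataset.
#'
#' @param records complete data.frame including the label column.
#' @param n_synthetic number of synthetic minority records (default 26).
#' @param minority_label value of the minority class in \code{label_col}
#'   (default 2, the positive state).
#' @param label_col name of the label column (default \code{"oa"}).
#' @param k_neighbors neighborhood size (default 5); must be smaller than
#'   the minority count.
#' @param categorical names of categorical columns copied rather than
#'   interpolated (default gender, education and the label).
#' @param seed RNG seed.
#' @return data.frame of \code{nrow(records) + n_synthetic} rows, the
#'   original rows first and bit-identical, with a \code{"provenance"}
#'   attribute flagging \code{"observed"} vs \code{"synthetic"} rows.
#' @export
smote_oversample <- function(records, n_synthetic = 26, minority_label = 2,
                             label_col = "oa", k_neighbors = 5,
                             categorical = NULL, seed = 1L) {
  stopifnot(n_synthetic >= 0, k_neighbors >= 1)
  if (anyNA(records)) stop("SMOTE requires imputed (complete) records")
  if (!label_col %in% names(records)) {
    stop("label column '", label_col, "' not found")
  }
  if (is.null(categorical)) {
    categorical <- intersect(c("gender", "education", label_col),
                             names(records))
  }
  prov <- rep("observed", nrow(records))
  if (n_synthetic == 0) {
    attr(records, "provenance") <- prov
    return(records)
  }
  minority <- which(records[[label_col]] == minority_label)
  n_min <- length(minority)
  if (n_min <= k_neighbors) {
    stop("minority count (", n_min, ") must exceed k_neighbors (",
         k_neighbors, "); use a smaller k")
  }
  cont <- setdiff(names(records), categorical)
  Z <- scale(as.matrix(records[minority, cont, drop = FALSE]))
  Z[, attr(Z, "scaled:scale") == 0] <- 0
  dd <- as.matrix(stats::dist(Z))
  nn <- t(apply(dd, 1, function(row) order(row)[2:(k_neighbors + 1)]))

  set.seed(seed)
  seeds_local <- if (n_synthetic <= n_min) {
    sample(n_min, n_synthetic)
  } else {
    sample(rep(seq_len(n_min), length.out = n_synthetic))
  }
  synth <- records[minority[seeds_local], , drop = FALSE]
  for (i in seq_len(n_synthetic)) {
    s <- seeds_local[i]
    nb <- minority[nn[s, sample(k_neighbors, 1)]]
    lam <- stats::runif(1)
    x <- records[minority[s], cont]
    synth[i, cont] <- x + lam * (records[nb, cont] - x)
  }
  rownames(synth) <- NULL
  out <- rbind(records, synth)
  rownames(out) <- NULL
  attr(out, "provenance") <- c(prov, rep("synthetic", n_synthetic))
  out
}
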
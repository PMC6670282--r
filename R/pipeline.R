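# Per-stage seeds derived from the single run seed so stages can be rerun
# in isolation; kept within 32-bit integer range.
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 1L, missing = 2L, smote = 3L, split = 4L,
               search = 5L, em = 6L, folds = 7L)
  (as.integer(seed) + 7919L * offsets[[stage]]) %% 2147483647L
}

# Small stable fingerprint of the configuration for artifact stamping.
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Default pipeline configuration
#'
#' @param seed run seed (required; every stochastic stage derives its own
#'   seed from it, so a config plus seed fully determines every output).
#' @param input_csv path to a raw cohort CSV, or \code{NULL} to simulate
#'   the default synthetic cohort.
#' @param n_subjects cohort size when simulating (default 131).
#' @param max_missing missingness filter threshold (default 6 of 18).
#' @param scheme \code{"learn"} (k-means cutpoints on the final balanced
#'   dataset, the default) or \code{"table3"} (the packaged reference
#'   scheme).
#' @param n_synthetic,k_neighbors SMOTE settings (defaults 26 and 5).
#' @param split_fraction structure-training share (default 0.3).
#' @param prevalences PPV/NPV prevalences (default 1%, 10%, 20%).
#' @param search_max_iter,search_restarts structure-search settings.
#' @param alpha CPT pseudo-count (default 1).
#' @return named list.
#' @export
run_config <- function(seed, input_csv = NULL, n_subjects = 131,
                       max_missing = 6, scheme = c("learn", "table3"),
                       n_synthetic = 26, k_neighbors = 5,
                       split_fraction = 0.3,
                       prevalences = c(0.01, 0.10, 0.20),
                       search_max_iter = 100, search_restarts = 2,
                       alpha = 1) {
  stopifnot(!missing(seed), split_fraction > 0, split_fraction < 1,
            all(prevalences > 0 & prevalences < 1))
  list(seed = as.integer(seed), input_csv = input_csv,
       n_subjects = n_subjects, max_missing = max_missing,
       scheme = match.arg(scheme), n_synthetic = n_synthetic,
       k_neighbors = k_neighbors, split_fraction = split_fraction,
       prevalences = prevalences, search_max_iter = search_max_iter,
       search_restarts = search_restarts, alpha = alpha)
}

#' Run the full prescreening pipeline
#'
#' End-to-end orchestration: ingest (or simulate) raw records, derive
#' BMI/WHR, drop records with too many missing attributes, mean/mode
#' impute, SMOTE-balance, discretize, split, refine the structure, fit
#' parameters and evaluate both the semihandcrafted and handcrafted
#' models. When \code{out_dir} is given, artifacts (cohort CSV, scheme
#' JSON, fitted networks in XMLBIF and JSON, search trace as JSON lines,
#' metrics JSON) are written, each stamped with the config hash and seed;
#' a rerun with the same config reproduces them byte for byte.
#'
#' @param config a [run_config()].
#' @param out_dir output directory, or \code{NULL} to skip writing.
#' @return list with the stage outputs: \code{records_raw},
#'   \code{records} (imputed), \code{balanced}, \code{scheme},
#'   \code{dataset} (discrete), \code{metrics_shbn}, \code{metrics_hbn},
#'   \code{network} (SHBN fitted on the evaluation split), \code{counts}
#'   (bookkeeping: kept, removed, synthetic, final) and \code{hash}.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  seed <- config$seed
  log_stage <- function(...) message("[oaknet] ", sprintf(...))

  raw <- if (is.null(config$input_csv)) {
    log_stage("simulate: n=%d seed=%d", config$n_subjects,
              stage_seed(seed, "simulate"))
    generate_cohort(cohort_profile(n_subjects = config$n_subjects),
                    seed = stage_seed(seed, "simulate"))
  } else {
    read_cohort(config$input_csv)
  }

  derived <- derive_indices(raw)
  kept <- filter_incomplete(derived, max_missing = config$max_missing)
  log_stage("preprocess: %d kept, %d removed (> %d of 18 missing)",
            nrow(kept), attr(kept, "n_removed"), config$max_missing)
  if (any(is.na(kept$oa))) stop("records with missing label after filtering")
  imputed <- impute_missing(kept)

  balanced <- smote_oversample(imputed, n_synthetic = config$n_synthetic,
                               k_neighbors = config$k_neighbors,
                               seed = stage_seed(seed, "smote"))
  n_pos <- sum(balanced$oa == 2)
  log_stage("balance: %d synthetic, %d final (%.1f%% positive)",
            config$n_synthetic, nrow(balanced), 100 * n_pos / nrow(balanced))

  scheme <- if (config$scheme == "table3") {
    table3_scheme()
  } else {
    learn_scheme(balanced)
  }
  dataset <- discretize(balanced, scheme)

  eval_args <- list(data = dataset, k = 5, seed = stage_seed(seed, "split"),
                    split_fraction = config$split_fraction,
                    prevalences = config$prevalences, alpha = config$alpha,
                    search_args = list(max_iter = config$search_max_iter,
                                       n_restarts = config$search_restarts))
  metrics_shbn <- do.call(evaluate_pipeline,
                          c(eval_args, structure_mode = "shbn"))
  metrics_hbn <- do.call(evaluate_pipeline,
                         c(eval_args, structure_mode = "hbn"))
  log_stage("evaluate: SHBN accuracy %.3f, HBN accuracy %.3f",
            metrics_shbn$accuracy, metrics_hbn$accuracy)

  # final SHBN fitted on the full evaluation split, for deployment/predict
  network <- fit_cpts(metrics_shbn$structure, dataset$data,
                      alpha = config$alpha)

  out <- list(
    records_raw = raw, records = imputed, balanced = balanced,
    scheme = scheme, dataset = dataset,
    metrics_shbn = metrics_shbn, metrics_hbn = metrics_hbn,
    network = network,
    counts = c(raw = nrow(raw), kept = nrow(kept),
               removed = attr(kept, "n_removed"),
               synthetic = config$n_synthetic, final = nrow(balanced),
               positive = n_pos),
    hash = config_hash(config), seed = seed
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- list(config_hash = out$hash, seed = seed)
    write_cohort(balanced, file.path(out_dir, "final_cohort.csv"))
    write_scheme_json(scheme, file.path(out_dir, "scheme.json"))
    write_xmlbif(network, file.path(out_dir, "network_shbn.xml"))
    write_bn_json(network, file.path(out_dir, "network_shbn.json"))
    trace <- metrics_shbn$search$trace
    writeLines(
      vapply(seq_len(NROW(trace)), function(i) {
        as.character(jsonlite::toJSON(as.list(trace[i, ]),
                                      auto_unbox = TRUE, digits = NA))
      }, character(1)),
      file.path(out_dir, "search_trace.jsonl"))
    for (tag in c("shbn", "hbn")) {
      m <- out[[paste0("metrics_", tag)]]
      jsonlite::write_json(
        c(stamp, list(model = m$model, accuracy = m$accuracy, auc = m$auc,
                      sensitivity = m$sensitivity,
                      specificity = m$specificity,
                      ppv = as.list(m$ppv), npv = as.list(m$npv),
                      folds = m$folds)),
        file.path(out_dir, paste0("metrics_", tag, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(c(stamp, as.list(out$counts)),
                         file.path(out_dir, "counts.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Posterior disease prediction from (possibly partial) evidence
#'
#' Accepts raw continuous measurements (auto-discretized through the
#' stored scheme), state indices, or state labels, for any subset of the
#' attributes; prints nothing, returns the posterior and thresholded
#' label. Unknown attributes or states raise an error listing the valid
#' states.
#'
#' @param net a fitted [bayes_net()] (e.g. from [run_pipeline()] or
#'   [read_bn_json()]).
#' @param evidence named list; numeric values for attributes with
#'   cutpoints in \code{scheme} are discretized, everything else is
#'   interpreted as a state index or label.
#' @param scheme the [discretization_scheme()] used at training time, or
#'   \code{NULL} if the evidence is already discrete.
#' @param threshold decision threshold (default 0.5; ties positive).
#' @return as [classify()].
#' @export
predict_oa <- function(net, evidence = list(), scheme = NULL,
                       threshold = 0.5) {
  if (length(evidence) > 0 && !is.null(scheme)) {
    for (v in names(evidence)) {
      spec <- scheme[[v]]
      if (!is.null(spec) && !is.null(spec$cutpoints) &&
          is.numeric(evidence[[v]])) {
        evidence[[v]] <- discretize_values(evidence[[v]], spec, name = v)
      }
    }
  }
  classify(net, evidence, threshold = threshold)
}
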
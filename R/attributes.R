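#' Canonical attribute set of the knee-OA model
#'
#' The 19 analysis attributes: 5 background characteristics (gender, age,
#' education, BMI, waist-to-hip ratio), the knee-osteoarthritis disease
#' node, and 13 physical-fitness predictors (single-leg stance balance,
#' body reaction time, modified sit-and-reach, leg extension power, timed
#' up-and-go, and the 8 normalized Star Excursion Balance Test directions).
#' All attributes are binary after discretization except education
#' (3 ordinal states) and the state labels follow the negative/positive,
#' low/high coding of the packaged discretization scheme.
#'
#' @return data.frame with columns \code{name}, \code{level},
#'   \code{n_states}.
#' @export
oa_attributes <- function() {
  sebt <- paste0("sebt_", c("anterior", "anterolateral", "lateral",
                            "posterolateral", "posterior", "posteromedial",
                            "medial", "anteromedial"))
  data.frame(
    name = c("gender", "age", "bmi", "whr", "education", "oa",
             "slsb", "brt", "msr", "lep", "tug", sebt),
    level = c(rep("background", 5), "disease", rep("predictor", 13)),
    n_states = c(2, 2, 2, 2, 3, 2, rep(2, 13)),
    stringsAsFactors = FALSE
  )
}

oa_state_labels <- function(attrs = oa_attributes()) {
  out <- lapply(seq_len(nrow(attrs)), function(i) {
    switch(attrs$name[i],
           gender = c("male", "female"),
           education = c("junior_and_below", "junior_high", "senior_high_and_above"),
           oa = c("negative", "positive"),
           as.character(seq_len(attrs$n_states[i])))
  })
  stats::setNames(out, attrs$name)
}

sebt_attribute_names <- function() {
  paste0("sebt_", c("anterior", "anterolateral", "lateral", "posterolateral",
                    "posterior", "posteromedial", "medial", "anteromedial"))
}
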
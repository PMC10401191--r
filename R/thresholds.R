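#' Load the triage decision-table thresholds
#'
#' All numeric band edges used by the rules engine live in one versioned
#' YAML config so they can be corrected against the deployed app's screens
#' without code change. Bands are half-open and lower-inclusive: a reading
#' exactly at an edge takes the more severe color.
#'
#' The shipped defaults encode the national guideline bands:
#' * Blood pressure: GREEN if SBP < 140 mmHg and DBP < 90 mmHg and shock
#'   index (HR/SBP) < 0.9; YELLOW if SBP in \[140, 160) or DBP in
#'   \[90, 110) or SI in \[0.9, 1.7); RED if SBP >= 160 or DBP >= 110 or
#'   SI >= 1.7 (vital-signs-alert device bands).
#' * Hemoglobin: RED below 7.0 g/dL (severe anemia), YELLOW in
#'   \[7.0, 11.0) with a referral-strength recommendation below 10.0
#'   (moderate-to-severe anemia), GREEN at or above 11.0.
#' * Nonfasting 2-h OGTT capillary glucose: GREEN below 140 mg/dL, YELLOW
#'   (gestational diabetes, refer) at or above 140, RED (overt diabetes,
#'   urgent) at or above 200.
#'
#' @param path path to a YAML thresholds file; `NULL` loads the packaged
#'   default (`inst/extdata/thresholds.yaml`).
#' @return a named list of class `"triage_thresholds"`. The loader refuses
#'   any config missing a required key.
#' @export
load_thresholds <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "thresholds.yaml", package = "anctriage")
  }
  if (!file.exists(path)) stop("thresholds config not found: ", path)
  th <- yaml::read_yaml(path)
  validate_thresholds(th)
}

required_threshold_keys <- list(
  bp = c("sbp_yellow", "sbp_red", "dbp_yellow", "dbp_red", "si_yellow", "si_red"),
  hb = c("red_below", "referral_below", "green_at_or_above"),
  ogtt = c("yellow_at_or_above", "red_at_or_above"),
  windows = c("enrol_min_days", "enrol_max_days", "pp_week1_start",
              "pp_week1_end", "pp_week6_start", "pp_week6_end"),
  resolution = c("bp", "hr", "hb", "glucose", "si")
)

validate_thresholds <- function(th) {
  for (section in names(required_threshold_keys)) {
    if (is.null(th[[section]])) stop("thresholds config missing section: ", section)
    for (key in required_threshold_keys[[section]]) {
      v <- th[[section]][[key]]
      if (is.null(v) || !is.numeric(v) || length(v) != 1L || is.na(v)) {
        stop("thresholds config missing numeric key: ", section, ".", key)
      }
    }
  }
  stopifnot(th$bp$sbp_yellow < th$bp$sbp_red, th$bp$dbp_yellow < th$bp$dbp_red,
            th$bp$si_yellow < th$bp$si_red,
            th$hb$red_below < th$hb$referral_below,
            th$hb$referral_below <= th$hb$green_at_or_above,
            th$ogtt$yellow_at_or_above < th$ogtt$red_at_or_above)
  structure(th, class = c("triage_thresholds", "list"))
}

#' Perturb one band edge by a number of resolution steps
#'
#' Used by the mutation-sensitivity check of the validation harness: a
#' faithful re-implementation must disagree with a copy whose decision
#' table differs in any single cell by one measurement resolution step
#' (1 mmHg for BP, 1 bpm for HR, 0.1 g/dL for Hb, 1 mg/dL for glucose,
#' 0.01 for the shock index ratio).
#'
#' @param thresholds a `triage_thresholds` object.
#' @param key band edge as `"section.key"`, e.g. `"bp.sbp_red"`.
#' @param steps signed number of resolution steps (default `1`).
#' @return the perturbed thresholds object.
#' @export
mutate_threshold <- function(thresholds, key, steps = 1) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2L || is.null(thresholds[[parts[1]]][[parts[2]]])) {
    stop("unknown threshold key: ", key)
  }
  res <- switch(parts[1],
    bp = if (startsWith(parts[2], "si_")) thresholds$resolution$si else thresholds$resolution$bp,
    hb = thresholds$resolution$hb,
    ogtt = thresholds$resolution$glucose,
    stop("only classifier band edges can be mutated: ", key)
  )
  thresholds[[parts[1]]][[parts[2]]] <- thresholds[[parts[1]]][[parts[2]]] + steps * res
  validate_thresholds(unclass(thresholds))
}

# every classifier band edge, as "section.key" strings (mutation targets)
threshold_edge_keys <- function() {
  c(paste0("bp.", required_threshold_keys$bp),
    paste0("hb.", required_threshold_keys$hb),
    paste0("ogtt.", required_threshold_keys$ogtt))
}

#' Load the referral / counseling recommendation catalogue
#'
#' Maps stable recommendation codes to the display text the health worker
#' sees. Codes, not texts, are the unit of comparison in validation.
#'
#' @param path CSV with columns `code,text`; `NULL` loads the packaged
#'   default catalogue.
#' @return data.frame with columns `code`, `text`.
#' @export
load_recommendations <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "recommendations.csv", package = "anctriage")
  }
  if (!file.exists(path)) stop("recommendation catalogue not found: ", path)
  cat <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("code", "text") %in% names(cat))) {
    stop("recommendation catalogue must have columns code,text")
  }
  if (!"HTN_SEVERE_URGENT" %in% cat$code) {
    stop("recommendation catalogue missing required code HTN_SEVERE_URGENT")
  }
  cat
}

recommendation_text <- function(codes, catalogue) {
  catalogue$text[match(codes, catalogue$code)]
}
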
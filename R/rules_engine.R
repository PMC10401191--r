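#' @name rules_engine
#' @title Traffic-light triage rules engine
#'
#' @description
#' Classifies each home-visit measurement set against the three priority
#' conditions of late-pregnancy community screening — hypertensive
#' disorders (blood pressure and shock index), anemia (hemoglobin), and
#' gestational diabetes (nonfasting 2-hour OGTT glucose) — on the ordered
#' GREEN/YELLOW/RED scale, and assembles referral and counseling
#' recommendations.
#'
#' The engine is table-driven: each classifier finds the band of each
#' reading with [findInterval()] against the cut points in the thresholds
#' config and takes the most severe band. Bands are lower-inclusive, so a
#' reading exactly at an edge takes the more severe color; classification
#' never silently defaults to GREEN — missing required readings are
#' errors.
NULL

#' Classify blood pressure and shock index
#'
#' The color is the worst of three criteria: systolic band, diastolic
#' band, and shock-index (HR/SBP) band.
#'
#' @param sbp,dbp systolic / diastolic blood pressure, mmHg.
#' @param heart_rate beats per minute.
#' @param thresholds a [load_thresholds()] object.
#' @return traffic-light factor, vectorized over inputs.
#' @export
classify_bp <- function(sbp, dbp, heart_rate, thresholds = load_thresholds()) {
  if (any(is.na(sbp)) || any(is.na(dbp)) || any(is.na(heart_rate))) {
    stop("classify_bp requires sbp, dbp and heart_rate")
  }
  si <- shock_index(heart_rate, sbp)
  b <- thresholds$bp
  band <- pmax(
    findInterval(sbp, c(b$sbp_yellow, b$sbp_red)),
    findInterval(dbp, c(b$dbp_yellow, b$dbp_red)),
    findInterval(si, c(b$si_yellow, b$si_red))
  )
  traffic_light(TRAFFIC_LEVELS[band + 1L])
}

#' Classify hemoglobin (anemia)
#'
#' @param hb hemoglobin, g/dL.
#' @inheritParams classify_bp
#' @return traffic-light factor: RED below the severe-anemia edge, YELLOW
#'   in the anemia band, GREEN at or above the normal edge.
#' @export
classify_hb <- function(hb, thresholds = load_thresholds()) {
  if (any(is.na(hb))) stop("classify_hb requires hb")
  h <- thresholds$hb
  band <- 2L - findInterval(hb, c(h$red_below, h$green_at_or_above))
  traffic_light(TRAFFIC_LEVELS[band + 1L])
}

#' Classify the 2-hour OGTT glucose (gestational diabetes screen)
#'
#' @param glucose_2h nonfasting 2-hour capillary glucose, mg/dL. A missing
#'   value is a "not screened" outcome, distinct from any color: the
#'   classifier errors, and [assess_visit()] records a missing-practice
#'   flag instead of a color.
#' @inheritParams classify_bp
#' @return traffic-light factor: YELLOW at or above the gestational
#'   diabetes edge, RED at or above the overt-diabetes edge.
#' @export
classify_ogtt <- function(glucose_2h, thresholds = load_thresholds()) {
  if (any(is.na(glucose_2h))) {
    stop("OGTT glucose missing: participant not screened (no color assigned)")
  }
  g <- thresholds$ogtt
  band <- findInterval(glucose_2h, c(g$yellow_at_or_above, g$red_at_or_above))
  traffic_light(TRAFFIC_LEVELS[band + 1L])
}

# Recommendation codes per condition colors; vectorized over cases.
# Ordering contract: RED items first, then YELLOW, then missing-practice
# prompts; stable within severity by condition order BP, Hb, GDM.
recommend_codes <- function(bp_color, hb_color, hb, gdm_color,
                            missing_practices = vector("list", length(bp_color)),
                            thresholds = load_thresholds()) {
  n <- length(bp_color)
  bp_s <- severity(bp_color)
  hb_s <- severity(hb_color)
  gdm_s <- severity(gdm_color)
  lapply(seq_len(n), function(i) {
    red <- c(
      if (bp_s[i] == 3L) "HTN_SEVERE_URGENT",
      if (hb_s[i] == 3L) "ANEMIA_SEVERE_URGENT",
      if (!is.na(gdm_s[i]) && gdm_s[i] == 3L) "DM_OVERT_URGENT"
    )
    yellow <- c(
      if (bp_s[i] == 2L) "HTN_REFER",
      if (hb_s[i] == 2L) {
        if (hb[i] < thresholds$hb$referral_below) "ANEMIA_REFER" else "ANEMIA_ADVICE"
      },
      if (!is.na(gdm_s[i]) && gdm_s[i] == 2L) "GDM_REFER"
    )
    c(red, yellow, missing_practices[[i]])
  })
}

#' Assess one visit against all three conditions
#'
#' Runs the per-condition classifiers, takes the most severe color as the
#' overall color, assembles the ordered recommendation list (urgent RED
#' items first, then YELLOW referrals, then missing-practice prompts), and
#' attaches the calculated variables.
#'
#' Missing-practice flags encode antenatal-care gaps visible from the
#' record: no gestational diabetes screening recorded, no OGTT on record
#' (including a week-6 postpartum visit without the repeat OGTT), no iron
#' and folic acid supply.
#'
#' @param participant one-row participant data.frame.
#' @param visit one-row visit data.frame for that participant.
#' @param thresholds a [load_thresholds()] object.
#' @param catalogue a [load_recommendations()] catalogue.
#' @return an object of class `"assessment"`: a list with the
#'   per-condition colors, `overall_color`, `recommendations`
#'   (data.frame of code + display text), `missing_practices`, and
#'   `derived` variables.
#' @export
assess_visit <- function(participant, visit, thresholds = load_thresholds(),
                         catalogue = load_recommendations()) {
  if (!identical(participant$participant_id, visit$participant_id)) {
    stop("visit does not belong to participant ", participant$participant_id)
  }
  bp <- tryCatch(
    classify_bp(visit$sbp, visit$dbp, visit$heart_rate, thresholds),
    error = function(e) stop("BP classification failed for ",
                             visit$participant_id, ": ", conditionMessage(e)))
  hb <- tryCatch(
    classify_hb(visit$hb, thresholds),
    error = function(e) stop("Hb classification failed for ",
                             visit$participant_id, ": ", conditionMessage(e)))
  screened <- !is.na(visit$ogtt_2h_glucose)
  gdm <- if (screened) classify_ogtt(visit$ogtt_2h_glucose, thresholds)
         else traffic_light(NA)

  missing <- character(0)
  if (isFALSE(visit$gdm_screened) && !screened) missing <- c(missing, "MISSING_GDM_SCREEN")
  if (!screened && !isTRUE(visit$ogtt_done)) missing <- c(missing, "MISSING_OGTT")
  if (isFALSE(visit$ifa_supplied)) missing <- c(missing, "MISSING_IFA")

  codes <- recommend_codes(bp, hb, visit$hb, gdm, list(missing), thresholds)[[1]]
  structure(list(
    participant_id = visit$participant_id,
    visit_type = visit$visit_type,
    visit_date = as.Date(visit$visit_date),
    bp_color = bp,
    hb_color = hb,
    gdm_color = gdm,
    overall_color = overall_color(bp, hb, gdm),
    recommendations = data.frame(code = codes,
                                 text = recommendation_text(codes, catalogue),
                                 stringsAsFactors = FALSE),
    missing_practices = missing,
    derived = derive_vars(participant, visit)
  ), class = "assessment")
}

#' @export
print.assessment <- function(x, ...) {
  cat(sprintf("<assessment> %s / %s on %s\n", x$participant_id, x$visit_type,
              format(x$visit_date)))
  cat(sprintf("  BP %s | Hb %s | GDM %s => overall %s\n",
              x$bp_color, x$hb_color,
              ifelse(is.na(x$gdm_color), "not screened", as.character(x$gdm_color)),
              x$overall_color))
  if (nrow(x$recommendations) > 0L) {
    cat(paste0("  - [", x$recommendations$code, "] ",
               x$recommendations$text, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.assessment <- function(x, ...) {
  d <- x$derived
  data.frame(
    participant_id = x$participant_id, visit_type = x$visit_type,
    visit_date = x$visit_date,
    bp_color = as.character(x$bp_color), hb_color = as.character(x$hb_color),
    gdm_color = as.character(x$gdm_color),
    overall_color = as.character(x$overall_color),
    recommendations = paste(x$recommendations$code, collapse = ";"),
    missing_practices = paste(x$missing_practices, collapse = ";"),
    age = d$age, bmi = d$bmi, gestational_age = d$gestational_age,
    edd = d$edd, shock_index = d$shock_index, postpartum_day = d$postpartum_day,
    stringsAsFactors = FALSE
  )
}

#' Assess every visit in a cohort
#'
#' @param participants,visits validated record tables
#'   ([read_participants()] / [read_visits()] or [simulate_cohort()]).
#' @inheritParams assess_visit
#' @return data.frame, one row per visit, re-writable with
#'   [write_assessments()].
#' @export
assess_cohort <- function(participants, visits, thresholds = load_thresholds(),
                          catalogue = load_recommendations()) {
  idx <- match(visits$participant_id, participants$participant_id)
  if (anyNA(idx)) {
    stop("visits reference unknown participant(s): ",
         paste(unique(visits$participant_id[is.na(idx)]), collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(visits)), function(i) {
    as.data.frame(assess_visit(participants[idx[i], , drop = FALSE],
                               visits[i, , drop = FALSE], thresholds, catalogue))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Is a gestational age within the enrolment window?
#'
#' Enrolment targets the last trimester, read as 28+0 through 36+6
#' completed weeks (196 through 258 days inclusive).
#'
#' @param ga_days gestational age in completed days.
#' @inheritParams classify_bp
#' @return logical vector.
#' @export
enrolment_eligible <- function(ga_days, thresholds = load_thresholds()) {
  w <- thresholds$windows
  ga_days >= w$enrol_min_days & ga_days <= w$enrol_max_days
}

#' Scheduled date window for a visit type
#'
#' Antenatal: 28+0 to 36+6 weeks from LMP. Postpartum week 1: delivery
#' through delivery + 7 days. Postpartum week 6: delivery + 36 through
#' delivery + 48 days (42 +/- 6).
#'
#' @param visit_type one of `"antenatal"`, `"postpartum_week1"`,
#'   `"postpartum_week6"`.
#' @param lmp_date LMP date (required for the antenatal window).
#' @param delivery_date delivery date (required for postpartum windows).
#' @inheritParams classify_bp
#' @return `Date` vector of length 2: `c(start, end)`, both inclusive.
#' @export
visit_window <- function(visit_type, lmp_date, delivery_date = NULL,
                         thresholds = load_thresholds()) {
  w <- thresholds$windows
  visit_type <- match.arg(visit_type, visit_types)
  if (visit_type == "antenatal") {
    lmp <- as.Date(lmp_date)
    return(c(lmp + w$enrol_min_days, lmp + w$enrol_max_days))
  }
  if (is.null(delivery_date) || is.na(delivery_date)) {
    stop("delivery_date required for postpartum visit windows")
  }
  del <- as.Date(delivery_date)
  switch(visit_type,
    postpartum_week1 = c(del + w$pp_week1_start, del + w$pp_week1_end),
    postpartum_week6 = c(del + w$pp_week6_start, del + w$pp_week6_end)
  )
}
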
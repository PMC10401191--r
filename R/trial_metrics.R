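#' @name trial_metrics
#' @title Feasibility, acceptability and clinical summaries
#'
#' @description
#' Recomputes the pilot-trial result surface from any cohort in the
#' records schema (real or simulated): recruitment speed per cluster,
#' retention, fidelity to the scheduled visit protocol, prevalence of the
#' three priority conditions, gestational-diabetes screening coverage,
#' and the arm-comparison table of means (SD) with two-sided p-values.
NULL

#' Retention (loss to follow-up) summary
#'
#' @param flow data.frame with one row per arm and columns `enrolled`,
#'   `lost` (as produced by [simulate_cohort()]).
#' @return list with `lost`, `enrolled`, `percent` (0-100, full
#'   precision) and `percent_display` (whole-percent rounding).
#' @export
retention_summary <- function(flow) {
  enrolled <- sum(flow$enrolled)
  lost <- sum(flow$lost)
  if (enrolled <= 0) stop("retention undefined for zero enrolled")
  pct <- 100 * lost / enrolled
  list(lost = lost, enrolled = enrolled, percent = pct,
       percent_display = round_half_up(pct))
}

#' Prevalence of a priority condition
#'
#' Operationalized through the rules engine, since the source protocol
#' gives no separate diagnostic algorithm:
#' * `anemia_lt10` — hemoglobin below the referral line (10.0 g/dL) at
#'   the baseline (antenatal) visit;
#' * `hdp` — any blood-pressure classification of YELLOW or worse during
#'   pregnancy (antenatal visits);
#' * `gdm` — any OGTT classification of YELLOW or worse.
#'
#' @param participants,visits record tables.
#' @param condition one of `"anemia_lt10"`, `"hdp"`, `"gdm"`.
#' @param arm `"both"` (default), `"intervention"` or `"control"`; the
#'   denominator is the number of participants in scope.
#' @param thresholds a [load_thresholds()] object.
#' @return list with `numerator`, `denominator`, `percent`.
#' @export
prevalence <- function(participants, visits,
                       condition = c("anemia_lt10", "hdp", "gdm"),
                       arm = c("both", "intervention", "control"),
                       thresholds = load_thresholds()) {
  condition <- match.arg(condition)
  arm <- match.arg(arm)
  if (arm != "both") participants <- participants[participants$arm == arm, ]
  if (nrow(participants) == 0L) stop("empty scope: no participants in arm ", arm)
  visits <- visits[visits$participant_id %in% participants$participant_id, ]

  flagged <- switch(condition,
    anemia_lt10 = {
      v <- visits[visits$visit_type == "antenatal", ]
      v$participant_id[v$hb < thresholds$hb$referral_below]
    },
    hdp = {
      v <- visits[visits$visit_type == "antenatal", ]
      col <- classify_bp(v$sbp, v$dbp, v$heart_rate, thresholds)
      v$participant_id[col >= traffic_light("YELLOW")]
    },
    gdm = {
      v <- visits[!is.na(visits$ogtt_2h_glucose), ]
      if (nrow(v) == 0L) character(0) else {
        col <- classify_ogtt(v$ogtt_2h_glucose, thresholds)
        v$participant_id[col >= traffic_light("YELLOW")]
      }
    })
  num <- length(unique(flagged))
  den <- nrow(participants)
  list(numerator = num, denominator = den, percent = 100 * num / den)
}

#' Expected visit schedule for fidelity assessment
#'
#' One row per scheduled visit: the three protocol visits (antenatal,
#' postpartum week 1, postpartum week 6) for every participant in scope.
#' Fidelity is a property of intervention delivery, so the default scope
#' is the intervention arm.
#'
#' @param participants participant table.
#' @param arm arm in scope (default `"intervention"`; `"both"` for all).
#' @return data.frame with columns `participant_id`, `visit_type`.
#' @export
expected_schedule <- function(participants, arm = "intervention") {
  if (arm != "both") participants <- participants[participants$arm == arm, ]
  expand.grid(participant_id = participants$participant_id,
              visit_type = visit_types, stringsAsFactors = FALSE,
              KEEP.OUT.ATTRS = FALSE)
}

#' Fidelity to the visit protocol
#'
#' Percent of scheduled visit entries that exist and were entered complete
#' and on time (the `entry_complete` and `entry_on_time` flags; on-time
#' means the visit date fell inside its [visit_window()]).
#'
#' @param visits visit table.
#' @param schedule expected visits ([expected_schedule()]).
#' @return list with `n_expected`, `n_ok`, `percent`.
#' @export
fidelity_summary <- function(visits, schedule) {
  if (nrow(schedule) == 0L) stop("empty schedule")
  key <- function(d) paste(d$participant_id, d$visit_type, sep = "\r")
  ok_vis <- visits[visits$entry_complete & visits$entry_on_time, ]
  n_ok <- sum(key(schedule) %in% key(ok_vis))
  list(n_expected = nrow(schedule), n_ok = n_ok,
       percent = 100 * n_ok / nrow(schedule))
}

#' Gestational-diabetes screening coverage
#'
#' Percent of participants whose record carries `gdm_screened = TRUE`
#' (screened before 28 weeks) and percent with `ogtt_done = TRUE` (a
#' prior oral glucose tolerance test reported), read off the antenatal
#' visit flags.
#'
#' @param participants,visits record tables.
#' @return list with `n`, `gdm_screened_percent`, `ogtt_done_percent` and
#'   the numerators.
#' @export
screening_summary <- function(participants, visits) {
  n <- nrow(participants)
  if (n == 0L) stop("no participants")
  v <- visits[visits$visit_type == "antenatal", ]
  idx <- match(participants$participant_id, v$participant_id)
  scr <- sum(v$gdm_screened[idx], na.rm = TRUE)
  ogt <- sum(v$ogtt_done[idx], na.rm = TRUE)
  list(n = n, gdm_screened = scr, ogtt_done = ogt,
       gdm_screened_percent = 100 * scr / n,
       ogtt_done_percent = 100 * ogt / n,
       gdm_screened_display = round_half_up(100 * scr / n),
       ogtt_done_display = round_half_up(100 * ogt / n))
}

# display rounding follows the usual half-up convention of clinical
# tables (18.5% prints as 19%), not IEC round-half-even
round_half_up <- function(x, digits = 0) {
  floor(x * 10^digits + 0.5) / 10^digits
}

# Welch's unequal-variance t-test, the package's single comparison choice;
# swap here to change the whole table. NA when degenerate.
welch_p <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) return(NA_real_)
  tryCatch(stats::t.test(x, y)$p.value, error = function(e) NA_real_)
}

format_p <- function(p) {
  ifelse(is.na(p), "NC",
         ifelse(p > 0.99, ">.99", sub("^0", "", sprintf("%.2f", p))))
}

#' Arm-comparison table of means (SD) and p-values
#'
#' Baseline demographics (age, BMI, schooling, household size, booking
#' hemoglobin), baseline study-visit measurements, and end-line (week-6)
#' measurements, per arm, with a two-sided Welch unequal-variance t-test
#' p-value per variable. Display conventions: 1 decimal for means/SDs,
#' p to 2 decimals with `>.99` for near-1 values and `NC` when the test
#' is not computable (degenerate variance).
#'
#' @param participants,visits record tables.
#' @return data.frame with columns `variable`, `intervention_mean/sd`,
#'   `control_mean/sd`, `p_value` (numeric), `p_display`.
#' @export
comparison_table <- function(participants, visits) {
  p <- participants
  p$age <- age_years(p$date_of_birth, p$registration_date)
  p$bmi <- bmi(p$weight_kg, p$height_m)
  pull_visit <- function(type, col) {
    v <- visits[visits$visit_type == type, ]
    v[[col]][match(p$participant_id, v$participant_id)]
  }
  vars <- list(
    age = p$age,
    bmi = p$bmi,
    schooling_years = p$schooling_years,
    household_size = p$household_size,
    booking_hb = p$booking_hb,
    baseline_hb = pull_visit("antenatal", "hb"),
    baseline_sbp = pull_visit("antenatal", "sbp"),
    baseline_dbp = pull_visit("antenatal", "dbp"),
    endline_hb = pull_visit("postpartum_week6", "hb"),
    endline_sbp = pull_visit("postpartum_week6", "sbp"),
    endline_dbp = pull_visit("postpartum_week6", "dbp")
  )
  int <- p$arm == "intervention"
  rows <- lapply(names(vars), function(nm) {
    x <- vars[[nm]][int]; y <- vars[[nm]][!int]
    if (sum(!is.na(x)) < 2L || sum(!is.na(y)) < 2L) {
      stop("comparison_table needs >= 2 observations per arm for ", nm)
    }
    pv <- welch_p(x, y)
    data.frame(
      variable = nm,
      intervention_mean = round(mean(x, na.rm = TRUE), 1),
      intervention_sd = round(stats::sd(x, na.rm = TRUE), 1),
      control_mean = round(mean(y, na.rm = TRUE), 1),
      control_sd = round(stats::sd(y, na.rm = TRUE), 1),
      p_value = pv, p_display = format_p(pv),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Recruitment speed per cluster
#'
#' Days from first to last registration in each cluster and the implied
#' monthly recruitment rate (n per 30.44-day month). A cluster with fewer
#' than 2 registrations, or zero elapsed days, gets an `NA` rate.
#'
#' @param participants participant table.
#' @return data.frame with `cluster_id`, `n`, `days`, `per_month`.
#' @export
recruitment_summary <- function(participants) {
  if (any(is.na(participants$registration_date)) ||
      any(is.na(participants$cluster_id))) {
    stop("recruitment_summary requires registration_date and cluster_id")
  }
  sp <- split(participants, participants$cluster_id)
  rows <- lapply(names(sp), function(cid) {
    d <- sp[[cid]]
    days <- if (nrow(d) < 2L) NA_real_ else
      as.numeric(max(d$registration_date) - min(d$registration_date))
    rate <- if (is.na(days) || days <= 0) NA_real_ else nrow(d) / (days / 30.44)
    data.frame(cluster_id = cid, n = nrow(d), days = days, per_month = rate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full trial summary
#'
#' Assembles every feasibility / acceptability / clinical metric into one
#' object mirroring a pilot-trial results section.
#'
#' @param participants,visits record tables.
#' @param flow per-arm flow table (`NULL` derives it: lost = enrolled
#'   participants without a week-6 visit).
#' @param thresholds a [load_thresholds()] object.
#' @return list of class `"trial_summary"`.
#' @export
trial_summary <- function(participants, visits, flow = NULL,
                          thresholds = load_thresholds()) {
  if (is.null(flow)) {
    has6 <- participants$participant_id %in%
      visits$participant_id[visits$visit_type == "postpartum_week6"]
    flow <- do.call(rbind, lapply(split(data.frame(has6 = has6,
                                                   arm = participants$arm),
                                        participants$arm), function(d) {
      data.frame(arm = d$arm[1], enrolled = nrow(d), lost = sum(!d$has6),
                 completed = sum(d$has6), stringsAsFactors = FALSE)
    }))
    rownames(flow) <- NULL
  }
  structure(list(
    recruitment = recruitment_summary(participants),
    retention = retention_summary(flow),
    fidelity = fidelity_summary(visits, expected_schedule(participants)),
    prevalence = list(
      anemia_baseline_intervention =
        prevalence(participants, visits, "anemia_lt10", "intervention", thresholds),
      anemia_baseline_control =
        prevalence(participants, visits, "anemia_lt10", "control", thresholds),
      hdp = prevalence(participants, visits, "hdp", "both", thresholds),
      gdm = prevalence(participants, visits, "gdm", "both", thresholds)
    ),
    screening = screening_summary(participants, visits),
    comparison = comparison_table(participants, visits),
    flow = flow
  ), class = "trial_summary")
}

#' @export
print.trial_summary <- function(x, ...) {
  fr <- function(p) sprintf("%g%% (%d/%d)", round(p$percent, 1), p$numerator,
                            p$denominator)
  cat("Recruitment (per cluster):\n")
  print(x$recruitment, row.names = FALSE, digits = 3)
  cat(sprintf("Retention: %d/%d lost to follow-up (%d%%)\n",
              x$retention$lost, x$retention$enrolled, x$retention$percent_display))
  cat(sprintf("Fidelity: %d/%d scheduled entries complete and on time (%g%%)\n",
              x$fidelity$n_ok, x$fidelity$n_expected, round(x$fidelity$percent, 2)))
  cat("Prevalence: anemia (<10 g/dL, baseline) ",
      fr(x$prevalence$anemia_baseline_intervention), " intervention, ",
      fr(x$prevalence$anemia_baseline_control), " control; HDP ",
      fr(x$prevalence$hdp), "; GDM ", fr(x$prevalence$gdm), "\n", sep = "")
  cat(sprintf("Screening: %g%% screened for GDM, %g%% had an OGTT\n",
              x$screening$gdm_screened_display,
              x$screening$ogtt_done_display))
  cat("Arm comparison, mean (SD) and Welch p:\n")
  tb <- x$comparison
  cat(sprintf("  %-16s %6.1f (%4.1f)  %6.1f (%4.1f)  %s\n", tb$variable,
              tb$intervention_mean, tb$intervention_sd, tb$control_mean,
              tb$control_sd, tb$p_display), sep = "")
  invisible(x)
}
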
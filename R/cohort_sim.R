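#' @name cohort_sim
#' @title Synthetic two-arm cluster-trial cohort simulator
#'
#' @description
#' Generates a complete synthetic pilot-trial cohort — participants,
#' scheduled home visits with measurements, and the participant flow —
#' emulating a two-arm, four-cluster (two states, one intervention and
#' one control facility per state) pregnancy cohort of 100 women per arm.
#'
#' Continuous variables are drawn from truncated normal distributions at
#' the configured moments; dichotomized quantities (anemia below the
#' 10 g/dL line, hypertensive and gestational-diabetes cases, screening
#' flags, loss to follow-up) are enforced EXACTLY by rank-based
#' assignment, so that downstream proportions recompute to the configured
#' numerator/denominator pairs exactly, not merely in expectation.
NULL

# inverse-CDF truncated normal; lo/hi may be vectors
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# shift + clamp so that exactly k of x fall strictly below cutoff after
# rounding to `digits`; rank order is preserved
enforce_count_below <- function(x, k, cutoff, digits = 1) {
  n <- length(x)
  stopifnot(k >= 0, k <= n)
  xs <- sort(x)
  lo_edge <- if (k >= 1) xs[k] else xs[1] - 1
  hi_edge <- if (k < n) xs[k + 1] else xs[n] + 1
  x <- round(x + (cutoff - (lo_edge + hi_edge) / 2), digits)
  step <- 10^-digits
  ord <- order(x)
  below <- ord[seq_len(k)]
  above <- if (k < n) ord[(k + 1):n] else integer(0)
  x[below] <- pmin(x[below], cutoff - step)
  x[above] <- pmax(x[above], cutoff)
  x
}

#' Default simulation configuration
#'
#' Every field is populated from the pilot trial this simulator emulates:
#' 100 women per arm across 2 clusters per arm; baseline age 23.5 (3.5) /
#' 24.0 (3.6) years, BMI 22.6 (4.0) / 22.1 (4.1) kg/m^2, schooling 12.2
#' (3.7) / 12.4 (4.0) years, household size 4.9 (2.1) / 4.8 (1.9),
#' booking hemoglobin 9.6 (1.4) / 9.4 (1.4) g/dL, baseline study-visit
#' hemoglobin 9.9 (1.7) / 9.6 (1.7) g/dL, baseline BP 108/70 mmHg in both
#' arms; end-line hemoglobin 11.1 (1.7) / 10.3 (1.7) g/dL and end-line BP
#' 110/72 vs 112/73 mmHg (intervention / control throughout). Exact
#' counts: baseline anemia below 10 g/dL in 47 / 58 women, 5 hypertensive
#' and 4 gestational-diabetes cases study-wide, 163/200 screened for
#' gestational diabetes, 37/200 with a prior OGTT, 4 control-arm women
#' (2 per state) lost to follow-up, 100% visit fidelity. Heart rate
#' moments (82, SD 10 bpm) are a realistic third-trimester resting choice;
#' they are not part of the emulated baseline table.
#'
#' @param seed integer seed stored in the config.
#' @return a list of class `"sim_config"`; arm-indexed fields are named
#'   vectors `c(intervention = , control = )`.
#' @export
default_sim_config <- function(seed = 1L) {
  cfg <- list(
    n_per_arm = 100L,
    clusters = data.frame(
      cluster_id = c("PHC-HR-INT", "PHC-AP-INT", "PHC-HR-CON", "PHC-AP-CON"),
      arm = c("intervention", "intervention", "control", "control"),
      recruit_days = c(50, 128, 90, 115),   # spans the observed 50-128 day range
      stringsAsFactors = FALSE
    ),
    study_start = as.Date("2019-10-01"),
    age_mean = c(intervention = 23.5, control = 24.0),
    age_sd = c(intervention = 3.5, control = 3.6),
    bmi_mean = c(intervention = 22.6, control = 22.1),
    bmi_sd = c(intervention = 4.0, control = 4.1),
    schooling_mean = c(intervention = 12.2, control = 12.4),
    schooling_sd = c(intervention = 3.7, control = 4.0),
    household_mean = c(intervention = 4.9, control = 4.8),
    household_sd = c(intervention = 2.1, control = 1.9),
    booking_hb_mean = c(intervention = 9.6, control = 9.4),
    booking_hb_sd = c(intervention = 1.4, control = 1.4),
    baseline_hb_mean = c(intervention = 9.9, control = 9.6),
    baseline_hb_sd = c(intervention = 1.7, control = 1.7),
    baseline_sbp_mean = c(intervention = 108, control = 108),
    baseline_sbp_sd = c(intervention = 11.3, control = 12.4),
    baseline_dbp_mean = c(intervention = 70, control = 70),
    baseline_dbp_sd = c(intervention = 8.5, control = 9.0),
    endline_hb_mean = c(intervention = 11.1, control = 10.3),
    endline_hb_sd = c(intervention = 1.7, control = 1.7),
    endline_sbp_mean = c(intervention = 110, control = 112),
    endline_sbp_sd = c(intervention = 11.6, control = 13.4),
    endline_dbp_mean = c(intervention = 72, control = 73),
    endline_dbp_sd = c(intervention = 8.2, control = 11.9),
    hr_mean = 82, hr_sd = 10,
    anemia_count = c(intervention = 47L, control = 58L),
    hdp_count = c(intervention = 2L, control = 3L),     # 5/200 study-wide
    gdm_count = c(intervention = 2L, control = 2L),     # 4/200 study-wide
    gdm_screened_count = c(intervention = 82L, control = 81L),  # 163/200
    ogtt_done_count = c(intervention = 19L, control = 18L),     # 37/200
    ifa_count = c(intervention = 90L, control = 90L),
    ltfu_count = c(intervention = 0L, control = 4L),
    fidelity = 1.0,
    endline_gap = FALSE,                   # pandemic end-line gaps, off by default
    endline_missing_count = c(intervention = 22L, control = 34L),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  n <- cfg$n_per_arm
  stopifnot(n >= 1)
  for (f in c("anemia_count", "hdp_count", "gdm_count", "gdm_screened_count",
              "ogtt_done_count", "ifa_count", "ltfu_count")) {
    if (any(cfg[[f]] < 0) || any(cfg[[f]] > n)) {
      stop("infeasible config: ", f, " must lie in [0, n_per_arm]")
    }
  }
  sds <- grep("_sd$", names(cfg), value = TRUE)
  if (any(unlist(cfg[sds]) <= 0) || cfg$hr_sd <= 0) stop("all SDs must be > 0")
  if (cfg$fidelity < 0 || cfg$fidelity > 1) stop("fidelity must be in [0, 1]")
  if (!all(table(cfg$clusters$arm) == 2L)) stop("config needs 2 clusters per arm")
  if (n %% 2L != 0L) stop("n_per_arm must split evenly across 2 clusters")
  structure(cfg, class = c("sim_config", "list"))
}

# evenly spread integer dates over [start, start + span] hitting both ends
spread_dates <- function(start, span, n) {
  if (n == 1L) return(start)
  offs <- sort(c(0, span, sample(0:span, n - 2L, replace = TRUE)))
  start + offs
}

# k TRUE positions out of n, chosen at random but exactly k
exact_flags <- function(n, k) {
  f <- rep(FALSE, n)
  if (k > 0) f[sample.int(n, k)] <- TRUE
  f
}

#' Simulate a two-arm trial cohort
#'
#' @param config a [default_sim_config()] list (fields may be edited
#'   before the call; the config re-validates).
#' @param thresholds a [load_thresholds()] object (used to place
#'   hypertensive / gestational-diabetes cases inside the YELLOW bands and
#'   everyone else strictly inside GREEN, so prevalence recomputed through
#'   the rules engine agrees with the configured labels).
#' @return list of class `"sim_cohort"` with `participants`, `visits`
#'   (readable/writable via the records module) and `flow` (one row per
#'   arm: enrolled, completed, lost). Deterministic per `config$seed`.
#' @export
simulate_cohort <- function(config = default_sim_config(),
                            thresholds = load_thresholds()) {
  cfg <- validate_sim_config(config)
  with_seed(cfg$seed, {
    arms <- c("intervention", "control")
    parts <- list(); vis <- list()
    for (arm in arms) {
      n <- cfg$n_per_arm
      prefix <- if (arm == "intervention") "I" else "C"
      ids <- sprintf("%s-%03d", prefix, seq_len(n))
      cl <- cfg$clusters[cfg$clusters$arm == arm, ]
      cluster_id <- rep(cl$cluster_id, each = n / 2L)
      reg <- as.Date(rep(NA, n))
      for (j in 1:2) {
        rows <- which(cluster_id == cl$cluster_id[j])
        reg[rows] <- spread_dates(cfg$study_start, cl$recruit_days[j], length(rows))
      }
      ga_reg <- sample(thresholds$windows$enrol_min_days:thresholds$windows$enrol_max_days,
                       n, replace = TRUE)
      lmp <- reg - ga_reg
      delivery_ga <- round(rtrunc_norm(n, 280, 8, 262, 292))
      delivery <- lmp + delivery_ga

      age <- round(rtrunc_norm(n, cfg$age_mean[arm], cfg$age_sd[arm], 16, 42))
      dob <- reg - round(age * 365.2425) - sample(0:360, n, replace = TRUE)
      height <- round(rtrunc_norm(n, 1.56, 0.06, 1.40, 1.80), 2)
      bmi_v <- rtrunc_norm(n, cfg$bmi_mean[arm], cfg$bmi_sd[arm], 14, 42)
      weight <- round(bmi_v * height^2, 1)
      schooling <- pmax(0L, round(rtrunc_norm(n, cfg$schooling_mean[arm],
                                              cfg$schooling_sd[arm], 0, 20)))
      household <- pmax(1L, round(rtrunc_norm(n, cfg$household_mean[arm],
                                              cfg$household_sd[arm], 1, 14)))
      booking_hb <- round(rtrunc_norm(n, cfg$booking_hb_mean[arm],
                                      cfg$booking_hb_sd[arm], 4, 16), 1)

      # baseline study-visit Hb with the anemia count enforced exactly
      hb0 <- rtrunc_norm(n, cfg$baseline_hb_mean[arm], cfg$baseline_hb_sd[arm], 4, 16)
      hb0 <- enforce_count_below(hb0, cfg$anemia_count[arm],
                                 thresholds$hb$referral_below)

      # blood pressure: everyone strictly GREEN except the HDP cases,
      # placed in the YELLOW hypertension band at the antenatal visit
      b <- thresholds$bp
      sbp0 <- round(rtrunc_norm(n, cfg$baseline_sbp_mean[arm],
                                cfg$baseline_sbp_sd[arm], 85, b$sbp_yellow - 1))
      dbp0 <- round(rtrunc_norm(n, cfg$baseline_dbp_mean[arm],
                                cfg$baseline_dbp_sd[arm], 45, b$dbp_yellow - 2))
      dbp0 <- pmin(dbp0, sbp0 - 10)
      hr0 <- round(rtrunc_norm(n, cfg$hr_mean, cfg$hr_sd, 55,
                               pmin(115, b$si_yellow * sbp0 - 2)))
      hdp <- exact_flags(n, cfg$hdp_count[arm])
      sbp0[hdp] <- sample((b$sbp_yellow + 2):(b$sbp_red - 4),
                          sum(hdp), replace = TRUE)
      dbp0[hdp] <- sample((b$dbp_yellow + 2):(b$dbp_red - 6),
                          sum(hdp), replace = TRUE)

      # everyone receives a home OGTT at the antenatal visit; GDM cases
      # sit inside the YELLOW band, everyone else strictly below it
      g <- thresholds$ogtt
      gdm <- exact_flags(n, cfg$gdm_count[arm])
      ogtt0 <- round(rtrunc_norm(n, 105, 15, 60, g$yellow_at_or_above - 1))
      ogtt0[gdm] <- sample((g$yellow_at_or_above + 5):(g$red_at_or_above - 15),
                           sum(gdm), replace = TRUE)

      gdm_screened <- exact_flags(n, cfg$gdm_screened_count[arm])
      ogtt_done <- exact_flags(n, cfg$ogtt_done_count[arm])
      ifa <- exact_flags(n, cfg$ifa_count[arm])

      parts[[arm]] <- data.frame(
        participant_id = ids, cluster_id = cluster_id, arm = arm,
        date_of_birth = dob, registration_date = reg,
        height_m = height, weight_kg = weight, lmp_date = lmp,
        delivery_date = delivery, schooling_years = as.integer(schooling),
        household_size = as.integer(household), booking_hb = booking_hb,
        stringsAsFactors = FALSE
      )

      # loss to follow-up: no end-line (week-6) visit; 2 per control cluster
      lost <- rep(FALSE, n)
      for (j in 1:2) {
        rows <- which(cluster_id == cl$cluster_id[j])
        k <- cfg$ltfu_count[arm] %/% 2L + (j == 1L) * (cfg$ltfu_count[arm] %% 2L)
        if (k > 0) lost[sample(rows, k)] <- TRUE
      }

      # postpartum measurements (all strictly GREEN; hypertension and
      # glucose have normalized after delivery in this stated world)
      hb1 <- pmin(16, pmax(4, round(hb0 + stats::rnorm(n, 0.2, 0.4), 1)))
      sbp1 <- round(rtrunc_norm(n, cfg$baseline_sbp_mean[arm],
                                cfg$baseline_sbp_sd[arm], 85, b$sbp_yellow - 1))
      dbp1 <- pmin(round(rtrunc_norm(n, cfg$baseline_dbp_mean[arm],
                                     cfg$baseline_dbp_sd[arm], 45, b$dbp_yellow - 2)),
                   sbp1 - 10)
      hr1 <- round(rtrunc_norm(n, cfg$hr_mean, cfg$hr_sd, 55,
                               pmin(115, b$si_yellow * sbp1 - 2)))
      hb6 <- round(rtrunc_norm(n, cfg$endline_hb_mean[arm],
                               cfg$endline_hb_sd[arm], 4, 17), 1)
      sbp6 <- round(rtrunc_norm(n, cfg$endline_sbp_mean[arm],
                                cfg$endline_sbp_sd[arm], 85, b$sbp_yellow - 1))
      dbp6 <- pmin(round(rtrunc_norm(n, cfg$endline_dbp_mean[arm],
                                     cfg$endline_dbp_sd[arm], 45, b$dbp_yellow - 2)),
                   sbp6 - 10)
      hr6 <- round(rtrunc_norm(n, cfg$hr_mean, cfg$hr_sd, 55,
                               pmin(115, b$si_yellow * sbp6 - 2)))

      visit_row <- function(type, date, sbp, dbp, hr, hb, ogtt, keep) {
        data.frame(
          participant_id = ids[keep], visit_type = type, visit_date = date[keep],
          sbp = sbp[keep], dbp = dbp[keep], heart_rate = hr[keep], hb = hb[keep],
          ogtt_2h_glucose = ogtt[keep],
          gdm_screened = gdm_screened[keep], ogtt_done = ogtt_done[keep],
          ifa_supplied = ifa[keep],
          entry_complete = TRUE, entry_on_time = TRUE,
          stringsAsFactors = FALSE
        )
      }
      all_rows <- rep(TRUE, n)
      keep6 <- !lost
      if (isTRUE(cfg$endline_gap)) {
        avail <- which(keep6)
        k <- min(cfg$endline_missing_count[arm], length(avail))
        if (k > 0) keep6[sample(avail, k)] <- FALSE
      }
      vis[[paste0(arm, "_ante")]] <- visit_row("antenatal", reg, sbp0, dbp0,
                                               hr0, hb0, ogtt0, all_rows)
      vis[[paste0(arm, "_pp1")]] <- visit_row("postpartum_week1", delivery + 3,
                                              sbp1, dbp1, hr1, hb1,
                                              rep(NA_real_, n), all_rows)
      vis[[paste0(arm, "_pp6")]] <- visit_row("postpartum_week6", delivery + 42,
                                              sbp6, dbp6, hr6, hb6,
                                              rep(NA_real_, n), keep6)
      attr(parts[[arm]], "lost") <- ids[lost]
    }

    participants <- do.call(rbind, unname(lapply(parts, identity)))
    visits <- do.call(rbind, unname(vis))
    visits <- visits[order(match(visits$participant_id, participants$participant_id),
                           match(visits$visit_type, visit_types)), ]
    rownames(participants) <- rownames(visits) <- NULL

    # imperfect-fidelity option: mark a fraction of intervention entries late
    if (cfg$fidelity < 1) {
      ivis <- which(visits$participant_id %in%
                      participants$participant_id[participants$arm == "intervention"])
      k <- round((1 - cfg$fidelity) * length(ivis))
      if (k > 0) visits$entry_on_time[sample(ivis, k)] <- FALSE
    }

    lost_ids <- c(attr(parts$intervention, "lost"), attr(parts$control, "lost"))
    flow <- data.frame(
      arm = arms,
      enrolled = rep(cfg$n_per_arm, 2L),
      lost = c(length(attr(parts$intervention, "lost")),
               length(attr(parts$control, "lost"))),
      stringsAsFactors = FALSE
    )
    flow$completed <- flow$enrolled - flow$lost
    flow$reason <- ifelse(flow$lost > 0, "moved out of area postpartum", "")

    structure(list(participants = participants, visits = visits, flow = flow,
                   lost_ids = lost_ids, config = cfg),
              class = "sim_cohort")
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d participants (%s), %d visits, seed %d\n",
              nrow(x$participants),
              paste(table(x$participants$arm), collapse = " + "),
              nrow(x$visits), x$config$seed))
  print(x$flow, row.names = FALSE)
  invisible(x)
}

#' Write a simulated cohort to a directory
#'
#' Writes `participants.csv`, `visits.csv` and `flow.json`.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_participants(cohort$participants, file.path(dir, "participants.csv"))
  write_visits(cohort$visits, file.path(dir, "visits.csv"))
  jsonlite::write_json(list(flow = cohort$flow, lost_ids = cohort$lost_ids,
                            seed = cohort$config$seed),
                       file.path(dir, "flow.json"), auto_unbox = TRUE,
                       dataframe = "rows", pretty = TRUE)
  invisible(dir)
}

#' Read a simulated (or real, same-schema) cohort directory
#'
#' @param dir directory holding `participants.csv`, `visits.csv` and
#'   optionally `flow.json`.
#' @return list with `participants`, `visits`, `flow` (`NULL` if absent).
#' @export
read_cohort <- function(dir) {
  pfile <- file.path(dir, "participants.csv")
  vfile <- file.path(dir, "visits.csv")
  if (!file.exists(pfile) || !file.exists(vfile)) {
    stop("cohort directory must contain participants.csv and visits.csv: ", dir)
  }
  flow <- NULL
  ffile <- file.path(dir, "flow.json")
  if (file.exists(ffile)) {
    fj <- jsonlite::read_json(ffile, simplifyVector = TRUE)
    flow <- as.data.frame(fj$flow, stringsAsFactors = FALSE)
  }
  list(participants = read_participants(pfile), visits = read_visits(vfile),
       flow = flow)
}
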
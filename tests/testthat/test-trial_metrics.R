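test_that("retention summary computes lost/enrolled percents", {
  flow <- data.frame(arm = c("intervention", "control"),
                     enrolled = c(100, 100), lost = c(0, 4))
  r <- retention_summary(flow)
  expect_identical(r$lost, 4)
  expect_equal(r$percent, 2)
  expect_identical(r$percent_display, 2)
  flow$lost <- c(0, 0)
  expect_equal(retention_summary(flow)$percent, 0)
  flow$lost <- flow$enrolled
  expect_equal(retention_summary(flow)$percent, 100)
  expect_error(retention_summary(data.frame(enrolled = 0, lost = 0)), "zero")
})

test_that("prevalence recomputes the configured fractions from the cohort", {
  co <- sim_default()
  an_i <- prevalence(co$participants, co$visits, "anemia_lt10", "intervention", TH)
  expect_identical(an_i$numerator, 47L)
  expect_identical(an_i$denominator, 100L)
  expect_equal(an_i$percent, 47)
  an_c <- prevalence(co$participants, co$visits, "anemia_lt10", "control", TH)
  expect_equal(an_c$percent, 58)
  hdp <- prevalence(co$participants, co$visits, "hdp", "both", TH)
  expect_identical(c(hdp$numerator, hdp$denominator), c(5L, 200L))
  expect_equal(hdp$percent, 2.5)
  gdm <- prevalence(co$participants, co$visits, "gdm", "both", TH)
  expect_equal(gdm$percent, 2)
  # zero-case cohort and empty scope
  clean <- co$visits
  clean$hb <- 12
  expect_equal(prevalence(co$participants, clean, "anemia_lt10", "both", TH)$percent, 0)
  expect_error(prevalence(co$participants[0, ], co$visits, "hdp", "both", TH),
               "empty scope")
})

test_that("fidelity is the fraction of scheduled entries complete and on time", {
  co <- sim_default()
  sched <- expected_schedule(co$participants)           # intervention arm
  expect_identical(nrow(sched), 300L)
  f <- fidelity_summary(co$visits, sched)
  expect_equal(f$percent, 100)
  # one missing visit among 300 expected -> 99.67%
  iv <- co$visits[co$visits$participant_id %in%
                    co$participants$participant_id[co$participants$arm ==
                                                     "intervention"], ]
  f2 <- fidelity_summary(iv[-1, ], sched)
  expect_equal(f2$percent, 100 * 299 / 300, tolerance = 1e-6)
  expect_equal(round(f2$percent, 2), 99.67)
  # empty visit set -> 0%
  expect_equal(fidelity_summary(iv[0, ], sched)$percent, 0)
  expect_error(fidelity_summary(iv, sched[0, ]), "empty")
  # late or incomplete entries do not count
  iv2 <- iv
  iv2$entry_on_time[1] <- FALSE
  expect_equal(fidelity_summary(iv2, sched)$n_ok, 299L)
})

test_that("screening summary reproduces 82% screened / 19% OGTT", {
  co <- sim_default()
  s <- screening_summary(co$participants, co$visits)
  expect_identical(s$gdm_screened, 163L)
  expect_identical(s$ogtt_done, 37L)
  expect_equal(s$gdm_screened_percent, 81.5)
  expect_identical(s$gdm_screened_display, 82)   # half-up display convention
  expect_equal(s$ogtt_done_percent, 18.5)
  expect_identical(s$ogtt_done_display, 19)
  # degenerate all-true / all-false
  v <- co$visits
  v$gdm_screened <- TRUE; v$ogtt_done <- TRUE
  s2 <- screening_summary(co$participants, v)
  expect_equal(c(s2$gdm_screened_percent, s2$ogtt_done_percent), c(100, 100))
  v$gdm_screened <- FALSE; v$ogtt_done <- FALSE
  s3 <- screening_summary(co$participants, v)
  expect_equal(c(s3$gdm_screened_percent, s3$ogtt_done_percent), c(0, 0))
})

test_that("comparison table: display conventions and degenerate cases", {
  co <- sim_default()
  tb <- comparison_table(co$participants, co$visits)
  expect_setequal(
    tb$variable,
    c("age", "bmi", "schooling_years", "household_size", "booking_hb",
      "baseline_hb", "baseline_sbp", "baseline_dbp",
      "endline_hb", "endline_sbp", "endline_dbp"))
  expect_true(all(tb$p_value >= 0 & tb$p_value <= 1, na.rm = TRUE))
  expect_true(all(grepl("^(\\.\\d{2}|>\\.99|NC)$", tb$p_display)))

  # identical arms: exact mean equality displays as >.99
  p <- co$participants
  swap <- p
  swap$arm <- ifelse(p$arm == "intervention", "control", "intervention")
  mirror <- rbind(
    transform(p[p$arm == "intervention", ],
              participant_id = paste0(participant_id, "x"), arm = "control"),
    p[p$arm == "intervention", ])
  vmirror <- co$visits[co$visits$participant_id %in%
                         p$participant_id[p$arm == "intervention"], ]
  vdup <- transform(vmirror, participant_id = paste0(participant_id, "x"))
  tbm <- comparison_table(mirror, rbind(vmirror, vdup))
  expect_true(all(tbm$p_display == ">.99"))

  # degenerate variance in both arms -> not-computable marker
  pc <- p
  pc$booking_hb <- 5
  tbc <- comparison_table(pc, co$visits)
  expect_identical(tbc$p_display[tbc$variable == "booking_hb"], "NC")

  # label-swap invariance of p-values
  tbs <- comparison_table(swap, co$visits)
  expect_equal(tbs$p_value, tb$p_value, tolerance = 1e-12)
})

test_that("Welch p-values are uniform under the null (KS over 1,000 replicates)", {
  set.seed(123)
  ps <- replicate(1000, {
    anctriage:::welch_p(rnorm(30), rnorm(30))
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("recruitment summary: per-cluster days and monthly rate", {
  mk <- function(cid, dates) data.frame(
    participant_id = paste0(cid, seq_along(dates)), cluster_id = cid,
    registration_date = as.Date(dates), stringsAsFactors = FALSE)
  p <- rbind(mk("A", c("2020-01-01", "2020-02-20")),         # 50 days apart
             mk("B", "2020-01-01"),                          # single recruit
             mk("C", c("2020-03-01", "2020-03-01")))         # same-day pair
  r <- recruitment_summary(p)
  expect_equal(r$days[r$cluster_id == "A"], 50)
  expect_true(is.na(r$per_month[r$cluster_id == "B"]))
  expect_equal(r$days[r$cluster_id == "C"], 0)
  expect_true(is.na(r$per_month[r$cluster_id == "C"]))
  # 50 recruits over 91.3 days ~ 16.7 per month
  expect_equal(50 / (91.3 / 30.44), 16.67, tolerance = 0.001)
  co <- sim_default()
  rs <- recruitment_summary(co$participants)
  expect_identical(sort(rs$days), sort(co$config$clusters$recruit_days))
  expect_equal(rs$per_month, rs$n / (rs$days / 30.44))
})

test_that("trial_summary assembles the full result surface", {
  co <- sim_default()
  s <- trial_summary(co$participants, co$visits, co$flow, TH)
  expect_s3_class(s, "trial_summary")
  expect_equal(s$retention$percent, 2)
  expect_equal(s$fidelity$percent, 100)
  expect_equal(s$prevalence$hdp$percent, 2.5)
  # flow can be derived from the visit table when absent
  s2 <- trial_summary(co$participants, co$visits, NULL, TH)
  expect_identical(s2$retention$lost, s$retention$lost)
  expect_output(print(s), "Retention: 4/200")
})
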
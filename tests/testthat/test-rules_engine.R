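test_that("BP classification follows the hypertension and shock-index bands", {
  cases <- list(
    list(sbp = 120, dbp = 76, hr = 80, want = "GREEN"),   # SI 0.67
    list(sbp = 165, dbp = 100, hr = 80, want = "RED"),    # severe HTN
    list(sbp = 100, dbp = 60, hr = 95, want = "YELLOW"),  # SI 0.95
    list(sbp = 140, dbp = 70, hr = 80, want = "YELLOW"),  # sbp edge inclusive
    list(sbp = 139, dbp = 70, hr = 80, want = "GREEN"),
    list(sbp = 160, dbp = 70, hr = 80, want = "RED"),
    list(sbp = 120, dbp = 110, hr = 80, want = "RED"),    # dbp edge
    list(sbp = 100, dbp = 60, hr = 170, want = "RED")     # SI 1.7
  )
  for (c_ in cases) {
    expect_identical(as.character(classify_bp(c_$sbp, c_$dbp, c_$hr, TH)),
                     c_$want,
                     info = sprintf("sbp=%g dbp=%g hr=%g", c_$sbp, c_$dbp, c_$hr))
  }
  expect_error(classify_bp(NA, 70, 80, TH), "requires")
})

test_that("Hb and OGTT classification follow their bands", {
  expect_identical(as.character(classify_hb(c(11.5, 9.9, 6.9, 11.0, 10.9, 7.0), TH)),
                   c("GREEN", "YELLOW", "RED", "GREEN", "YELLOW", "YELLOW"))
  expect_error(classify_hb(NA, TH), "requires")
  expect_identical(as.character(classify_ogtt(c(120, 140, 200, 139, 199), TH)),
                   c("GREEN", "YELLOW", "RED", "GREEN", "YELLOW"))
  expect_error(classify_ogtt(NA, TH), "not screened")
})

test_that("classifier severity is monotone in each input", {
  # totality + monotonicity over coarse measurement grids
  sbp_grid <- seq(80, 250, by = 5)
  cols <- classify_bp(sbp_grid, 40, 60, TH)
  expect_false(anyNA(cols))
  expect_true(all(diff(as.integer(cols)) >= 0))
  dbp_grid <- seq(40, 115, by = 5)
  cols <- classify_bp(120, dbp_grid, 60, TH)
  expect_false(anyNA(cols))
  expect_true(all(diff(as.integer(cols)) >= 0))
  hr_grid <- seq(30, 240, by = 5)
  expect_true(all(diff(as.integer(classify_bp(120, 70, hr_grid, TH))) >= 0))
  hb_grid <- seq(2, 20, by = 0.1)
  expect_true(all(diff(as.integer(classify_hb(hb_grid, TH))) <= 0))
  glu_grid <- seq(30, 600, by = 1)
  expect_true(all(diff(as.integer(classify_ogtt(glu_grid, TH))) >= 0))
})

test_that("overall color is the maximum severity on the exhaustive color grid", {
  lv <- c("GREEN", "YELLOW", "RED")
  grid <- expand.grid(bp = lv, hb = lv, gdm = c(lv, NA), stringsAsFactors = FALSE)
  got <- overall_color(grid$bp, grid$hb, grid$gdm)
  want <- apply(grid, 1, function(r) {
    lv[max(match(r, lv), na.rm = TRUE)]
  })
  expect_identical(as.character(got), unname(want))
})

test_that("assess_visit composes colors, recommendations and flags", {
  p <- fixture_participant()
  # all-normal visit: overall GREEN, zero referral recommendations
  a <- assess_visit(p, fixture_visit(), TH, CAT)
  expect_identical(as.character(a$overall_color), "GREEN")
  expect_identical(nrow(a$recommendations), 0L)
  expect_identical(a$missing_practices, character(0))

  # anemia + moderate hypertension: overall YELLOW, two referrals in
  # condition order (BP, then Hb)
  a <- assess_visit(p, fixture_visit(sbp = 150, dbp = 95, hb = 9.0), TH, CAT)
  expect_identical(as.character(a$overall_color), "YELLOW")
  expect_identical(a$recommendations$code, c("HTN_REFER", "ANEMIA_REFER"))

  # severe hypertension: RED first, urgent ambulance text verbatim
  a <- assess_visit(p, fixture_visit(sbp = 170, dbp = 112), TH, CAT)
  expect_identical(as.character(a$overall_color), "RED")
  expect_identical(a$recommendations$code[1], "HTN_SEVERE_URGENT")
  expect_identical(a$recommendations$text[1],
                   paste("This woman has evidence of severe hypertension.",
                         "Call ambulance and refer patient to hospital urgently."))

  # RED in any condition implies an urgent-referral item (all RED cells)
  urgent <- c("HTN_SEVERE_URGENT", "ANEMIA_SEVERE_URGENT", "DM_OVERT_URGENT")
  red_visits <- list(fixture_visit(sbp = 180), fixture_visit(hb = 5),
                     fixture_visit(ogtt_2h_glucose = 250))
  for (v in red_visits) {
    a <- assess_visit(p, v, TH, CAT)
    expect_identical(as.character(a$overall_color), "RED")
    expect_true(any(a$recommendations$code %in% urgent))
  }

  # mild anemia (>= referral line) downgrades to counseling advice
  a <- assess_visit(p, fixture_visit(hb = 10.4), TH, CAT)
  expect_identical(a$recommendations$code, "ANEMIA_ADVICE")
})

test_that("missing OGTT is a distinct not-screened outcome with practice flags", {
  p <- fixture_participant()
  a <- assess_visit(p, fixture_visit(ogtt_2h_glucose = NA, ogtt_done = FALSE,
                                     gdm_screened = FALSE, ifa_supplied = FALSE),
                    TH, CAT)
  expect_true(is.na(a$gdm_color))
  expect_identical(as.character(a$overall_color), "GREEN")
  expect_setequal(a$missing_practices,
                  c("MISSING_GDM_SCREEN", "MISSING_OGTT", "MISSING_IFA"))
  # missing-practice prompts come after clinical items
  a2 <- assess_visit(p, fixture_visit(hb = 9.0, ogtt_2h_glucose = NA,
                                      ogtt_done = FALSE), TH, CAT)
  expect_identical(a2$recommendations$code, c("ANEMIA_REFER", "MISSING_OGTT"))
})

test_that("enrolment window is 196-258 days inclusive", {
  expect_identical(enrolment_eligible(c(195, 196, 258, 259), TH),
                   c(FALSE, TRUE, TRUE, FALSE))
})

test_that("visit windows follow the schedule rules", {
  w <- visit_window("antenatal", as.Date("2020-01-01"), thresholds = TH)
  expect_identical(w, as.Date(c("2020-07-15", "2020-09-15")))
  w <- visit_window("postpartum_week1", as.Date("2020-01-01"),
                    as.Date("2020-10-01"), TH)
  expect_identical(w, as.Date(c("2020-10-01", "2020-10-08")))
  # week-6 window always contains delivery + 42
  for (d in as.Date(c("2020-02-29", "2020-12-31", "2021-06-15"))) {
    w <- visit_window("postpartum_week6", as.Date("2020-01-01"), d, TH)
    expect_true(w[1] <= d + 42 && d + 42 <= w[2])
  }
  expect_error(visit_window("postpartum_week6", as.Date("2020-01-01"), NULL, TH),
               "delivery_date")
})

test_that("thresholds config refuses missing keys and perturbs by resolution", {
  broken <- unclass(TH)
  broken$bp$sbp_red <- NULL
  expect_error(anctriage:::validate_thresholds(broken), "bp.sbp_red")
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(bp = list(sbp_yellow = 140)), f)
  expect_error(load_thresholds(f), "missing")

  m <- mutate_threshold(TH, "hb.red_below", 1)
  expect_equal(m$hb$red_below, TH$hb$red_below + 0.1)
  m <- mutate_threshold(TH, "bp.si_yellow", -1)
  expect_equal(m$bp$si_yellow, 0.89)
  expect_error(mutate_threshold(TH, "bp.nope"), "unknown")
})

test_that("recommendation catalogue must contain the urgent hypertension code", {
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(code = "X", text = "y"), f, row.names = FALSE)
  expect_error(load_recommendations(f), "HTN_SEVERE_URGENT")
})
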
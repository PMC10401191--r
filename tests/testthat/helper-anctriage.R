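# shared objects: loading YAML once keeps the suite fast
TH <- load_thresholds()
CAT <- load_recommendations()

# one small valid participant + matching visit, overridable per test
fixture_participant <- function(...) {
  p <- data.frame(
    participant_id = "P1", cluster_id = "PHC-A", arm = "intervention",
    date_of_birth = as.Date("1996-05-10"),
    registration_date = as.Date("2020-03-01"),
    height_m = 1.55, weight_kg = 60, lmp_date = as.Date("2019-08-01"),
    delivery_date = as.Date("2020-05-07"), schooling_years = 12L,
    household_size = 5L, booking_hb = 10.5, stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) p[[nm]] <- over[[nm]]
  p
}

fixture_visit <- function(...) {
  v <- data.frame(
    participant_id = "P1", visit_type = "antenatal",
    visit_date = as.Date("2020-03-01"), sbp = 110, dbp = 70, heart_rate = 78,
    hb = 12.0, ogtt_2h_glucose = 110, gdm_screened = TRUE, ogtt_done = TRUE,
    ifa_supplied = TRUE, entry_complete = TRUE, entry_on_time = TRUE,
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) v[[nm]] <- over[[nm]]
  v
}

# small default cohort reused across metric tests (seed fixed)
sim_default <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) memo <<- simulate_cohort(default_sim_config(20191001L))
    memo
  }
})
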
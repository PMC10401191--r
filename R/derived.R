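#' Completed age in whole years
#'
#' Floor of completed years at the reference date, accounting for whether
#' the birthday has occurred in the reference year (a Feb-29 birthday
#' counts as completed on Mar 1 in non-leap years). This matches clinical
#' registration practice.
#'
#' @param date_of_birth,reference_date `Date` vectors (recycled).
#' @return integer vector of completed years.
#' @export
age_years <- function(date_of_birth, reference_date) {
  dob <- as.Date(date_of_birth)
  ref <- as.Date(reference_date)
  if (any(ref < dob)) stop("reference_date before date_of_birth")
  dob_lt <- as.POSIXlt(dob)
  ref_lt <- as.POSIXlt(ref)
  yrs <- ref_lt$year - dob_lt$year
  pre_birthday <- ref_lt$mon < dob_lt$mon |
    (ref_lt$mon == dob_lt$mon & ref_lt$mday < dob_lt$mday)
  as.integer(yrs - pre_birthday)
}

#' Body mass index
#'
#' @param weight booking weight in kilograms.
#' @param height height in meters.
#' @return BMI in kg/m^2.
#' @export
bmi <- function(weight, height) {
  if (any(!is.finite(height) | height <= 0)) stop("height must be positive")
  weight / height^2
}

#' Gestational age in completed days since the last menstrual period
#'
#' @param lmp_date LMP date.
#' @param on_date date at which gestational age is evaluated.
#' @return integer days; 196 days is 28+0 weeks, 280 days the estimated
#'   date of delivery.
#' @export
gestational_age_days <- function(lmp_date, on_date) {
  lmp <- as.Date(lmp_date)
  on <- as.Date(on_date)
  if (any(on < lmp)) stop("on_date before lmp_date")
  as.integer(on - lmp)
}

#' Estimated date of delivery (280-day rule)
#'
#' Naegele's rule by calendar-day arithmetic: LMP plus 280 days.
#'
#' @param lmp_date LMP date.
#' @return `Date` vector.
#' @export
estimated_delivery_date <- function(lmp_date) {
  as.Date(lmp_date) + 280L
}

#' Shock index
#'
#' Heart rate divided by systolic blood pressure; elevated values flag
#' hemodynamic compromise (e.g. postpartum hemorrhage) even at normal BP.
#'
#' @param heart_rate beats per minute.
#' @param sbp systolic blood pressure, mmHg; must be positive — the index
#'   is a domain error, never infinity, when SBP is missing or zero.
#' @return dimensionless ratio.
#' @export
shock_index <- function(heart_rate, sbp) {
  if (any(is.na(sbp)) || any(is.na(heart_rate))) {
    stop("shock index undefined for missing heart rate or SBP")
  }
  if (any(sbp <= 0)) stop("shock index undefined for SBP <= 0")
  heart_rate / sbp
}

#' All calculated variables for one participant-visit pair
#'
#' @param participant one-row participant record (see [read_participants]).
#' @param visit one-row visit record (see [read_visits]).
#' @return list with `age`, `bmi`, `gestational_age`, `edd`,
#'   `shock_index`, and `postpartum_day` (`NA` before delivery).
#' @export
derive_vars <- function(participant, visit) {
  vd <- as.Date(visit$visit_date)
  del <- as.Date(participant$delivery_date)
  list(
    age = age_years(participant$date_of_birth, vd),
    bmi = bmi(participant$weight, participant$height),
    gestational_age = if (vd >= as.Date(participant$lmp_date))
      gestational_age_days(participant$lmp_date, vd) else NA_integer_,
    edd = estimated_delivery_date(participant$lmp_date),
    shock_index = shock_index(visit$heart_rate, visit$sbp),
    postpartum_day = if (!is.na(del) && vd >= del) as.integer(vd - del) else NA_integer_
  )
}
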
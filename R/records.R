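#' @name records
#' @title Participant and visit record I/O
#'
#' @description
#' Readers and writers for the two flat files the triage tools consume:
#' `participants` (one enrolled woman per row) and `visits` (one home-visit
#' measurement set per row). Both CSV and JSON-lines dialects are accepted,
#' chosen by file extension (`.csv` vs `.jsonl`/`.ndjson`/`.json`). Dates
#' are ISO-8601 strings; missing optional numerics are empty fields (CSV)
#' or `null` (JSON-lines), never 0 or sentinels.
#'
#' Validation is total: every row is either accepted or yields a
#' diagnostic naming the row, the record id, and the violated field.
#' Diagnostics are collected across the whole file — data collected by
#' community health workers in the field needs batch hygiene reporting,
#' not abort-on-first-error. With `strict = TRUE` (default) any diagnostic
#' raises an error carrying the full table in `$problems`; with
#' `strict = FALSE` the valid rows are returned with the diagnostics
#' attached as `attr(x, "problems")`.
NULL

participant_columns <- c(
  "participant_id", "cluster_id", "arm", "date_of_birth", "registration_date",
  "height_m", "weight_kg", "lmp_date", "delivery_date", "schooling_years",
  "household_size", "booking_hb"
)

visit_columns <- c(
  "participant_id", "visit_type", "visit_date", "sbp", "dbp", "heart_rate",
  "hb", "ogtt_2h_glucose", "gdm_screened", "ogtt_done", "ifa_supplied",
  "entry_complete", "entry_on_time"
)

visit_types <- c("antenatal", "postpartum_week1", "postpartum_week6")

read_records_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.(jsonl|ndjson|json)$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) return(NULL)
    rows <- lapply(lines, function(l) {
      x <- jsonlite::fromJSON(l)
      x[vapply(x, is.null, logical(1))] <- NA
      as.data.frame(x, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  }
}

write_records_file <- function(df, path) {
  if (grepl("\\.(jsonl|ndjson|json)$", path, ignore.case = TRUE)) {
    out <- df
    for (nm in names(out)) if (inherits(out[[nm]], "Date")) out[[nm]] <- format(out[[nm]])
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(out))) {
      writeLines(jsonlite::toJSON(as.list(out[i, , drop = FALSE]),
                                  auto_unbox = TRUE, na = "null", digits = NA), con)
    }
  } else {
    utils::write.csv(df, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

as_iso_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(rep(NA_character_, length(x)))
  chr <- as.character(x)
  ok <- !is.na(chr) & grepl("^\\d{4}-\\d{2}-\\d{2}$", chr)
  out[ok] <- as.Date(chr[ok])
  out[!ok & !is.na(chr)] <- NA
  out
}

# append one diagnostic row; problems is an environment-held data.frame
add_problem <- function(problems, row, id, field, message) {
  rbind(problems, data.frame(row = row, id = id, field = field,
                             message = message, stringsAsFactors = FALSE))
}

finish_read <- function(df, problems, strict, what) {
  attr(df, "problems") <- problems
  if (strict && nrow(problems) > 0L) {
    cond <- simpleError(paste0(
      nrow(problems), " invalid ", what, " row(s):\n",
      paste(sprintf("  row %s [%s] %s: %s", problems$row, problems$id,
                    problems$field, problems$message), collapse = "\n")))
    cond$problems <- problems
    class(cond) <- c("anctriage_validation_error", class(cond))
    stop(cond)
  }
  df
}

no_problems <- function() {
  data.frame(row = integer(), id = character(), field = character(),
             message = character(), stringsAsFactors = FALSE)
}

check_range <- function(problems, keep, df, field, lo, hi, optional = FALSE) {
  v <- df[[field]]
  bad <- !is.na(v) & (v < lo | v > hi)
  if (!optional) bad <- bad | is.na(v)
  for (i in which(bad)) {
    problems <- add_problem(problems, i, df$participant_id[i], field,
                            sprintf("value %s outside [%s, %s]",
                                    ifelse(is.na(v[i]), "missing", v[i]), lo, hi))
  }
  list(problems = problems, keep = keep & !bad)
}

#' Read participant records
#'
#' @param path CSV or JSON-lines file with columns `participant_id`,
#'   `cluster_id`, `arm`, `date_of_birth`, `registration_date`, `height_m`
#'   (or `height_cm`, converted on read), `weight_kg`, `lmp_date`,
#'   `delivery_date`, `schooling_years`, `household_size`, `booking_hb`.
#' @param strict raise an error listing every invalid row (default), or
#'   return valid rows with diagnostics in `attr(, "problems")`.
#' @return data.frame of validated participants, dates as `Date`. The
#'   height dialect actually read is recorded in `attr(, "height_dialect")`.
#' @export
read_participants <- function(path, strict = TRUE) {
  df <- read_records_file(path)
  if (is.null(df) || nrow(df) == 0L) {
    empty <- as.data.frame(stats::setNames(rep(list(character(0)),
                                               length(participant_columns)),
                                           participant_columns))
    attr(empty, "problems") <- no_problems()
    return(empty)
  }
  dialect <- "height_m"
  if (!"height_m" %in% names(df) && "height_cm" %in% names(df)) {
    df$height_m <- as.numeric(df$height_cm) / 100
    df$height_cm <- NULL
    dialect <- "height_cm"
  }
  missing_cols <- setdiff(participant_columns, names(df))
  if (length(missing_cols) > 0L) {
    stop("participants file missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[participant_columns]
  for (col in c("date_of_birth", "registration_date", "lmp_date", "delivery_date")) {
    df[[col]] <- as_iso_date(df[[col]])
  }
  for (col in c("height_m", "weight_kg", "booking_hb")) df[[col]] <- as.numeric(df[[col]])
  for (col in c("schooling_years", "household_size")) df[[col]] <- as.integer(df[[col]])

  problems <- no_problems()
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    id <- df$participant_id[i]
    fail <- function(field, msg) problems <<- add_problem(problems, i, id, field, msg)
    if (is.na(id) || !nzchar(id)) { fail("participant_id", "missing"); keep[i] <- FALSE; next }
    if (!df$arm[i] %in% c("intervention", "control")) {
      fail("arm", "must be intervention or control"); keep[i] <- FALSE; next
    }
    if (is.na(df$date_of_birth[i]) || is.na(df$registration_date[i]) ||
        is.na(df$lmp_date[i])) {
      fail("dates", "date_of_birth, registration_date, lmp_date required (ISO-8601)")
      keep[i] <- FALSE; next
    }
    if (df$registration_date[i] <= df$date_of_birth[i]) {
      fail("registration_date", "registration_date > date_of_birth violated")
      keep[i] <- FALSE; next
    }
    if (df$lmp_date[i] >= df$registration_date[i]) {
      fail("lmp_date", "lmp_date < registration_date violated")
      keep[i] <- FALSE; next
    }
    if (!is.na(df$delivery_date[i]) && df$delivery_date[i] <= df$lmp_date[i]) {
      fail("delivery_date", "delivery_date > lmp_date violated")
      keep[i] <- FALSE; next
    }
    if (is.na(df$height_m[i]) || df$height_m[i] <= 0.5 || df$height_m[i] >= 2.5) {
      fail("height_m", "height outside (0.5, 2.5) m"); keep[i] <- FALSE; next
    }
    if (!is.na(df$weight_kg[i]) && (df$weight_kg[i] <= 25 || df$weight_kg[i] >= 200)) {
      fail("weight_kg", "weight outside (25, 200) kg"); keep[i] <- FALSE; next
    }
    if (!is.na(df$schooling_years[i]) && df$schooling_years[i] < 0) {
      fail("schooling_years", "negative"); keep[i] <- FALSE; next
    }
    if (!is.na(df$household_size[i]) && df$household_size[i] < 1) {
      fail("household_size", "must be positive"); keep[i] <- FALSE
    }
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "height_dialect") <- dialect
  finish_read(out, problems, strict, "participant")
}

#' Read visit records
#'
#' @param path CSV or JSON-lines file with columns `participant_id`,
#'   `visit_type`, `visit_date`, `sbp`, `dbp`, `heart_rate`, `hb`,
#'   `ogtt_2h_glucose`, `gdm_screened`, `ogtt_done`, `ifa_supplied`,
#'   `entry_complete`, `entry_on_time`.
#' @inheritParams read_participants
#' @return data.frame of validated visits.
#' @export
read_visits <- function(path, strict = TRUE) {
  df <- read_records_file(path)
  if (is.null(df) || nrow(df) == 0L) {
    empty <- as.data.frame(stats::setNames(rep(list(character(0)),
                                               length(visit_columns)),
                                           visit_columns))
    attr(empty, "problems") <- no_problems()
    return(empty)
  }
  missing_cols <- setdiff(visit_columns, names(df))
  if (length(missing_cols) > 0L) {
    stop("visits file missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[visit_columns]
  df$visit_date <- as_iso_date(df$visit_date)
  for (col in c("sbp", "dbp", "heart_rate", "hb", "ogtt_2h_glucose")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  for (col in c("gdm_screened", "ogtt_done", "ifa_supplied",
                "entry_complete", "entry_on_time")) {
    df[[col]] <- as.logical(df[[col]])
  }

  problems <- no_problems()
  keep <- rep(TRUE, nrow(df))
  res <- check_range(problems, keep, df, "sbp", 30, 300)
  res <- check_range(res$problems, res$keep, df, "dbp", 30, 300)
  res <- check_range(res$problems, res$keep, df, "heart_rate", 20, 250)
  res <- check_range(res$problems, res$keep, df, "hb", 2, 20)
  res <- check_range(res$problems, res$keep, df, "ogtt_2h_glucose", 30, 600,
                     optional = TRUE)
  problems <- res$problems; keep <- res$keep
  for (i in seq_len(nrow(df))) {
    if (!keep[i]) next
    id <- df$participant_id[i]
    if (is.na(id) || !nzchar(id)) {
      problems <- add_problem(problems, i, id, "participant_id", "missing")
      keep[i] <- FALSE; next
    }
    if (!df$visit_type[i] %in% visit_types) {
      problems <- add_problem(problems, i, id, "visit_type",
                              paste("must be one of:", paste(visit_types, collapse = ", ")))
      keep[i] <- FALSE; next
    }
    if (is.na(df$visit_date[i])) {
      problems <- add_problem(problems, i, id, "visit_date", "missing or not ISO-8601")
      keep[i] <- FALSE; next
    }
    if (df$sbp[i] <= df$dbp[i]) {
      problems <- add_problem(problems, i, id, "sbp", "sbp > dbp violated")
      keep[i] <- FALSE
    }
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  finish_read(out, problems, strict, "visit")
}

#' Write participant / visit / assessment tables
#'
#' Deterministic column order, ISO dates, empty-field encoding for missing
#' optionals; the written file round-trips through the matching reader.
#'
#' @param x data.frame as returned by the matching reader (or by
#'   [simulate_cohort] / [assess_cohort]).
#' @param path output path; `.csv` or `.jsonl` selects the dialect.
#' @return the path, invisibly.
#' @export
write_participants <- function(x, path) {
  write_records_file(x[participant_columns], path)
}

#' @rdname write_participants
#' @export
write_visits <- function(x, path) {
  write_records_file(x[visit_columns], path)
}

#' @rdname write_participants
#' @export
write_assessments <- function(x, path) {
  cols <- assessment_columns
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols) > 0L) {
    stop("assessment table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- x[cols]
  for (col in c("bp_color", "hb_color", "gdm_color", "overall_color")) {
    out[[col]] <- as.character(out[[col]])
  }
  write_records_file(out, path)
}

#' @rdname write_participants
#' @export
read_assessments <- function(path) {
  df <- read_records_file(path)
  if (is.null(df) || nrow(df) == 0L) {
    return(as.data.frame(stats::setNames(rep(list(character(0)),
                                             length(assessment_columns)),
                                         assessment_columns)))
  }
  df <- df[assessment_columns]
  df$visit_date <- as_iso_date(df$visit_date)
  df$edd <- as_iso_date(df$edd)
  for (col in c("recommendations", "missing_practices")) {
    df[[col]] <- ifelse(is.na(df[[col]]), "", as.character(df[[col]]))
  }
  for (col in c("bp_color", "hb_color", "gdm_color", "overall_color")) {
    df[[col]] <- traffic_light(df[[col]])
  }
  df
}

assessment_columns <- c(
  "participant_id", "visit_type", "visit_date", "bp_color", "hb_color",
  "gdm_color", "overall_color", "recommendations", "missing_practices",
  "age", "bmi", "gestational_age", "edd", "shock_index", "postpartum_day"
)
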
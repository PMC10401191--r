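#' @name validation
#' @title Two-step validation harness
#'
#' @description
#' The triage rules were validated in two steps: first against a 200-case
#' clinical fixture covering every decision-table band, then against
#' 10,000 randomly generated cases spanning the full valid ranges of all
#' inputs, each time requiring a 100% match with an independently coded
#' second implementation. This module reproduces that protocol in one
#' codebase: the "oracle" is a nested exhaustive if/else decision tree
#' written directly from the thresholds config, sharing no classification
#' code with the table-driven engine — the independence that matters is
#' of control flow, not vendor.
NULL

# evaluate expr under a temporary RNG state; restores .Random.seed
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

make_cases <- function(case_id, sbp, dbp, heart_rate, hb, ogtt, stratum) {
  data.frame(case_id = case_id, sbp = sbp, dbp = dbp, heart_rate = heart_rate,
             hb = hb, ogtt_2h_glucose = ogtt, stratum = stratum,
             stringsAsFactors = FALSE)
}

#' Generate the 200-case clinical validation fixture
#'
#' Deterministic boundary cases place at least one case at every
#' decision-table band edge and one resolution step below it, for every
#' condition (BP systolic/diastolic, shock index, hemoglobin, OGTT),
#' plus multi-condition combinations; the remainder is filled with
#' seeded stratified draws so that every band of every condition is
#' represented.
#'
#' @param seed integer seed; the fixture is a pure function of it.
#' @param thresholds a [load_thresholds()] object.
#' @return data.frame of exactly 200 cases with columns `case_id`, `sbp`,
#'   `dbp`, `heart_rate`, `hb`, `ogtt_2h_glucose`, `stratum`.
#' @export
generate_clinical_fixture <- function(seed = 1L, thresholds = load_thresholds()) {
  b <- thresholds$bp; h <- thresholds$hb; g <- thresholds$ogtt
  r <- thresholds$resolution
  # neutral all-green background readings
  base <- list(sbp = 110, dbp = 70, hr = 80, hb = 12.0, glu = 100)

  rows <- list()
  push <- function(stratum, sbp = base$sbp, dbp = base$dbp, hr = base$hr,
                   hb = base$hb, glu = base$glu) {
    rows[[length(rows) + 1L]] <<- make_cases(NA_character_, sbp, dbp, hr, hb,
                                             glu, stratum)
  }
  push("all_green")
  # systolic edges, +/- one resolution step
  for (e in c(b$sbp_yellow, b$sbp_red)) {
    push(paste0("sbp_edge_", e), sbp = e)
    push(paste0("sbp_below_", e), sbp = e - r$bp)
  }
  # diastolic edges (systolic kept above diastolic, inside its green band)
  for (e in c(b$dbp_yellow, b$dbp_red)) {
    push(paste0("dbp_edge_", e), sbp = e + 15, dbp = e)
    push(paste0("dbp_below_", e), sbp = e + 15, dbp = e - r$bp)
  }
  # shock-index edges via HR at SBP 100
  for (e in c(b$si_yellow, b$si_red)) {
    push(paste0("si_edge_", e), sbp = 100, hr = round(100 * e))
    push(paste0("si_below_", e), sbp = 100, hr = round(100 * e) - r$hr)
  }
  # hemoglobin edges (severe, referral-strength, normal)
  for (e in c(h$red_below, h$referral_below, h$green_at_or_above)) {
    push(paste0("hb_edge_", e), hb = e)
    push(paste0("hb_below_", e), hb = e - r$hb)
  }
  # OGTT edges
  for (e in c(g$yellow_at_or_above, g$red_at_or_above)) {
    push(paste0("ogtt_edge_", e), glu = e)
    push(paste0("ogtt_below_", e), glu = e - r$glucose)
  }
  push("ogtt_not_screened", glu = NA)
  # multi-condition scenarios: severity composition and ordering
  push("htn_severe_example", sbp = 165, dbp = 100)
  push("anemia_plus_htn", sbp = 150, dbp = 95, hb = 9.0)
  push("all_red", sbp = 170, dbp = 112, hr = 150, hb = 6.0, glu = 220)
  push("shock_normotensive", sbp = 100, dbp = 60, hr = 95)

  fixed <- do.call(rbind, rows)

  # stratified random fill to 200 cases: cycle through band combinations
  n_fill <- 200L - nrow(fixed)
  fill <- with_seed(seed, {
    sbp_bands <- list(c(80, b$sbp_yellow - 1), c(b$sbp_yellow, b$sbp_red - 1),
                      c(b$sbp_red, 220))
    hb_bands <- list(c(h$green_at_or_above, 16), c(h$red_below, h$green_at_or_above - 0.1),
                     c(3, h$red_below - 0.1))
    glu_bands <- list(c(60, g$yellow_at_or_above - 1),
                      c(g$yellow_at_or_above, g$red_at_or_above - 1),
                      c(g$red_at_or_above, 400))
    idx <- seq_len(n_fill)
    sbp <- dbp <- hr <- numeric(n_fill); hb <- glu <- numeric(n_fill)
    for (i in idx) {
      sb <- sbp_bands[[(i %% 3L) + 1L]]
      sbp[i] <- sample(sb[1]:sb[2], 1L)
      dbp[i] <- sample(40:min(89, sbp[i] - 10), 1L)
      hr[i] <- sample(55:min(115, floor(b$si_yellow * sbp[i]) - 1L), 1L)
      hbb <- hb_bands[[((i %/% 3L) %% 3L) + 1L]]
      hb[i] <- round(stats::runif(1, hbb[1], hbb[2]), 1)
      gb <- glu_bands[[((i %/% 9L) %% 3L) + 1L]]
      glu[i] <- sample(gb[1]:gb[2], 1L)
    }
    make_cases(NA_character_, sbp, dbp, hr, hb, glu,
               paste0("stratified_fill_", idx))
  })
  out <- rbind(fixed, fill)
  out$case_id <- sprintf("C%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Generate random validation cases over the full measurement ranges
#'
#' Each variable is drawn uniformly over its valid record range at its
#' measurement resolution (BP 1 mmHg, HR 1 bpm, Hb 0.1 g/dL, glucose
#' 1 mg/dL); the OGTT value is missing ("not screened") in 15% of cases.
#' With probability `boundary_prob` per variable a value is set exactly
#' to a configured band edge (for the shock index, an SBP/HR pair with an
#' exact edge ratio), so that any one-step threshold discrepancy between
#' two implementations is guaranteed to surface.
#'
#' @param n number of cases.
#' @param seed integer seed.
#' @param thresholds a [load_thresholds()] object.
#' @param boundary_prob per-variable probability of pinning to a band edge.
#' @return data.frame of `n` cases, deterministic per seed.
#' @export
generate_random_cases <- function(n, seed = 1L, thresholds = load_thresholds(),
                                  boundary_prob = 0.1) {
  stopifnot(n >= 1)
  b <- thresholds$bp; h <- thresholds$hb; g <- thresholds$ogtt
  with_seed(seed, {
    sbp <- sample(31:300, n, replace = TRUE)
    hr <- sample(20:250, n, replace = TRUE)
    hb <- round(stats::runif(n, 2, 20), 1)
    glu <- sample(30:600, n, replace = TRUE)
    glu[stats::runif(n) < 0.15] <- NA

    pin <- function() stats::runif(n) < boundary_prob
    k <- pin(); sbp[k] <- sample(c(b$sbp_yellow, b$sbp_red), sum(k), replace = TRUE)
    # exact shock-index edge pairs: SBP a multiple of 10 so HR is integral
    k <- pin()
    if (any(k)) {
      s <- sample(seq(50, 140, by = 10), sum(k), replace = TRUE)
      e <- sample(c(b$si_yellow, b$si_red), sum(k), replace = TRUE)
      sbp[k] <- s
      hr[k] <- round(s * e)
    }
    dbp <- floor(stats::runif(n, 30, sbp))  # integer in [30, sbp - 1]
    k <- pin(); dbp[k] <- sample(c(b$dbp_yellow, b$dbp_red), sum(k), replace = TRUE)
    sbp <- pmax(sbp, dbp + 1)
    k <- pin()
    hb[k] <- sample(c(h$red_below, h$referral_below, h$green_at_or_above),
                    sum(k), replace = TRUE)
    k <- pin() & !is.na(glu)
    glu[k] <- sample(c(g$yellow_at_or_above, g$red_at_or_above),
                     sum(k), replace = TRUE)

    make_cases(sprintf("R%05d", seq_len(n)), sbp, dbp, hr, hb, glu, "random")
  })
}

# Engine-side classification of bare validation cases: the same table-
# driven classifiers used on real visits, plus the recommendation codes.
engine_assess_cases <- function(cases, thresholds = load_thresholds()) {
  bp <- classify_bp(cases$sbp, cases$dbp, cases$heart_rate, thresholds)
  hb <- classify_hb(cases$hb, thresholds)
  screened <- !is.na(cases$ogtt_2h_glucose)
  gdm <- traffic_light(rep(NA_character_, nrow(cases)))
  if (any(screened)) {
    gdm[screened] <- classify_ogtt(cases$ogtt_2h_glucose[screened], thresholds)
  }
  codes <- recommend_codes(bp, hb, cases$hb, gdm, thresholds = thresholds)
  data.frame(
    case_id = cases$case_id,
    bp_color = as.character(bp), hb_color = as.character(hb),
    gdm_color = as.character(gdm),
    overall_color = as.character(overall_color(bp, hb, gdm)),
    codes = vapply(codes, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Independently coded oracle classification
#'
#' A second implementation of the full decision table as one nested
#' exhaustive if/else tree per case, written directly from the thresholds
#' config. It deliberately shares no code with the rules engine (no
#' [classify_bp()] / [findInterval()] machinery, no shared recommendation
#' assembly): it exists to catch transcription errors in either copy.
#'
#' @param case a one-row case data.frame (columns as in
#'   [generate_random_cases()]).
#' @param thresholds a [load_thresholds()] object.
#' @return list with `bp_color`, `hb_color`, `gdm_color` (NA when not
#'   screened), `overall_color`, and `codes` (character vector).
#' @export
oracle_assess <- function(case, thresholds = load_thresholds()) {
  t <- thresholds
  sbp <- case$sbp; dbp <- case$dbp; hr <- case$heart_rate
  hb <- case$hb; glu <- case$ogtt_2h_glucose
  if (is.na(sbp) || is.na(dbp) || is.na(hr) || is.na(hb)) {
    stop("oracle requires sbp, dbp, heart_rate, hb")
  }
  if (sbp <= 0) stop("oracle: SBP must be positive")
  si <- hr / sbp

  if (sbp >= t$bp$sbp_red) {
    bp_color <- "RED"
  } else if (dbp >= t$bp$dbp_red) {
    bp_color <- "RED"
  } else if (si >= t$bp$si_red) {
    bp_color <- "RED"
  } else if (sbp >= t$bp$sbp_yellow) {
    bp_color <- "YELLOW"
  } else if (dbp >= t$bp$dbp_yellow) {
    bp_color <- "YELLOW"
  } else if (si >= t$bp$si_yellow) {
    bp_color <- "YELLOW"
  } else {
    bp_color <- "GREEN"
  }

  if (hb < t$hb$red_below) {
    hb_color <- "RED"
  } else if (hb < t$hb$green_at_or_above) {
    hb_color <- "YELLOW"
  } else {
    hb_color <- "GREEN"
  }

  if (is.na(glu)) {
    gdm_color <- NA_character_
  } else if (glu >= t$ogtt$red_at_or_above) {
    gdm_color <- "RED"
  } else if (glu >= t$ogtt$yellow_at_or_above) {
    gdm_color <- "YELLOW"
  } else {
    gdm_color <- "GREEN"
  }

  if (identical(bp_color, "RED") || identical(hb_color, "RED") ||
      identical(gdm_color, "RED")) {
    overall <- "RED"
  } else if (identical(bp_color, "YELLOW") || identical(hb_color, "YELLOW") ||
             identical(gdm_color, "YELLOW")) {
    overall <- "YELLOW"
  } else {
    overall <- "GREEN"
  }

  codes <- character(0)
  if (identical(bp_color, "RED")) codes <- c(codes, "HTN_SEVERE_URGENT")
  if (identical(hb_color, "RED")) codes <- c(codes, "ANEMIA_SEVERE_URGENT")
  if (identical(gdm_color, "RED")) codes <- c(codes, "DM_OVERT_URGENT")
  if (identical(bp_color, "YELLOW")) codes <- c(codes, "HTN_REFER")
  if (identical(hb_color, "YELLOW")) {
    if (hb < t$hb$referral_below) {
      codes <- c(codes, "ANEMIA_REFER")
    } else {
      codes <- c(codes, "ANEMIA_ADVICE")
    }
  }
  if (identical(gdm_color, "YELLOW")) codes <- c(codes, "GDM_REFER")

  list(bp_color = bp_color, hb_color = hb_color, gdm_color = gdm_color,
       overall_color = overall, codes = codes)
}

oracle_assess_cases <- function(cases, thresholds = load_thresholds()) {
  n <- nrow(cases)
  bp <- hbc <- gdm <- ov <- codes <- character(n)
  for (i in seq_len(n)) {
    o <- oracle_assess(list(sbp = cases$sbp[i], dbp = cases$dbp[i],
                            heart_rate = cases$heart_rate[i], hb = cases$hb[i],
                            ogtt_2h_glucose = cases$ogtt_2h_glucose[i]),
                       thresholds)
    bp[i] <- o$bp_color
    hbc[i] <- o$hb_color
    gdm[i] <- if (is.na(o$gdm_color)) NA_character_ else o$gdm_color
    ov[i] <- o$overall_color
    codes[i] <- paste(o$codes, collapse = ";")
  }
  data.frame(case_id = cases$case_id, bp_color = bp, hb_color = hbc,
             gdm_color = gdm, overall_color = ov, codes = codes,
             stringsAsFactors = FALSE)
}

#' Concordance between the rules engine and the independent oracle
#'
#' Runs both implementations on every case. A case is concordant iff all
#' per-condition colors, the overall color, AND the ordered recommendation
#' code set agree. Discordance is data, not an error; the report lists
#' every discordant case. `oracle_thresholds` lets the mutation
#' sensitivity check feed the oracle a deliberately perturbed copy of the
#' decision table.
#'
#' @param cases case data.frame ([generate_clinical_fixture()] /
#'   [generate_random_cases()]).
#' @param thresholds thresholds used by the engine.
#' @param oracle_thresholds thresholds used by the oracle (defaults to the
#'   same object).
#' @return object of class `"validation_report"`: `n_cases`,
#'   `n_concordant`, `match_fraction`, `discordances` data.frame.
#' @export
concordance <- function(cases, thresholds = load_thresholds(),
                        oracle_thresholds = thresholds) {
  stopifnot(nrow(cases) > 0L)
  eng <- engine_assess_cases(cases, thresholds)
  ora <- oracle_assess_cases(cases, oracle_thresholds)
  same_na <- function(a, b) (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
  ok <- same_na(eng$bp_color, ora$bp_color) &
    same_na(eng$hb_color, ora$hb_color) &
    same_na(eng$gdm_color, ora$gdm_color) &
    eng$overall_color == ora$overall_color &
    eng$codes == ora$codes
  disc <- data.frame(
    case_id = cases$case_id[!ok],
    engine = paste(eng$bp_color, eng$hb_color, eng$gdm_color, eng$overall_color,
                   eng$codes, sep = "|")[!ok],
    oracle = paste(ora$bp_color, ora$hb_color, ora$gdm_color, ora$overall_color,
                   ora$codes, sep = "|")[!ok],
    stringsAsFactors = FALSE
  )
  structure(list(n_cases = nrow(cases), n_concordant = sum(ok),
                 match_fraction = sum(ok) / nrow(cases), discordances = disc),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d/%d concordant (match fraction %.4f)\n",
              x$n_concordant, x$n_cases, x$match_fraction))
  if (nrow(x$discordances) > 0L) {
    cat("discordances:\n")
    print(utils::head(x$discordances, 20L), row.names = FALSE)
    if (nrow(x$discordances) > 20L) {
      cat("  ... and", nrow(x$discordances) - 20L, "more\n")
    }
  }
  invisible(x)
}

#' Run the full two-step validation protocol
#'
#' Step 1: the seeded 200-case clinical fixture. Step 2: `n` random
#' boundary-enriched cases. Both must reach a 100% match for the
#' validation to pass.
#'
#' @param n size of the random step (default 10,000).
#' @param seed integer seed for both steps.
#' @param thresholds a [load_thresholds()] object.
#' @return list with `clinical` and `random` validation reports and a
#'   logical `pass`.
#' @export
validate_two_step <- function(n = 10000L, seed = 1L,
                              thresholds = load_thresholds()) {
  clin <- concordance(generate_clinical_fixture(seed, thresholds), thresholds)
  rand <- concordance(generate_random_cases(n, seed + 1L, thresholds), thresholds)
  list(clinical = clin, random = rand,
       pass = clin$match_fraction == 1 && rand$match_fraction == 1)
}
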
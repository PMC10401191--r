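#' Traffic-light severity levels
#'
#' The triage engine codes every reading as one of three ordered severity
#' levels: `GREEN` (normal), `YELLOW` (moderate concern, referral), `RED`
#' (urgent referral and management). Colors are represented as an ordered
#' factor so that `max()` gives the most severe level.
#'
#' @param x character vector of color names (any case).
#' @return an ordered factor with levels `GREEN < YELLOW < RED`.
#' @examples
#' max(traffic_light(c("GREEN", "RED", "YELLOW")))
#' @export
traffic_light <- function(x) {
  x <- toupper(as.character(x))
  bad <- !is.na(x) & !x %in% TRAFFIC_LEVELS
  if (any(bad)) {
    stop("unknown traffic-light color(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  factor(x, levels = TRAFFIC_LEVELS, ordered = TRUE)
}

TRAFFIC_LEVELS <- c("GREEN", "YELLOW", "RED")

#' Most severe color among per-condition colors
#'
#' @param ... traffic-light factors (or color strings) of equal length;
#'   `NA` entries (e.g. an unscreened OGTT) are ignored.
#' @return an ordered traffic-light factor, elementwise maximum severity.
#' @export
overall_color <- function(...) {
  cols <- lapply(list(...), traffic_light)
  m <- do.call(pmax, c(lapply(cols, as.integer), list(na.rm = TRUE)))
  traffic_light(TRAFFIC_LEVELS[m])
}

# integer severity 1..3, NA-safe
severity <- function(color) as.integer(traffic_light(color))
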
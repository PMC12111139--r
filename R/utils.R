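#' Calendar-day difference between two dates
#'
#' Start-exclusive day count `d2 - d1`, the convention under which the
#' anniversary of a monthly refill lies a multiple of the gap away (e.g.
#' 2014-01-16 to 2014-04-23 is 97 days).
#'
#' @param d1,d2 `Date` vectors (recycled); requires `d1 <= d2` elementwise.
#' @return Integer vector of day counts.
#' @export
days_between <- function(d1, d2) {
  d1 <- as.Date(d1)
  d2 <- as.Date(d2)
  if (any(d1 > d2)) stop("days_between(): d1 must not be after d2", call. = FALSE)
  as.integer(d2 - d1)
}

#' Fractional age in years at a given date
#'
#' Days since birth divided by 365.25; ages are reported to two decimals
#' elsewhere but returned at full precision here.
#'
#' @param birth_date,on `Date` vectors (recycled); `birth_date <= on`.
#' @return Numeric vector of ages in years.
#' @export
patient_age <- function(birth_date, on) {
  birth_date <- as.Date(birth_date)
  on <- as.Date(on)
  if (any(on < birth_date)) {
    stop("patient_age(): reference date precedes birth date", call. = FALSE)
  }
  as.numeric(on - birth_date) / 365.25
}

# 1-based calendar-month index within the study grid (1 = first study month)
study_month_index <- function(dates, study_start) {
  study_start <- as.Date(study_start)
  y0 <- as.integer(format(study_start, "%Y"))
  m0 <- as.integer(format(study_start, "%m"))
  y <- as.integer(format(as.Date(dates), "%Y"))
  m <- as.integer(format(as.Date(dates), "%m"))
  12L * (y - y0) + (m - m0) + 1L
}

study_month_label <- function(idx, study_start) {
  study_start <- as.Date(study_start)
  y0 <- as.integer(format(study_start, "%Y"))
  m0 <- as.integer(format(study_start, "%m"))
  mm <- (m0 - 1L + as.integer(idx) - 1L) %% 12L + 1L
  yy <- y0 + (m0 - 1L + as.integer(idx) - 1L) %/% 12L
  sprintf("%04d-%02d", yy, mm)
}

claim_year <- function(dates) as.integer(format(as.Date(dates), "%Y"))

#' Percentage formatted to two decimals
#'
#' Matches the reporting style used throughout the summary tables
#' (e.g. 56 of 89 renders as "62.92"). Empty denominators render blank,
#' never "0.00".
#'
#' @param num,den Numerators and denominators (recycled).
#' @return Character vector, two-decimal percentages without the \% sign.
#' @export
pct <- function(num, den) {
  out <- ifelse(den > 0, sprintf("%.2f", 100 * num / den), "")
  out
}

#' Analysis configuration
#'
#' Central bag of tunable parameters for the pipeline. Unknown keys are
#' rejected so configuration typos fail loudly.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A named list of configuration values, class `adhere_config`.
#' @details Defaults: five-year study window 2012-01-01 to 2016-12-31 with
#'   database end 2017-01-01; index year 2015; eligible ages 18--40;
#'   TAG rule of >= 12 issue months overall AND >= 7 within any rolling
#'   12-month window; month-reassignment rule 1 minimum gap 21 days and
#'   rule 2 dose-match tolerance 20\%; short-supply cut-off 14 days;
#'   90-day standard assessment period with the documented extension /
#'   shortening bands; uncapped per-period PDC; PDC adherence threshold
#'   0.80; methylphenidate DDD 30 mg.
#' @export
adherence_config <- function(...) {
  cfg <- list(
    study_start = as.Date("2012-01-01"),
    study_end = as.Date("2016-12-31"),
    database_end = as.Date("2017-01-01"),
    index_year = 2015L,
    min_age = 18L,
    max_age = 40L,
    n_months = 60L,
    tca_short_term_days = 14L,
    mood_icd_prefixes = c("F32", "F33", "F34", "F38", "F39", "F41"),
    tag_policy = "AND",
    tag_total_min = 12L,
    tag_window_min = 7L,
    tag_window_months = 12L,
    rule1_min_gap_days = 21L,
    rule2_tolerance = 0.2,
    short_supply_days = 14L,
    standard_period_days = 90L,
    upto119_max_days = 119L,
    r120_min_days = 120L,
    r120_max_days = 129L,
    less90_min_days = 75L,
    less90_next_cov_min = 60L,
    less90_next_window_days = 91L,
    regular_max_gap_days = 45L,
    cap_pdc = FALSE,
    pdc_threshold = 0.8,
    mph_ddd_mg = 30,
    dose_allowed = c(0.5, 1, 1.5, 2, 3),
    dose_gap_min = 7L,
    dose_gap_max = 45L,
    dose_stability = 0.5
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad) || is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("adherence_config(): unknown configuration key(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
    cfg$study_start <- as.Date(cfg$study_start)
    cfg$study_end <- as.Date(cfg$study_end)
    cfg$database_end <- as.Date(cfg$database_end)
  }
  structure(cfg, class = "adhere_config")
}
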
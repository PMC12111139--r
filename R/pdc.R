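#' Predicted date of the next supply
#'
#' The day on which the current dispensing's cover runs out:
#' `issue_date + supply_days` (e.g. a 30-day supply issued 2014-03-20 is
#' exhausted on 2014-04-19). Supplies below one day are floored to one.
#'
#' @param issue_date Dispense date(s).
#' @param supply_days Days of cover implied by the dispensing.
#' @return `Date` vector.
#' @export
predict_next_supply <- function(issue_date, supply_days) {
  as.Date(issue_date) + pmax(1L, as.integer(supply_days))
}

#' Coverage intervals for one patient and drug type
#'
#' One half-open interval `[start, start + supply_days)` per dispensing,
#' with supply derived from quantity over the estimated units-per-day rate
#' (never from the claimed days-supply field, which is ignored for
#' consistency of method).
#'
#' @param claims Classified claim rows for one patient.
#' @param drug_type "MPH" or "AD".
#' @param config [adherence_config()].
#' @return Tibble: start, supply_days, end -- sorted by start.
#' @export
coverage_intervals <- function(claims, drug_type = c("MPH", "AD"),
                               config = adherence_config()) {
  drug_type <- match.arg(drug_type)
  sel <- claims[plot_drug_type(claims$drug_class) %in% drug_type, ,
                drop = FALSE]
  if (nrow(sel) == 0L) {
    return(tibble::tibble(start = as.Date(character()),
                          supply_days = integer(),
                          end = as.Date(character())))
  }
  sel <- dplyr::arrange(sel, dispense_date)
  upd <- claim_units_per_day(sel, config)
  sd <- claim_supply_days(sel$quantity_units, upd)
  tibble::tibble(start = sel$dispense_date, supply_days = sd,
                 end = predict_next_supply(sel$dispense_date, sd))
}

#' Days covered within a window
#'
#' Size of the union of the day sets implied by the coverage intervals,
#' clipped to `[start, end)`; overlapping supplies never double-count.
#'
#' @param start,end Window bounds (`end` exclusive).
#' @param intervals Coverage intervals ([coverage_intervals()]).
#' @return Integer day count.
#' @export
covered_days <- function(start, end, intervals) {
  start <- as.Date(start); end <- as.Date(end)
  if (nrow(intervals) == 0L || end <= start) return(0L)
  s <- pmax(as.integer(intervals$start), as.integer(start))
  e <- pmin(as.integer(intervals$end), as.integer(end))
  keep <- e > s
  if (!any(keep)) return(0L)
  s <- s[keep]; e <- e[keep]
  ord <- order(s, e)
  s <- s[ord]; e <- e[ord]
  total <- 0L
  cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] <= cur_e) {
      cur_e <- max(cur_e, e[i])
    } else {
      total <- total + (cur_e - cur_s)
      cur_s <- s[i]; cur_e <- e[i]
    }
  }
  as.integer(total + (cur_e - cur_s))
}

# any calendar month strictly between the months of s and e with no issue?
has_empty_month_between <- function(s, e, issue_dates) {
  ms <- format(as.Date(s), "%Y-%m"); me <- format(as.Date(e), "%Y-%m")
  first_next <- as.Date(paste0(ms, "-01"))
  seq_months <- seq(first_next, as.Date(paste0(me, "-01")), by = "month")
  inner <- setdiff(format(seq_months, "%Y-%m"), c(ms, me))
  if (!length(inner)) return(FALSE)
  occupied <- unique(format(as.Date(issue_dates), "%Y-%m"))
  any(!inner %in% occupied)
}

#' Segment a dispensing stream into PDC assessment periods
#'
#' Greedy left-to-right segmentation anchored on issue dates. Each period
#' opens at a dispensing and nominally runs 90 days, adjusted by the
#' observed dispensing dates:
#' \itemize{
#'   \item shortened below 90 days when a month inside the period holds no
#'     issue and the next period opens slightly before the nominal end
#'     (>= `less90_min_days`) with at least 60 covered days in its first
#'     91 days ("less than 90");
#'   \item extended to a next issue falling 120--129 days out under a
#'     regular refill pattern ("120--129 days");
#'   \item extended to a next issue falling 91--119 days out ("over 90");
#'   \item extended to the final coverage end, capped at 119 days, when no
#'     further issue follows within the bands above ("up to 119");
#'   \item otherwise closed at the standard 90 days.
#' }
#' Any period running past the database end is truncated there (terminal
#' period; may be shorter than 90 days). Rule precedence follows
#' specific-before-general; the applied rule is recorded per period.
#' Streams separated by a break of more than 129 days start a new period at
#' the next issue.
#'
#' @param intervals Coverage intervals for one patient and drug type.
#' @param config [adherence_config()]; `database_end` closes the terminal
#'   period.
#' @return Tibble of periods: start, end, duration_days, covered_days, pdc,
#'   rule. With `cap_pdc = FALSE` (default) covered days run to the end of
#'   supply (clipped only at the database end), so per-period PDC may
#'   exceed 1; with capping they are clipped to the period.
#' @export
segment_periods <- function(intervals, config = adherence_config()) {
  empty <- tibble::tibble(start = as.Date(character()),
                          end = as.Date(character()),
                          duration_days = integer(), covered_days = integer(),
                          pdc = numeric(), rule = character())
  n <- nrow(intervals)
  if (n == 0L) return(empty)
  stopifnot(!is.unsorted(intervals$start))
  d <- intervals$start
  cov_end_i <- intervals$end
  db_end <- as.Date(config$database_end)
  std <- config$standard_period_days

  periods <- list()
  i <- 1L
  while (i <= n) {
    s <- d[i]
    in_win <- which(d >= s & d < s + std)
    nxt <- if (max(in_win) < n) max(in_win) + 1L else NA_integer_
    cov_end <- max(cov_end_i[in_win])
    D <- function(x) days_between(s, x)
    rule <- NA_character_; e <- NULL

    # less-than-90: an empty month inside the period, next period opening
    # slightly before the nominal end with solid coverage
    cand <- rev(in_win[in_win > i])
    for (j in cand) {
      if (D(d[j]) >= config$less90_min_days && D(d[j]) < std &&
          has_empty_month_between(s, d[j], d) ) {
        nx_rows <- which(d >= d[j] & d < d[j] + config$less90_next_window_days)
        nx_cov <- covered_days(d[j], d[j] + config$less90_next_window_days,
                               intervals[nx_rows, , drop = FALSE])
        if (nx_cov >= config$less90_next_cov_min) {
          e <- d[j]; rule <- "less_90"
        }
        break
      }
    }
    if (is.null(e) && !is.na(nxt)) {
      Dn <- D(d[nxt])
      if (Dn >= config$r120_min_days && Dn <= config$r120_max_days &&
          regular_pattern(d[in_win], config)) {
        e <- d[nxt]; rule <- "120_129"
      } else if (Dn > std && Dn <= config$upto119_max_days) {
        e <- d[nxt]; rule <- "over_90"
      }
    }
    if (is.null(e) && cov_end > s + std) {
      e <- min(cov_end, s + config$upto119_max_days); rule <- "up_to_119"
    }
    if (is.null(e)) {
      e <- s + std; rule <- "standard"
    }
    if (e > db_end) {
      e <- db_end; rule <- "db_end"
    }
    in_period <- which(d >= s & d < e)
    if (!length(in_period)) in_period <- i  # degenerate: issue on db_end
    clip_end <- if (isTRUE(config$cap_pdc)) e else db_end
    cov <- covered_days(s, clip_end, intervals[in_period, , drop = FALSE])
    dur <- max(1L, days_between(s, e))
    periods[[length(periods) + 1L]] <- tibble::tibble(
      start = s, end = e, duration_days = dur,
      covered_days = cov, pdc = cov / dur, rule = rule)
    nxt_i <- which(d >= e)
    if (!length(nxt_i)) break
    i <- min(nxt_i)
  }
  dplyr::bind_rows(periods)
}

# monthly-looking refill cadence within a period window
regular_pattern <- function(dates, config) {
  if (length(dates) < 2L) return(FALSE)
  gaps <- as.integer(diff(sort(dates)))
  max(gaps) <= config$regular_max_gap_days
}

#' Average PDC per patient and drug type
#'
#' Unweighted mean of per-period PDC values; a patient with no assessment
#' periods yields NA (missing, never zero).
#'
#' @param periods Output of [segment_periods()].
#' @return Numeric scalar (possibly NA).
#' @export
average_pdc <- function(periods) {
  if (nrow(periods) == 0L) return(NA_real_)
  mean(periods$pdc)
}

#' Prescribed Daily Dose
#'
#' Total dispensed drug mass over the days of drug cover, with an optional
#' ratio to the Defined Daily Dose.
#'
#' @param claims Methylphenidate claim rows for one patient.
#' @param covered_days_total Days of drug cover (union of coverage
#'   intervals clipped at the database end).
#' @param ddd_mg Reference DDD in mg (default from config, 30 mg for
#'   methylphenidate); NA suppresses the ratio.
#' @return Tibble: total_mg, covered_days, pdd_mg_per_day, ratio_to_ddd.
#'   Zero covered days yields NA doses (missing, never zero).
#' @export
compute_pdd <- function(claims, covered_days_total, ddd_mg = NA_real_) {
  total_mg <- sum(claims$strength_mg * claims$quantity_units)
  if (is.na(covered_days_total) || covered_days_total <= 0) {
    return(tibble::tibble(total_mg = total_mg, covered_days = 0L,
                          pdd_mg_per_day = NA_real_,
                          ratio_to_ddd = NA_real_))
  }
  pdd <- total_mg / covered_days_total
  tibble::tibble(total_mg = total_mg,
                 covered_days = as.integer(covered_days_total),
                 pdd_mg_per_day = pdd,
                 ratio_to_ddd = if (is.finite(ddd_mg)) pdd / ddd_mg
                 else NA_real_)
}

#' Per-patient, per-drug-type adherence summary
#'
#' Runs segmentation and PDC averaging for both drug types of every
#' included patient, joins the TAG classification and months supplied, and
#' derives the methylphenidate PDD.
#'
#' @param claims_set A `claims_set`.
#' @param cohort [build_cohort()] output.
#' @param plots [build_monthly_plots()] output.
#' @param tags [classify_tag_all()] output.
#' @param formulary Formulary tibble.
#' @param config [adherence_config()].
#' @return List: `summary` (patient_id, group, gender, drug_type,
#'   n_periods, months_supplied, average_pdc, total_mg, pdd_mg_per_day,
#'   ratio_to_ddd, tag) and `periods` (stacked period table).
#' @export
adherence_summary <- function(claims_set, cohort, plots, tags,
                              formulary = default_formulary(),
                              config = adherence_config()) {
  keep <- cohort$patient_id[cohort$status == "INCLUDED"]
  cl <- claims_set$claims[claims_set$claims$patient_id %in% keep, ,
                          drop = FALSE]
  filt <- filter_tricyclic_misuse(cl, formulary, config)
  cl <- filt$kept
  rows <- list(); pds <- list()
  for (pid in keep) {
    pcl <- cl[cl$patient_id == pid, , drop = FALSE]
    for (ty in c("MPH", "AD")) {
      iv <- coverage_intervals(pcl, ty, config)
      per <- segment_periods(iv, config)
      if (nrow(per)) {
        per$patient_id <- pid; per$drug_type <- ty
        pds[[length(pds) + 1L]] <- per
      }
      months_ty <- sum(plots$grid$n_nonshort[
        plots$grid$patient_id == pid & plots$grid$drug_type == ty] > 0L)
      if (ty == "MPH") {
        mph_cl <- pcl[plot_drug_type(pcl$drug_class) == "MPH", , drop = FALSE]
        cov_total <- covered_days(config$study_start, config$database_end, iv)
        pdd <- compute_pdd(mph_cl, cov_total, config$mph_ddd_mg)
      } else {
        pdd <- tibble::tibble(total_mg = NA_real_, covered_days = NA_integer_,
                              pdd_mg_per_day = NA_real_,
                              ratio_to_ddd = NA_real_)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        patient_id = pid, drug_type = ty, n_periods = nrow(per),
        months_supplied = months_ty, average_pdc = average_pdc(per),
        total_mg = pdd$total_mg, pdd_mg_per_day = pdd$pdd_mg_per_day,
        ratio_to_ddd = pdd$ratio_to_ddd)
    }
  }
  smry <- dplyr::bind_rows(rows)
  smry <- dplyr::left_join(smry, cohort[, c("patient_id", "group")],
                           by = "patient_id")
  smry <- dplyr::left_join(smry,
                           claims_set$patients[, c("patient_id", "gender")],
                           by = "patient_id")
  smry <- dplyr::left_join(smry, tags[, c("patient_id", "tag")],
                           by = "patient_id")
  list(summary = smry,
       periods = if (length(pds)) dplyr::bind_rows(pds) else
         tibble::tibble())
}
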
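#' Estimate units per day from a refill stream
#'
#' When a stream shows at least two stable refill gaps in the monthly-refill
#' range, the daily dose is the median quantity/gap ratio snapped to the
#' nearest sensible tablet rate; otherwise the default of one unit per day
#' is assumed (the fallback when dispensed quantities cannot be empirically
#' linked to a dosage).
#'
#' @param dates Dispense dates of consecutive same-drug claims (sorted or
#'   not; sorted internally).
#' @param quantities Units dispensed per claim.
#' @param default Fallback rate (1 unit/day).
#' @param config [adherence_config()]; uses `dose_gap_min`, `dose_gap_max`,
#'   `dose_stability` and the snap set `dose_allowed`.
#' @return A single units-per-day value.
#' @export
estimate_daily_dose <- function(dates, quantities, default = 1,
                                config = adherence_config()) {
  ord <- order(as.Date(dates))
  dates <- as.Date(dates)[ord]
  quantities <- quantities[ord]
  if (length(dates) < 3L) return(default)
  gaps <- as.integer(diff(dates))
  valid <- which(gaps >= config$dose_gap_min & gaps <= config$dose_gap_max)
  if (length(valid) < 2L) return(default)
  g <- gaps[valid]
  if ((max(g) - min(g)) / stats::median(g) > config$dose_stability) {
    return(default)  # gaps too erratic to evidence a rate
  }
  ratio <- stats::median(quantities[valid] / g)
  allowed <- config$dose_allowed
  # evidence far outside any plausible tablet rate is no evidence at all
  if (ratio > 1.5 * max(allowed) || ratio < min(allowed) / 1.5) return(default)
  allowed[which.min(abs(allowed - ratio))]
}

# per-claim units/day, estimated per patient x drug_code stream
claim_units_per_day <- function(claims, config = adherence_config()) {
  upd <- rep(1, nrow(claims))
  key <- paste(claims$patient_id, claims$drug_code)
  for (k in unique(key)) {
    rows <- which(key == k)
    upd[rows] <- estimate_daily_dose(claims$dispense_date[rows],
                                     claims$quantity_units[rows],
                                     config = config)
  }
  upd
}

# days of cover implied by one claim
claim_supply_days <- function(quantity_units, upd) {
  pmax(1L, as.integer(floor(quantity_units / upd)))
}

# ---- dispensing-month reassignment ---------------------------------------

# attempt the two reassignment rules on a month holding exactly two claims;
# tbl: claim table for one patient x drug type with assigned_month, moved
try_reassign <- function(tbl, m, config) {
  none <- list(rule = "NONE")
  rows <- which(tbl$assigned_month == m)
  if (length(rows) != 2L) return(none)
  rows <- rows[order(tbl$dispense_date[rows])]
  c1 <- rows[1]; c2 <- rows[2]
  occupied <- unique(tbl$assigned_month)
  prev_empty <- (m - 1L) >= 1L && !(m - 1L) %in% occupied
  next_empty <- (m + 1L) <= config$n_months && !(m + 1L) %in% occupied
  gap <- days_between(tbl$dispense_date[c1], tbl$dispense_date[c2])

  win <- which(tbl$assigned_month >= m - 3L & tbl$assigned_month <= m + 3L)
  sig <- paste(tbl$drug_code[win], tbl$strength_mg[win],
               tbl$quantity_units[win])
  modal <- names(sort(table(sig), decreasing = TRUE))[1]
  matches_modal <- function(i) {
    paste(tbl$drug_code[i], tbl$strength_mg[i], tbl$quantity_units[i]) == modal
  }

  # Rule 1: wide gap, an adjacent month is empty, and the moving claim fits
  # the stable local pattern; the claim nearer the empty month moves into it
  if (gap >= config$rule1_min_gap_days && (prev_empty || next_empty)) {
    cand <- list()
    if (next_empty && !tbl$moved[c2] && matches_modal(c2)) {
      month_end <- as.Date(paste0(study_month_label(m + 1L, config$study_start),
                                  "-01")) - 1L
      cand[[length(cand) + 1L]] <- list(
        row = c2, to = m + 1L,
        dist = days_between(tbl$dispense_date[c2], month_end))
    }
    if (prev_empty && !tbl$moved[c1] && matches_modal(c1)) {
      month_start <- as.Date(paste0(study_month_label(m, config$study_start),
                                    "-01"))
      cand[[length(cand) + 1L]] <- list(
        row = c1, to = m - 1L,
        dist = days_between(month_start, tbl$dispense_date[c1]))
    }
    if (length(cand)) {
      best <- cand[[which.min(vapply(cand, `[[`, 0, "dist"))]]
      return(list(rule = "RULE1", row = best$row, to = best$to,
                  rationale = sprintf(
                    "gap %d days >= %d, adjacent month empty, matches stable pattern",
                    gap, config$rule1_min_gap_days)))
    }
  }

  # Rule 2: regular local trend whose units/day ratio matches the estimated
  # dose; the later (early-refill) claim is attributed to the next month
  if (next_empty && !tbl$moved[c2] && length(win) >= 4L) {
    win <- win[order(tbl$dispense_date[win])]
    span <- days_between(tbl$dispense_date[win[1]],
                         tbl$dispense_date[win[length(win)]])
    if (span > 0) {
      ratio <- sum(tbl$quantity_units[win[-length(win)]]) / span
      est <- stats::median(tbl$upd[win])
      if (est > 0 && abs(ratio - est) / est <= config$rule2_tolerance) {
        return(list(rule = "RULE2", row = c2, to = m + 1L,
                    rationale = sprintf(
                      "window units/day %.2f within %.0f%% of estimated dose %.2f",
                      ratio, 100 * config$rule2_tolerance, est)))
      }
    }
  }
  none
}

#' Reassign dispensing months for a claim stream
#'
#' Iteratively applies the two reassignment rules to every calendar month
#' holding exactly two same-type dispensings, until the grid is stable.
#' Each claim moves at most one month and actual dispensing records are
#' never altered -- only the plotted month.
#'
#' @param tbl Claim table for one patient and drug type with columns
#'   dispense_date, drug_code, strength_mg, quantity_units, upd,
#'   assigned_month (initially the calendar month index).
#' @param config [adherence_config()].
#' @return List with the updated `claims` table (assigned_month, moved) and
#'   an `audit` tibble of reassignment decisions.
#' @export
reassign_months <- function(tbl, config = adherence_config()) {
  tbl$moved <- rep(FALSE, nrow(tbl))
  audit <- list()
  for (iter in seq_len(50L)) {
    counts <- table(tbl$assigned_month)
    months2 <- sort(as.integer(names(counts)[counts == 2L]))
    changed <- FALSE
    for (m in months2) {
      dec <- try_reassign(tbl, m, config)
      if (dec$rule != "NONE") {
        audit[[length(audit) + 1L]] <- tibble::tibble(
          patient_id = tbl$patient_id[dec$row],
          drug_type = tbl$drug_type[dec$row],
          dispense_date = tbl$dispense_date[dec$row],
          original_month = m, assigned_month = dec$to,
          rule = dec$rule, rationale = dec$rationale)
        tbl$assigned_month[dec$row] <- dec$to
        tbl$moved[dec$row] <- TRUE
        changed <- TRUE
        break
      }
    }
    if (!changed) break
  }
  list(claims = tbl,
       audit = if (length(audit)) dplyr::bind_rows(audit) else
         tibble::tibble(patient_id = character(), drug_type = character(),
                        dispense_date = as.Date(character()),
                        original_month = integer(),
                        assigned_month = integer(), rule = character(),
                        rationale = character()))
}

#' Build the monthly issuance grid for one patient and drug type
#'
#' Consolidates dispensing events into the 60-month study grid: each claim
#' is assigned its (possibly reassigned) issuance month; claims whose
#' implied coverage is below the short-supply cut-off are flagged so they
#' are never read as a month of medicine coverage.
#'
#' @param claims Classified claim rows for one patient (tricyclic filter
#'   already applied for the antidepressant type).
#' @param drug_type "MPH" (methylphenidate/atomoxetine) or "AD"
#'   (antidepressants).
#' @param config [adherence_config()].
#' @return List with `grid` (patient_id, drug_type, month_index, ym, units,
#'   n_issues, n_nonshort, short_supply, reassigned) covering all 60 months,
#'   and `audit` of reassignment decisions.
#' @export
build_monthly_grid <- function(claims, drug_type = c("MPH", "AD"),
                               config = adherence_config()) {
  drug_type <- match.arg(drug_type)
  pid <- if (nrow(claims)) claims$patient_id[1] else NA_character_
  sel <- claims[plot_drug_type(claims$drug_class) %in% drug_type, ,
                drop = FALSE]
  months <- tibble::tibble(
    patient_id = pid, drug_type = drug_type,
    month_index = seq_len(config$n_months),
    ym = study_month_label(seq_len(config$n_months), config$study_start),
    units = 0L, n_issues = 0L, n_nonshort = 0L,
    short_supply = FALSE, reassigned = FALSE)
  audit <- reassign_months(empty_plot_claims(), config)$audit
  if (nrow(sel) == 0L) return(list(grid = months, audit = audit))

  sel <- dplyr::arrange(sel, dispense_date)
  sel$drug_type <- drug_type
  sel$upd <- claim_units_per_day(sel, config)
  sel$supply_days <- claim_supply_days(sel$quantity_units, sel$upd)
  sel$short <- sel$supply_days < config$short_supply_days
  sel$assigned_month <- study_month_index(sel$dispense_date,
                                          config$study_start)
  res <- reassign_months(sel, config)
  sel <- res$claims

  agg <- dplyr::summarise(
    dplyr::group_by(sel, month_index = assigned_month),
    units = sum(quantity_units),
    n_issues = dplyr::n(),
    n_nonshort = sum(!short),
    reassigned = any(moved), .groups = "drop")
  i <- match(agg$month_index, months$month_index)
  months$units[i] <- as.integer(agg$units)
  months$n_issues[i] <- as.integer(agg$n_issues)
  months$n_nonshort[i] <- as.integer(agg$n_nonshort)
  months$short_supply[i] <- agg$n_nonshort == 0L
  months$reassigned[i] <- agg$reassigned
  list(grid = months, audit = res$audit)
}

empty_plot_claims <- function() {
  tibble::tibble(patient_id = character(), drug_type = character(),
                 dispense_date = as.Date(character()), drug_code = character(),
                 strength_mg = numeric(), quantity_units = integer(),
                 upd = numeric(), assigned_month = integer())
}

utils::globalVariables(c("moved", "short"))

#' Monthly plots for every included patient
#'
#' Applies the tricyclic filter to the antidepressant stream, then builds
#' both drug-type grids per patient.
#'
#' @param claims_set A `claims_set`.
#' @param cohort Output of [build_cohort()]; only INCLUDED patients are
#'   plotted.
#' @param formulary Formulary tibble.
#' @param config [adherence_config()].
#' @return List: `grid` (stacked monthly grids), `audit` (reassignment
#'   decisions), `tca_excluded` (audited tricyclic exclusions).
#' @export
build_monthly_plots <- function(claims_set, cohort,
                                formulary = default_formulary(),
                                config = adherence_config()) {
  keep <- cohort$patient_id[cohort$status == "INCLUDED"]
  cl <- claims_set$claims[claims_set$claims$patient_id %in% keep, ,
                          drop = FALSE]
  filt <- filter_tricyclic_misuse(cl, formulary, config)
  grids <- list(); audits <- list()
  for (pid in keep) {
    pcl <- filt$kept[filt$kept$patient_id == pid, , drop = FALSE]
    for (ty in c("MPH", "AD")) {
      g <- build_monthly_grid(pcl, ty, config)
      g$grid$patient_id <- pid
      grids[[length(grids) + 1L]] <- g$grid
      audits[[length(audits) + 1L]] <- g$audit
    }
  }
  list(grid = dplyr::bind_rows(grids),
       audit = dplyr::bind_rows(audits),
       tca_excluded = filt$excluded)
}

#' Treatment-adherent-group classification
#'
#' A patient belongs to the TAG when they received 12 or more monthly
#' issues of either drug type over the five-year window and at least seven
#' monthly issues within some 12-month span. A month counts once, however
#' many drug types were issued in it, and months holding only short-supply
#' issues never count.
#'
#' @param grid Monthly grid rows for one patient (both drug types).
#' @param policy "AND" (default; both criteria must hold) or "OR".
#' @param config [adherence_config()].
#' @return Tibble: patient_id, tag, total_monthly_issues,
#'   max_issues_in_any_12_months.
#' @export
classify_tag <- function(grid, policy = NULL, config = adherence_config()) {
  policy <- toupper(policy %||% config$tag_policy)
  stopifnot(policy %in% c("AND", "OR"))
  issue_months <- sort(unique(grid$month_index[grid$n_nonshort > 0L]))
  total <- length(issue_months)
  nwin <- config$n_months - config$tag_window_months + 1L
  maxwin <- 0L
  if (total) {
    for (w in seq_len(nwin)) {
      maxwin <- max(maxwin, sum(issue_months >= w &
                                  issue_months < w + config$tag_window_months))
    }
  }
  c1 <- total >= config$tag_total_min
  c2 <- maxwin >= config$tag_window_min
  tibble::tibble(
    patient_id = if (nrow(grid)) grid$patient_id[1] else NA_character_,
    tag = if (policy == "AND") c1 && c2 else c1 || c2,
    total_monthly_issues = total,
    max_issues_in_any_12_months = as.integer(maxwin))
}

#' TAG classification for every patient in a stacked grid
#'
#' @param grid Stacked monthly grid from [build_monthly_plots()].
#' @inheritParams classify_tag
#' @return One row per patient, as in [classify_tag()].
#' @export
classify_tag_all <- function(grid, policy = NULL,
                             config = adherence_config()) {
  dplyr::bind_rows(lapply(split(grid, grid$patient_id), classify_tag,
                          policy = policy, config = config))
}
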
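#' Eligibility status for one patient
#'
#' Applies the first two cohort gates in order: the age gate (at least 18.0
#' years at study start, and between `min_age` and `max_age` at some point
#' during the index year) and the index-claim gate (at least one claim of
#' the index drug classification -- methylphenidate, atomoxetine or
#' flumazenil -- dispensed during the index year).
#'
#' @param claims Claim rows for one patient (classified).
#' @param birth_date Patient date of birth.
#' @param config [adherence_config()].
#' @return One of "INCLUDED" (provisionally), "EXCLUDED_AGE",
#'   "EXCLUDED_NO_INDEX_CLAIM".
#' @export
assess_eligibility <- function(claims, birth_date, config = adherence_config()) {
  iy_start <- as.Date(sprintf("%d-01-01", config$index_year))
  iy_end <- as.Date(sprintf("%d-12-31", config$index_year))
  age_at_start <- patient_age(birth_date, config$study_start)
  # in-band at some point of the index year: old enough by its end,
  # not over the cap at its start
  if (age_at_start < config$min_age ||
      patient_age(birth_date, iy_end) < config$min_age ||
      patient_age(birth_date, iy_start) > config$max_age) {
    return("EXCLUDED_AGE")
  }
  idx <- claims$drug_class %in% INDEX_CLASSES &
    claim_year(claims$dispense_date) == config$index_year
  if (!any(idx)) return("EXCLUDED_NO_INDEX_CLAIM")
  "INCLUDED"
}

#' Flumazenil-only gate
#'
#' TRUE (exclude) when the patient's index-class claims are exclusively
#' flumazenil and no F90 code appears on any claim: such patients received
#' no ADHD-indicated drug and carry no ADHD diagnosis.
#'
#' @inheritParams assess_eligibility
#' @return Logical scalar.
#' @export
exclude_flumazenil_only <- function(claims) {
  idx <- claims$drug_class %in% INDEX_CLASSES
  if (!any(idx)) return(FALSE)
  all(claims$drug_class[idx] == "FLUMAZENIL") &&
    !any(has_icd_prefix(claims$icd10_codes, "F90"))
}

#' Diagnostic group from ICD-10 codes
#'
#' F90 when any claim over the whole study window carries a code beginning
#' "F90" (F90.0, F90.1, F90.8, F90.9 all match, case-insensitively);
#' otherwise NON_F90. Monotone: adding an F90 code never removes the label.
#'
#' @inheritParams assess_eligibility
#' @return "F90" or "NON_F90".
#' @export
assign_diagnostic_group <- function(claims) {
  if (any(has_icd_prefix(claims$icd10_codes, "F90"))) "F90" else "NON_F90"
}

#' Apply the full cohort cascade
#'
#' Gates run in a fixed order -- age, index claim, flumazenil-only -- so
#' each exclusion is attributed to exactly one gate and the per-gate counts
#' plus the included count always sum to the input patient count.
#'
#' @param claims_set A `claims_set` from [read_claims()] /
#'   [as_claims_set()].
#' @param config [adherence_config()].
#' @return Tibble: patient_id, status, group, reasons.
#' @export
build_cohort <- function(claims_set, config = adherence_config()) {
  stopifnot(inherits(claims_set, "claims_set"))
  pats <- claims_set$patients
  cl <- claims_set$claims
  by_pat <- split(seq_len(nrow(cl)), cl$patient_id)
  out <- lapply(seq_len(nrow(pats)), function(i) {
    pid <- pats$patient_id[i]
    pcl <- cl[by_pat[[pid]] %||% integer(0), , drop = FALSE]
    status <- assess_eligibility(pcl, pats$birth_date[i], config)
    reasons <- character(0)
    if (status == "INCLUDED" && exclude_flumazenil_only(pcl)) {
      status <- "EXCLUDED_FLUMAZENIL_ONLY"
    }
    group <- "NOT_ASSIGNED"
    if (status == "INCLUDED") {
      group <- assign_diagnostic_group(pcl)
    } else {
      reasons <- switch(status,
        EXCLUDED_AGE = sprintf("under %d years at study start or outside %d-%d in index year",
                               config$min_age, config$min_age, config$max_age),
        EXCLUDED_NO_INDEX_CLAIM = sprintf("no index-class claim in %d",
                                          config$index_year),
        EXCLUDED_FLUMAZENIL_ONLY = "only flumazenil of the index drug classes, no F90 code")
    }
    tibble::tibble(patient_id = pid, status = status, group = group,
                   reasons = paste(reasons, collapse = "; "))
  })
  dplyr::bind_rows(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gate-count summary for the exclusion cascade
#'
#' @param cohort Output of [build_cohort()].
#' @return Tibble mirroring the cascade: total, excluded per gate, included.
#' @export
gate_summary <- function(cohort) {
  tibble::tibble(
    gate = c("total_identified", "excluded_age", "excluded_no_index_claim",
             "excluded_flumazenil_only", "included"),
    n = c(nrow(cohort),
          sum(cohort$status == "EXCLUDED_AGE"),
          sum(cohort$status == "EXCLUDED_NO_INDEX_CLAIM"),
          sum(cohort$status == "EXCLUDED_FLUMAZENIL_ONLY"),
          sum(cohort$status == "INCLUDED"))
  )
}

#' Filter sub-therapeutic / off-indication tricyclic claims
#'
#' Tricyclic antidepressant dispensings are excluded from the
#' antidepressant analysis when the implied daily dose falls below the
#' accepted minimum antidepressant dose for the agent, the implied coverage
#' is short-term, or the claim carries diagnostic codes none of which is a
#' mood-disorder code. Excluded claims are retained for audit.
#'
#' @param claims Classified claim rows (any number of patients).
#' @param formulary Formulary with `min_antidepressant_dose_mg` per agent.
#' @param config [adherence_config()]; uses `tca_short_term_days` and
#'   `mood_icd_prefixes`.
#' @return List with `kept` and `excluded` claim tibbles (the latter with a
#'   `reason` column).
#' @export
filter_tricyclic_misuse <- function(claims, formulary = default_formulary(),
                                    config = adherence_config()) {
  is_tca <- claims$drug_class == "AD_TCA"
  if (!any(is_tca)) {
    return(list(kept = claims, excluded = claims[0, , drop = FALSE]))
  }
  # units/day estimated per patient x drug stream, default 1
  upd <- rep(1, nrow(claims))
  tca <- which(is_tca)
  key <- paste(claims$patient_id[tca], claims$drug_code[tca])
  for (k in unique(key)) {
    rows <- tca[key == k]
    upd[rows] <- estimate_daily_dose(claims$dispense_date[rows],
                                     claims$quantity_units[rows],
                                     config = config)
  }
  min_dose <- formulary$min_antidepressant_dose_mg[
    match(claims$drug_code, formulary$drug_code)]
  min_dose[is.na(min_dose)] <- 75  # conservative default for unlisted TCAs

  daily_mg <- claims$strength_mg * upd
  coverage <- claims$quantity_units / upd
  no_icd <- is.na(claims$icd10_codes) | claims$icd10_codes == ""
  mood <- has_icd_prefix(claims$icd10_codes, config$mood_icd_prefixes)

  reason <- rep(NA_character_, nrow(claims))
  reason[is_tca & daily_mg < min_dose] <- "sub-therapeutic daily dose"
  reason[is_tca & is.na(reason) & coverage < config$tca_short_term_days] <-
    "short-term coverage"
  reason[is_tca & is.na(reason) & !no_icd & !mood] <-
    "no mood-disorder diagnostic code"

  drop <- !is.na(reason)
  excluded <- claims[drop, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- reason[drop]
  list(kept = claims[!drop, , drop = FALSE], excluded = excluded)
}
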
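CLAIMS_SCHEMA <- c("patient_id", "gender", "birth_date", "dispense_date",
                   "drug_code", "drug_name", "strength_mg", "quantity_units",
                   "days_supply", "icd10_codes")

#' Read, validate and classify a dispensing-claims CSV
#'
#' Parses the canonical flat claims table, classifies every claim against
#' the formulary, sorts claims by patient and dispense date, and collects
#' malformed rows into a rejects report rather than dropping them silently.
#'
#' @param path Path to a claims CSV with header
#'   `patient_id, gender, birth_date, dispense_date, drug_code, drug_name,
#'   strength_mg, quantity_units, days_supply, icd10_codes`
#'   (`days_supply` and `icd10_codes` may be blank; multiple ICD-10 codes
#'   are semicolon-delimited).
#' @param formulary Formulary tibble, see [default_formulary()].
#' @param config [adherence_config()]; the study window bounds valid
#'   dispense dates.
#' @return A `claims_set`: list with `patients` (one row per patient:
#'   patient_id, gender, birth_date), `claims` (classified, sorted claim
#'   rows) and `rejects` (row_number, reason).
#' @export
read_claims <- function(path, formulary = default_formulary(),
                        config = adherence_config()) {
  if (!file.exists(path)) stop("claims file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(CLAIMS_SCHEMA, names(raw))
  if (length(missing_cols)) {
    stop("claims schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  as_claims_set(raw[, CLAIMS_SCHEMA, drop = FALSE], formulary, config)
}

#' Build a claims_set from an in-memory claims table
#'
#' Same validation and classification path as [read_claims()], for claim
#' tables produced in code (e.g. by [generate_cohort()]).
#'
#' @param raw Data frame with the canonical claim columns (character or
#'   typed).
#' @inheritParams read_claims
#' @return A `claims_set` (see [read_claims()]).
#' @export
as_claims_set <- function(raw, formulary = default_formulary(),
                          config = adherence_config()) {
  raw <- as.data.frame(raw, stringsAsFactors = FALSE)
  missing_cols <- setdiff(CLAIMS_SCHEMA, names(raw))
  if (length(missing_cols)) {
    stop("claims schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  if (n == 0L) {
    return(structure(list(
      patients = tibble::tibble(patient_id = character(),
                                gender = character(),
                                birth_date = as.Date(character())),
      claims = empty_claims(),
      rejects = tibble::tibble(row_number = integer(), reason = character())
    ), class = "claims_set"))
  }

  dd <- as.Date(as.character(raw$dispense_date), format = "%Y-%m-%d")
  bd <- as.Date(as.character(raw$birth_date), format = "%Y-%m-%d")
  qty <- suppressWarnings(as.integer(raw$quantity_units))
  strn <- suppressWarnings(as.numeric(raw$strength_mg))
  dsup <- suppressWarnings(as.integer(raw$days_supply))
  gen <- toupper(trimws(as.character(raw$gender)))

  reason <- rep(NA_character_, n)
  flag <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    reason[is.na(reason) & cond] <<- why
  }
  flag(is.na(dd), "unparseable dispense_date")
  flag(dd < config$study_start | dd > config$study_end,
       "dispense_date outside study window")
  flag(is.na(bd), "unparseable birth_date")
  flag(is.na(qty) | qty < 1L, "quantity_units must be a positive integer")
  flag(is.na(strn) | strn < 0, "strength_mg must be non-negative")
  flag(!gen %in% c("F", "M"), "gender must be F or M")

  ok <- is.na(reason)
  rejects <- tibble::tibble(row_number = which(!ok), reason = reason[!ok])

  claims <- tibble::tibble(
    patient_id = as.character(raw$patient_id)[ok],
    dispense_date = dd[ok],
    drug_code = as.character(raw$drug_code)[ok],
    drug_name = as.character(raw$drug_name)[ok],
    drug_class = classify_drug(as.character(raw$drug_code)[ok], formulary),
    strength_mg = strn[ok],
    quantity_units = qty[ok],
    days_supply = dsup[ok],
    icd10_codes = toupper(trimws(as.character(raw$icd10_codes)[ok]))
  )
  claims <- dplyr::arrange(claims, patient_id, dispense_date, drug_code)

  patients <- tibble::tibble(
    patient_id = as.character(raw$patient_id)[ok],
    gender = gen[ok],
    birth_date = bd[ok]
  )
  patients <- dplyr::distinct(dplyr::arrange(patients, patient_id),
                              patient_id, .keep_all = TRUE)

  structure(list(patients = patients, claims = claims, rejects = rejects),
            class = "claims_set")
}

empty_claims <- function() {
  tibble::tibble(
    patient_id = character(), dispense_date = as.Date(character()),
    drug_code = character(), drug_name = character(),
    drug_class = character(), strength_mg = numeric(),
    quantity_units = integer(), days_supply = integer(),
    icd10_codes = character()
  )
}

#' @export
print.claims_set <- function(x, ...) {
  cat("<claims_set> ", nrow(x$claims), " claims, ",
      nrow(x$patients), " patients, ", nrow(x$rejects), " rejected rows\n",
      sep = "")
  invisible(x)
}

#' Write a claims_set back to the canonical CSV layout
#'
#' Round-trips the valid rows of [read_claims()]: dates ISO-8601, ICD-10
#' codes semicolon-delimited, blanks for missing days_supply.
#'
#' @param x A `claims_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_claims <- function(x, path) {
  stopifnot(inherits(x, "claims_set"))
  df <- dplyr::left_join(x$claims, x$patients, by = "patient_id")
  out <- data.frame(
    patient_id = df$patient_id,
    gender = df$gender,
    birth_date = format(df$birth_date, "%Y-%m-%d"),
    dispense_date = format(df$dispense_date, "%Y-%m-%d"),
    drug_code = df$drug_code,
    drug_name = df$drug_name,
    strength_mg = df$strength_mg,
    quantity_units = df$quantity_units,
    days_supply = ifelse(is.na(df$days_supply), "", df$days_supply),
    icd10_codes = df$icd10_codes,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# split semicolon-delimited ICD strings into a list of code vectors
parse_icd <- function(x) {
  strsplit(ifelse(is.na(x), "", x), ";\\s*")
}

# TRUE where any code on the claim starts with any of the given prefixes
has_icd_prefix <- function(icd10_codes, prefixes) {
  pat <- paste0("(^|;)\\s*(", paste(toupper(prefixes), collapse = "|"), ")")
  grepl(pat, toupper(ifelse(is.na(icd10_codes), "", icd10_codes)))
}
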
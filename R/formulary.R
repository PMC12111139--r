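#' Recognised drug classes
#'
#' The MIMS-style classification the pipeline operates on: the index
#' "central nervous system other" drugs (methylphenidate, atomoxetine,
#' flumazenil), antidepressant subclasses, and an OTHER sink for anything
#' not in the formulary.
#' @export
DRUG_CLASSES <- c("MPH", "ATX", "AD_SSRI", "AD_TCA", "AD_OTHER",
                  "FLUMAZENIL", "OTHER")

# classes counted as the index drug classification ("CNS other")
INDEX_CLASSES <- c("MPH", "ATX", "FLUMAZENIL")
AD_CLASSES <- c("AD_SSRI", "AD_TCA", "AD_OTHER")

#' Read a formulary table
#'
#' @param path CSV with columns drug_code, drug_name, drug_class,
#'   default_units_per_day, min_antidepressant_dose_mg, ddd_mg.
#' @return A tibble of formulary entries, validated.
#' @export
read_formulary <- function(path) {
  req <- c("drug_code", "drug_name", "drug_class", "default_units_per_day",
           "min_antidepressant_dose_mg", "ddd_mg")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("formulary schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    drug_code = df$drug_code,
    drug_name = df$drug_name,
    drug_class = df$drug_class,
    default_units_per_day = as.numeric(df$default_units_per_day),
    min_antidepressant_dose_mg = suppressWarnings(
      as.numeric(df$min_antidepressant_dose_mg)),
    ddd_mg = suppressWarnings(as.numeric(df$ddd_mg))
  )
  validate_formulary(out)
  out
}

#' Packaged default formulary
#'
#' A compact formulary covering the drugs the analysis needs:
#' methylphenidate, atomoxetine, flumazenil, and common antidepressants
#' with their accepted minimum antidepressant daily doses (used by the
#' tricyclic sub-therapeutic filter). Override with [read_formulary()].
#'
#' @return Formulary tibble.
#' @export
default_formulary <- function() {
  read_formulary(system.file("extdata", "formulary.csv", package = "adhere",
                             mustWork = TRUE))
}

validate_formulary <- function(f) {
  if (anyDuplicated(f$drug_code)) {
    stop("formulary: duplicated drug_code", call. = FALSE)
  }
  bad <- setdiff(unique(f$drug_class), DRUG_CLASSES)
  if (length(bad)) {
    stop("formulary: unknown drug_class ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (cl in c("MPH", "ATX", "FLUMAZENIL")) {
    if (!any(f$drug_class == cl)) {
      stop("formulary: no entry of class ", cl, call. = FALSE)
    }
  }
  tca <- f$drug_class %in% AD_CLASSES
  if (any(tca & !is.finite(f$min_antidepressant_dose_mg))) {
    stop("formulary: every antidepressant entry needs ",
         "min_antidepressant_dose_mg", call. = FALSE)
  }
  invisible(f)
}

#' Classify a drug code against the formulary
#'
#' Pure lookup: unknown codes fall into the OTHER sink, never an error.
#'
#' @param drug_code Character vector of drug identifiers.
#' @param formulary Formulary tibble (default [default_formulary()]).
#' @return Character vector of drug classes (see [DRUG_CLASSES]).
#' @export
classify_drug <- function(drug_code, formulary = default_formulary()) {
  idx <- match(drug_code, formulary$drug_code)
  out <- formulary$drug_class[idx]
  out[is.na(idx)] <- "OTHER"
  out
}

# map a drug class onto the two plotted therapy types (or NA)
plot_drug_type <- function(drug_class) {
  ifelse(drug_class %in% c("MPH", "ATX"), "MPH",
         ifelse(drug_class %in% AD_CLASSES, "AD", NA_character_))
}
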
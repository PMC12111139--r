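#' Specification for a synthetic dispensing cohort
#'
#' Defines the statistical structure of a generated five-year claims
#' stream. Defaults mirror the study conditions the pipeline targets:
#' a 2012--2016 monthly dispensing window with 2015 as index year, an
#' F90 / non-F90 mix of 0.56/0.44, antidepressant co-therapy probability
#' 0.40 (F90) and 0.33 (non-F90), refill jitter of 3 days, diagnostic
#' codes absent in 2012--2013, and methylphenidate dispensed as 90 x 10 mg
#' units per month at three units a day (30 mg/day prescribed dose).
#'
#' @param n_patients Number of non-decoy patients.
#' @param seed Master RNG seed; the same (spec, seed) pair reproduces the
#'   cohort byte-for-byte, and per-patient substreams are keyed on the
#'   patient index so adding patients never perturbs earlier ones.
#' @param group_mix Named proportions over F90 / NON_F90 (sum 1).
#' @param archetype_mix Named proportions over REGULAR, IRREGULAR, HOLIDAY,
#'   DISCONTINUER, AD_DOMINANT (sum 1).
#' @param ad_cotherapy_prob Named per-group probability of an
#'   antidepressant stream.
#' @param refill_jitter_days Uniform jitter (+/- days) on scheduled refill
#'   dates.
#' @param missing_icd_years Years whose claims carry no ICD-10 codes.
#' @param decoys Named counts of UNDERAGE, FLUMAZENIL_ONLY,
#'   TCA_SUBTHERAPEUTIC decoy patients appended after the main cohort.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 89L, seed = 1L,
                        group_mix = c(F90 = 0.56, NON_F90 = 0.44),
                        archetype_mix = c(REGULAR = 0.30, IRREGULAR = 0.30,
                                          HOLIDAY = 0.15, DISCONTINUER = 0.15,
                                          AD_DOMINANT = 0.10),
                        ad_cotherapy_prob = c(F90 = 0.40, NON_F90 = 0.33),
                        refill_jitter_days = 3L,
                        missing_icd_years = c(2012L, 2013L),
                        decoys = c(UNDERAGE = 0L, FLUMAZENIL_ONLY = 0L,
                                   TCA_SUBTHERAPEUTIC = 0L)) {
  if (n_patients < 1L) stop("cohort_spec(): n_patients >= 1", call. = FALSE)
  if (abs(sum(group_mix) - 1) > 1e-8 || abs(sum(archetype_mix) - 1) > 1e-8) {
    stop("cohort_spec(): mixture proportions must sum to 1", call. = FALSE)
  }
  if (refill_jitter_days < 0) {
    stop("cohort_spec(): refill_jitter_days must be non-negative",
         call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 group_mix = group_mix, archetype_mix = archetype_mix,
                 ad_cotherapy_prob = ad_cotherapy_prob,
                 refill_jitter_days = as.integer(refill_jitter_days),
                 missing_icd_years = as.integer(missing_icd_years),
                 decoys = decoys),
            class = "cohort_spec")
}

# stable per-patient substream seed (31-bit)
patient_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 10007 + as.numeric(i) * 7919) %% 2147483647)
}

# a monthly refill schedule: every `step` days from `from`, jittered,
# truncated to the study window, optionally skipping calendar months
refill_schedule <- function(from, until, jitter, step = 30L,
                            skip_months = integer(0), n_max = Inf) {
  dates <- as.Date(character(0))
  d <- as.Date(from)
  k <- 0L
  while (d <= as.Date(until) && k < n_max) {
    dd <- d
    if (jitter > 0) dd <- d + sample(seq(-jitter, jitter), 1L)
    if (dd >= as.Date(from) && dd <= as.Date(until) &&
        !(as.integer(format(d, "%m")) %in% skip_months)) {
      dates <- c(dates, dd)
      k <- k + 1L
    } else if (!(as.integer(format(d, "%m")) %in% skip_months)) {
      # jittered off the window edge: keep the scheduled date
      dates <- c(dates, d)
      k <- k + 1L
    }
    d <- d + step
  }
  as.Date(dates, origin = "1970-01-01")
}

mph_claim_row <- function(pid, dates, quantity = 90L) {
  tibble::tibble(patient_id = pid, dispense_date = as.Date(dates),
                 drug_code = "MPH10", drug_name = "methylphenidate 10 mg tablet",
                 strength_mg = 10, quantity_units = as.integer(quantity),
                 icd10_codes = "")
}

ad_claim_row <- function(pid, dates, drug) {
  info <- list(FLX20 = c("fluoxetine 20 mg capsule", 20),
               SER50 = c("sertraline 50 mg tablet", 50),
               CIT20 = c("citalopram 20 mg tablet", 20),
               VEN75 = c("venlafaxine 75 mg capsule", 75))[[drug]]
  tibble::tibble(patient_id = pid, dispense_date = as.Date(dates),
                 drug_code = drug, drug_name = info[1],
                 strength_mg = as.numeric(info[2]), quantity_units = 30L,
                 icd10_codes = "")
}

#' Generate a seeded synthetic dispensing cohort
#'
#' Emits a claims table in the canonical schema together with
#' ground-truth labels per patient. Archetypes: REGULAR patients refill
#' monthly across the whole window; HOLIDAY patients skip June and
#' December (two one-month treatment breaks a year); DISCONTINUER streams
#' start in the index year and truncate after 6--11 fills; IRREGULAR
#' patients collect 6--11 isolated fills; AD_DOMINANT patients take
#' antidepressants monthly with sporadic methylphenidate. F90-group
#' patients carry F90 codes on stimulant claims, but only outside the
#' missing-code years; antidepressant claims carry mood-disorder codes on
#' the same terms. Decoy patients exercise the exclusion cascade and the
#' tricyclic filter.
#'
#' @param spec A [cohort_spec()].
#' @return List: `claims` (canonical claim columns plus gender/birth_date),
#'   `labels` (patient_id, archetype, group_true, status_true, tag_true,
#'   decoy_type, true_pdd, true_mean_pdc).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  cfg <- adherence_config()
  start <- cfg$study_start; endd <- cfg$study_end
  claims <- list(); labels <- list()

  add_patient <- function(i, decoy_type = NA_character_) {
    set.seed(patient_seed(spec$seed, i))
    pid <- sprintf("P%04d", i)
    gender <- sample(c("F", "M"), 1L)
    age2012 <- stats::runif(1, 18.3, 36.5)
    birth <- start - round(age2012 * 365.25)
    group <- sample(names(spec$group_mix), 1L, prob = spec$group_mix)
    archetype <- sample(names(spec$archetype_mix), 1L,
                        prob = spec$archetype_mix)
    jit <- spec$refill_jitter_days
    status_true <- "INCLUDED"
    mph <- NULL; ad <- NULL; flu <- NULL; tca <- NULL

    if (!is.na(decoy_type)) {
      archetype <- "REGULAR"
      if (decoy_type == "UNDERAGE") {
        birth <- start - round(stats::runif(1, 16.5, 17.9) * 365.25)
        mph <- refill_schedule(as.Date("2015-01-10"), as.Date("2015-12-20"),
                               jit)
        status_true <- "EXCLUDED_AGE"
      } else if (decoy_type == "FLUMAZENIL_ONLY") {
        flu <- as.Date("2015-01-01") + sample(20:320, sample(1:3, 1L))
        status_true <- "EXCLUDED_FLUMAZENIL_ONLY"
        group <- "NON_F90"
      } else if (decoy_type == "TCA_SUBTHERAPEUTIC") {
        group <- "NON_F90"  # no F90 codes are stamped on decoy claims
        mph <- refill_schedule(start + sample(5:20, 1L), endd, jit)
        tca <- refill_schedule(as.Date("2014-02-10"), as.Date("2014-08-20"),
                               jit)
      }
    } else {
      first <- start + sample(2:24, 1L)
      if (archetype == "REGULAR") {
        mph <- refill_schedule(first, endd, jit)
      } else if (archetype == "HOLIDAY") {
        mph <- refill_schedule(first, endd, jit, skip_months = c(6L, 12L))
      } else if (archetype == "DISCONTINUER") {
        mph <- refill_schedule(as.Date(sprintf("%d-01-%02d", cfg$index_year,
                                               sample(5:20, 1L))),
                               endd, jit, n_max = sample(6:11, 1L))
      } else if (archetype == "IRREGULAR") {
        mos <- sort(unique(c(sample(1:60, sample(5:10, 1L)),
                             sample(38:46, 1L))))  # ensure an index-year fill
        mph <- as.Date(paste0(study_month_label(mos, start), "-",
                              sprintf("%02d", sample(8:20, length(mos),
                                                     replace = TRUE))))
        if (jit > 0) mph <- mph + sample(seq(-jit, jit), length(mph),
                                         replace = TRUE)
      } else if (archetype == "AD_DOMINANT") {
        mos <- seq(1L, 60L, by = 5L)
        mph <- as.Date(paste0(study_month_label(mos, start), "-",
                              sprintf("%02d", sample(8:20, length(mos),
                                                     replace = TRUE))))
        if (jit > 0) mph <- mph + sample(seq(-jit, jit), length(mph),
                                         replace = TRUE)
      }
    }

    # antidepressant stream
    want_ad <- FALSE
    if (is.na(decoy_type)) {
      want_ad <- archetype == "AD_DOMINANT" ||
        stats::runif(1) < spec$ad_cotherapy_prob[[group]]
    }
    ad_drug <- sample(c("FLX20", "SER50", "CIT20", "VEN75"), 1L)
    if (want_ad) {
      if (archetype == "AD_DOMINANT") {
        ad <- refill_schedule(start + sample(2:24, 1L), endd, jit)
      } else {
        block <- sample(6:54, 1L)
        first_m <- sample(seq_len(61L - block), 1L)
        ad_first <- as.Date(paste0(study_month_label(first_m, start), "-",
                                   sprintf("%02d", sample(5:20, 1L))))
        ad <- refill_schedule(ad_first, min(endd, ad_first + 30L * block - 15L),
                              jit)
      }
    }

    # quantities: sustained monthly MPH streams are 90 units at 3/day,
    # sporadic ones 30 units at the default 1/day
    mph_qty <- if (!is.na(decoy_type) || archetype %in%
                   c("REGULAR", "HOLIDAY", "DISCONTINUER")) 90L else 30L
    rows <- list()
    if (length(mph)) rows$mph <- mph_claim_row(pid, sort(mph), mph_qty)
    if (length(ad)) rows$ad <- ad_claim_row(pid, sort(ad), ad_drug)
    if (length(flu)) {
      rows$flu <- tibble::tibble(
        patient_id = pid, dispense_date = as.Date(sort(flu)),
        drug_code = "FLU05", drug_name = "flumazenil 0.5 mg injection",
        strength_mg = 0.5, quantity_units = 2L, icd10_codes = "")
    }
    if (length(tca)) {
      rows$tca <- tibble::tibble(
        patient_id = pid, dispense_date = as.Date(sort(tca)),
        drug_code = "AMI25", drug_name = "amitriptyline 25 mg tablet",
        strength_mg = 25, quantity_units = 30L, icd10_codes = "M79.2")
    }
    cl <- dplyr::bind_rows(rows)

    # diagnostic codes, absent in the missing-code years
    if (nrow(cl)) {
      yr <- claim_year(cl$dispense_date)
      codeable <- !(yr %in% spec$missing_icd_years)
      if (group == "F90" && is.na(decoy_type)) {
        f90_code <- sample(c("F90.0", "F90.1", "F90.9"), 1L)
        stim <- cl$drug_code %in% c("MPH10", "CONC18", "ATX25")
        cl$icd10_codes[stim & codeable] <- f90_code
      }
      is_ad <- cl$drug_code %in% c("FLX20", "SER50", "CIT20", "VEN75")
      if (any(is_ad)) {
        mood <- sample(c("F32.1", "F33.1", "F41.2"), 1L)
        cl$icd10_codes[is_ad & codeable] <- mood
      }
    }
    if (nrow(cl)) {
      cl$gender <- gender
      cl$birth_date <- birth
      cl$days_supply <- ifelse(claim_year(cl$dispense_date) == 2016L,
                               30L, NA_integer_)
    }

    # ground-truth TAG intent from the intended (non-short) issue months
    short <- claim_supply_days(
      cl$quantity_units,
      ifelse(cl$quantity_units >= 90L, 3, 1)) < cfg$short_supply_days
    plot_cl <- cl[!short & cl$drug_code != "FLU05" &
                    cl$drug_code != "AMI25", , drop = FALSE]
    months <- sort(unique(study_month_index(plot_cl$dispense_date, start)))
    months <- months[months >= 1L & months <= 60L]
    total <- length(months)
    maxwin <- 0L
    for (w in seq_len(49L)) {
      maxwin <- max(maxwin, sum(months >= w & months < w + 12L))
    }
    tag_true <- status_true == "INCLUDED" && total >= cfg$tag_total_min &&
      maxwin >= cfg$tag_window_min

    labels[[length(labels) + 1L]] <<- tibble::tibble(
      patient_id = pid, archetype = archetype,
      group_true = if (status_true == "INCLUDED") group else "NOT_ASSIGNED",
      status_true = status_true, tag_true = tag_true,
      decoy_type = decoy_type,
      ad_cotherapy_true = want_ad,
      true_pdd = if (length(mph)) mph_qty / 3 * (if (mph_qty == 90L) 1 else 3)
      else NA_real_,
      true_mean_pdc = if (archetype == "REGULAR" && is.na(decoy_type))
        1.0 else NA_real_)
    claims[[length(claims) + 1L]] <<- cl
    invisible(NULL)
  }

  for (i in seq_len(spec$n_patients)) add_patient(i)
  j <- spec$n_patients
  for (dt in names(spec$decoys)) {
    for (k in seq_len(spec$decoys[[dt]])) {
      j <- j + 1L
      add_patient(j, decoy_type = dt)
    }
  }

  cl <- dplyr::bind_rows(claims)
  cl <- dplyr::arrange(cl, patient_id, dispense_date, drug_code)
  cl <- cl[, c("patient_id", "gender", "birth_date", "dispense_date",
               "drug_code", "drug_name", "strength_mg", "quantity_units",
               "days_supply", "icd10_codes")]
  list(claims = cl, labels = dplyr::bind_rows(labels))
}

#' Deterministic worked-example dispensing streams
#'
#' A six-patient fixture whose methylphenidate dispensing dates are
#' exactly the worked examples for the assessment-period rules: an
#' over-90-day stream (first period 97 days), an up-to-119-day stream
#' (118 days), a 120--129-day stream (125 days), a less-than-90-day stream
#' (82 days, whose next period spans 91 days with 60 covered), and a
#' terminal stream closed at the database end (60 days, 57 covered). Each
#' claim is 30 units at the default one unit per day (30-day supplies).
#'
#' @return Claims table in the canonical schema.
#' @export
worked_example_fixture <- function() {
  streams <- list(
    `EX-A` = c("2014-01-16", "2014-02-18", "2014-03-20", "2014-04-23"),
    `EX-B` = c("2014-08-03", "2014-10-30"),
    `EX-C` = c("2015-04-28", "2015-06-03", "2015-07-03", "2015-08-31"),
    `EX-E` = c("2013-02-25", "2013-04-13", "2013-05-18", "2013-06-27",
               "2013-08-17"),
    `EX-F` = c("2016-11-02", "2016-12-05"))
  rows <- lapply(names(streams), function(pid) {
    tibble::tibble(
      patient_id = pid, gender = "F",
      birth_date = as.Date("1990-06-15"),
      dispense_date = as.Date(streams[[pid]]),
      drug_code = "MPH10", drug_name = "methylphenidate 10 mg tablet",
      strength_mg = 10, quantity_units = 30L,
      days_supply = NA_integer_, icd10_codes = "F90.0")
  })
  dplyr::bind_rows(rows)
}
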
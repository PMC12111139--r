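#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Direct hypergeometric enumeration at fixed margins: the p-value is the
#' sum of the probabilities of all tables no more probable than the
#' observed one (probability-mass method, with a small relative tolerance
#' for floating-point ties). A zero margin yields p = 1 by convention.
#'
#' @param table 2x2 matrix of non-negative counts, or the four cells
#'   `a, b, c, d` (row-wise) as a numeric vector of length 4.
#' @return The two-sided p-value in (0, 1].
#' @export
fisher_exact <- function(table) {
  if (is.matrix(table)) {
    stopifnot(all(dim(table) == c(2L, 2L)))
    x <- as.vector(t(table))
  } else {
    stopifnot(length(table) == 4L)
    x <- as.numeric(table)
  }
  if (any(x < 0) || any(x != floor(x))) {
    stop("fisher_exact(): cells must be non-negative integers", call. = FALSE)
  }
  a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  K <- a + b; M <- c + d; n <- a + c
  if (K == 0 || M == 0 || n == 0 || (b + d) == 0) return(1)
  support <- max(0, n - M):min(K, n)
  probs <- stats::dhyper(support, K, M, n)
  obs <- stats::dhyper(a, K, M, n)
  p <- sum(probs[probs <= obs * (1 + 1e-7)])
  min(p, 1)
}

#' Dichotomise average PDC into a 2x2 adherence table
#'
#' Splits patients at `average_pdc >= threshold` (inclusive, default the
#' 0.80 adherence convention) and crosses the split with a binary grouping
#' factor. Patients with missing PDC are excluded and counted.
#'
#' @param summaries Per-patient tibble with `average_pdc` and the grouping
#'   column.
#' @param group_var Name of the grouping column (two levels).
#' @param threshold PDC cut-point, default 0.8.
#' @return List: `table` (2x2 matrix, rows = group levels, cols =
#'   adherent/non_adherent), `excluded_n` (missing-PDC count).
#' @export
dichotomise_pdc <- function(summaries, group_var, threshold = 0.8) {
  stopifnot(group_var %in% names(summaries))
  ok <- !is.na(summaries$average_pdc)
  g <- factor(summaries[[group_var]][ok])
  if (nlevels(g) != 2L) {
    stop("dichotomise_pdc(): grouping column must have exactly two levels",
         call. = FALSE)
  }
  adherent <- factor(summaries$average_pdc[ok] >= threshold,
                     levels = c(TRUE, FALSE),
                     labels = c("adherent", "non_adherent"))
  list(table = table(g, adherent), excluded_n = sum(!ok))
}

#' Logistic regression on TAG membership
#'
#' Maximum-likelihood logistic fit of the binary treatment-adherent-group
#' flag on patient covariates, reporting per-coefficient odds ratios and
#' Wald chi-square tests plus a type-3 likelihood-ratio test per variable
#' (full model against the model with the whole variable dropped). Factor
#' variables keep their first level as reference; age bands should be
#' ordered youngest-first.
#'
#' @param data Tibble with the outcome and covariates.
#' @param outcome Name of the logical/binary outcome column (default
#'   "tag").
#' @param terms Covariate column names.
#' @return List of class `tag_logistic`: `coefficients` (term, estimate,
#'   odds_ratio, se, wald_chisq, wald_p), `type3` (variable, df, lrt_stat,
#'   lrt_p), `n`, `status` ("ok" or "separation"), and the underlying
#'   `fit`. Degenerate input (constant outcome, n < 20) is an error;
#'   separation is flagged, not an error.
#' @export
fit_tag_logistic <- function(data, outcome = "tag",
                             terms = c("gender", "group", "ad_cotherapy",
                                       "age_band")) {
  stopifnot(outcome %in% names(data), all(terms %in% names(data)))
  df <- data[stats::complete.cases(data[, c(outcome, terms)]), , drop = FALSE]
  y <- as.integer(as.logical(df[[outcome]]))
  if (nrow(df) < 20L) {
    stop("fit_tag_logistic(): need at least 20 complete observations",
         call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop("fit_tag_logistic(): outcome is constant", call. = FALSE)
  }
  df$.y <- y
  fml <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                     data = df))
  status <- "ok"
  if (!fit$converged || any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE)) {
    status <- "separation"
    warning("fit_tag_logistic(): possible separation; estimates unreliable",
            call. = FALSE)
  }
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  wald <- (est / se)^2
  coefs <- tibble::tibble(
    term = names(est), estimate = unname(est),
    odds_ratio = exp(unname(est)), se = unname(se),
    wald_chisq = unname(wald),
    wald_p = stats::pchisq(unname(wald), df = 1, lower.tail = FALSE))

  # type-3 LRT: refit with the whole variable removed
  type3 <- lapply(terms, function(v) {
    red_terms <- setdiff(terms, v)
    red_fml <- stats::as.formula(
      if (length(red_terms)) paste(".y ~", paste(red_terms, collapse = " + "))
      else ".y ~ 1")
    red <- suppressWarnings(stats::glm(red_fml, family = stats::binomial(),
                                       data = df))
    lrt <- as.numeric(2 * (stats::logLik(fit) - stats::logLik(red)))
    dfree <- length(stats::coef(fit)) - length(stats::coef(red))
    tibble::tibble(variable = v, df = dfree, lrt_stat = lrt,
                   lrt_p = stats::pchisq(lrt, df = dfree, lower.tail = FALSE))
  })
  structure(list(coefficients = coefs, type3 = dplyr::bind_rows(type3),
                 n = nrow(df), status = status, fit = fit),
            class = "tag_logistic")
}

#' @export
print.tag_logistic <- function(x, ...) {
  cat("TAG logistic regression (n = ", x$n, ", status: ", x$status, ")\n",
      sep = "")
  print(as.data.frame(x$coefficients), digits = 4)
  cat("Type-3 likelihood-ratio tests:\n")
  print(as.data.frame(x$type3), digits = 4)
  invisible(x)
}

#' Reference-year age bands
#'
#' Age at the index year midpoint cut into the four strata used for the
#' adherence model, youngest band first (the reference level).
#'
#' @param birth_date Dates of birth.
#' @param config [adherence_config()].
#' @return Factor with levels "20-24", "25-29", "30-34", "35-39" (the
#'   youngest band absorbs anyone under 25).
#' @export
age_band <- function(birth_date, config = adherence_config()) {
  ref <- as.Date(sprintf("%d-06-30", config$index_year))
  age <- patient_age(birth_date, ref)
  cut(age, breaks = c(-Inf, 25, 30, 35, Inf),
      labels = c("20-24", "25-29", "30-34", "35-39"), right = FALSE)
}

#' Month proportions of drug types within the TAG
#'
#' For each treatment-adherent patient, the number of months representing
#' methylphenidate versus antidepressant therapy (non-short-supply issue
#' months per type) proportioned per member, with unweighted group means.
#' Patients with zero months of both types are excluded and counted.
#'
#' @param grid Stacked monthly grid ([build_monthly_plots()]).
#' @param tags [classify_tag_all()] output; only `tag == TRUE` patients
#'   enter.
#' @return List: `members` (patient_id, mph_months, ad_months, mph_share,
#'   ad_share), `means` (unweighted mean shares), `excluded_n`.
#' @export
month_proportions <- function(grid, tags) {
  tag_ids <- tags$patient_id[tags$tag]
  g <- grid[grid$patient_id %in% tag_ids, , drop = FALSE]
  counts <- dplyr::summarise(
    dplyr::group_by(g, patient_id, drug_type),
    months = sum(n_nonshort > 0L), .groups = "drop")
  wide <- tidyr::pivot_wider(counts, names_from = drug_type,
                             values_from = months, values_fill = 0L)
  if (!"MPH" %in% names(wide)) wide$MPH <- 0L
  if (!"AD" %in% names(wide)) wide$AD <- 0L
  tot <- wide$MPH + wide$AD
  excluded_n <- sum(tot == 0L)
  keep <- tot > 0L
  members <- tibble::tibble(
    patient_id = wide$patient_id[keep],
    mph_months = as.integer(wide$MPH[keep]),
    ad_months = as.integer(wide$AD[keep]),
    mph_share = wide$MPH[keep] / tot[keep],
    ad_share = wide$AD[keep] / tot[keep])
  means <- tibble::tibble(
    n = nrow(members),
    mean_mph_share = mean(members$mph_share),
    mean_ad_share = mean(members$ad_share))
  list(members = members, means = means, excluded_n = excluded_n)
}

#' Simulate a covariate design with known TAG odds ratios
#'
#' Draws patient covariates (gender, diagnostic group, antidepressant
#' co-therapy, age band) and a Bernoulli TAG outcome from a logistic model
#' with the given true odds ratios, for parameter-recovery and null
#' calibration checks of [fit_tag_logistic()].
#'
#' @param n Number of patients.
#' @param or_ad,or_group,or_female True odds ratios for antidepressant
#'   co-therapy, F90 diagnosis and female gender.
#' @param intercept Baseline log-odds.
#' @param seed RNG seed.
#' @return Tibble with gender, group, ad_cotherapy, age_band, tag.
#' @export
simulate_tag_design <- function(n, or_ad = 20, or_group = 2,
                                or_female = 1.5, intercept = -2.2,
                                seed = 1L) {
  set.seed(seed)
  gender <- factor(sample(c("M", "F"), n, replace = TRUE),
                   levels = c("M", "F"))
  group <- factor(sample(c("NON_F90", "F90"), n, replace = TRUE),
                  levels = c("NON_F90", "F90"))
  ad_cotherapy <- stats::runif(n) < 0.45
  band <- factor(sample(c("20-24", "25-29", "30-34", "35-39"), n,
                        replace = TRUE),
                 levels = c("20-24", "25-29", "30-34", "35-39"))
  eta <- intercept + log(or_female) * (gender == "F") +
    log(or_group) * (group == "F90") + log(or_ad) * ad_cotherapy
  tag <- stats::runif(n) < stats::plogis(eta)
  tibble::tibble(gender = gender, group = group,
                 ad_cotherapy = ad_cotherapy, age_band = band, tag = tag)
}
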
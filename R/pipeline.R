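#' Render a grouped adherence summary table
#'
#' Counts, two-decimal percentages and mean PDC per cell for the
#' adherence-by-therapy-by-group layout: within each diagnostic group (and
#' gender stratum) patients are cross-classified by regular versus
#' irregular use (TAG membership) and by therapy arm (methylphenidate with
#' antidepressants versus methylphenidate alone). Percentages are computed
#' against the group row's denominator; empty cells render a zero count
#' with a blank PDC, never 0.0.
#'
#' @param summary Per-patient x drug-type summary
#'   ([adherence_summary()]`$summary`).
#' @return Tibble, one row per group / gender stratum.
#' @export
render_group_table <- function(summary) {
  wide <- tidyr::pivot_wider(
    summary[, c("patient_id", "group", "gender", "tag", "drug_type",
                "average_pdc")],
    names_from = drug_type, values_from = average_pdc)
  if (!"MPH" %in% names(wide)) wide$MPH <- NA_real_
  if (!"AD" %in% names(wide)) wide$AD <- NA_real_
  wide$on_ad <- !is.na(wide$AD)

  cell <- function(df, den) {
    m_pdc <- function(x) if (any(!is.na(x))) mean(x, na.rm = TRUE) else NA_real_
    tibble::tibble(
      n_both_reg = sum(df$on_ad & df$tag),
      pct_both_reg = pct(sum(df$on_ad & df$tag), den),
      pdc_ad_both_reg = m_pdc(df$AD[df$on_ad & df$tag]),
      pdc_mph_both_reg = m_pdc(df$MPH[df$on_ad & df$tag]),
      n_both_irr = sum(df$on_ad & !df$tag),
      pct_both_irr = pct(sum(df$on_ad & !df$tag), den),
      pdc_ad_both_irr = m_pdc(df$AD[df$on_ad & !df$tag]),
      pdc_mph_both_irr = m_pdc(df$MPH[df$on_ad & !df$tag]),
      n_alone_reg = sum(!df$on_ad & df$tag),
      pct_alone_reg = pct(sum(!df$on_ad & df$tag), den),
      pdc_mph_alone_reg = m_pdc(df$MPH[!df$on_ad & df$tag]),
      n_alone_irr = sum(!df$on_ad & !df$tag),
      pct_alone_irr = pct(sum(!df$on_ad & !df$tag), den),
      pdc_mph_alone_irr = m_pdc(df$MPH[!df$on_ad & !df$tag]),
      pct_regular = pct(sum(df$tag), den),
      pct_irregular = pct(sum(!df$tag), den))
  }
  rows <- list()
  for (g in sort(unique(wide$group))) {
    gdf <- wide[wide$group == g, , drop = FALSE]
    rows[[length(rows) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(group = g, stratum = "all", n = nrow(gdf)),
      cell(gdf, nrow(gdf)))
    for (sx in c("F", "M")) {
      sdf <- gdf[gdf$gender == sx, , drop = FALSE]
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(group = g, stratum = sx, n = nrow(sdf)),
        cell(sdf, nrow(sdf)))
    }
  }
  dplyr::bind_rows(rows)
}

# therapy-arm / group / gender PDC and PDD means (population comparison)
therapy_arm_table <- function(summary) {
  wide <- tidyr::pivot_wider(
    summary[, c("patient_id", "group", "gender", "drug_type", "average_pdc",
                "pdd_mg_per_day")],
    names_from = drug_type, values_from = c(average_pdc, pdd_mg_per_day))
  if (!"average_pdc_AD" %in% names(wide)) wide$average_pdc_AD <- NA_real_
  wide$arm <- ifelse(!is.na(wide$average_pdc_AD), "concurrent_ad",
                     "mph_monotherapy")
  out <- list()
  pop <- list(entire = wide)
  for (g in sort(unique(wide$group))) pop[[g]] <- wide[wide$group == g, ]
  for (nm in names(pop)) {
    df <- pop[[nm]]
    for (arm in c("concurrent_ad", "mph_monotherapy")) {
      for (sx in c("all", "M", "F")) {
        sel <- df[df$arm == arm & (sx == "all" | df$gender == sx), ,
                  drop = FALSE]
        out[[length(out) + 1L]] <- tibble::tibble(
          population = nm, arm = arm, stratum = sx, n = nrow(sel),
          ad_pdc = if (arm == "concurrent_ad" && nrow(sel))
            mean(sel$average_pdc_AD, na.rm = TRUE) else NA_real_,
          mph_pdc = if (nrow(sel)) mean(sel$average_pdc_MPH, na.rm = TRUE)
          else NA_real_,
          mph_pdd = if (nrow(sel)) mean(sel$pdd_mg_per_day_MPH, na.rm = TRUE)
          else NA_real_)
      }
    }
  }
  dplyr::bind_rows(out)
}

# overall MPH PDC/PDD by group and gender
overall_mph_table <- function(summary) {
  mph <- summary[summary$drug_type == "MPH", , drop = FALSE]
  rows <- list()
  pops <- list(entire = mph)
  for (g in sort(unique(mph$group))) pops[[g]] <- mph[mph$group == g, ]
  for (nm in names(pops)) {
    df <- pops[[nm]]
    for (sx in c("all", "F", "M")) {
      sel <- df[sx == "all" | df$gender == sx, , drop = FALSE]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        population = nm, stratum = sx, n = nrow(sel),
        mph_pdc = if (nrow(sel)) mean(sel$average_pdc, na.rm = TRUE)
        else NA_real_,
        mph_pdd = if (nrow(sel)) mean(sel$pdd_mg_per_day, na.rm = TRUE)
        else NA_real_)
    }
  }
  dplyr::bind_rows(rows)
}

#' Run the full adherence pipeline
#'
#' Orchestrates every stage -- claims ingestion, cohort cascade, monthly
#' plotting, TAG classification, PDC/PDD computation, month proportions,
#' contingency tests and the TAG logistic model -- and writes the report
#' files into `out_dir`. The run is a pure function of (claims, formulary,
#' config): repeated runs produce byte-identical outputs.
#'
#' @param claims Either a path to a claims CSV or a `claims_set`.
#' @param out_dir Output directory (created if needed).
#' @param formulary Formulary tibble.
#' @param config [adherence_config()].
#' @return Invisibly, a list with every intermediate object and the vector
#'   of files written.
#' @export
run_pipeline <- function(claims, out_dir,
                         formulary = default_formulary(),
                         config = adherence_config()) {
  cs <- if (inherits(claims, "claims_set")) claims else
    read_claims(claims, formulary, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- build_cohort(cs, config)
  gates <- gate_summary(cohort)
  plots <- build_monthly_plots(cs, cohort, formulary, config)
  tags <- classify_tag_all(plots$grid, config = config)
  adh <- adherence_summary(cs, cohort, plots, tags, formulary, config)
  props <- month_proportions(plots$grid, tags)

  smry <- adh$summary
  mph <- smry[smry$drug_type == "MPH", , drop = FALSE]
  tests <- list()
  if (length(unique(mph$group[!is.na(mph$average_pdc)])) == 2L) {
    di <- dichotomise_pdc(mph, "group", config$pdc_threshold)
    tests$mph_pdc_by_group <- tibble::tibble(
      comparison = "mph_pdc_by_group",
      a = di$table[1, 1], b = di$table[1, 2],
      c = di$table[2, 1], d = di$table[2, 2],
      p_value = fisher_exact(as.vector(t(di$table))),
      method = "fisher_exact", excluded_n = di$excluded_n)
  }
  # TAG membership against AD co-therapy
  wide <- tidyr::pivot_wider(
    smry[, c("patient_id", "tag", "drug_type", "average_pdc")],
    names_from = drug_type, values_from = average_pdc)
  if (!"AD" %in% names(wide)) wide$AD <- NA_real_
  tab <- table(factor(!is.na(wide$AD), levels = c(TRUE, FALSE)),
               factor(wide$tag, levels = c(TRUE, FALSE)))
  tests$tag_by_ad_cotherapy <- tibble::tibble(
    comparison = "tag_by_ad_cotherapy",
    a = tab[1, 1], b = tab[1, 2], c = tab[2, 1], d = tab[2, 2],
    p_value = fisher_exact(as.vector(t(tab))),
    method = "fisher_exact", excluded_n = 0L)
  stats_report <- dplyr::bind_rows(tests)

  # TAG logistic model when the design supports it
  design <- dplyr::left_join(
    cohort[cohort$status == "INCLUDED", c("patient_id", "group")],
    cs$patients, by = "patient_id")
  design$age_band <- age_band(design$birth_date, config)
  design$ad_cotherapy <- design$patient_id %in%
    wide$patient_id[!is.na(wide$AD)]
  design <- dplyr::left_join(design, tags[, c("patient_id", "tag")],
                             by = "patient_id")
  logistic <- NULL
  lg_ok <- nrow(design) >= 20L && length(unique(design$tag)) == 2L
  if (lg_ok) {
    logistic <- tryCatch(
      fit_tag_logistic(design),
      error = function(e) NULL, warning = function(w) {
        suppressWarnings(fit_tag_logistic(design))
      })
  }

  w <- function(df, name) {
    path <- file.path(out_dir, name)
    df <- as.data.frame(df)
    for (cn in names(df)) if (inherits(df[[cn]], "Date"))
      df[[cn]] <- format(df[[cn]], "%Y-%m-%d")
    utils::write.csv(df, path, row.names = FALSE, na = "")
    path
  }
  files <- c(
    w(cohort, "cohort_report.csv"),
    w(gates, "gate_summary.csv"),
    w(plots$grid[plots$grid$units > 0L, ], "monthly_plot.csv"),
    w(plots$audit, "reassignment_audit.csv"),
    w(plots$tca_excluded, "tca_excluded.csv"),
    w(adh$periods, "periods.csv"),
    w(smry, "adherence_summary.csv"),
    w(props$members, "tag_month_proportions.csv"),
    w(props$means, "tag_month_proportion_means.csv"),
    w(stats_report, "stats_report.csv"),
    w(render_group_table(smry), "group_table.csv"),
    w(therapy_arm_table(smry), "therapy_arm_table.csv"),
    w(overall_mph_table(smry), "overall_mph_table.csv"),
    w(cs$rejects, "rejects.csv"))
  if (!is.null(logistic)) {
    files <- c(files,
               w(logistic$coefficients, "logistic_coefficients.csv"),
               w(logistic$type3, "logistic_type3.csv"))
  }
  # manifest: configuration echo for reproducibility (no timestamps)
  cfg_lines <- vapply(names(config), function(k) {
    paste0(k, "=", paste(format(config[[k]]), collapse = ","))
  }, "")
  manifest <- file.path(out_dir, "run_manifest.txt")
  writeLines(c(paste0("adhere_version=",
                      as.character(utils::packageVersion("adhere"))),
               sort(cfg_lines)), manifest)
  files <- c(files, manifest)

  invisible(list(claims_set = cs, cohort = cohort, gates = gates,
                 plots = plots, tags = tags, summary = smry,
                 periods = adh$periods, proportions = props,
                 stats = stats_report, logistic = logistic, files = files))
}
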
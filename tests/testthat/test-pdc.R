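test_that("the predicted next-supply date is issue date plus supply", {
  expect_equal(predict_next_supply(as.Date("2014-03-20"), 30),
               as.Date("2014-04-19"))
  expect_equal(predict_next_supply(as.Date("2014-10-30"), 30),
               as.Date("2014-11-29"))
  # supplies are floored at one day
  expect_equal(predict_next_supply(as.Date("2014-10-30"), 0),
               as.Date("2014-10-31"))
})

worked_streams <- list(
  `EX-A` = list(dates = c("2014-01-16", "2014-02-18", "2014-03-20",
                          "2014-04-23"),
                first_duration = 97L, first_rule = "over_90"),
  `EX-B` = list(dates = c("2014-08-03", "2014-10-30"),
                first_duration = 118L, first_rule = "up_to_119"),
  `EX-C` = list(dates = c("2015-04-28", "2015-06-03", "2015-07-03",
                          "2015-08-31"),
                first_duration = 125L, first_rule = "120_129"),
  `EX-E` = list(dates = c("2013-02-25", "2013-04-13", "2013-05-18",
                          "2013-06-27", "2013-08-17"),
                first_duration = 82L, first_rule = "less_90"))

test_that("period segmentation reproduces every worked refill pattern", {
  for (nm in names(worked_streams)) {
    ws <- worked_streams[[nm]]
    iv <- coverage_intervals(mk_classified(mk_claims(nm, ws$dates)), "MPH")
    per <- segment_periods(iv)
    expect_equal(per$duration_days[1], ws$first_duration, label = nm)
    expect_equal(per$rule[1], ws$first_rule, label = nm)
  }
  # the shortened period hands over to a 91-day period with 60 covered days
  ivE <- coverage_intervals(
    mk_classified(mk_claims("E", worked_streams$`EX-E`$dates)), "MPH")
  perE <- segment_periods(ivE)
  expect_equal(perE$duration_days[2], 91L)
  expect_equal(perE$covered_days[2], 60L)
})

test_that("a terminal period is truncated at the database end", {
  iv <- coverage_intervals(
    mk_classified(mk_claims("F", c("2016-11-02", "2016-12-05"))), "MPH")
  per <- segment_periods(iv)
  expect_equal(nrow(per), 1L)
  expect_equal(per$rule, "db_end")
  expect_equal(per$duration_days, 60L)
  expect_equal(per$covered_days, 57L)
  expect_equal(round(per$pdc, 2), 0.95)
})

test_that("every issue lies in exactly one period and periods do not overlap", {
  set.seed(19)
  for (rep in 1:25) {
    n <- sample(2:30, 1)
    dates <- sort(as.Date("2012-01-10") +
                    cumsum(sample(c(10:60, 150), n, replace = TRUE)))
    dates <- dates[dates <= as.Date("2016-12-31")]
    if (length(dates) < 1) next
    iv <- coverage_intervals(mk_classified(mk_claims("P", dates)), "MPH")
    per <- segment_periods(iv)
    # assignment: date in [start, end) for exactly one period (terminal
    # period absorbs any issue on the database end boundary)
    for (d in as.list(dates)) {
      hits <- sum(d >= per$start & d < per$end)
      expect_true(hits == 1L ||
                    (hits == 0L && d >= per$end[nrow(per)]))
    }
    expect_true(all(per$start[-1] >= per$end[-nrow(per)]))
    expect_true(all(per$duration_days <= 129L))
    expect_true(all(per$duration_days[-nrow(per)] >= 60L))
    # contiguity holds whenever the next issue falls within the extension
    # bands; a coverage break only opens a new period beyond 119 days
    gap_idx <- which(per$start[-1] > per$end[-nrow(per)])
    if (length(gap_idx)) {
      expect_true(all(days_between(per$start[gap_idx],
                                   per$start[gap_idx + 1]) > 119L))
    }
  }
})

test_that("covered days equal the brute-force day enumeration", {
  # two overlapping supplies on the same date count once
  iv <- tibble::tibble(start = as.Date(c("2015-01-01", "2015-01-01")),
                       supply_days = c(30L, 30L),
                       end = as.Date(c("2015-01-31", "2015-01-31")))
  expect_equal(covered_days("2015-01-01", "2015-04-01", iv), 30L)
  expect_equal(covered_days("2015-01-01", "2015-04-01", iv),
               brute_covered_days("2015-01-01", "2015-04-01", iv))

  set.seed(23)
  for (rep in 1:40) {
    n <- sample(1:12, 1)
    starts <- as.Date("2015-01-01") + sample(0:400, n, replace = TRUE)
    sup <- sample(1:60, n, replace = TRUE)
    iv <- tibble::tibble(start = starts, supply_days = sup,
                         end = starts + sup)
    a <- as.Date("2015-01-01") + sample(0:100, 1)
    b <- a + sample(1:400, 1)
    expect_equal(covered_days(a, b, iv), brute_covered_days(a, b, iv))
  }
})

test_that("average PDC is the unweighted period mean, NA when empty", {
  per <- tibble::tibble(pdc = c(0.95, 0.55))
  expect_equal(average_pdc(per), 0.75)
  expect_true(is.na(average_pdc(per[0, , drop = FALSE])))
})

test_that("perfect 30-day refills yield an average PDC of one", {
  dates <- monthly_dates("2012-01-10", 30)  # ten standard periods
  iv <- coverage_intervals(mk_classified(mk_claims("P", dates)), "MPH")
  per <- segment_periods(iv)
  expect_equal(nrow(per), 10L)
  expect_equal(average_pdc(per), 1.00, tolerance = 0.01)
})

test_that("with capping on, PDC stays in [0,1] and is monotone under deletion", {
  cfg <- adherence_config(cap_pdc = TRUE)
  dates <- monthly_dates("2013-01-08", 24)
  cl <- mk_classified(mk_claims("P", dates))
  iv <- coverage_intervals(cl, "MPH", cfg)
  full <- segment_periods(iv, cfg)
  expect_true(all(full$pdc >= 0 & full$pdc <= 1))
  expect_true(all(full$covered_days <= full$duration_days))
  set.seed(5)
  for (rep in 1:5) {
    drop <- sort(sample(seq_along(dates), sample(1:8, 1)))
    cl2 <- mk_classified(mk_claims("P", dates[-drop]))
    iv2 <- coverage_intervals(cl2, "MPH", cfg)
    thin <- segment_periods(iv2, cfg)
    expect_lte(mean(thin$pdc), mean(full$pdc) + 1e-12)
  }
})

test_that("PDD is total mass over days of cover, missing when uncovered", {
  cl <- mk_classified(mk_claims("P", monthly_dates("2015-01-10", 3)))
  res <- compute_pdd(cl, 90L, ddd_mg = 30)
  expect_equal(res$total_mg, 3 * 30 * 10)
  expect_equal(res$pdd_mg_per_day, 10)
  expect_equal(res$ratio_to_ddd, 1 / 3)

  cl2 <- mk_classified(mk_claims("P", "2015-01-10", quantity_units = 60L))
  expect_equal(compute_pdd(cl2, 20L)$pdd_mg_per_day, 30)
  expect_true(is.na(compute_pdd(cl2, 0L)$pdd_mg_per_day))
})

test_that("a generated cohort at a 30 mg prescribed dose recovers it", {
  # zero refill jitter: early refills overlap supplies and legitimately
  # raise measured PDD, so parameter recovery is read off the noiseless case
  g <- generate_cohort(cohort_spec(n_patients = 40, seed = 5,
                                   refill_jitter_days = 0L))
  cs <- as_claims_set(g$claims)
  cohort <- build_cohort(cs)
  plots <- build_monthly_plots(cs, cohort)
  tags <- classify_tag_all(plots$grid)
  adh <- adherence_summary(cs, cohort, plots, tags)
  sustained <- g$labels$patient_id[g$labels$archetype %in%
                                     c("REGULAR", "HOLIDAY")]
  pdd <- adh$summary$pdd_mg_per_day[adh$summary$drug_type == "MPH" &
                                      adh$summary$patient_id %in% sustained]
  expect_equal(mean(pdd, na.rm = TRUE), 30, tolerance = 1 / 30)
})
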
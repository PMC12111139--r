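test_that("calendar-day differences use the start-exclusive convention", {
  expect_equal(days_between(as.Date("2014-01-16"), as.Date("2014-04-23")), 97L)
  expect_equal(days_between(as.Date("2013-02-25"), as.Date("2013-05-18")), 82L)
  expect_equal(days_between(as.Date("2015-06-01"), as.Date("2015-06-01")), 0L)
  expect_error(days_between(as.Date("2015-06-02"), as.Date("2015-06-01")))
})

test_that("daily dose snaps to sensible rates and defaults to one unit/day", {
  # 60 units every 30 days: two units a day
  expect_equal(estimate_daily_dose(monthly_dates("2014-01-05", 5),
                                   rep(60L, 5)), 2)
  # a single isolated claim: the default assumption
  expect_equal(estimate_daily_dose(as.Date("2014-01-05"), 28L), 1)
  expect_equal(estimate_daily_dose(monthly_dates("2014-01-05", 4),
                                   rep(30L, 4)), 1)
  # erratic gaps give no dosage evidence
  expect_equal(estimate_daily_dose(
    as.Date(c("2014-01-05", "2014-01-15", "2014-03-20", "2014-03-29")),
    rep(90L, 4)), 1)
})

test_that("rule 1 moves the claim nearer an empty adjacent month", {
  # stable monthly 30-unit pattern; March holds issues on the 2nd and 28th,
  # April is empty
  dates <- c("2015-01-05", "2015-02-03", "2015-03-02", "2015-03-28",
             "2015-05-05", "2015-06-03")
  cl <- mk_classified(mk_claims("A", dates))
  g <- build_monthly_grid(cl, "MPH")
  expect_equal(nrow(g$audit), 1L)
  expect_equal(g$audit$rule, "RULE1")
  expect_equal(g$audit$dispense_date, as.Date("2015-03-28"))
  expect_equal(g$audit$assigned_month - g$audit$original_month, 1L)
  expect_true(all(g$grid$n_issues <= 1L))
})

test_that("a narrow gap without a trend stays put", {
  dates <- c("2015-03-05", "2015-03-15")
  g <- build_monthly_grid(mk_classified(mk_claims("A", dates)), "MPH")
  expect_equal(nrow(g$audit), 0L)
  expect_equal(sum(g$grid$n_issues == 2L), 1L)
})

test_that("rule 2 attributes an early refill to the following month", {
  # regular 30-unit/30-day trend with one early refill 20 days after the
  # March issue (gap < 21, so rule 1 cannot apply); April empty
  dates <- c("2015-01-05", "2015-02-04", "2015-03-06", "2015-03-26",
             "2015-05-05", "2015-06-04")
  g <- build_monthly_grid(mk_classified(mk_claims("A", dates)), "MPH")
  expect_equal(g$audit$rule, "RULE2")
  expect_true(all(g$grid$n_issues <= 1L))
  expect_equal(sum(g$grid$n_issues), length(dates))
})

test_that("the monthly grid conserves units and flags short supplies", {
  cl <- mk_classified(mk_claims("A", monthly_dates("2015-01-10", 12)))
  g <- build_monthly_grid(cl, "MPH")$grid
  expect_equal(sum(g$units), 12L * 30L)
  expect_equal(sum(g$n_issues > 0L), 12L)
  expect_true(all(g$month_index[g$n_issues > 0L] %in% 37:48))

  short <- mk_classified(mk_claims("B", "2015-04-10", quantity_units = 7L))
  gs <- build_monthly_grid(short, "MPH")$grid
  expect_equal(sum(gs$units), 7L)
  expect_true(gs$short_supply[gs$n_issues > 0L])
  expect_equal(sum(gs$n_nonshort), 0L)
})

test_that("units are conserved under reassignment on random streams", {
  set.seed(7)
  for (rep in 1:15) {
    n <- sample(4:40, 1)
    dates <- sort(as.Date("2012-01-05") +
                    cumsum(sample(10:45, n, replace = TRUE)))
    dates <- dates[dates <= as.Date("2016-12-31")]
    qty <- sample(c(30L, 60L, 90L), length(dates), replace = TRUE)
    cl <- mk_classified(mk_claims("P", dates, quantity_units = qty))
    g <- build_monthly_grid(cl, "MPH")$grid
    expect_equal(sum(g$units), sum(qty))
    expect_true(all(g$n_issues >= 0L))
  }
})

test_that("reassignment is idempotent on a consolidated grid", {
  dates <- c("2015-01-05", "2015-02-03", "2015-03-02", "2015-03-28",
             "2015-05-05", "2015-06-03")
  cl <- mk_classified(mk_claims("A", dates))
  cl$drug_type <- "MPH"
  cl$upd <- 1
  cl$assigned_month <- adhere:::study_month_index(cl$dispense_date,
                                                  as.Date("2012-01-01"))
  first <- reassign_months(cl)
  again <- reassign_months(first$claims[, setdiff(names(first$claims),
                                                  "moved")])
  expect_equal(nrow(again$audit), 0L)
  expect_equal(again$claims$assigned_month, first$claims$assigned_month)
})

test_that("TAG criteria combine issue months over both drug types", {
  # 12 consecutive monthly issues: in under either policy
  cl <- mk_classified(mk_claims("A", monthly_dates("2014-01-10", 12)))
  grid <- rbind(build_monthly_grid(cl, "MPH")$grid,
                build_monthly_grid(cl, "AD")$grid)
  t12 <- classify_tag(grid)
  expect_true(t12$tag)
  expect_equal(t12$total_monthly_issues, 12L)
  expect_equal(t12$max_issues_in_any_12_months, 12L)

  # 11 issues: out (total below the threshold)
  cl11 <- mk_classified(mk_claims("B", monthly_dates("2014-01-10", 11)))
  g11 <- build_monthly_grid(cl11, "MPH")$grid
  expect_false(classify_tag(g11)$tag)

  # 12 issues spread one per 5 months: window max 3, AND fails, OR passes
  months <- seq(1L, by = 5L, length.out = 12L)
  dates <- as.Date(paste0(adhere:::study_month_label(
    months, as.Date("2012-01-01")), "-10"))
  gsp <- build_monthly_grid(mk_classified(mk_claims("C", dates)), "MPH")$grid
  sp_and <- classify_tag(gsp, policy = "AND")
  sp_or <- classify_tag(gsp, policy = "OR")
  expect_equal(sp_and$max_issues_in_any_12_months, 3L)
  expect_false(sp_and$tag)
  expect_true(sp_or$tag)

  # exhaustive rolling-window oracle
  win_oracle <- function(months) {
    max(vapply(1:49, function(w) sum(months >= w & months < w + 12L), 0L))
  }
  expect_equal(sp_and$max_issues_in_any_12_months, win_oracle(months))
})

test_that("a month issued on both drug types counts once for TAG", {
  dates <- monthly_dates("2014-01-10", 10)
  mph <- mk_claims("A", dates)
  ad <- mk_claims("A", dates + 2L, drug_code = "FLX20", strength_mg = 20)
  cl <- mk_classified(mph, ad)
  grid <- rbind(build_monthly_grid(cl, "MPH")$grid,
                build_monthly_grid(cl, "AD")$grid)
  expect_equal(classify_tag(grid)$total_monthly_issues, 10L)
})

test_that("adding a qualifying monthly issue never flips TAG off", {
  set.seed(11)
  for (rep in 1:10) {
    months <- sort(sample(1:60, sample(5:20, 1)))
    dates <- as.Date(paste0(adhere:::study_month_label(
      months, as.Date("2012-01-01")), "-12"))
    g1 <- build_monthly_grid(mk_classified(mk_claims("P", dates)), "MPH")$grid
    before <- classify_tag(g1)$tag
    extra <- setdiff(1:60, months)[1]
    dates2 <- sort(c(dates, as.Date(paste0(adhere:::study_month_label(
      extra, as.Date("2012-01-01")), "-12"))))
    g2 <- build_monthly_grid(mk_classified(mk_claims("P", dates2)),
                             "MPH")$grid
    after <- classify_tag(g2)$tag
    expect_true(!before || after)
  }
})
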
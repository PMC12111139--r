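test_that("the exact test handles symmetric and degenerate tables", {
  expect_equal(fisher_exact(c(5, 5, 5, 5)), 1.0)
  expect_equal(fisher_exact(c(1, 0, 0, 1)), 1.0)  # both tables equally likely
  expect_equal(fisher_exact(c(0, 0, 3, 4)), 1.0)  # zero margin convention
  expect_error(fisher_exact(c(-1, 2, 3, 4)))
})

test_that("the exact test matches enumeration and fisher.test on random tables", {
  set.seed(31)
  for (rep in 1:60) {
    x <- sample(0:12, 4, replace = TRUE)
    if (sum(x) == 0) next
    p <- fisher_exact(x)
    expect_equal(p, oracle_fisher(x[1], x[2], x[3], x[4]), tolerance = 1e-12)
    m <- matrix(x, 2, 2, byrow = TRUE)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) {
      expect_equal(p, stats::fisher.test(m)$p.value, tolerance = 1e-6)
    }
  }
})

test_that("PDC dichotomisation is inclusive at the threshold", {
  df <- tibble::tibble(average_pdc = c(0.9, 0.7, 0.8, NA),
                       group = c("F90", "NON_F90", "F90", "NON_F90"))
  res <- dichotomise_pdc(df, "group", threshold = 0.8)
  expect_equal(res$excluded_n, 1L)
  expect_equal(unname(res$table["F90", "adherent"]), 2L)  # 0.8 counts as adherent
  expect_equal(unname(res$table["NON_F90", "non_adherent"]), 1L)
  expect_equal(sum(res$table), 3L)
})

test_that("a single binary covariate reproduces the closed-form odds ratio", {
  a <- 20L; b <- 10L; c <- 8L; d <- 22L
  df <- tibble::tibble(
    x = factor(rep(c("yes", "no"), c(a + b, c + d)), levels = c("no", "yes")),
    y = c(rep(c(TRUE, FALSE), c(a, b)), rep(c(TRUE, FALSE), c(c, d))))
  fit <- fit_tag_logistic(df, outcome = "y", terms = "x")
  or_hat <- fit$coefficients$odds_ratio[fit$coefficients$term == "xyes"]
  expect_equal(or_hat, (a * d) / (b * c), tolerance = 1e-6)
})

test_that("degenerate logistic inputs error or flag separation", {
  const <- tibble::tibble(x = rnorm(30), y = rep(TRUE, 30))
  expect_error(fit_tag_logistic(const, outcome = "y", terms = "x"),
               "constant")
  expect_error(fit_tag_logistic(tibble::tibble(x = 1:5, y = c(TRUE, FALSE,
                                                              TRUE, FALSE,
                                                              TRUE)),
                                outcome = "y", terms = "x"), "at least 20")
  sep <- tibble::tibble(x = c(rep(0, 15), rep(1, 15)),
                        y = c(rep(FALSE, 15), rep(TRUE, 15)))
  expect_warning(fit <- fit_tag_logistic(sep, outcome = "y", terms = "x"),
                 "separation")
  expect_equal(fit$status, "separation")
})

test_that("type-3 likelihood-ratio p-values ignore term ordering", {
  df <- simulate_tag_design(300, or_ad = 3, or_group = 2, seed = 9)
  f1 <- fit_tag_logistic(df, terms = c("gender", "group", "ad_cotherapy",
                                       "age_band"))
  f2 <- fit_tag_logistic(df, terms = c("age_band", "ad_cotherapy", "group",
                                       "gender"))
  for (v in f1$type3$variable) {
    expect_equal(f1$type3$lrt_p[f1$type3$variable == v],
                 f2$type3$lrt_p[f2$type3$variable == v], tolerance = 1e-10)
  }
  # Wald chi-square is (beta/se)^2 with exponentiated coefficients as ORs
  expect_equal(f1$coefficients$odds_ratio,
               exp(f1$coefficients$estimate))
})

test_that("month proportions are per-member shares with sane group means", {
  mk_grid <- function(pid, mph_months, ad_months) {
    rbind(
      tibble::tibble(patient_id = pid, drug_type = "MPH",
                     month_index = 1:60,
                     n_nonshort = as.integer(1:60 %in% mph_months)),
      tibble::tibble(patient_id = pid, drug_type = "AD",
                     month_index = 1:60,
                     n_nonshort = as.integer(1:60 %in% ad_months)))
  }
  grid <- rbind(mk_grid("A", 1:10, 11:20),     # 10 MPH vs 10 AD months
                mk_grid("B", 30, 1:5),         # 1 MPH vs 5 AD months
                mk_grid("C", 1:12, integer(0)))
  tags <- tibble::tibble(patient_id = c("A", "B", "C"), tag = TRUE)
  res <- month_proportions(grid, tags)
  m <- res$members
  expect_equal(m$ad_share[m$patient_id == "A"], 0.5)
  expect_equal(round(100 * m$ad_share[m$patient_id == "B"], 2), 83.33)
  expect_equal(m$mph_share[m$patient_id == "C"], 1)
  expect_equal(m$ad_share + m$mph_share, rep(1, 3))
  expect_true(res$means$mean_ad_share >= min(m$ad_share) &&
                res$means$mean_ad_share <= max(m$ad_share))
})

test_that("synthetic designs recover their simulated odds ratios", {
  df <- simulate_tag_design(2000, or_ad = 20, seed = 42)
  fit <- fit_tag_logistic(df)
  or_ad <- fit$coefficients$odds_ratio[
    fit$coefficients$term == "ad_cotherapyTRUE"]
  expect_gt(or_ad, 15)
  expect_lt(or_ad, 26)
})

test_that("age banding is youngest-referenced at the index year", {
  b <- age_band(as.Date(c("1993-01-01", "1988-01-01", "1983-01-01",
                          "1978-06-01")))
  expect_equal(as.character(b), c("20-24", "25-29", "30-34", "35-39"))
  expect_equal(levels(b)[1], "20-24")
})
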
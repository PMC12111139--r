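# builders for claim fixtures used across the suite

mk_claims <- function(patient_id, dates, drug_code = "MPH10",
                      strength_mg = 10, quantity_units = 30L,
                      icd10_codes = "", gender = "F",
                      birth_date = "1990-06-15") {
  n <- length(dates)
  tibble::tibble(
    patient_id = rep_len(patient_id, n),
    gender = rep_len(gender, n),
    birth_date = as.Date(rep_len(birth_date, n)),
    dispense_date = as.Date(dates),
    drug_code = rep_len(drug_code, n),
    drug_name = rep_len(drug_code, n),
    strength_mg = rep_len(strength_mg, n),
    quantity_units = as.integer(rep_len(quantity_units, n)),
    days_supply = rep_len(NA_integer_, n),
    icd10_codes = rep_len(icd10_codes, n))
}

mk_set <- function(...) {
  as_claims_set(dplyr::bind_rows(...))
}

# classified claim rows (bypassing the CSV layer) for one patient
mk_classified <- function(...) {
  cs <- mk_set(...)
  cs$claims
}

# brute-force day-enumeration coverage oracle
brute_covered_days <- function(start, end, intervals) {
  start <- as.Date(start); end <- as.Date(end)
  if (end <= start) return(0L)
  days <- seq(start, end - 1L, by = "day")
  covered <- rep(FALSE, length(days))
  for (i in seq_len(nrow(intervals))) {
    covered <- covered | (days >= intervals$start[i] &
                            days < intervals$end[i])
  }
  sum(covered)
}

# independent hypergeometric enumeration via binomial coefficients
oracle_fisher <- function(a, b, c, d) {
  K <- a + b; M <- c + d; n <- a + c; N <- K + M
  if (K == 0 || M == 0 || n == 0 || n == N) return(1)
  support <- max(0, n - M):min(K, n)
  probs <- choose(K, support) * choose(M, n - support) / choose(N, n)
  obs <- probs[match(a, support)]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# a monthly refill stream (no jitter)
monthly_dates <- function(from, n, step = 30L) {
  as.Date(from) + step * (seq_len(n) - 1L)
}
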
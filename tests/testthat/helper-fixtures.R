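# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# life table where everyone dies in the year they turn `age_die`
degenerate_life_table <- function(age_die = 90, max_age = 100) {
  q <- rep(0, max_age + 1)
  q[age_die + 1] <- 1
  q[max_age + 1] <- 1
  life_table(0:max_age, q)
}

# constant-hazard table, long enough that truncation is negligible
constant_q_life_table <- function(q = 0.1, max_age = 300) {
  life_table(0:max_age, c(rep(q, max_age), 1))
}

# the canonical worked timeline: tumor detectable at age 60, metastasis at
# 65, breast-cancer death at 72, other-cause death at 92 (ages in months)
worked_history <- function() {
  data.frame(id = 1L, has_tumor = TRUE, progressive = TRUE,
             age_fmc = 690, age_detectable = 720, age_surface = 792,
             age_metastasis = 780, age_bca_death = 864,
             age_other_death = 1104, alpha = 0.0181, d_surface = 2,
             d_met = 3, has_np = FALSE, np_age_fmc = NA_real_,
             np_age_detectable = NA_real_, np_alpha = NA_real_)
}

no_screening_detection <- function(h) {
  data.frame(id = h$id, mode = "clinical", age_detect = h$age_surface,
             np_detected = FALSE, np_age_detect = NA_real_, n_exams = 0L)
}

# independent brute-force life expectancy: expected whole years lived from
# `age`, plus half a year, by direct enumeration of death-year probabilities
brute_force_life_expectancy <- function(lt, age) {
  q <- lt$qx[(age + 1):nrow(lt)]
  surv_to <- c(1, cumprod(1 - q)) # P(alive k years after `age`)
  p_die_in_year <- surv_to[seq_along(q)] * q
  sum(p_die_in_year * (seq_along(q) - 1)) + 0.5
}

# exact CDF of the sampled other-cause death age (uniform within death year)
life_table_death_cdf <- function(lt) {
  q <- lt$qx
  surv <- c(1, cumprod(1 - q)) # survival to exact integer ages
  function(a) {
    y <- pmin(floor(a), length(q) - 1)
    pmax(0, 1 - surv[y + 1] + surv[y + 1] * q[y + 1] * pmin(a - y, 1))
  }
}

# month-by-month state-machine replay of one woman's screen-PLL trajectory,
# independent of the closed-form window arithmetic in cohort_pll()
replay_pll_monthly <- function(h, det, n_months = 1213L) {
  out <- numeric(n_months)
  if (!isTRUE(h$has_tumor) || !isTRUE(h$progressive)) return(out)
  if (is.na(h$age_metastasis) || is.na(h$age_bca_death)) return(out)
  if (!(h$age_bca_death < h$age_other_death)) return(out)
  if (!(h$age_metastasis < h$age_surface)) return(out)
  pll <- h$age_other_death - h$age_bca_death
  state <- "pre_detectable"
  for (m in seq_len(n_months) - 1L) {
    if (state == "pre_detectable" && m >= h$age_detectable) state <- "at_risk"
    if (state == "at_risk") {
      if (m >= h$age_metastasis) state <- "resolved"
      if (identical(det$mode, "screen") && m >= det$age_detect) state <- "resolved"
    }
    if (state == "at_risk") out[m + 1L] <- pll
  }
  out
}
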
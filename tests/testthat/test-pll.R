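calib <- make_fixture_calibration()

test_that("the canonical timeline yields 240 life-months over ages [60, 65)", {
  h <- worked_history()
  tr <- individual_pll(h, no_screening_detection(h))
  expect_equal(tr$value, 240)
  expect_true(tr$premature)
  expect_equal(tr$window_start, 720)
  expect_equal(tr$window_end, 780)

  cv <- cohort_curve(data.frame(value = tr$value,
                                window_start = tr$window_start,
                                window_end = tr$window_end))
  v <- cv$screen_pll_life_months
  expect_equal(v[720 + 1], 240)
  expect_equal(v[779 + 1], 240)
  expect_equal(v[719 + 1], 0)
  expect_equal(v[780 + 1], 0)
  expect_equal(sum(v), 240 * 60)
})

test_that("screen detection truncates the window but keeps the plateau", {
  h <- worked_history()
  det <- data.frame(id = 1L, mode = "screen", age_detect = 62 * 12,
                    np_detected = FALSE, np_age_detect = NA_real_,
                    n_exams = 2L)
  tr <- individual_pll(h, det)
  expect_equal(tr$value, 240)
  expect_equal(tr$window_start, 720)
  expect_equal(tr$window_end, 744)
  v <- cohort_curve(list(tr))$screen_pll_life_months
  expect_equal(v[743 + 1], 240)
  expect_equal(v[744 + 1], 0)
})

test_that("women who cannot die prematurely of breast cancer contribute 0", {
  # non-progressive reservoir tumor only
  h_np <- worked_history()
  h_np$has_tumor <- FALSE
  h_np$progressive <- FALSE
  h_np[c("age_fmc", "age_detectable", "age_surface", "age_metastasis",
         "age_bca_death")] <- NA_real_
  h_np$has_np <- TRUE
  h_np[c("np_age_fmc", "np_age_detectable", "np_alpha")] <- c(690, 720, 0.0181)
  det <- data.frame(id = 1L, mode = "none", age_detect = NA_real_,
                    np_detected = TRUE, np_age_detect = 744, n_exams = 3L)
  tr <- individual_pll(h_np, det)
  expect_equal(tr$value, 0)
  expect_false(tr$premature)

  # clinical surfacing before metastasis: cured anyway on her own path
  h_cure <- worked_history()
  h_cure$age_metastasis <- 800
  h_cure$age_surface <- 792
  tr2 <- individual_pll(h_cure, no_screening_detection(h_cure))
  expect_equal(tr2$value, 0)

  # other-cause death before the breast-cancer death
  h_oc <- worked_history()
  h_oc$age_other_death <- 850
  tr3 <- individual_pll(h_oc, no_screening_detection(h_oc))
  expect_equal(tr3$value, 0)
  expect_false(tr3$premature)
})

test_that("inconsistent history/detection pairs are rejected", {
  h <- worked_history()
  det <- data.frame(id = 1L, mode = "screen", age_detect = 700,
                    np_detected = FALSE, np_age_detect = NA_real_,
                    n_exams = 1L)
  expect_error(individual_pll(h, det), "inconsistent")
})

test_that("the any_progressive counterfactual credits clinically-cured women", {
  h <- worked_history()
  h$age_metastasis <- 800 # after surfacing at 792
  h$age_bca_death <- 880
  tr_d <- individual_pll(h, no_screening_detection(h), "destined_death")
  tr_a <- individual_pll(h, no_screening_detection(h), "any_progressive")
  expect_equal(tr_d$value, 0)
  expect_equal(tr_a$value, 1104 - 880)
  expect_equal(tr_a$window_end, 792) # clinical detection ends the window
})

test_that("cohort curves sum trajectories pointwise on the month grid", {
  empty <- cohort_curve(data.frame(value = numeric(0),
                                   window_start = numeric(0),
                                   window_end = numeric(0)))
  expect_true(all(empty$screen_pll_life_months == 0))
  expect_equal(nrow(empty), 1213)

  two <- data.frame(value = c(240, 120),
                    window_start = c(720, 750), window_end = c(780, 800))
  v <- cohort_curve(two)$screen_pll_life_months
  expect_equal(v[721], 240)
  expect_equal(v[751], 360)
  expect_equal(v[781], 120)
  expect_equal(v[801], 0)
  expect_equal(v[700], 0)
})

test_that("curve construction matches a brute-force month-by-month sum", {
  set.seed(8)
  n <- 500
  ws <- runif(n, 0, 1100)
  traj <- data.frame(value = round(runif(n, 0, 300), 3),
                     window_start = ws, window_end = ws + runif(n, 0, 200))
  v <- cohort_curve(traj)$screen_pll_life_months
  brute <- numeric(1213)
  for (m in 0:1212) {
    for (k in seq_len(n)) {
      if (m >= traj$window_start[k] && m < traj$window_end[k]) {
        brute[m + 1] <- brute[m + 1] + traj$value[k]
      }
    }
  }
  expect_equal(v, brute)
})

test_that("simulated trajectories are zero outside the Fig-1 window", {
  hh <- simulate_cohort(calib, 4000, master_seed = 31)
  exams <- schedule_exams(screening_strategy("uspstf"), calib$life_table)
  det <- apply_screening_cohort(hh, exams, calib$params, 31)
  traj <- cohort_pll(hh, det)
  expect_true(all(traj$value >= 0))
  pos <- traj[traj$value > 0, ]
  expect_gt(nrow(pos), 20)
  expect_true(all(pos$window_end > pos$window_start))
  # positive value requires the premature no-intervention path
  expect_true(all(traj$premature[traj$value > 0]))
  # window starts at detectability and ends by detection or metastasis
  k <- match(pos$id, hh$id)
  expect_equal(pos$window_start, pmax(0, hh$age_detectable[k]))
  end_cap <- pmin(ifelse(det$mode[k] == "screen", det$age_detect[k], Inf),
                  hh$age_metastasis[k])
  expect_equal(pos$window_end, end_cap)
  # if she dies of something else mid-window she was never premature
  expect_true(all(hh$age_other_death[k] > hh$age_bca_death[k]))
})
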
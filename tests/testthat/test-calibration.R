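test_that("life table CSV parsing validates and round-trips exactly", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,qx", paste(0:100, c(rep(0.005, 100), 1), sep = ",")), path)
  lt <- load_life_table(path)
  expect_s3_class(lt, "life_table")
  expect_identical(attr(lt, "max_age"), 100L)
  expect_equal(lt$qx[101], 1)

  # out-of-range q cites the offending age
  bad <- data.frame(age = 0:100, qx = c(rep(0.005, 100), 1))
  bad$qx[41] <- 1.2
  expect_error(life_table(bad$age, bad$qx), "age 40")

  # non-contiguous ages rejected
  expect_error(life_table(c(0:40, 42:101), rep(0.01, 101)), "contiguous")
  expect_error(life_table(1:50, rep(0.01, 50)), "contiguous")

  # write -> read reproduces the fixture table bit-identically
  fix <- make_fixture_calibration()
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_life_table(fix$life_table, p2)
  expect_identical(load_life_table(p2)$qx, fix$life_table$qx)
  p3 <- withr::local_tempfile(fileext = ".csv")
  write_incidence_table(fix$incidence, p3)
  expect_identical(load_incidence_table(p3)$rate_per_100k,
                   fix$incidence$rate_per_100k)
})

test_that("life expectancy follows the curtate-plus-half convention", {
  # everyone dies in the year they turn 90: 10 whole years + half at age 80
  lt <- degenerate_life_table(90)
  expect_equal(life_expectancy(lt, 80), 10.5)
  expect_equal(life_expectancy(lt, 90), 0.5)
  expect_equal(life_expectancy(lt, 100), 0.5) # absorbing age

  # constant hazard: geometric mean whole lifetime 9, plus half
  ltc <- constant_q_life_table(0.1)
  expect_equal(life_expectancy(ltc, 0), 9.5, tolerance = 1e-8)

  # matches independent brute-force enumeration on the fixture table
  fix <- make_fixture_calibration()$life_table
  for (a in c(0, 40, 65, 80, 95)) {
    expect_equal(life_expectancy(fix, a), brute_force_life_expectancy(fix, a),
                 tolerance = 1e-10)
  }
  expect_error(life_expectancy(fix, 101), "age")
})

test_that("with a US-like table, expectancy first drops below 10 near 80", {
  lt <- make_fixture_calibration()$life_table
  le <- vapply(0:100, function(a) life_expectancy(lt, a), numeric(1))
  first <- which(le < 10)[1] - 1
  expect_gte(first, 78)
  expect_lte(first, 82)
})

test_that("life expectancy is non-increasing in q", {
  set.seed(42)
  for (rep in 1:20) {
    q <- c(runif(60, 0, 0.3), 1)
    lt <- life_table(0:60, q)
    j <- sample(59, 1)
    q2 <- q
    q2[j] <- min(1, q2[j] + runif(1, 0, 0.5))
    lt2 <- life_table(0:60, q2)
    for (a in c(0, j - 1)) {
      expect_lte(life_expectancy(lt2, a), life_expectancy(lt, a) + 1e-12)
    }
  }
})

test_that("sampled death ages follow the life table", {
  lt <- degenerate_life_table(90)
  set.seed(1)
  draws <- replicate(50, sample_death_age(lt))
  expect_true(all(draws >= 90 & draws < 91))

  # constant hazard: survival past age 10 is 0.9^10
  ltc <- constant_q_life_table(0.1)
  set.seed(2)
  d <- replicate(20000, sample_death_age(ltc))
  p10 <- mean(d >= 10)
  se <- sqrt(0.9^10 * (1 - 0.9^10) / 20000)
  expect_lt(abs(p10 - 0.9^10), 3 * se)

  # mean of many draws matches the summation-based expectancy
  fix <- make_fixture_calibration()$life_table
  set.seed(3)
  d <- replicate(20000, sample_death_age(fix))
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - life_expectancy(fix, 0)), 3 * se)
})

test_that("empirical death-age CDF converges to the life-table survival", {
  fix <- make_fixture_calibration()$life_table
  set.seed(4)
  d <- replicate(1e5, sample_death_age(fix))
  ks <- suppressWarnings(stats::ks.test(d, life_table_death_cdf(fix)))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("the synthetic calibration is deterministic, valid and realistic", {
  b1 <- make_fixture_calibration()
  b2 <- make_fixture_calibration()
  expect_identical(b1$life_table$qx, b2$life_table$qx)
  expect_identical(b1$incidence$rate_per_100k, b2$incidence$rate_per_100k)
  expect_silent(validate_life_table(b1$life_table))
  expect_silent(validate_incidence_table(b1$incidence))
  # incidence rises with age: young women rarely affected
  r <- function(a) b1$incidence$rate_per_100k[b1$incidence$age == a]
  expect_lt(r(25), r(65))
  expect_lt(r(25), 20)
  expect_gt(r(65), 200)
})

test_that("bundle construction enforces matching age spans", {
  fix <- make_fixture_calibration()
  short_inc <- incidence_table(0:80, rep(10, 81))
  expect_error(calibration_bundle(fix$life_table, short_inc), "age range")
})

test_that("model params validate and round-trip through YAML and JSON", {
  expect_error(model_params(d_cell = 0.3), "d_cell")
  expect_error(model_params(sens_max_pre = 0.9, sens_max_post = 0.5),
               "post-menopause")
  expect_error(model_params(alpha_log_sd = -1), "sd")
  expect_error(model_params(not_a_param = 1), "unknown")

  p <- model_params(p_nonprogressive = 0.4, sens_mid = 0.7)
  for (ext in c(".yaml", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    write_model_params(p, f)
    p2 <- load_model_params(f)
    expect_equal(p2$p_nonprogressive, 0.4)
    expect_equal(p2$sens_mid, 0.7)
    expect_equal(unclass(p2), unclass(p), tolerance = 1e-12)
  }
})

test_that("non-progressive reservoir rate hits the target tumor share", {
  fix <- make_fixture_calibration()
  for (p in c(0.1, 0.3, 0.5)) {
    cc <- np_rate_factor(fix$incidence, p)
    r <- fix$incidence$rate_per_100k / 1e5
    p_prog <- 1 - prod(1 - r)
    p_np <- 1 - prod(1 - cc * r)
    expect_equal(p_np / (p_np + p_prog), p, tolerance = 1e-9)
  }
  expect_identical(np_rate_factor(fix$incidence, 0), 0)
})
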
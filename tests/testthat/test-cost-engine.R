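test_that("average salary uses Woreda range midpoints", {
  srv <- tibble::tibble(woreda_id = c("a", "b"),
                        setting = "rural",
                        salary_low = c(1400, 1450),
                        salary_high = c(1600, 1450))
  expect_equal(average_salary(srv[1, ], "rural"), 1500)
  srv2 <- tibble::tibble(woreda_id = c("a", "b"), setting = "urban",
                         salary_low = c(1450, 1575),
                         salary_high = c(1450, 1575))
  expect_equal(average_salary(srv2, "urban"), 1512.5)
  expect_error(average_salary(srv, "urban"), "no salary records")
})

test_that("salary per billable minute is the unrounded quotient", {
  expect_equal(salary_per_minute(1513, 1600), 1513 / 1600)
  expect_equal(round_half_up(salary_per_minute(1000, 1000), 2), 1)
  # the published convention reports these truncated: 0.94 and 1.57
  expect_equal(trunc(salary_per_minute(1513, 1600) * 100) / 100, 0.94)
  expect_equal(trunc(salary_per_minute(1419, 900) * 100) / 100, 1.57)
  expect_error(salary_per_minute(1513, 0))
})

test_that("campaign uplift spreads salary over non-campaign time", {
  expect_equal(campaign_uplift(0), 1)
  expect_equal(campaign_uplift(0.5), 2)
  expect_equal(campaign_uplift(0.1742), 1.2110, tolerance = 1e-4)
  expect_error(campaign_uplift(1))
  expect_error(campaign_uplift(-0.1))
})

test_that("multipliers derive from cost shares as share/salary-share", {
  expect_warning(sh <- cost_shares(0.27, 0.55, 0.09, 0.13), "1.04")
  m <- derive_multipliers(sh)
  expect_equal(m$management, 0.09 / 0.27)
  expect_equal(m$overhead, 0.13 / 0.27)
  expect_equal(m$supplies, 0.55 / 0.27)
  expect_error(cost_shares(0.1, 0.1, 0.1, 0.1))
})

test_that("explicit multipliers total 270% with and 82% without supplies", {
  m <- multiplier_set(1.88, 0.33, 0.49)
  expect_equal(m$total_with_supplies, 2.70)
  expect_equal(m$total_no_supplies, 0.82)
  expect_error(multiplier_set(-1, 0.3, 0.5))
})

test_that("per-encounter costs chain with decimal half-up rounding", {
  expect_equal(cost_per_encounter(16.6, 0.82), 30.2)
  expect_equal(cost_per_encounter(5.3, 2.70), 19.6)
  expect_equal(cost_per_encounter(0, 2.70), 0)
  # half-up ties that banker's rounding would get wrong
  expect_equal(cost_per_encounter(56.5, 2.70), 209.1)   # 209.05
  expect_equal(cost_per_encounter(124.5, 2.70), 460.7)  # 460.65
  expect_equal(round_half_up(0.945, 2), 0.95)
  expect_error(cost_per_encounter(-1, 0.82))
})

test_that("base salary per encounter is rate times duration", {
  expect_equal(round_half_up(base_salary_per_encounter(1.25, 4.2), 1), 5.3)
  expect_equal(round_half_up(base_salary_per_encounter(1.88, 29.2), 1), 54.9)
  expect_equal(base_salary_per_encounter(1, 0), 0)
})

test_that("currency conversion rounds half-up to cents", {
  expect_equal(to_usd(16.6, 22), 0.75)
  expect_equal(to_usd(22, 22), 1)
  expect_equal(to_usd(219.4, 22), 9.97)
  expect_error(to_usd(10, 0))
})

test_that("multiplier algebra distributes within one rounding unit", {
  set.seed(403)
  for (i in 1:100) {
    b <- round(runif(1, 0, 500), 1)
    m <- c(runif(1, 0, 2), runif(1, 0, 1), runif(1, 0, 1))
    total <- cost_per_encounter(b, sum(m))
    parts <- b + b * m[1] + b * m[2] + b * m[3]
    expect_lte(abs(total - parts), 0.05 + 1e-9)
  }
})

test_that("costs are monotone and scale-equivariant", {
  expect_lt(cost_per_encounter(10, 0.82), cost_per_encounter(11, 0.82))
  expect_lt(cost_per_encounter(10, 0.82), cost_per_encounter(10, 2.70))
  expect_lt(base_salary_per_encounter(1.25, 4), base_salary_per_encounter(1.25, 5))
  # doubling salary doubles every unrounded birr quantity exactly
  r1 <- salary_per_minute(1513, 1600)
  r2 <- salary_per_minute(2 * 1513, 1600)
  expect_identical(r2, 2 * r1)
  expect_identical(base_salary_per_encounter(r2, 4.2),
                   2 * base_salary_per_encounter(r1, 4.2))
})

test_that("currency conversion round-trips within a cent", {
  set.seed(404)
  for (e in c(5, 22, 27.5)) {
    x <- round(runif(50, 0, 500), 1)
    expect_true(all(abs(to_usd(x, e) * e - x) <= 0.01 * e / 2 + 1e-9))
  }
})

test_that("cost parameters derive the uplifted rate unless overridden", {
  p <- cost_parameters("rural", 1513, 1600)
  expect_equal(p$rate_base, 1513 / 1600)
  expect_equal(p$rate_uplifted, (1513 / 1600) / (1 - 0.1742))
  p2 <- cost_parameters("rural", 1513, 1600, rate_uplifted = 1.25)
  expect_equal(p2$rate_uplifted, 1.25)
  expect_output(print(p2), "uplifted rate")
})
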
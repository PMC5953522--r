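test_that("outlier rule matches direct evaluation on fixed examples", {
  # single value: SD is 0, nothing can exceed mean + 3 SD
  ex <- exclude_outliers(10)
  expect_equal(ex$kept, 10)
  expect_equal(ex$n_excluded, 0)

  # masking case: a 500-minute spike among nine 5s inflates the SD so much
  # that the cut (54.5 + 3 * 156.5 = 524) is never crossed; the single-pass
  # rule keeps everything, exactly as direct evaluation says
  x <- c(rep(5, 9), 500)
  ex <- exclude_outliers(x)
  orc <- oracle_exclude(x)
  expect_equal(ex$kept, orc$kept)
  expect_equal(ex$n_excluded, 0)

  expect_equal(exclude_outliers(c(2, 4, 6, 8))$n_excluded, 0)
  expect_error(exclude_outliers(numeric(0)))
})

test_that("outlier rule agrees with the brute-force oracle on random samples", {
  set.seed(401)
  for (i in 1:50) {
    n <- sample(1:100, 1)
    x <- round(rlnorm(n, meanlog = 2, sdlog = runif(1, 0.2, 1.5)), 2)
    if (runif(1) < 0.3) x[sample(n, 1)] <- max(x) * 50  # plant a spike
    got <- exclude_outliers(x)
    want <- oracle_exclude(x)
    expect_equal(got$kept, want$kept)
    expect_equal(got$n_excluded, want$n_excluded)
    # idempotence: nothing kept exceeds the original cut
    expect_true(all(got$kept <= got$mean + 3 * got$sd))
  }
})

test_that("two-sided variant also drops low extremes", {
  x <- c(rep(50, 30), 0.001)
  one <- exclude_outliers(x, rule = "one_sided")
  two <- exclude_outliers(x, rule = "two_sided")
  expect_equal(one$n_excluded, 0)
  expect_equal(two$n_excluded, 1)
  expect_false(0.001 %in% two$kept)
})

test_that("encounter summaries report per-category statistics and shares", {
  rec <- make_records(rep("Provide TB related services", 2), c(10, 20))
  st <- summarize_encounters(rec, "rural")
  tb <- st[st$category_id == "tb_services", ]
  expect_equal(tb$mean_min, 15)
  expect_equal(tb$sd_min, sd(c(10, 20)))
  expect_equal(tb$pct_encounters, 100)
  # categories without encounters stay visible with n = 0 and NA stats
  expect_equal(nrow(st), 14)
  expect_equal(st$n_encounters[st$category_id == "vct_hiv"], 0)
  expect_true(is.na(st$mean_min[st$category_id == "vct_hiv"]))

  rec2 <- make_records(c(rep("Provide TB related services", 3),
                         "Provide contraceptives"),
                       c(4, 5, 6, 12))
  st2 <- summarize_encounters(rec2, "rural")
  expect_equal(st2$pct_encounters[st2$category_id == "tb_services"], 75)
  expect_equal(st2$pct_encounters[st2$category_id == "contraceptives"], 25)
})

test_that("summaries agree with a brute-force recomputation on random logs", {
  set.seed(402)
  rural_names <- billable_categories("rural")$display_name
  for (i in 1:10) {
    n <- sample(20:100, 1)
    rec <- make_records(sample(c(rural_names, "travel"), n, replace = TRUE),
                        round(rlnorm(n, 2.3, 0.9), 1))
    got <- summarize_encounters(rec, "rural")
    want <- oracle_summarize(rec, "rural")
    expect_equal(got$n_encounters, want$n_encounters)
    expect_equal(got$pct_encounters, want$pct_encounters)
    expect_equal(got$mean_min, want$mean_min)
    expect_equal(got$sd_min, want$sd_min)
    # conservation: kept counts sum to the kept billable total
    expect_equal(sum(got$n_encounters),
                 sum(want$n_encounters))
    expect_equal(sum(got$pct_encounters), 100, tolerance = 1e-9)
  }
})

test_that("billable minutes standardize to a 30-day month", {
  # 1120 billable minutes over 21 days scale by 30/21 to 1600 per month
  rec <- make_records(rep("Provide contraceptives", 21),
                      rep(1120 / 21, 21),
                      date = as.Date("2014-05-01") + 0:20)
  bm <- billable_minutes_per_month(rec, "rural")
  expect_equal(bm$billable_min_per_month, 1600)
  expect_equal(bm$n_workers, 1)
  expect_equal(bm$n_days_observed, 21)

  # a 30-day window is the identity
  rec2 <- make_records(rep("Provide contraceptives", 30), rep(30, 30),
                       date = as.Date("2014-05-01") + 0:29)
  expect_equal(billable_minutes_per_month(rec2, "rural")$billable_min_per_month,
               900)
})

test_that("malformed logs and empty settings fail loudly", {
  expect_error(summarize_encounters(small_rural_log(), "urban"),
               "no records")
  nb_only <- make_records("travel", 60)
  expect_error(summarize_encounters(nb_only, "rural"), "billable")

  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("worker_id,setting,date,activity_label,duration_min",
               "w1,rural,2014-05-01,travel,30",
               "w1,suburban,2014-05-01,travel,30",
               "w1,rural,2014-05-02,travel,-5"), path)
  err <- expect_error(read_observation_log(path), class = "hewcost_bad_log")
  expect_match(conditionMessage(err), "line 3")
  expect_match(conditionMessage(err), "line 4")
})
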
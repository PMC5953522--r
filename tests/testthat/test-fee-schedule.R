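chained_schedule <- function(setting) {
  ref <- reference_fee_table(setting)
  build_fee_schedule(
    ref[, c("category_id", "pct_encounters", "mean_min", "sd_min")],
    published_cost_parameters(setting),
    mode = "chained",
    base_override = setNames(ref$base_birr, ref$category_id))
}

test_that("chained schedules reproduce the reference money cells exactly", {
  for (setting in c("urban", "rural")) {
    sched <- chained_schedule(setting)
    disc <- compare_to_reference(sched)
    expect_equal(nrow(disc), 0)
  }
})

test_that("individual fee lines chain from printed bases", {
  rural <- chained_schedule("rural")$lines
  tb <- rural[rural$category_id == "tb_services", ]
  expect_equal(unlist(tb[, c("base_birr", "base_usd", "cost82_birr",
                             "cost82_usd", "cost270_birr", "cost270_usd")],
                      use.names = FALSE),
               c(5.3, 0.24, 9.6, 0.44, 19.6, 0.89))
  urban <- chained_schedule("urban")$lines
  hyg <- urban[urban$category_id == "hygiene_sanitation", ]
  expect_equal(unlist(hyg[, c("cost82_birr", "cost82_usd",
                              "cost270_birr", "cost270_usd")],
                      use.names = FALSE),
               c(30.2, 1.37, 61.4, 2.79))
})

test_that("schedules have the setting's row count in canonical order", {
  urban <- chained_schedule("urban")
  rural <- chained_schedule("rural")
  expect_equal(nrow(urban$lines), 12)
  expect_equal(nrow(rural$lines), 14)
  expect_equal(rural$lines$category_id,
               billable_categories("rural")$id)
  # ordering is stable: building twice gives identical line order
  expect_identical(chained_schedule("rural")$lines$category_id,
                   rural$lines$category_id)
})

test_that("missing categories and zero durations are handled explicitly", {
  ref <- reference_fee_table("rural")
  stats <- ref[ref$category_id != "tb_services",
               c("category_id", "pct_encounters", "mean_min", "sd_min")]
  expect_error(build_fee_schedule(stats, published_cost_parameters("rural")),
               "tb_services")

  zero <- ref[, c("category_id", "pct_encounters", "mean_min", "sd_min")]
  zero$mean_min <- 0
  sched <- build_fee_schedule(zero, published_cost_parameters("rural"))
  expect_true(all(sched$lines$base_birr == 0))
  expect_true(all(sched$lines$cost270_usd == 0))
})

test_that("cost ordering invariant holds line by line", {
  for (setting in c("urban", "rural")) {
    l <- chained_schedule(setting)$lines
    expect_true(all(l$cost270_birr >= l$cost82_birr))
    expect_true(all(l$cost82_birr >= l$base_birr))
    expect_true(all(l$base_birr >= 0))
    expect_equal(l$cost270_usd,
                 to_usd(l$cost270_birr, 22))
  }
})

test_that("comparator flags perturbations and structural mismatches", {
  sched <- chained_schedule("rural")
  sched$lines$cost82_birr[3] <- sched$lines$cost82_birr[3] + 1
  disc <- compare_to_reference(sched)
  expect_equal(nrow(disc), 1)
  expect_equal(disc$column, "cost82_birr")
  expect_equal(disc$diff, 1)

  ref_bad <- reference_fee_table("rural")
  ref_bad <- ref_bad[ref_bad$category_id != "vct_hiv", ]
  expect_error(compare_to_reference(chained_schedule("rural"), ref_bad),
               "different category sets")
})

test_that("fee schedules round-trip through disk", {
  sched <- chained_schedule("rural")
  path <- withr::local_tempfile(fileext = ".csv")
  write_fee_schedule(sched, path)
  back <- read_fee_schedule(path)
  expect_equal(back$lines, sched$lines)
  expect_equal(back$setting, sched$setting)
  expect_equal(back$mode, sched$mode)
  expect_equal(back$parameters$rate_uplifted, sched$parameters$rate_uplifted)
  expect_equal(back$parameters$multipliers$total_with_supplies,
               sched$parameters$multipliers$total_with_supplies)
})

test_that("encounter form has one row per billable activity", {
  rural_form <- render_encounter_form(chained_schedule("rural"))
  urban_form <- render_encounter_form(chained_schedule("urban"))
  body_rows <- function(form) sum(grepl("^\\| ", form)) - 2  # header + rule
  expect_equal(body_rows(rural_form), 14)
  expect_equal(body_rows(urban_form), 12)
  expect_true(any(grepl("Provide TB related services", rural_form)))

  empty <- chained_schedule("rural")
  empty$lines <- empty$lines[0, ]
  expect_error(render_encounter_form(empty), "empty")
})

test_that("config loading resolves parameters per setting", {
  cfg_path <- system.file("extdata", "example_config.yaml", package = "hewcost")
  resolved <- load_costing_config(cfg_path)
  expect_named(resolved$parameters, c("urban", "rural"))
  expect_equal(resolved$parameters$rural$rate_uplifted, 1.25)
  expect_equal(resolved$parameters$urban$rate_uplifted, 1.88)
  expect_equal(resolved$parameters$rural$multipliers$total_with_supplies, 2.70)
  expect_equal(resolved$outlier_rule, "one_sided")
})
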
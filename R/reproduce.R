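#' Published study inputs
#'
#' The headline inputs of the published Ethiopian costing study, as
#' constants: average salaries of 1419 (urban) / 1513 (rural) birr/month,
#' 900 / 1600 billable minutes per worker-month, the printed uplifted
#' salary-per-minute rates of 1.88 / 1.25 birr (which embed the study's own
#' campaign-uplift convention), the non-salary multipliers (supplies 188%,
#' management 33%, overhead 49% of salary) and the 22 birr/US$ exchange
#' rate.
#'
#' @param setting `"urban"` or `"rural"`.
#' @return a [cost_parameters()] object for the setting.
#' @export
published_cost_parameters <- function(setting) {
  check_setting(setting)
  inputs <- switch(setting,
                   urban = list(salary = 1419, minutes = 900, rate = 1.88),
                   rural = list(salary = 1513, minutes = 1600, rate = 1.25))
  cost_parameters(setting = setting,
                  salary_month = inputs$salary,
                  billable_min_month = inputs$minutes,
                  campaign_fraction = 0.1742,
                  rate_uplifted = inputs$rate,
                  multipliers = multiplier_set(),
                  exchange_rate = 22)
}

#' Reproduce the published fee schedules
#'
#' Rebuilds the urban and rural fee schedules from the published inputs and
#' compares every money cell against the packaged reference tables. In
#' `"chained"` mode (default) the printed base-salary cells are taken as
#' inputs and every downstream cell — the 82% and 270% scenarios in birr
#' and US$ — is recomputed from them with decimal half-up rounding, the
#' convention the published tables themselves follow; the printed bases
#' cannot be recovered from the printed durations because they were chained
#' from unrounded source durations. In `"unrounded"` mode the bases are
#' recomputed as `rate × mean duration` at full precision, which reproduces
#' the tables only approximately.
#'
#' @param mode `"chained"` or `"unrounded"`.
#' @return a list with `schedules` (per setting), `discrepancies` (tibble;
#'   zero rows in chained mode), and `summary` (headline quantities:
#'   salary-per-minute rates, multiplier totals, fee ranges).
#' @export
reproduce_fee_schedules <- function(mode = c("chained", "unrounded")) {
  mode <- match.arg(mode)
  out <- lapply(c("urban", "rural"), function(setting) {
    ref <- reference_fee_table(setting)
    params <- published_cost_parameters(setting)
    stats <- ref[, c("category_id", "pct_encounters", "mean_min", "sd_min")]
    sched <- build_fee_schedule(
      stats, params, mode = mode,
      base_override = if (mode == "chained") {
        stats::setNames(ref$base_birr, ref$category_id)
      },
      provenance = sprintf("published inputs, %s mode", mode))
    tol_birr <- if (mode == "chained") 0.1 else 0.5
    disc <- compare_to_reference(sched, ref, tol_birr = tol_birr,
                                 tol_usd = if (mode == "chained") 0.01 else 0.05)
    list(schedule = sched, discrepancies = disc)
  })
  names(out) <- c("urban", "rural")
  mults <- multiplier_set()
  # the published per-minute rates are truncated, not rounded, at 2 decimals
  # (1513/1600 = 0.9456 is reported as 0.94; 1419/900 = 1.5767 as 1.57)
  trunc2 <- function(x) trunc(round(x * 100, 9)) / 100
  summary <- list(
    salary_per_min_rural = trunc2(salary_per_minute(1513, 1600)),
    salary_per_min_urban = trunc2(salary_per_minute(1419, 900)),
    multiplier_total_with_supplies_pct = 100 * mults$total_with_supplies,
    multiplier_total_no_supplies_pct = 100 * mults$total_no_supplies,
    urban_fee270_range = range(out$urban$schedule$lines$cost270_birr),
    rural_fee270_range = range(out$rural$schedule$lines$cost270_birr))
  list(schedules = list(urban = out$urban$schedule,
                        rural = out$rural$schedule),
       discrepancies = dplyr::bind_rows(
         urban = out$urban$discrepancies,
         rural = out$rural$discrepancies, .id = "setting"),
       summary = summary)
}
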
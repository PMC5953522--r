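#' Read a Woreda salary survey
#'
#' One row per Woreda (district): `woreda_id`, `setting`, `salary_low`,
#' `salary_high` in birr/month. A Woreda reporting a single salary repeats
#' it in both columns.
#'
#' @param path path to a delimited text file with the columns above.
#' @return a tibble of salary records.
#' @export
read_salary_survey <- function(path) {
  srv <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           woreda_id = readr::col_character(),
                           setting = readr::col_character(),
                           salary_low = readr::col_double(),
                           salary_high = readr::col_double()))
  if (any(!srv$setting %in% c("urban", "rural"))) {
    abort("salary survey contains unknown settings")
  }
  if (any(srv$salary_low <= 0) || any(srv$salary_high < srv$salary_low)) {
    abort("salary ranges must satisfy 0 < salary_low <= salary_high")
  }
  srv
}

#' Average monthly salary for a setting
#'
#' Each Woreda contributes the midpoint of its reported salary range; the
#' setting's salary is the unweighted mean of those midpoints.
#'
#' @param records salary-record tibble (see [read_salary_survey()]).
#' @param setting `"urban"` or `"rural"`.
#' @return average salary in birr/month.
#' @export
average_salary <- function(records, setting) {
  check_setting(setting)
  sub <- records[records$setting == setting, , drop = FALSE]
  if (nrow(sub) == 0) abort(sprintf("no salary records for setting '%s'", setting))
  mean((sub$salary_low + sub$salary_high) / 2)
}

#' Salary cost per billable minute
#'
#' Monthly salary divided by billable minutes per worker-month. The value is
#' returned unrounded (downstream arithmetic carries full precision); report
#' it with `round_half_up(x, 2)`.
#'
#' @param salary_month birr/month.
#' @param billable_min_month minutes of billable activity per worker-month.
#' @return birr per billable minute (unrounded).
#' @export
salary_per_minute <- function(salary_month, billable_min_month) {
  if (!all(salary_month > 0)) abort("`salary_month` must be positive")
  if (!all(billable_min_month > 0)) abort("`billable_min_month` must be positive")
  salary_month / billable_min_month
}

#' Campaign opportunity-cost uplift
#'
#' Health extension workers lose a fraction `f` of the year to seasonal
#' campaigns (immunization drives, development campaigns, in-service
#' training) during which no billable encounters occur. Spreading the
#' year's salary over the remaining `1 - f` of billable time raises the
#' per-minute rate by `u = 1 / (1 - f)`.
#'
#' @param campaign_fraction fraction of the year on campaigns, in `[0, 1)`.
#' @return the multiplicative uplift factor (>= 1).
#' @export
campaign_uplift <- function(campaign_fraction) {
  if (!is.numeric(campaign_fraction) || any(campaign_fraction < 0) ||
      any(campaign_fraction >= 1)) {
    abort("`campaign_fraction` must lie in [0, 1)")
  }
  1 / (1 - campaign_fraction)
}

#' National program cost shares
#'
#' Proportions of total program cost attributable to salary, supplies,
#' management, and other overhead. The shares are validated individually in
#' (0, 1); a total outside `[0.95, 1.10]` is an error, and any total other
#' than 1 draws a warning (published national estimates do not always sum
#' to 100%).
#'
#' @param salary,supplies,management,overhead proportions of total cost.
#' @return a named list of class `"cost_shares"`.
#' @export
cost_shares <- function(salary = 0.27, supplies = 0.55, management = 0.09,
                        overhead = 0.13) {
  shares <- list(salary = salary, supplies = supplies,
                 management = management, overhead = overhead)
  if (any(unlist(shares) <= 0) || any(unlist(shares) >= 1)) {
    abort("each cost share must lie in (0, 1)")
  }
  total <- sum(unlist(shares))
  if (total < 0.95 || total > 1.10) {
    abort(sprintf("cost shares sum to %.2f; expected a total near 1", total))
  }
  if (abs(total - 1) > 1e-9) {
    warn(sprintf("cost shares sum to %.2f, not 1; multipliers derived from them are approximate", total))
  }
  structure(shares, class = "cost_shares")
}

#' Non-salary cost multipliers
#'
#' Each non-salary cost component expressed as a fraction of salary cost.
#' The defaults are the published Ethiopia-specific multipliers — supplies
#' 188%, management 33%, overhead 49% of salary — whose totals are 270%
#' with supplies and 82% without. [derive_multipliers()] builds a set from
#' national cost shares instead (`m_x = share_x / share_salary`); explicit
#' multipliers are canonical for reproducing the published fee schedules
#' because the printed shares are not exactly consistent with the printed
#' multipliers.
#'
#' @param supplies,management,overhead multipliers as fractions of salary
#'   cost.
#' @return a list of class `"multiplier_set"` with the components plus
#'   `total_with_supplies` and `total_no_supplies`.
#' @export
multiplier_set <- function(supplies = 1.88, management = 0.33,
                           overhead = 0.49) {
  vals <- c(supplies = supplies, management = management, overhead = overhead)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("multipliers must be non-negative numbers")
  }
  structure(list(supplies = supplies,
                 management = management,
                 overhead = overhead,
                 total_with_supplies = supplies + management + overhead,
                 total_no_supplies = management + overhead),
            class = "multiplier_set")
}

#' @rdname multiplier_set
#' @param shares a [cost_shares()] object.
#' @export
derive_multipliers <- function(shares) {
  if (!inherits(shares, "cost_shares")) shares <- do.call(cost_shares, as.list(shares))
  if (shares$salary <= 0) abort("salary share must be positive")
  multiplier_set(supplies = shares$supplies / shares$salary,
                 management = shares$management / shares$salary,
                 overhead = shares$overhead / shares$salary)
}

#' Base salary cost of an average encounter
#'
#' The uplifted salary-per-minute rate times the mean encounter duration.
#' Returned unrounded; fee-schedule columns report it half-up to 1 decimal
#' birr.
#'
#' @param rate_uplifted uplifted salary per minute, birr/min.
#' @param mean_min mean encounter duration, minutes.
#' @return base salary cost per encounter in birr (unrounded).
#' @export
base_salary_per_encounter <- function(rate_uplifted, mean_min) {
  if (any(rate_uplifted < 0) || any(mean_min < 0)) {
    abort("rate and duration must be non-negative")
  }
  rate_uplifted * mean_min
}

#' Total cost per encounter under a non-salary multiplier
#'
#' Full cost recovery adds the non-salary components on top of the salary
#' base: `total = base * (1 + m_total)`, reported half-up to 1 decimal birr.
#' With the default multipliers this is base × 1.82 (management + overhead)
#' or base × 3.70 (supplies included).
#'
#' @param base_salary_per_encounter salary cost per encounter, birr.
#' @param m_total total non-salary multiplier (e.g. 0.82 or 2.70).
#' @return total cost per encounter in birr, rounded half-up to 1 decimal.
#' @export
cost_per_encounter <- function(base_salary_per_encounter, m_total) {
  if (any(base_salary_per_encounter < 0)) abort("`base_salary_per_encounter` must be non-negative")
  if (any(m_total < 0)) abort("`m_total` must be non-negative")
  round_half_up(base_salary_per_encounter * (1 + m_total), 1)
}

#' Bundle the cost parameters for one setting
#'
#' Collects every input of the cost arithmetic — salary, billable minutes,
#' campaign fraction, multipliers, exchange rate — and derives the base and
#' uplifted salary-per-minute rates. `rate_uplifted` may be supplied
#' explicitly to override the `1/(1-f)` uplift formula (used when
#' reproducing a published schedule whose printed rates embed a different
#' uplift convention).
#'
#' @param setting `"urban"` or `"rural"`.
#' @param salary_month average salary, birr/month.
#' @param billable_min_month billable minutes per worker-month.
#' @param campaign_fraction fraction of the year on campaigns (default
#'   0.1742, i.e. about 9 weeks).
#' @param rate_uplifted optional explicit uplifted rate, birr/min.
#' @param multipliers a [multiplier_set()].
#' @param exchange_rate birr per US$ (default 22).
#' @return a list of class `"cost_parameters"`.
#' @export
cost_parameters <- function(setting, salary_month, billable_min_month,
                            campaign_fraction = 0.1742,
                            rate_uplifted = NULL,
                            multipliers = multiplier_set(),
                            exchange_rate = 22) {
  check_setting(setting)
  rate_base <- salary_per_minute(salary_month, billable_min_month)
  uplift <- campaign_uplift(campaign_fraction)
  if (is.null(rate_uplifted)) rate_uplifted <- rate_base * uplift
  if (rate_uplifted <= 0) abort("`rate_uplifted` must be positive")
  if (!inherits(multipliers, "multiplier_set")) {
    abort("`multipliers` must be a multiplier_set()")
  }
  structure(list(setting = setting,
                 salary_month = salary_month,
                 billable_min_month = billable_min_month,
                 rate_base = rate_base,
                 campaign_fraction = campaign_fraction,
                 uplift_factor = uplift,
                 rate_uplifted = rate_uplifted,
                 multipliers = multipliers,
                 exchange_rate = exchange_rate),
            class = "cost_parameters")
}

#' @export
print.cost_parameters <- function(x, ...) {
  cat(sprintf("Cost parameters (%s)\n", x$setting))
  cat(sprintf("  salary:            %.1f birr/month\n", x$salary_month))
  cat(sprintf("  billable minutes:  %.0f /month\n", x$billable_min_month))
  cat(sprintf("  base rate:         %.2f birr/min\n",
              round_half_up(x$rate_base, 2)))
  cat(sprintf("  uplifted rate:     %.2f birr/min (campaign fraction %.4f)\n",
              round_half_up(x$rate_uplifted, 2), x$campaign_fraction))
  cat(sprintf("  multipliers:       supplies %.2f, management %.2f, overhead %.2f (totals %.2f / %.2f)\n",
              x$multipliers$supplies, x$multipliers$management,
              x$multipliers$overhead, x$multipliers$total_with_supplies,
              x$multipliers$total_no_supplies))
  cat(sprintf("  exchange rate:     %.0f birr/US$\n", x$exchange_rate))
  invisible(x)
}
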
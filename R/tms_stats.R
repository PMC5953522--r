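#' Read a time-motion observation log
#'
#' One row per contiguous observed activity event: `worker_id`, `setting`,
#' `date` (ISO-8601), `activity_label`, `duration_min`. Malformed rows —
#' negative durations, unknown settings, unparseable dates — are rejected
#' with their line numbers so field data can be corrected at the source.
#'
#' @param path path to a delimited text file with the columns above.
#' @return a tibble of observation records.
#' @export
read_observation_log <- function(path) {
  log <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           worker_id = readr::col_character(),
                           setting = readr::col_character(),
                           date = readr::col_date(),
                           activity_label = readr::col_character(),
                           duration_min = readr::col_double()))
  problems <- character()
  line <- function(i) i + 1L  # header occupies line 1
  bad <- which(!log$setting %in% c("urban", "rural"))
  if (length(bad)) {
    problems <- c(problems, sprintf("line %d: unknown setting '%s'",
                                    line(bad), log$setting[bad]))
  }
  bad <- which(is.na(log$duration_min) | log$duration_min < 0)
  if (length(bad)) {
    problems <- c(problems, sprintf("line %d: invalid duration_min '%s'",
                                    line(bad), log$duration_min[bad]))
  }
  bad <- which(is.na(log$date))
  if (length(bad)) {
    problems <- c(problems, sprintf("line %d: unparseable date", line(bad)))
  }
  if (length(problems)) {
    abort(c("invalid observation log", problems),
          class = "hewcost_bad_log")
  }
  log
}

#' Exclude extreme encounter durations
#'
#' Removes durations more than 3 standard deviations above the mean. The
#' mean and SD are computed once, on the full sample — the rule is a single
#' pass, not iterated — so re-applying it with the original statistics
#' removes nothing. The default is one-sided (only values *above*
#' `mean + 3*SD` are dropped): durations are bounded below at zero, so on
#' right-skewed duration data nothing can sit 3 SDs below a positive mean;
#' a two-sided variant is available via `rule`.
#'
#' @param durations numeric vector of encounter durations in minutes.
#' @param rule `"one_sided"` (default) or `"two_sided"`.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @param n_sd cutoff in standard deviations (default 3).
#' @return a list with `kept` (surviving durations, order preserved),
#'   `n_excluded`, and the full-sample `mean` and `sd` used for the cut.
#' @export
exclude_outliers <- function(durations, rule = c("one_sided", "two_sided"),
                             sd_type = c("sample", "population"), n_sd = 3) {
  rule <- match.arg(rule)
  sd_type <- match.arg(sd_type)
  if (!is.numeric(durations) || length(durations) == 0) {
    abort("`durations` must be a non-empty numeric vector")
  }
  mu <- mean(durations)
  n <- length(durations)
  sigma <- if (n == 1L) 0 else sd(durations)
  if (sd_type == "population") sigma <- sigma * sqrt((n - 1) / n)
  keep <- durations <= mu + n_sd * sigma
  if (rule == "two_sided") keep <- keep & durations >= mu - n_sd * sigma
  list(kept = durations[keep],
       n_excluded = sum(!keep),
       mean = mu,
       sd = sigma)
}

# classify the log once and flag, within each billable category of the
# setting, which records survive the outlier rule
kept_billable_records <- function(records, setting,
                                  taxonomy = hew_taxonomy(),
                                  synonyms = hew_synonyms(taxonomy = taxonomy),
                                  rule = "one_sided", sd_type = "sample") {
  check_setting(setting)
  records <- records[records$setting == setting, , drop = FALSE]
  if (nrow(records) == 0) abort("no records for this setting")
  cls <- classify_activity(records$activity_label, setting,
                           taxonomy = taxonomy, synonyms = synonyms)
  records$category_id <- cls$category_id
  records$billable <- cls$billable
  billable <- records[records$billable, , drop = FALSE]
  if (nrow(billable) == 0) abort("no billable encounters in the log")
  billable$keep <- TRUE
  for (cat in unique(billable$category_id)) {
    idx <- which(billable$category_id == cat)
    ex <- exclude_outliers(billable$duration_min[idx], rule = rule,
                           sd_type = sd_type)
    billable$keep[idx] <- billable$duration_min[idx] <=
      ex$mean + 3 * ex$sd
    if (rule == "two_sided") {
      billable$keep[idx] <- billable$keep[idx] &
        billable$duration_min[idx] >= ex$mean - 3 * ex$sd
    }
  }
  billable
}

#' Per-category encounter statistics
#'
#' For each billable category in the setting's scope of practice: the number
#' of encounters kept after outlier exclusion, the percent those encounters
#' represent of all kept billable encounters, and the mean and sample SD of
#' the kept durations. Categories with no encounters are reported with
#' `n_encounters = 0` and `NA` statistics rather than dropped, so a missing
#' service is visible.
#'
#' @param records observation-record tibble (see [read_observation_log()]).
#' @param setting `"urban"` or `"rural"`.
#' @param taxonomy,synonyms taxonomy and synonym map.
#' @param rule,sd_type outlier-rule options passed to [exclude_outliers()].
#' @return a tibble with one row per billable category in canonical order:
#'   `category_id`, `display_name`, `n_encounters`, `n_excluded`,
#'   `pct_encounters`, `mean_min`, `sd_min`.
#' @export
summarize_encounters <- function(records, setting,
                                 taxonomy = hew_taxonomy(),
                                 synonyms = hew_synonyms(taxonomy = taxonomy),
                                 rule = "one_sided", sd_type = "sample") {
  billable <- kept_billable_records(records, setting, taxonomy, synonyms,
                                    rule, sd_type)
  cats <- billable_categories(setting, taxonomy)
  per_cat <- billable |>
    dplyr::group_by(.data$category_id) |>
    dplyr::summarise(
      n_encounters = sum(.data$keep),
      n_excluded = sum(!.data$keep),
      mean_min = mean(.data$duration_min[.data$keep]),
      sd_min = sd(.data$duration_min[.data$keep]),
      .groups = "drop")
  out <- tibble::tibble(category_id = cats$id,
                        display_name = cats$display_name) |>
    dplyr::left_join(per_cat, by = "category_id") |>
    dplyr::mutate(
      n_encounters = ifelse(is.na(.data$n_encounters), 0L, .data$n_encounters),
      n_excluded = ifelse(is.na(.data$n_excluded), 0L, .data$n_excluded))
  total <- sum(out$n_encounters)
  out$pct_encounters <- 100 * out$n_encounters / total
  out[, c("category_id", "display_name", "n_encounters", "n_excluded",
          "pct_encounters", "mean_min", "sd_min")]
}

#' Billable minutes per worker-month
#'
#' Total kept billable minutes per worker, standardized to a 30-day month by
#' the factor `30 / days observed` (days observed = distinct calendar dates
#' in the worker's log), then averaged over the setting's workers. This is
#' the denominator of the salary-per-billable-minute rate.
#'
#' @inheritParams summarize_encounters
#' @param days_per_month month standardization (default 30 days).
#' @return a one-row tibble: `setting`, `billable_min_per_month`,
#'   `n_workers`, `n_days_observed` (mean over workers).
#' @export
billable_minutes_per_month <- function(records, setting,
                                       taxonomy = hew_taxonomy(),
                                       synonyms = hew_synonyms(taxonomy = taxonomy),
                                       days_per_month = 30,
                                       rule = "one_sided",
                                       sd_type = "sample") {
  billable <- kept_billable_records(records, setting, taxonomy, synonyms,
                                    rule, sd_type)
  sub <- records[records$setting == setting, , drop = FALSE]
  days <- sub |>
    dplyr::group_by(.data$worker_id) |>
    dplyr::summarise(n_days = dplyr::n_distinct(.data$date), .groups = "drop")
  if (any(days$n_days == 0)) abort("zero observed days for a worker")
  per_worker <- billable[billable$keep, , drop = FALSE] |>
    dplyr::group_by(.data$worker_id) |>
    dplyr::summarise(minutes = sum(.data$duration_min), .groups = "drop") |>
    dplyr::right_join(days, by = "worker_id") |>
    dplyr::mutate(minutes = ifelse(is.na(.data$minutes), 0, .data$minutes),
                  monthly = .data$minutes * days_per_month / .data$n_days)
  tibble::tibble(setting = setting,
                 billable_min_per_month = mean(per_worker$monthly),
                 n_workers = nrow(per_worker),
                 n_days_observed = mean(per_worker$n_days))
}
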
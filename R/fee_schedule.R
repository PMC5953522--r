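#' Build a full-cost-recovery fee schedule
#'
#' Assembles one fee line per billable category of the setting from
#' encounter statistics and cost parameters. Two computation modes:
#'
#' * `"unrounded"` (default): the salary base `rate_uplifted * mean_min`
#'   and the scenario totals are carried at full precision and rounded
#'   half-up only in the report columns.
#' * `"chained"`: the salary base is rounded half-up to 1 decimal birr
#'   first and the scenario totals are computed from that rounded cell —
#'   the convention a published table follows when its columns chain from
#'   printed cells. `base_override` (named by `category_id`) injects base
#'   cells directly, for reproducing a table whose bases came from
#'   unrounded source durations that are no longer available.
#'
#' @param stats encounter statistics from [summarize_encounters()] (or any
#'   tibble with `category_id`, `pct_encounters`, `mean_min`, `sd_min`).
#' @param params a [cost_parameters()] object.
#' @param mode `"unrounded"` or `"chained"`.
#' @param base_override optional named numeric vector of base birr cells.
#' @param taxonomy taxonomy tibble.
#' @param provenance optional character notes (input paths, config digest)
#'   stored with the schedule for audit.
#' @return an object of class `"fee_schedule"`: a list with `setting`,
#'   `lines` (a tibble in canonical row order), `parameters`, `mode`,
#'   `provenance`.
#' @export
build_fee_schedule <- function(stats, params,
                               mode = c("unrounded", "chained"),
                               base_override = NULL,
                               taxonomy = hew_taxonomy(),
                               provenance = character()) {
  mode <- match.arg(mode)
  if (!inherits(params, "cost_parameters")) {
    abort("`params` must be a cost_parameters() object")
  }
  cats <- billable_categories(params$setting, taxonomy)
  missing <- setdiff(cats$id, stats$category_id)
  if (length(missing)) {
    abort(c("encounter statistics do not cover every billable category",
            sprintf("missing: %s", paste(missing, collapse = ", "))))
  }
  stats <- stats[match(cats$id, stats$category_id), , drop = FALSE]

  e <- params$exchange_rate
  m82 <- params$multipliers$total_no_supplies
  m270 <- params$multipliers$total_with_supplies
  mean_min <- ifelse(is.na(stats$mean_min), 0, stats$mean_min)
  base_raw <- base_salary_per_encounter(params$rate_uplifted, mean_min)

  if (mode == "chained") {
    base <- round_half_up(base_raw, 1)
    if (!is.null(base_override)) {
      idx <- match(cats$id, names(base_override))
      base <- ifelse(is.na(idx), base, base_override[idx])
    }
    lines <- tibble::tibble(
      category_id = cats$id,
      display_name = cats$display_name,
      pct_encounters = stats$pct_encounters,
      mean_min = stats$mean_min,
      sd_min = stats$sd_min,
      base_birr = base,
      base_usd = to_usd(base, e),
      cost82_birr = cost_per_encounter(base, m82),
      cost82_usd = to_usd(cost_per_encounter(base, m82), e),
      cost270_birr = cost_per_encounter(base, m270),
      cost270_usd = to_usd(cost_per_encounter(base, m270), e))
  } else {
    lines <- tibble::tibble(
      category_id = cats$id,
      display_name = cats$display_name,
      pct_encounters = stats$pct_encounters,
      mean_min = stats$mean_min,
      sd_min = stats$sd_min,
      base_birr = round_half_up(base_raw, 1),
      base_usd = to_usd(base_raw, e),
      cost82_birr = round_half_up(base_raw * (1 + m82), 1),
      cost82_usd = to_usd(base_raw * (1 + m82), e),
      cost270_birr = round_half_up(base_raw * (1 + m270), 1),
      cost270_usd = to_usd(base_raw * (1 + m270), e))
  }
  if ("n_encounters" %in% names(stats)) {
    lines <- tibble::add_column(lines,
                                n_encounters = stats$n_encounters,
                                .after = "display_name")
  }
  structure(list(setting = params$setting,
                 lines = lines,
                 parameters = params,
                 mode = mode,
                 provenance = as.character(provenance)),
            class = "fee_schedule")
}

#' @export
print.fee_schedule <- function(x, ...) {
  cat(sprintf("Fee schedule — %s setting (%s mode, %d billable activities)\n",
              x$setting, x$mode, nrow(x$lines)))
  print(x$parameters)
  cat("\n")
  print(as.data.frame(x$lines), digits = 4)
  invisible(x)
}

#' Load a packaged reference fee table
#'
#' The published urban and rural fee schedules, packaged as plain-text
#' fixtures for regression comparison: percent breakdown, mean (SD)
#' duration, and the base / 82% / 270% cost columns in birr and US$.
#'
#' @param setting `"urban"` or `"rural"`.
#' @return a tibble keyed by `category_id`.
#' @export
reference_fee_table <- function(setting) {
  check_setting(setting)
  readr::read_csv(hc_extdata(sprintf("reference_fee_%s.csv", setting)),
                  show_col_types = FALSE)
}

#' Compare a fee schedule against a reference table
#'
#' Cell-by-cell regression check of the money columns (and optionally the
#' encounter statistics) against a reference table. Row sets must match
#' exactly — a missing or extra category is a structural error, not a
#' discrepancy. Default tolerances suit printed-cell chaining mode
#' (±0.1 birr / ±0.01 US$); end-to-end unrounded runs warrant a looser
#' birr tolerance because the reference chained from rounded cells.
#'
#' @param schedule a `fee_schedule`.
#' @param reference a reference tibble (default: the packaged table for the
#'   schedule's setting).
#' @param tol_birr,tol_usd absolute tolerances for birr and US$ cells.
#' @param include_stats also compare `pct_encounters`, `mean_min`, `sd_min`
#'   (with `tol_stats`).
#' @param tol_stats tolerance for the statistics columns.
#' @return a tibble of discrepancies (`category_id`, `column`, `value`,
#'   `reference`, `diff`); zero rows means the schedule reproduces the
#'   reference within tolerance.
#' @export
compare_to_reference <- function(schedule,
                                 reference = reference_fee_table(schedule$setting),
                                 tol_birr = 0.1, tol_usd = 0.01,
                                 include_stats = FALSE, tol_stats = 0.5) {
  stopifnot(inherits(schedule, "fee_schedule"))
  lines <- schedule$lines
  if (!setequal(lines$category_id, reference$category_id)) {
    abort(c("schedule and reference cover different category sets",
            sprintf("schedule only: %s",
                    paste(setdiff(lines$category_id, reference$category_id),
                          collapse = ", ") %|e|% "none"),
            sprintf("reference only: %s",
                    paste(setdiff(reference$category_id, lines$category_id),
                          collapse = ", ") %|e|% "none")))
  }
  reference <- reference[match(lines$category_id, reference$category_id), ]
  cols <- c(base_birr = tol_birr, cost82_birr = tol_birr,
            cost270_birr = tol_birr,
            base_usd = tol_usd, cost82_usd = tol_usd, cost270_usd = tol_usd)
  if (include_stats) {
    cols <- c(cols, pct_encounters = tol_stats, mean_min = tol_stats,
              sd_min = tol_stats)
  }
  out <- lapply(names(cols), function(cl) {
    got <- lines[[cl]]
    want <- reference[[cl]]
    bad <- which(abs(got - want) > cols[[cl]] + 1e-9)
    tibble::tibble(category_id = lines$category_id[bad],
                   column = rep(cl, length(bad)),
                   value = got[bad],
                   reference = want[bad],
                   diff = got[bad] - want[bad])
  })
  dplyr::bind_rows(out)
}

`%|e|%` <- function(x, alt) if (nzchar(x)) x else alt

#' Write and read a fee schedule
#'
#' The line table goes to a delimited text file; the parameter snapshot,
#' computation mode, setting and provenance go to a JSON sidecar
#' (`<path>.params.json`) so every fee is auditable back to its salary,
#' minutes, uplift and multipliers. [read_fee_schedule()] reverses the pair.
#'
#' @param schedule a `fee_schedule`.
#' @param path path for the lines file (CSV).
#' @return `write_fee_schedule()` returns `path` invisibly;
#'   `read_fee_schedule()` returns the reconstructed `fee_schedule`.
#' @export
write_fee_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "fee_schedule"))
  readr::write_csv(schedule$lines, path)
  p <- schedule$parameters
  meta <- list(setting = schedule$setting,
               mode = schedule$mode,
               provenance = schedule$provenance,
               parameters = list(
                 setting = p$setting,
                 salary_month = p$salary_month,
                 billable_min_month = p$billable_min_month,
                 rate_base = p$rate_base,
                 campaign_fraction = p$campaign_fraction,
                 uplift_factor = p$uplift_factor,
                 rate_uplifted = p$rate_uplifted,
                 multipliers = unclass(p$multipliers),
                 exchange_rate = p$exchange_rate))
  jsonlite::write_json(meta, paste0(path, ".params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_fee_schedule
#' @export
read_fee_schedule <- function(path) {
  lines <- readr::read_csv(path, show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".params.json"),
                              simplifyVector = TRUE)
  pm <- meta$parameters
  params <- cost_parameters(
    setting = pm$setting,
    salary_month = pm$salary_month,
    billable_min_month = pm$billable_min_month,
    campaign_fraction = pm$campaign_fraction,
    rate_uplifted = pm$rate_uplifted,
    multipliers = multiplier_set(pm$multipliers$supplies,
                                 pm$multipliers$management,
                                 pm$multipliers$overhead),
    exchange_rate = pm$exchange_rate)
  structure(list(setting = meta$setting,
                 lines = lines,
                 parameters = params,
                 mode = meta$mode,
                 provenance = as.character(meta$provenance %||% character())),
            class = "fee_schedule")
}

#' Render an encounter tally form
#'
#' A printable markdown tally sheet a health worker can use to track
#' billable encounters against the fee schedule: one row per billable
#' activity with the fee under each cost-recovery scenario and a blank
#' tally column. Layout is deterministic (canonical category order).
#'
#' @param schedule a `fee_schedule`.
#' @param scenarios which fee columns to show (default both scenarios).
#' @return a character vector of markdown lines (one element per line).
#' @export
render_encounter_form <- function(schedule,
                                  scenarios = c("cost82_birr", "cost270_birr")) {
  stopifnot(inherits(schedule, "fee_schedule"))
  lines <- schedule$lines
  if (nrow(lines) == 0) abort("cannot render a form for an empty schedule")
  lab <- c(cost82_birr = "Fee, no supplies (birr)",
           cost270_birr = "Fee, full cost (birr)",
           base_birr = "Salary base (birr)")
  header <- c("Activity", unname(lab[scenarios]), "Tally", "Count")
  fmt_fee <- function(x) formatC(x, format = "f", digits = 1)
  rows <- lapply(seq_len(nrow(lines)), function(i) {
    c(lines$display_name[i],
      vapply(scenarios, function(s) fmt_fee(lines[[s]][i]), character(1)),
      "", "")
  })
  tbl <- rbind(header, paste0(rep("---", length(header))), do.call(rbind, rows))
  body <- apply(tbl, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(sprintf("# Encounter form — %s health extension workers", schedule$setting),
    "",
    sprintf("Mark one tally per encounter. Fees assume an exchange rate of %.0f birr/US$.",
            schedule$parameters$exchange_rate),
    "",
    body)
}
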
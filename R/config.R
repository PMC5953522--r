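#' Load a costing configuration
#'
#' Reads a YAML configuration (see the packaged
#' `example_config.yaml` for an annotated template) and resolves it into
#' one [cost_parameters()] object per configured setting. Salary may be a
#' fixed monthly value or derived from a salary-survey file; billable
#' minutes may be fixed or measured from an observation log; an explicit
#' uplifted rate overrides the campaign-uplift formula. Non-salary cost
#' recovery comes from explicit multipliers or is derived from national
#' cost shares (with a warning when the shares do not sum to 1).
#'
#' @param path path to the YAML configuration.
#' @param log optional observation-record tibble, required when a setting
#'   block sets `derive_from_log: true`.
#' @param base_dir directory against which relative paths in the config are
#'   resolved (default: the config file's directory).
#' @return a list with `parameters` (named list of [cost_parameters()] per
#'   setting), `outlier_rule`, and the raw `config`.
#' @export
load_costing_config <- function(path, log = NULL, base_dir = dirname(path)) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$settings) || !length(cfg$settings)) {
    abort("config must contain a `settings` block")
  }
  mults <- if (!is.null(cfg$multipliers)) {
    multiplier_set(supplies = cfg$multipliers$supplies,
                   management = cfg$multipliers$management,
                   overhead = cfg$multipliers$overhead)
  } else if (!is.null(cfg$cost_shares)) {
    derive_multipliers(cost_shares(salary = cfg$cost_shares$salary,
                                   supplies = cfg$cost_shares$supplies,
                                   management = cfg$cost_shares$management,
                                   overhead = cfg$cost_shares$overhead))
  } else {
    multiplier_set()
  }
  campaign_fraction <- cfg$campaign_fraction %||% 0.1742
  exchange_rate <- cfg$exchange_rate %||% 22
  outlier_rule <- cfg$outlier_rule %||% "one_sided"

  params <- lapply(names(cfg$settings), function(setting) {
    blk <- cfg$settings[[setting]]
    salary <- if (!is.null(blk$salary_month)) {
      blk$salary_month
    } else if (!is.null(blk$salary_survey_path)) {
      srv_path <- blk$salary_survey_path
      if (!file.exists(srv_path)) srv_path <- file.path(base_dir, blk$salary_survey_path)
      average_salary(read_salary_survey(srv_path), setting)
    } else {
      abort(sprintf("setting '%s': need salary_month or salary_survey_path",
                    setting))
    }
    minutes <- if (!is.null(blk$billable_min_month)) {
      blk$billable_min_month
    } else if (isTRUE(blk$derive_from_log)) {
      if (is.null(log)) {
        abort(sprintf("setting '%s' derives minutes from a log, but no log was supplied",
                      setting))
      }
      billable_minutes_per_month(log, setting,
                                 rule = outlier_rule)$billable_min_per_month
    } else {
      abort(sprintf("setting '%s': need billable_min_month or derive_from_log: true",
                    setting))
    }
    cost_parameters(setting = setting,
                    salary_month = salary,
                    billable_min_month = minutes,
                    campaign_fraction = campaign_fraction,
                    rate_uplifted = blk$rate_uplifted_override,
                    multipliers = mults,
                    exchange_rate = exchange_rate)
  })
  names(params) <- names(cfg$settings)
  list(parameters = params, outlier_rule = outlier_rule, config = cfg)
}
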
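#' Configuration for the synthetic time-motion study generator
#'
#' Describes the study a generated observation log should emulate. The
#' defaults reproduce the design of the field study the pipeline was built
#' around: 2 workers in each of 22 districts (44 total, split evenly
#' between urban and rural postings) observed for 21 consecutive days;
#' per-category encounter-duration means and SDs and the encounter mix
#' taken from the packaged reference tables; billable workload of about
#' 900 (urban) / 1600 (rural) minutes per worker-month; a 7-Woreda salary
#' survey whose range midpoints average 1419 (urban) / 1513 (rural)
#' birr/month.
#'
#' @param setting `"urban"` or `"rural"`.
#' @param n_workers number of observed workers (default 22 per setting).
#' @param n_days consecutive observation days per worker (default 21).
#' @param seed integer seed; the same config generates byte-identical data.
#' @param duration_targets tibble with `category_id`, `mean_min`, `sd_min`;
#'   defaults to the packaged reference values for the setting.
#' @param encounter_mix tibble with `category_id`, `pct`; defaults to the
#'   reference percent breakdown. Must sum to ~100.
#' @param billable_min_month_target billable minutes per worker-month the
#'   log should realize (default 900 urban / 1600 rural).
#' @param outlier_rate probability that an encounter is replaced by an
#'   extreme duration beyond the 3-SD cut (default 0.005, matching the
#'   "under 1% of encounters" the outlier rule is meant to absorb).
#' @param n_woredas districts in the salary survey (default 7).
#' @param salary_target mean of the per-Woreda salary-range midpoints
#'   (default 1419 urban / 1513 rural birr/month).
#' @param salary_spread SD of midpoints around the target before centering
#'   (default 60 birr).
#' @param salary_range_width maximum width of a Woreda's reported salary
#'   range (default 150 birr; individual widths are uniform on [0, width]).
#' @param nonbillable_min_per_day minutes of enabling activities (travel,
#'   recordkeeping, training received) inserted per worker-day (default
#'   240; enabling work dominates the observed day).
#' @return a list of class `"generator_config"`.
#' @export
generator_config <- function(setting,
                             n_workers = 22,
                             n_days = 21,
                             seed = 1,
                             duration_targets = NULL,
                             encounter_mix = NULL,
                             billable_min_month_target = NULL,
                             outlier_rate = 0.005,
                             n_woredas = 7,
                             salary_target = NULL,
                             salary_spread = 60,
                             salary_range_width = 150,
                             nonbillable_min_per_day = 240) {
  check_setting(setting)
  ref <- reference_fee_table(setting)
  duration_targets <- duration_targets %||%
    ref[, c("category_id", "mean_min", "sd_min")]
  encounter_mix <- encounter_mix %||%
    tibble::tibble(category_id = ref$category_id, pct = ref$pct_encounters)
  billable_min_month_target <- billable_min_month_target %||%
    switch(setting, urban = 900, rural = 1600)
  salary_target <- salary_target %||% switch(setting, urban = 1419, rural = 1513)

  if (abs(sum(encounter_mix$pct) - 100) > 1) {
    abort("encounter mix percentages must sum to ~100")
  }
  if (any(duration_targets$mean_min <= 0)) {
    abort("duration mean targets must be positive")
  }
  if (any(duration_targets$sd_min < 0)) {
    abort("duration SD targets must be non-negative")
  }
  if (!setequal(duration_targets$category_id, encounter_mix$category_id)) {
    abort("duration targets and encounter mix must cover the same categories")
  }
  if (billable_min_month_target <= 0 || salary_target <= 0) {
    abort("billable-minutes and salary targets must be positive")
  }
  if (outlier_rate < 0 || outlier_rate >= 0.5) {
    abort("`outlier_rate` must lie in [0, 0.5)")
  }
  structure(list(setting = setting, n_workers = n_workers, n_days = n_days,
                 seed = as.integer(seed),
                 duration_targets = duration_targets,
                 encounter_mix = encounter_mix,
                 billable_min_month_target = billable_min_month_target,
                 outlier_rate = outlier_rate,
                 n_woredas = n_woredas,
                 salary_target = salary_target,
                 salary_spread = salary_spread,
                 salary_range_width = salary_range_width,
                 nonbillable_min_per_day = nonbillable_min_per_day),
            class = "generator_config")
}

# lognormal parameters matched to a target mean m and SD s
lnorm_params <- function(m, s) {
  sigma2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
}

# mean, sd and keep-probability of a lognormal truncated above at t
lnorm_kept_moments <- function(meanlog, sdlog, t) {
  beta <- (log(t) - meanlog) / sdlog
  p_keep <- stats::pnorm(beta)
  m1 <- exp(meanlog + sdlog^2 / 2) * stats::pnorm(beta - sdlog) / p_keep
  m2 <- exp(2 * meanlog + 2 * sdlog^2) * stats::pnorm(beta - 2 * sdlog) / p_keep
  list(mean = m1, sd = sqrt(pmax(m2 - m1^2, 0)), p_keep = p_keep)
}

# Published duration statistics are post-exclusion (the tables drop values
# beyond mean + 3 SD), so a generator that moment-matches the *raw* draw and
# is then run through the same cut recovers means biased a few percent low —
# the lognormal's upper tail carries a disproportionate share of minutes.
# Calibrate raw lognormal parameters by fixed point so that the moments of
# the distribution truncated at (raw mean + 3 raw SD) hit the targets.
calibrate_lnorm <- function(m_target, s_target, n_sd = 3, iters = 40) {
  m_raw <- m_target
  s_raw <- s_target
  for (i in seq_len(iters)) {
    p <- lnorm_params(m_raw, s_raw)
    t <- m_raw + n_sd * s_raw
    k <- lnorm_kept_moments(p$meanlog, p$sdlog, t)
    m_raw <- m_raw * m_target / k$mean
    s_raw <- s_raw * s_target / k$sd
  }
  p <- lnorm_params(m_raw, s_raw)
  t <- m_raw + n_sd * s_raw
  c(p, list(cut = t, p_keep = lnorm_kept_moments(p$meanlog, p$sdlog, t)$p_keep))
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic time-motion observation log
#'
#' Emulates continuous observation of health extension workers. Per worker:
#' the number of billable encounters is set so realized billable minutes
#' per 30-day month approximate the configured target; category counts are
#' drawn multinomially from the encounter mix (so the realized mix tracks
#' the target tightly); durations are drawn from log-normal distributions
#' (durations are positive and right-skewed, which a normal model would
#' violate) calibrated so that the *post-exclusion* moments match each
#' category's target mean and SD — the targets are statistics reported
#' after a 3-SD cut, and an uncalibrated heavy-tailed draw would recover
#' them a few percent low; a
#' configurable fraction of encounters is replaced by extreme durations
#' well beyond the 3-SD cut to exercise outlier exclusion; and enabling
#' (non-billable) records — travel, recordkeeping, training received — fill
#' the rest of each observed day. Output is fully determined by the
#' config's seed.
#'
#' @param config a [generator_config()].
#' @return an observation-record tibble (`worker_id`, `setting`, `date`,
#'   `activity_label`, `duration_min`) sorted by worker and date.
#' @export
generate_observation_log <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  tax <- hew_taxonomy()
  tg <- dplyr::inner_join(config$duration_targets, config$encounter_mix,
                          by = "category_id")
  tg$display_name <- tax$display_name[match(tg$category_id, tax$id)]
  mix <- tg$pct / sum(tg$pct)
  cal <- lapply(seq_len(nrow(tg)), function(i) {
    if (tg$sd_min[i] == 0) {
      list(meanlog = NA_real_, sdlog = 0, cut = Inf, p_keep = 1)
    } else {
      calibrate_lnorm(tg$mean_min[i], tg$sd_min[i])
    }
  })
  p_keep <- vapply(cal, `[[`, numeric(1), "p_keep")
  # expected *kept* billable minutes contributed by one drawn encounter:
  # injected outliers and natural beyond-3SD draws are excluded downstream
  kept_min_per_enc <- sum(mix * (1 - config$outlier_rate) * p_keep *
                            tg$mean_min)
  total_target <- config$billable_min_month_target * config$n_days / 30
  n_enc <- max(1L, round(total_target / kept_min_per_enc))
  start_date <- as.Date("2014-04-14")
  nb_labels <- c("travel", "recordkeeping and recording",
                 "receiving training and supervision")
  nb_weights <- c(0.5, 0.3, 0.2)

  with_seed(config$seed, {
    logs <- lapply(seq_len(config$n_workers), function(w) {
      counts <- as.integer(rmultinom(1, n_enc, mix))
      enc <- lapply(seq_along(counts), function(i) {
        n_i <- counts[i]
        if (n_i == 0) return(NULL)
        if (tg$sd_min[i] == 0) {
          dur <- rep(tg$mean_min[i], n_i)
        } else {
          dur <- rlnorm(n_i, cal[[i]]$meanlog, cal[[i]]$sdlog)
        }
        if (config$outlier_rate > 0) {
          flip <- rbinom(n_i, 1, config$outlier_rate) == 1
          dur[flip] <- tg$mean_min[i] + (8 + runif(sum(flip), 0, 4)) * tg$sd_min[i]
        }
        tibble::tibble(activity_label = tg$display_name[i],
                       duration_min = dur)
      })
      enc <- dplyr::bind_rows(enc)
      enc$day <- sample.int(config$n_days, nrow(enc), replace = TRUE)
      n_nb <- config$n_days * 3L
      nb <- tibble::tibble(
        activity_label = sample(nb_labels, n_nb, replace = TRUE,
                                prob = nb_weights),
        duration_min = round(rlnorm(n_nb,
                                    lnorm_params(config$nonbillable_min_per_day / 3,
                                                 20)$meanlog,
                                    lnorm_params(config$nonbillable_min_per_day / 3,
                                                 20)$sdlog), 1),
        day = rep(seq_len(config$n_days), each = 3L))
      out <- dplyr::bind_rows(enc, nb)
      out$worker_id <- sprintf("%s_hew_%02d", config$setting, w)
      out
    })
    log <- dplyr::bind_rows(logs)
    log$setting <- config$setting
    log$date <- start_date + log$day - 1L
    log$duration_min <- round(log$duration_min, 1)
    log <- log[order(log$worker_id, log$date, log$activity_label,
                     log$duration_min), ]
    tibble::as_tibble(log[, c("worker_id", "setting", "date",
                              "activity_label", "duration_min")])
  })
}

#' Generate a synthetic Woreda salary survey
#'
#' Per-Woreda salary ranges whose midpoints average exactly the configured
#' target: midpoints are drawn around the target and then re-centered so
#' their mean matches it, and each Woreda's reported range is a uniform
#' width around its midpoint (width 0 gives point reports). Seed-
#' deterministic; uses an offset of the log seed so a log and survey from
#' the same config are independent draws.
#'
#' @param config a [generator_config()].
#' @return a salary-record tibble (`woreda_id`, `setting`, `salary_low`,
#'   `salary_high`).
#' @export
generate_salary_survey <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed + 10000L, {
    n <- config$n_woredas
    mids <- config$salary_target + rnorm(n, 0, config$salary_spread)
    mids <- mids - mean(mids) + config$salary_target
    widths <- runif(n, 0, config$salary_range_width)
    tibble::tibble(
      woreda_id = sprintf("%s_woreda_%02d", config$setting, seq_len(n)),
      setting = config$setting,
      salary_low = round(mids - widths / 2, 2),
      salary_high = round(mids + widths / 2, 2))
  })
}
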
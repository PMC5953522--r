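# In-code fixtures: observation records and salary surveys are always built
# programmatically, never stored.

make_records <- function(labels, durations,
                         setting = "rural",
                         worker_id = "w1",
                         date = as.Date("2014-05-01")) {
  tibble::tibble(worker_id = worker_id,
                 setting = setting,
                 date = date,
                 activity_label = labels,
                 duration_min = durations)
}

# a small mixed log: one worker, two billable categories plus enabling time
small_rural_log <- function() {
  make_records(
    labels = c(rep("Provide TB related services", 3),
               "Provide contraceptives",
               "travel", "recordkeeping"),
    durations = c(4, 5, 3, 10, 60, 30))
}

# independent brute-force oracle for the outlier rule: statistics computed
# once on the full sample, one-sided cut at mean + 3 * sample SD
oracle_exclude <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  sigma <- if (n == 1) 0 else sqrt(sum((x - mu)^2) / (n - 1))
  keep <- x <= mu + 3 * sigma
  list(kept = x[keep], n_excluded = sum(!keep))
}

# independent per-category recomputation of encounter statistics
oracle_summarize <- function(records, setting) {
  tax <- hewcost::hew_taxonomy()
  cls <- hewcost::classify_activity(records$activity_label, setting)
  records$category_id <- cls$category_id
  records <- records[cls$billable & records$setting == setting, ]
  cats <- hewcost::billable_categories(setting)
  kept <- lapply(split(records$duration_min, records$category_id),
                 oracle_exclude)
  total <- sum(vapply(kept, function(k) length(k$kept), numeric(1)))
  do.call(rbind, lapply(cats$id, function(id) {
    k <- kept[[id]]
    if (is.null(k)) {
      data.frame(category_id = id, n_encounters = 0, pct_encounters = 0,
                 mean_min = NA_real_, sd_min = NA_real_)
    } else {
      data.frame(category_id = id,
                 n_encounters = length(k$kept),
                 pct_encounters = 100 * length(k$kept) / total,
                 mean_min = mean(k$kept),
                 sd_min = stats::sd(k$kept))
    }
  }))
}
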
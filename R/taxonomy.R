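#' The billable-activity taxonomy
#'
#' Loads the packaged activity taxonomy: one row per category with a stable
#' id, display name, activity group, billability flags for the urban and
#' rural scopes of practice, and the canonical fee-schedule row order. The
#' taxonomy uses the fee-schedule row granularity (12 urban / 14 rural
#' billable categories) as the costing unit; two categories — voluntary HIV
#' counseling & testing and TB services — are rural-only because urban health
#' extension workers do not provide them. Enabling activities (travel,
#' recordkeeping, training/supervision received, idle time) carry
#' non-billable flags in both settings.
#'
#' @param path optional path to a taxonomy file with the same columns;
#'   defaults to the packaged taxonomy.
#' @return a tibble with columns `id`, `display_name`, `group`,
#'   `urban_billable`, `rural_billable`, `order`.
#' @export
hew_taxonomy <- function(path = NULL) {
  path <- path %||% hc_extdata("activity_taxonomy.csv")
  tax <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           id = readr::col_character(),
                           display_name = readr::col_character(),
                           group = readr::col_character(),
                           urban_billable = readr::col_logical(),
                           rural_billable = readr::col_logical(),
                           order = readr::col_integer()))
  validate_taxonomy(tax)
  tax
}

valid_groups <- c("hygiene_environment", "family_health", "disease_prevention",
                  "first_aid", "ncd", "group_training", "non_billable")

validate_taxonomy <- function(tax) {
  if (anyDuplicated(tax$id)) abort("taxonomy ids must be unique")
  bad_group <- setdiff(tax$group, valid_groups)
  if (length(bad_group)) {
    abort(sprintf("unknown activity group(s): %s",
                  paste(bad_group, collapse = ", ")))
  }
  nb <- tax$group == "non_billable"
  if (any(tax$urban_billable[nb]) || any(tax$rural_billable[nb])) {
    abort("non_billable categories must have both billability flags FALSE")
  }
  if (any(tax$urban_billable & !tax$rural_billable)) {
    abort("urban billable categories must be a subset of rural ones")
  }
  invisible(tax)
}

#' The raw-label synonym map
#'
#' Raw activity labels as they appear in time-motion observation logs,
#' mapped to taxonomy category ids. Matching is case- and
#' whitespace-insensitive but never fuzzy: an unrecognized label is an
#' error, because a costing pipeline must be auditable. The map is data, not
#' code — new label vocabularies are added by extending the file.
#'
#' @param path optional path to a synonym file (columns `raw_label`,
#'   `category_id`); defaults to the packaged map.
#' @param taxonomy taxonomy tibble used to check that every target id exists.
#' @return a tibble with columns `raw_label`, `category_id`.
#' @export
hew_synonyms <- function(path = NULL, taxonomy = hew_taxonomy()) {
  path <- path %||% hc_extdata("activity_synonyms.csv")
  syn <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           raw_label = readr::col_character(),
                           category_id = readr::col_character()))
  bad <- setdiff(syn$category_id, taxonomy$id)
  if (length(bad)) {
    abort(sprintf("synonym map targets unknown categories: %s",
                  paste(unique(bad), collapse = ", ")))
  }
  syn
}

check_setting <- function(setting) {
  if (!is.character(setting) || length(setting) != 1L ||
      !setting %in% c("urban", "rural")) {
    abort("`setting` must be \"urban\" or \"rural\"")
  }
  setting
}

normalize_label <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Billable categories for a setting
#'
#' @param setting `"urban"` or `"rural"`.
#' @param taxonomy taxonomy tibble.
#' @return taxonomy rows billable in `setting`, in canonical row order.
#' @export
billable_categories <- function(setting, taxonomy = hew_taxonomy()) {
  check_setting(setting)
  flag <- paste0(setting, "_billable")
  out <- taxonomy[taxonomy[[flag]], , drop = FALSE]
  out[order(out$order), , drop = FALSE]
}

#' Classify raw activity labels
#'
#' Resolves free-text activity labels to taxonomy categories through the
#' synonym map (display names match too), and reports whether each resolved
#' category is billable in the given setting. A category that exists but is
#' outside the setting's scope of practice (e.g. TB services in an urban
#' log) classifies successfully with `billable = FALSE`. Labels with no
#' mapping raise an error that lists them — they are never silently dropped.
#'
#' @param raw_label character vector of labels; matching is case- and
#'   whitespace-insensitive.
#' @param setting `"urban"` or `"rural"`.
#' @param taxonomy taxonomy tibble.
#' @param synonyms synonym-map tibble.
#' @return a tibble with columns `raw_label`, `category_id`, `display_name`,
#'   `group`, `billable`.
#' @export
classify_activity <- function(raw_label, setting,
                              taxonomy = hew_taxonomy(),
                              synonyms = hew_synonyms(taxonomy = taxonomy)) {
  check_setting(setting)
  if (length(raw_label) == 0 || any(!nzchar(trimws(raw_label)))) {
    abort("`raw_label` must be non-empty")
  }
  lookup <- c(stats::setNames(synonyms$category_id,
                              normalize_label(synonyms$raw_label)),
              stats::setNames(taxonomy$id, normalize_label(taxonomy$display_name)),
              stats::setNames(taxonomy$id, taxonomy$id))
  ids <- unname(lookup[normalize_label(raw_label)])
  if (anyNA(ids)) {
    missing <- unique(raw_label[is.na(ids)])
    abort(c(sprintf("unmapped activity label(s): %s",
                    paste(sprintf('"%s"', missing), collapse = ", ")),
            i = "add them to the synonym map to make them classifiable"),
          class = "hewcost_unmapped_label")
  }
  idx <- match(ids, taxonomy$id)
  tibble::tibble(
    raw_label = raw_label,
    category_id = ids,
    display_name = taxonomy$display_name[idx],
    group = taxonomy$group[idx],
    billable = taxonomy[[paste0(setting, "_billable")]][idx]
  )
}
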
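#' Deduplicate case versions
#'
#' Spontaneous reporting databases carry several versions of the same case;
#' only the most recent version is analysed. Exactly one report per
#' `case_id` is retained: the one with the latest `version_date`, ties
#' broken by the lexicographically greatest `report_id` (the standard
#' "latest case version supersedes" rule). Idempotent.
#'
#' @param rs A [report_set].
#' @return The deduplicated report set, with provenance updated.
#' @export
dedup_reports <- function(rs) {
  stopifnot(is_report_set(rs))
  keep <- rs$reports |>
    dplyr::arrange(.data$case_id, dplyr::desc(.data$version_date),
                   dplyr::desc(.data$report_id)) |>
    dplyr::distinct(.data$case_id, .keep_all = TRUE) |>
    dplyr::pull("report_id")
  rs <- keep_reports(rs, keep)
  add_provenance(rs, "deduplicate", "latest version per case")
}

#' Split a report set on an adverse-event term list
#'
#' Retains reports whose reactions intersect the event PT list
#' (case-insensitive exact preferred-term match) — or, with
#' `keep = "non-event"`, the complement, so the two calls partition the
#' input into the cases and non-cases of the 2x2 design.
#'
#' @param rs A [report_set].
#' @param event_terms Non-empty character vector of MedDRA preferred terms.
#' @param keep `"event"` (default) or `"non-event"`.
#' @return The filtered report set.
#' @export
filter_event_reports <- function(rs, event_terms,
                                 keep = c("event", "non-event")) {
  stopifnot(is_report_set(rs))
  keep <- rlang::arg_match(keep)
  if (length(event_terms) == 0 || all(is.na(event_terms))) {
    abort("event_terms must be a non-empty set of preferred terms")
  }
  terms <- stringr::str_to_upper(stringr::str_trim(event_terms))
  event_ids <- rs$reactions |>
    dplyr::filter(stringr::str_to_upper(.data$pt) %in% terms) |>
    dplyr::pull("report_id") |>
    unique()
  ids <- if (keep == "event") {
    event_ids
  } else {
    setdiff(rs$reports$report_id, event_ids)
  }
  rs <- keep_reports(rs, ids)
  add_provenance(rs, paste0("filter_", keep, "_reports"),
                 paste0("terms: ", paste(terms, collapse = ", ")))
}

#' Restrict analysis to primary-suspect drug entries
#'
#' Within each report only primary-suspect drug entries are kept for
#' analysis. An ingredient that appears in the same report both as primary
#' suspect and under any other role (concomitant, secondary suspect,
#' interacting) is excluded from that report entirely, since its suspect
#' status is ambiguous. Reports left with no analysable drug are dropped
#' and counted.
#'
#' Call after [normalize_drug_names()] so role conflicts are detected on
#' the consolidated ingredient, not on brand spellings.
#'
#' @param rs A [report_set].
#' @return The filtered report set.
#' @export
filter_primary_suspect <- function(rs) {
  stopifnot(is_report_set(rs))
  if (anyNA(rs$drugs$ingredient)) {
    abort("run normalize_drug_names() before filter_primary_suspect()")
  }
  ps_pairs <- rs$drugs |>
    dplyr::filter(.data$role == "primary-suspect") |>
    dplyr::distinct(.data$report_id, .data$ingredient)
  other_pairs <- rs$drugs |>
    dplyr::filter(.data$role != "primary-suspect") |>
    dplyr::distinct(.data$report_id, .data$ingredient)
  conflicted <- dplyr::inner_join(ps_pairs, other_pairs,
                                  by = c("report_id", "ingredient"))
  rs$drugs <- rs$drugs |>
    dplyr::filter(.data$role == "primary-suspect") |>
    dplyr::anti_join(conflicted, by = c("report_id", "ingredient"))
  rs <- keep_reports(rs, unique(rs$drugs$report_id))
  add_provenance(rs, "filter_primary_suspect",
                 paste0(nrow(conflicted), " report-ingredient role conflicts excluded"))
}

#' Demographic plausibility and completeness filters
#'
#' Retains reports with complete, plausible demographics: age present and
#' at most `max_age` years, weight present and at most `max_weight` kg, and
#' sex recorded as female or male. The boundary values themselves are
#' retained — only ages *exceeding* 120 years and weights *over* 400 kg are
#' implausible.
#'
#' @param rs A [report_set].
#' @param max_age Maximum plausible age in years (inclusive).
#' @param max_weight Maximum plausible weight in kg (inclusive).
#' @return The filtered report set.
#' @export
filter_demographics <- function(rs, max_age = 120, max_weight = 400) {
  stopifnot(is_report_set(rs))
  ok <- rs$reports |>
    dplyr::filter(!is.na(.data$age_years), .data$age_years <= max_age,
                  !is.na(.data$weight_kg), .data$weight_kg <= max_weight,
                  .data$sex %in% c("female", "male")) |>
    dplyr::pull("report_id")
  rs <- keep_reports(rs, ok)
  add_provenance(rs, "filter_demographics",
                 paste0("complete age/sex/weight; age <= ", max_age,
                        " y, weight <= ", max_weight, " kg"))
}

#' Run the full cleaning cascade
#'
#' Convenience wrapper chaining [normalize_drug_names()], [dedup_reports()],
#' [filter_primary_suspect()] and [filter_demographics()] in the canonical
#' order. The event split is not part of the cascade; it happens when the
#' 2x2 tables are built ([contingency_tables()]) or via
#' [filter_event_reports()].
#'
#' @inheritParams normalize_drug_names
#' @inheritParams filter_demographics
#' @return The cleaned report set with a full provenance trail.
#' @export
clean_reports <- function(rs, name_map = NULL,
                          salt_suffixes = default_salt_suffixes(),
                          max_age = 120, max_weight = 400) {
  rs |>
    normalize_drug_names(name_map, salt_suffixes) |>
    dedup_reports() |>
    filter_primary_suspect() |>
    filter_demographics(max_age = max_age, max_weight = max_weight)
}
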
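#' Per-drug 2x2 contingency tables for a case/non-case design
#'
#' Cross-tabulates every primary-suspect ingredient against the event of
#' interest over a cleaned report set. For drug *D* the cells are:
#' `a` event reports naming *D*, `b` non-event reports naming *D*, `c`
#' event reports without *D*, `d` non-event reports without *D* — so all
#' tables share the margins `a + c` (total event reports) and `b + d`
#' (total non-event reports). A report is an event report when its
#' reactions intersect `event_terms` (case-insensitive exact PT match).
#' Drugs on `exclude_drugs` (e.g. medications intended to *treat* the
#' event) are omitted from the output.
#'
#' @param rs A cleaned [report_set] (see [clean_reports()]).
#' @param event_terms Non-empty character vector of event preferred terms.
#' @param exclude_drugs Optional character vector of ingredients to omit.
#' @return A tibble with columns `drug`, `a`, `b`, `c`, `d`, one row per
#'   ingredient appearing as primary suspect in at least one report.
#' @export
contingency_tables <- function(rs, event_terms, exclude_drugs = NULL) {
  stopifnot(is_report_set(rs))
  if (n_reports(rs) == 0) {
    abort("no analysable reports: the cleaned set is empty")
  }
  if (length(event_terms) == 0) {
    abort("event_terms must be a non-empty set of preferred terms")
  }
  terms <- stringr::str_to_upper(stringr::str_trim(event_terms))
  event_ids <- rs$reactions |>
    dplyr::filter(stringr::str_to_upper(.data$pt) %in% terms) |>
    dplyr::pull("report_id") |>
    unique()
  n_event <- length(event_ids)
  n_nonevent <- n_reports(rs) - n_event

  tabs <- rs$drugs |>
    dplyr::filter(.data$role == "primary-suspect") |>
    dplyr::distinct(.data$report_id, .data$ingredient) |>
    dplyr::mutate(is_event = .data$report_id %in% event_ids) |>
    dplyr::summarise(a = sum(.data$is_event),
                     b = sum(!.data$is_event),
                     .by = "ingredient") |>
    dplyr::mutate(c = n_event - .data$a, d = n_nonevent - .data$b) |>
    dplyr::rename(drug = "ingredient") |>
    dplyr::arrange(.data$drug)
  if (!is.null(exclude_drugs)) {
    tabs <- dplyr::filter(
      tabs, !.data$drug %in% stringr::str_to_upper(exclude_drugs))
  }
  tabs
}
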
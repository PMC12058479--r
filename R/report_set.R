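#' Spontaneous-report set container
#'
#' A `report_set` holds one batch of individual case safety reports in
#' relational form, mirroring the quarterly file layout of spontaneous
#' reporting databases: one report-level table plus long tables for drug
#' entries, reaction preferred terms (PTs) and outcome codes, all keyed by
#' `report_id`. A provenance table records the size of the collection after
#' every cleaning stage, so the screening cascade is auditable.
#'
#' @param reports Tibble with one row per report: `report_id` (unique),
#'   `case_id`, `version_date` (Date), `event_date` (Date, may be `NA`),
#'   `report_year` (integer), `age_years`, `sex` (`"female"`, `"male"` or
#'   `"unknown"`), `weight_kg`, `country`.
#' @param drugs Tibble with one row per drug entry: `report_id`, `name_raw`,
#'   `ingredient` (filled by [normalize_drug_names()], `NA` until then),
#'   `role` (one of `"primary-suspect"`, `"secondary-suspect"`,
#'   `"concomitant"`, `"interacting"`), `therapy_start`, `therapy_end`
#'   (Dates, may be `NA`).
#' @param reactions Tibble with one row per reaction: `report_id`, `pt`
#'   (MedDRA preferred term, stored upper-case).
#' @param outcomes Tibble with one row per outcome code: `report_id`,
#'   `outcome` (one of [outcome_levels()]). A report whose only outcome is
#'   `"missing"` had no outcome rows in the source files.
#' @param provenance Tibble logging the cleaning cascade: `stage`,
#'   `n_reports`, `n_dropped`, `note`.
#'
#' @return An object of class `report_set`.
#' @seealso [read_faers_quarter()], [simulate_reports()], [clean_reports()]
#' @export
report_set <- function(reports, drugs, reactions, outcomes,
                       provenance = empty_provenance()) {
  reports   <- tibble::as_tibble(reports)
  drugs     <- tibble::as_tibble(drugs)
  reactions <- tibble::as_tibble(reactions)
  outcomes  <- tibble::as_tibble(outcomes)
  rs <- structure(
    list(reports = reports, drugs = drugs, reactions = reactions,
         outcomes = outcomes, provenance = tibble::as_tibble(provenance)),
    class = "report_set"
  )
  validate_report_set(rs)
}

#' @rdname report_set
#' @param x Object to test or print.
#' @export
is_report_set <- function(x) inherits(x, "report_set")

validate_report_set <- function(rs) {
  rep_cols <- c("report_id", "case_id", "version_date", "event_date",
                "report_year", "age_years", "sex", "weight_kg", "country")
  missing_cols <- setdiff(rep_cols, names(rs$reports))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("report table is missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(rs$reports$report_id) > 0) {
    rlang::abort("report_id must be unique within a report_set")
  }
  bad_age <- rs$reports$age_years < 0
  bad_wt  <- rs$reports$weight_kg < 0
  if (any(bad_age, na.rm = TRUE) || any(bad_wt, na.rm = TRUE)) {
    rlang::abort("age_years and weight_kg must be absent (NA) or >= 0")
  }
  bad_role <- !rs$drugs$role %in% drug_roles()
  if (any(bad_role)) {
    rlang::abort(paste0("unknown drug role(s): ",
                        paste(unique(rs$drugs$role[bad_role]), collapse = ", ")))
  }
  orphans <- !c(rs$drugs$report_id, rs$reactions$report_id,
                rs$outcomes$report_id) %in% rs$reports$report_id
  if (any(orphans)) {
    rlang::abort("child tables reference report_ids absent from the report table")
  }
  rs
}

#' Vocabulary helpers
#'
#' Fixed vocabularies of the report container: the four drug role codes and
#' the outcome categories, the latter ordered from most to least serious.
#' The severity order is used when a report with several outcome codes must
#' be attributed to a single category (see [baseline_table()]).
#'
#' @return Character vector of levels.
#' @export
drug_roles <- function() {
  c("primary-suspect", "secondary-suspect", "concomitant", "interacting")
}

#' @rdname drug_roles
#' @export
outcome_levels <- function() {
  c("death", "life-threatening", "disability", "congenital-anomaly",
    "required-intervention", "hospitalization", "other-serious", "missing")
}

#' @rdname report_set
#' @export
n_reports <- function(x) {
  stopifnot(is_report_set(x))
  nrow(x$reports)
}

#' Cleaning-cascade provenance
#'
#' Every ingestion or filtering stage appends a row to the provenance table;
#' `provenance()` retrieves it. Counters are non-increasing along the
#' cascade and always equal the actual collection size at that stage.
#'
#' @param x A `report_set`.
#' @return A tibble with columns `stage`, `n_reports`, `n_dropped`, `note`.
#' @export
provenance <- function(x) {
  stopifnot(is_report_set(x))
  x$provenance
}

empty_provenance <- function() {
  tibble::tibble(stage = character(), n_reports = integer(),
                 n_dropped = integer(), note = character())
}

add_provenance <- function(rs, stage, note = "") {
  prev <- if (nrow(rs$provenance) > 0) {
    rs$provenance$n_reports[nrow(rs$provenance)]
  } else {
    NA_integer_
  }
  n_now <- nrow(rs$reports)
  rs$provenance <- dplyr::bind_rows(
    rs$provenance,
    tibble::tibble(stage = stage, n_reports = n_now,
                   n_dropped = if (is.na(prev)) 0L else prev - n_now,
                   note = note)
  )
  rs
}

# Drop reports (and their child rows) whose ids are in `ids`.
drop_reports <- function(rs, ids) {
  rs$reports   <- dplyr::filter(rs$reports, !.data$report_id %in% ids)
  keep <- rs$reports$report_id
  rs$drugs     <- dplyr::filter(rs$drugs, .data$report_id %in% keep)
  rs$reactions <- dplyr::filter(rs$reactions, .data$report_id %in% keep)
  rs$outcomes  <- dplyr::filter(rs$outcomes, .data$report_id %in% keep)
  rs
}

# Keep only reports whose ids are in `ids`, preserving table order.
keep_reports <- function(rs, ids) {
  rs$reports   <- dplyr::filter(rs$reports, .data$report_id %in% ids)
  keep <- rs$reports$report_id
  rs$drugs     <- dplyr::filter(rs$drugs, .data$report_id %in% keep)
  rs$reactions <- dplyr::filter(rs$reactions, .data$report_id %in% keep)
  rs$outcomes  <- dplyr::filter(rs$outcomes, .data$report_id %in% keep)
  rs
}

#' @export
print.report_set <- function(x, ...) {
  cat("<report_set>\n")
  cat("  reports:   ", nrow(x$reports), "\n", sep = "")
  cat("  drug rows: ", nrow(x$drugs), "\n", sep = "")
  cat("  reactions: ", nrow(x$reactions), "\n", sep = "")
  cat("  outcomes:  ", nrow(x$outcomes), "\n", sep = "")
  if (nrow(x$provenance) > 0) {
    cat("  provenance:\n")
    stages <- utils::capture.output(print(as.data.frame(x$provenance),
                                          row.names = FALSE))
    cat(paste0("    ", stages, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Flatten a report set to one row per report
#'
#' Joins the relational tables into a single report-level tibble: drug
#' entries, reactions and outcomes are packed into `|`-separated strings.
#' Convenient for eyeballing and for the flat TSV dialect
#' ([write_report_tsv()]).
#'
#' @param x A `report_set`.
#' @param ... Unused.
#' @return A tibble with one row per report.
#' @export
as_tibble.report_set <- function(x, ...) {
  drugs <- x$drugs |>
    dplyr::mutate(packed = paste(.data$name_raw,
                                 dplyr::coalesce(.data$ingredient, ""),
                                 .data$role,
                                 pack_date(.data$therapy_start),
                                 pack_date(.data$therapy_end),
                                 sep = ":")) |>
    dplyr::summarise(drugs = paste(.data$packed, collapse = "|"),
                     .by = "report_id")
  reac <- x$reactions |>
    dplyr::summarise(reactions = paste(.data$pt, collapse = "|"),
                     .by = "report_id")
  outc <- x$outcomes |>
    dplyr::summarise(outcomes = paste(.data$outcome, collapse = "|"),
                     .by = "report_id")
  x$reports |>
    dplyr::left_join(drugs, by = "report_id") |>
    dplyr::left_join(reac, by = "report_id") |>
    dplyr::left_join(outc, by = "report_id")
}

pack_date <- function(d) {
  out <- format(d, "%Y%m%d")
  out[is.na(d)] <- ""
  out
}
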
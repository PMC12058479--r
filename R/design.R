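#' Report-level design matrix for risk modelling
#'
#' Builds the modelling table of the univariate-to-LASSO-to-multivariate
#' cascade: one row per report in the cleaned set, a binary `event`
#' outcome, one 0/1 exposure indicator per candidate drug (1 iff the drug
#' is a primary suspect of that report), and the unstandardized demographic
#' covariates `age_years`, `weight_kg` and `sex_female` (1 = female).
#' Standardization, where needed, happens inside the penalized fit only, so
#' reported odds ratios stay on the per-year / per-kg scale.
#'
#' Rows are ordered canonically by `report_id`, which makes every
#' downstream seeded computation (fold assignment in particular) invariant
#' to the input row order. The set is complete-case by construction because
#' the demographic filters ran upstream.
#'
#' @param rs A cleaned [report_set].
#' @param candidates Character vector of candidate ingredients (typically
#'   [candidate_drugs()] on the univariate screen). Candidates with no
#'   exposed report are dropped with a warning.
#' @param event_terms Event PT list defining the outcome indicator.
#' @return A tibble with columns `report_id`, `event`, one column per
#'   retained candidate, `age_years`, `weight_kg`, `sex_female`; candidate
#'   column names are carried in the `drug_cols` attribute.
#' @export
build_design_matrix <- function(rs, candidates, event_terms) {
  stopifnot(is_report_set(rs))
  if (length(candidates) == 0) abort("no candidate drugs supplied")
  terms <- stringr::str_to_upper(stringr::str_trim(event_terms))
  if (anyNA(rs$reports$age_years) || anyNA(rs$reports$weight_kg) ||
      any(!rs$reports$sex %in% c("female", "male"))) {
    abort("design matrix requires a demographically complete set; run filter_demographics()")
  }

  event_ids <- rs$reactions |>
    dplyr::filter(stringr::str_to_upper(.data$pt) %in% terms) |>
    dplyr::pull("report_id") |>
    unique()

  ps <- rs$drugs |>
    dplyr::filter(.data$role == "primary-suspect",
                  .data$ingredient %in% candidates) |>
    dplyr::distinct(.data$report_id, .data$ingredient)

  exposed <- unique(ps$ingredient)
  missing <- setdiff(candidates, exposed)
  if (length(missing) > 0) {
    warn(paste0("dropping candidate(s) with no exposed report: ",
                paste(missing, collapse = ", ")))
  }
  kept <- intersect(candidates, exposed)
  if (length(kept) == 0) abort("no candidate has any exposed report")

  wide <- ps |>
    dplyr::mutate(value = 1L) |>
    tidyr::pivot_wider(names_from = "ingredient", values_from = "value",
                       values_fill = 0L)

  dm <- rs$reports |>
    dplyr::transmute(
      report_id = .data$report_id,
      event = as.integer(.data$report_id %in% event_ids),
      age_years = .data$age_years,
      weight_kg = .data$weight_kg,
      sex_female = as.integer(.data$sex == "female")
    ) |>
    dplyr::left_join(wide, by = "report_id") |>
    dplyr::mutate(dplyr::across(dplyr::all_of(kept),
                                ~ dplyr::coalesce(.x, 0L))) |>
    dplyr::relocate(dplyr::all_of(kept), .after = "event") |>
    dplyr::arrange(.data$report_id)

  if (dplyr::n_distinct(dm$event) < 2) {
    abort("outcome is constant; design matrix is unusable")
  }
  attr(dm, "drug_cols") <- kept
  attr(dm, "demog_cols") <- c("age_years", "weight_kg", "sex_female")
  dm
}

# Internal: split a design tibble into response / predictor matrix pieces.
dm_pieces <- function(dm) {
  drug_cols <- attr(dm, "drug_cols")
  demog_cols <- attr(dm, "demog_cols")
  if (is.null(drug_cols)) {
    drug_cols <- setdiff(names(dm), c("report_id", "event", "age_years",
                                      "weight_kg", "sex_female"))
  }
  if (is.null(demog_cols)) demog_cols <- c("age_years", "weight_kg", "sex_female")
  preds <- c(drug_cols, demog_cols)
  x <- as.matrix(dm[, preds])
  storage.mode(x) <- "double"
  list(y = dm$event, x = x, drug_cols = drug_cols, demog_cols = demog_cols)
}
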
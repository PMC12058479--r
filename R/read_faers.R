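#' Parse FAERS-style quarterly report files
#'
#' Reads one quarter of `$`-delimited ASCII tables (DEMO, DRUG, REAC, OUTC,
#' THER) and assembles a [report_set]. The dialect is the public FAERS
#' quarterly layout restricted to the columns this pipeline uses:
#'
#' * DEMO: `primaryid`, `caseid`, `fda_dt`, `event_dt`, `age`, `sex`, `wt`,
#'   `occr_country`
#' * DRUG: `primaryid`, `drug_seq`, `role_cod` (`PS`/`SS`/`C`/`I`),
#'   `drugname`
#' * REAC: `primaryid`, `pt`
#' * OUTC: `primaryid`, `outc_cod` (`DE`, `LT`, `HO`, `DS`, `CA`, `RI`, `OT`)
#' * THER: `primaryid`, `dsg_drug_seq`, `start_dt`, `end_dt`
#'
#' A report is kept when its DEMO row joins at least one DRUG and one REAC
#' row; join failures are not silently dropped but counted in the
#' provenance. Dates are `YYYYMMDD`; partial dates are resolved
#' deterministically (`YYYYMM` to the first of the month, `YYYY` to July 1,
#' the median-unbiased day within the year). Malformed rows are skipped and
#' counted. Filtering (age/weight plausibility, completeness) is *not*
#' applied at parse time; see [clean_reports()].
#'
#' @param demo_path,drug_path,reac_path,outc_path,ther_path Paths to the
#'   five quarter files.
#' @return A [report_set] whose provenance records the raw DEMO row count,
#'   skipped malformed rows and join failures.
#' @export
read_faers_quarter <- function(demo_path, drug_path, reac_path, outc_path,
                               ther_path) {
  paths <- c(demo = demo_path, drug = drug_path, reac = reac_path,
             outc = outc_path, ther = ther_path)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0("input file(s) not found: ", paste(missing, collapse = ", ")))
  }

  demo <- read_dollar_table(demo_path, c("primaryid", "caseid", "fda_dt",
                                         "event_dt", "age", "sex", "wt",
                                         "occr_country"))
  drug <- read_dollar_table(drug_path, c("primaryid", "drug_seq", "role_cod",
                                         "drugname"))
  reac <- read_dollar_table(reac_path, c("primaryid", "pt"))
  outc <- read_dollar_table(outc_path, c("primaryid", "outc_cod"))
  ther <- read_dollar_table(ther_path, c("primaryid", "dsg_drug_seq",
                                         "start_dt", "end_dt"))
  n_malformed <- sum(demo$n_skipped, drug$n_skipped, reac$n_skipped,
                     outc$n_skipped, ther$n_skipped)

  reports <- demo$table |>
    dplyr::mutate(
      report_id    = .data$primaryid,
      case_id      = .data$caseid,
      version_date = faers_date(.data$fda_dt),
      event_date   = faers_date(.data$event_dt),
      age_years    = suppressWarnings(as.numeric(.data$age)),
      sex          = decode_sex(.data$sex),
      weight_kg    = suppressWarnings(as.numeric(.data$wt)),
      country      = dplyr::coalesce(.data$occr_country, ""),
      .keep = "none"
    ) |>
    dplyr::mutate(report_year = as.integer(format(.data$version_date, "%Y"))) |>
    dplyr::select("report_id", "case_id", "version_date", "event_date",
                  "report_year", "age_years", "sex", "weight_kg", "country")

  ther_tbl <- ther$table |>
    dplyr::mutate(therapy_start = faers_date(.data$start_dt),
                  therapy_end   = faers_date(.data$end_dt)) |>
    dplyr::select("primaryid", drug_seq = "dsg_drug_seq",
                  "therapy_start", "therapy_end")

  drugs <- drug$table |>
    dplyr::left_join(ther_tbl, by = c("primaryid", "drug_seq")) |>
    dplyr::mutate(
      report_id  = .data$primaryid,
      name_raw   = dplyr::coalesce(.data$drugname, ""),
      ingredient = NA_character_,
      role       = decode_role(.data$role_cod),
      .keep = "unused"
    ) |>
    dplyr::select("report_id", "name_raw", "ingredient", "role",
                  "therapy_start", "therapy_end")
  n_bad_role <- sum(is.na(drugs$role))
  drugs <- dplyr::filter(drugs, !is.na(.data$role))

  reactions <- reac$table |>
    dplyr::transmute(report_id = .data$primaryid,
                     pt = stringr::str_to_upper(stringr::str_trim(
                       dplyr::coalesce(.data$pt, "")))) |>
    dplyr::filter(.data$pt != "")

  outcomes <- outc$table |>
    dplyr::transmute(report_id = .data$primaryid,
                     outcome = decode_outcome(.data$outc_cod)) |>
    dplyr::filter(!is.na(.data$outcome))

  # join rule: a report must bring >= 1 drug and >= 1 reaction
  has_drug <- reports$report_id %in% drugs$report_id
  has_reac <- reports$report_id %in% reactions$report_id
  n_join_fail <- sum(!(has_drug & has_reac))
  kept <- reports$report_id[has_drug & has_reac]

  reports   <- dplyr::filter(reports, .data$report_id %in% kept)
  drugs     <- dplyr::filter(drugs, .data$report_id %in% kept)
  reactions <- dplyr::filter(reactions, .data$report_id %in% kept)
  outcomes  <- dplyr::filter(outcomes, .data$report_id %in% kept)

  # reports with no outcome rows carry the explicit "missing" category
  no_outc <- setdiff(reports$report_id, outcomes$report_id)
  if (length(no_outc) > 0) {
    outcomes <- dplyr::bind_rows(
      outcomes, tibble(report_id = no_outc, outcome = "missing"))
  }

  rs <- report_set(reports, drugs, reactions, outcomes)
  rs$provenance <- tibble(
    stage = c("raw_demo_rows", "parsed"),
    n_reports = c(nrow(demo$table) + demo$n_skipped, nrow(reports)),
    n_dropped = c(0L, n_join_fail + demo$n_skipped),
    note = c("DEMO rows in input",
             paste0(n_join_fail, " join failures (no DRUG or no REAC row); ",
                    n_malformed, " malformed lines skipped; ",
                    n_bad_role, " drug rows with unknown role code skipped"))
  )
  rs
}

# Read a "$"-delimited table, returning the requested columns (missing ones
# filled with NA) and a count of malformed/skipped lines.
read_dollar_table <- function(path, cols) {
  tbl <- suppressWarnings(readr::read_delim(
    path, delim = "$", col_types = readr::cols(.default = "c"),
    na = c("", "NA"), progress = FALSE, show_col_types = FALSE,
    name_repair = "minimal"
  ))
  probs <- readr::problems(tbl)
  n_skipped <- 0L
  if (nrow(probs) > 0) {
    bad_rows <- unique(probs$row)
    n_skipped <- length(bad_rows)
    tbl <- tbl[-bad_rows, , drop = FALSE]
  }
  for (cl in setdiff(cols, names(tbl))) tbl[[cl]] <- NA_character_
  list(table = tibble::as_tibble(tbl[, cols]), n_skipped = n_skipped)
}

#' Parse FAERS numeric dates, resolving partial dates
#'
#' `YYYYMMDD` parses exactly; `YYYYMM` resolves to the first day of the
#' month and a bare `YYYY` to July 1 (the median-unbiased day within the
#' year). Anything else is `NA`.
#'
#' @param x Character vector of date codes.
#' @return A `Date` vector.
#' @export
faers_date <- function(x) {
  x <- stringr::str_trim(as.character(x))
  x[is.na(x)] <- ""
  full <- dplyr::case_when(
    stringr::str_detect(x, "^\\d{8}$") ~ x,
    stringr::str_detect(x, "^\\d{6}$") ~ paste0(x, "01"),
    stringr::str_detect(x, "^\\d{4}$") ~ paste0(x, "0701"),
    .default = NA_character_
  )
  as.Date(full, format = "%Y%m%d")
}

decode_sex <- function(x) {
  x <- stringr::str_to_upper(stringr::str_trim(dplyr::coalesce(x, "")))
  dplyr::case_when(
    x == "F" ~ "female",
    x == "M" ~ "male",
    .default = "unknown"
  )
}

# Unknown role codes map to NA; the caller skips and counts those rows.
decode_role <- function(x) {
  x <- stringr::str_to_upper(stringr::str_trim(dplyr::coalesce(x, "")))
  dplyr::case_when(
    x == "PS" ~ "primary-suspect",
    x == "SS" ~ "secondary-suspect",
    x == "C"  ~ "concomitant",
    x == "I"  ~ "interacting",
    .default = NA_character_
  )
}

decode_outcome <- function(x) {
  x <- stringr::str_to_upper(stringr::str_trim(dplyr::coalesce(x, "")))
  dplyr::case_when(
    x == "DE" ~ "death",
    x == "LT" ~ "life-threatening",
    x == "HO" ~ "hospitalization",
    x == "DS" ~ "disability",
    x == "CA" ~ "congenital-anomaly",
    x == "RI" ~ "required-intervention",
    x == "OT" ~ "other-serious",
    .default = NA_character_
  )
}
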
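#' Flat single-file TSV dialect
#'
#' A compact one-row-per-report serialization used for cleaned analysis
#' sets and small fixtures: drug entries are packed as
#' `name_raw:ingredient:role:start:end` joined by `|`, reactions and
#' outcomes as `|`-joined lists, dates as `YYYYMMDD`. `read_report_tsv()`
#' inverts `write_report_tsv()` field for field; provenance is not carried
#' by the file and restarts at the read stage.
#'
#' @param rs A [report_set].
#' @param path File path.
#' @return `write_report_tsv()` returns `path` invisibly;
#'   `read_report_tsv()` returns a [report_set].
#' @export
write_report_tsv <- function(rs, path) {
  stopifnot(is_report_set(rs))
  flat <- as_tibble(rs) |>
    dplyr::mutate(version_date = pack_date(.data$version_date),
                  event_date = pack_date(.data$event_date))
  readr::write_tsv(flat, path, na = "")
  invisible(path)
}

#' @rdname write_report_tsv
#' @export
read_report_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  flat <- readr::read_tsv(path, col_types = readr::cols(
    report_id = "c", case_id = "c", version_date = "c", event_date = "c",
    report_year = "i", age_years = "d", sex = "c", weight_kg = "d",
    country = "c", drugs = "c", reactions = "c", outcomes = "c"
  ), na = "", progress = FALSE)

  unpack <- function(col, fn) {
    parts <- stringr::str_split(dplyr::coalesce(col, ""), stringr::fixed("|"))
    tibble(report_id = rep(flat$report_id, lengths(parts)),
           item = unlist(parts)) |>
      dplyr::filter(.data$item != "") |>
      fn()
  }
  drugs <- unpack(flat$drugs, function(tbl) {
    f <- stringr::str_split_fixed(tbl$item, stringr::fixed(":"), 5)
    tibble(report_id = tbl$report_id,
           name_raw = f[, 1],
           ingredient = dplyr::na_if(f[, 2], ""),
           role = f[, 3],
           therapy_start = faers_date(f[, 4]),
           therapy_end = faers_date(f[, 5]))
  })
  reactions <- unpack(flat$reactions, function(tbl) {
    tibble(report_id = tbl$report_id, pt = tbl$item)
  })
  outcomes <- unpack(flat$outcomes, function(tbl) {
    tibble(report_id = tbl$report_id, outcome = tbl$item)
  })

  reports <- flat |>
    dplyr::mutate(version_date = faers_date(.data$version_date),
                  event_date = faers_date(.data$event_date),
                  country = dplyr::coalesce(.data$country, "")) |>
    dplyr::select(-"drugs", -"reactions", -"outcomes")
  rs <- report_set(reports, drugs, reactions, outcomes)
  add_provenance(rs, "read_report_tsv", basename(path))
}
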
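test_that("header-only quarter files parse to an empty set with zero raw count", {
  paths <- write_empty_quarter(withr::local_tempdir())
  rs <- read_fixture_quarter(paths)
  expect_equal(n_reports(rs), 0)
  prov <- provenance(rs)
  expect_equal(prov$n_reports[prov$stage == "raw_demo_rows"], 0L)
})

test_that("quarter fixture parses with join failures counted, not dropped silently", {
  paths <- write_quarter_fixture(withr::local_tempdir())
  rs <- read_fixture_quarter(paths)
  # 12 DEMO rows, 3 without any REAC row -> 9 reports survive the join
  expect_equal(n_reports(rs), 9)
  prov <- provenance(rs)
  expect_equal(prov$n_reports[prov$stage == "raw_demo_rows"], 12L)
  expect_equal(prov$n_dropped[prov$stage == "parsed"], 3L)
  expect_match(prov$note[prov$stage == "parsed"], "3 join failures")
})

test_that("parsing preserves implausible values and resolves partial dates", {
  paths <- write_quarter_fixture(withr::local_tempdir())
  rs <- read_fixture_quarter(paths)
  rep <- rs$reports
  # age 121 parses as-is; plausibility filtering is a later stage
  expect_equal(rep$age_years[rep$report_id == "R01"], 121)
  # YYYYMM -> first of month; YYYY -> July 1
  expect_equal(rep$version_date[rep$report_id == "R02"], as.Date("2020-06-01"))
  expect_equal(rep$event_date[rep$report_id == "R03"], as.Date("2019-07-01"))
  # report_year is derived from the version date
  expect_equal(rep$report_year[rep$report_id == "R02"], 2020L)
  # THER partial date joined onto the drug entry
  r03 <- rs$drugs[rs$drugs$report_id == "R03", ]
  expect_equal(r03$therapy_start, as.Date("2019-02-01"))
  # sex code UNK and absent weight survive as unknown / NA
  expect_equal(rep$sex[rep$report_id == "R07"], "unknown")
  expect_true(is.na(rep$weight_kg[rep$report_id == "R08"]))
  # a report with no OUTC rows carries the explicit missing category
  expect_equal(rs$outcomes$outcome[rs$outcomes$report_id == "R05"], "missing")
})

test_that("malformed data lines are skipped and counted", {
  dir <- withr::local_tempdir()
  paths <- write_quarter_fixture(dir)
  # append a DEMO line with too many fields
  cat("RBAD$CX$20200101$$50$F$70$US$EXTRA$EXTRA2\n",
      file = paths$demo, append = TRUE)
  rs <- read_fixture_quarter(paths)
  expect_equal(n_reports(rs), 9)
  expect_match(provenance(rs)$note[2], "1 malformed")
})

test_that("drug name normalization maps brands, strips salts, and is idempotent", {
  ids <- c("A", "B", "C")
  rs <- mk_rs(tibble::tibble(report_id = ids),
              drugs = tibble::tibble(
                report_id = ids,
                name_raw = c("Lipitor", "  atorvastatin calcium ",
                             "TIOTROPIUM BROMIDE MONOHYDRATE"),
                ingredient = NA_character_))
  map <- tibble::tibble(brand = "LIPITOR", ingredient = "ATORVASTATIN")
  out <- normalize_drug_names(rs, map)
  expect_equal(out$drugs$ingredient[1], "ATORVASTATIN")
  # empty map: cleanup alone consolidates case, whitespace and salt suffix
  out2 <- normalize_drug_names(rs, NULL)
  expect_equal(out2$drugs$ingredient[2], "ATORVASTATIN")
  # stacked salt words are stripped from the end
  expect_equal(out2$drugs$ingredient[3], "TIOTROPIUM")
  # idempotence: renormalizing changes nothing
  twice <- normalize_drug_names(out, map)
  expect_equal(twice$drugs, out$drugs)
})

test_that("deduplication keeps the latest case version with report_id tie-break", {
  distinct <- mk_rs(tibble::tibble(report_id = c("A", "B", "C")))
  expect_equal(dedup_reports(distinct)$reports$report_id, c("A", "B", "C"))

  versions <- mk_rs(tibble::tibble(
    report_id = c("V1", "V2"),
    case_id = c("C1", "C1"),
    version_date = as.Date(c("2020-01-01", "2021-06-01"))
  ))
  expect_equal(dedup_reports(versions)$reports$report_id, "V2")

  tie <- mk_rs(tibble::tibble(
    report_id = c("100A", "100B"),
    case_id = c("C1", "C1"),
    version_date = as.Date(c("2020-01-01", "2020-01-01"))
  ))
  expect_equal(dedup_reports(tie)$reports$report_id, "100B")

  # idempotence
  once <- dedup_reports(versions)
  again <- dedup_reports(once)
  expect_equal(again$reports, once$reports)
})

test_that("event filtering matches PTs case-insensitively and partitions the set", {
  rs <- mk_ten_report_set()
  events <- filter_event_reports(rs, "CATARACT")
  expect_equal(n_reports(events), 4)
  # "Cataract" in data matches "cataract" as a term
  expect_equal(n_reports(filter_event_reports(rs, "cataract")), 4)
  # a term with no hits yields a legal empty result
  none <- filter_event_reports(rs, "CATARACT SUBCAPSULAR")
  expect_equal(n_reports(none), 0)
  # empty term set is a configuration error
  expect_error(filter_event_reports(rs, character(0)), "non-empty")
  # event + complement partition the input
  non_events <- filter_event_reports(rs, "CATARACT", keep = "non-event")
  expect_setequal(c(events$reports$report_id, non_events$reports$report_id),
                  rs$reports$report_id)
  expect_length(intersect(events$reports$report_id,
                          non_events$reports$report_id), 0)
})

test_that("primary-suspect filter drops ambiguous-role ingredients and empty reports", {
  ids <- c("R1", "R2", "R3")
  rs <- mk_rs(
    tibble::tibble(report_id = ids),
    drugs = tibble::tibble(
      report_id = c("R1", "R2", "R2", "R3", "R3"),
      name_raw = c("X", "X", "X", "X", "Y"),
      role = c("primary-suspect",
               "primary-suspect", "concomitant",      # same drug, two roles
               "primary-suspect", "concomitant")
    )
  )
  rs <- normalize_drug_names(rs)
  out <- filter_primary_suspect(rs)
  # R1: X retained; R2: X ambiguous -> report dropped; R3: X kept, Y not analysed
  expect_setequal(out$reports$report_id, c("R1", "R3"))
  expect_equal(out$drugs$ingredient[out$drugs$report_id == "R3"], "X")
  expect_true(all(out$drugs$role == "primary-suspect"))
})

test_that("demographic filters respect inclusive boundaries and completeness", {
  rs <- mk_rs(tibble::tibble(
    report_id = sprintf("R%d", 1:6),
    age_years = c(121, 120, 60, 60, 60, NA),
    weight_kg = c(70, 70, 400.0, 400.1, 70, 70),
    sex = c("female", "female", "male", "male", "unknown", "female")
  ))
  out <- filter_demographics(rs)
  expect_setequal(out$reports$report_id, c("R2", "R3"))
})

test_that("the cleaning cascade is monotone with provenance matching actual sizes", {
  sim <- simulate_reports(sim_config(n_reports = 3000, seed = 5))
  cl <- clean_reports(sim$reports)
  prov <- provenance(cl)
  expect_true(all(diff(prov$n_reports) <= 0))
  expect_equal(prov$n_reports[nrow(prov)], n_reports(cl))
  # each recorded count equals the size after that stage: replay stepwise
  step1 <- normalize_drug_names(sim$reports)
  step2 <- dedup_reports(step1)
  step3 <- filter_primary_suspect(step2)
  step4 <- filter_demographics(step3)
  expect_equal(prov$n_reports,
               c(n_reports(sim$reports), n_reports(step1), n_reports(step2),
                 n_reports(step3), n_reports(step4)))
})

test_that("flat TSV dialect round-trips a report set field for field", {
  sim <- simulate_reports(sim_config(n_reports = 150, seed = 9))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report_tsv(sim$reports, path)
  back <- read_report_tsv(path)
  srt <- function(rs) {
    lapply(rs[c("reports", "drugs", "reactions", "outcomes")],
           function(tb) as.data.frame(dplyr::arrange(tb, report_id)))
  }
  expect_equal(srt(back), srt(sim$reports))
})
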
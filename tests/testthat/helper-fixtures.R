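# In-code fixture builders shared across the suite.

# Build a report_set from compact per-report specs; unspecified fields get
# sensible defaults (complete demographics, one PS drug, one reaction).
mk_rs <- function(reports, drugs = NULL, reactions = NULL, outcomes = NULL) {
  reports <- tibble::as_tibble(reports)
  n <- nrow(reports)
  defaults <- list(
    case_id = reports$report_id,
    version_date = as.Date("2020-01-01"),
    event_date = as.Date(NA),
    report_year = 2020L,
    age_years = 60,
    sex = "female",
    weight_kg = 70,
    country = "US"
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(reports)) reports[[nm]] <- defaults[[nm]]
  }
  if (is.null(drugs)) {
    drugs <- tibble::tibble(report_id = reports$report_id, name_raw = "DRUGA")
  }
  drugs <- tibble::as_tibble(drugs)
  ddef <- list(ingredient = NA, role = "primary-suspect",
               therapy_start = as.Date("2019-01-01"),
               therapy_end = as.Date(NA))
  if (!"ingredient" %in% names(drugs)) drugs$ingredient <- drugs$name_raw
  for (nm in setdiff(names(ddef), "ingredient")) {
    if (!nm %in% names(drugs)) drugs[[nm]] <- ddef[[nm]]
  }
  if (is.null(reactions)) {
    reactions <- tibble::tibble(report_id = reports$report_id, pt = "CATARACT")
  }
  if (is.null(outcomes)) {
    outcomes <- tibble::tibble(report_id = reports$report_id, outcome = "missing")
  }
  report_set(reports, tibble::as_tibble(drugs), tibble::as_tibble(reactions),
             tibble::as_tibble(outcomes))
}

# A 10-report set: 4 cataract reports (E1-E4), 6 others; drug X is primary
# suspect of 3 event and 2 non-event reports.
mk_ten_report_set <- function() {
  ids <- sprintf("R%02d", 1:10)
  pts <- c(rep("CATARACT", 4), rep("NAUSEA", 6))
  drug <- c("X", "X", "X", "Y", "X", "X", "Y", "Y", "Y", "Y")
  mk_rs(
    tibble::tibble(report_id = ids),
    drugs = tibble::tibble(report_id = ids, name_raw = drug),
    reactions = tibble::tibble(report_id = ids, pt = pts)
  )
}

# Write the 12-report raw quarterly fixture: 12 DEMO rows, 3 of which
# (R10-R12) have no REAC row and must fail the join.
write_quarter_fixture <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  demo <- c(
    "primaryid$caseid$fda_dt$event_dt$age$sex$wt$occr_country",
    "R01$C01$20200115$20200110$121$F$70$US",     # implausible age kept at parse
    "R02$C02$202006$$63$M$81$US",                # partial fda_dt -> 2020-06-01
    "R03$C03$20210301$2019$55$F$66$US",          # partial event_dt -> 2019-07-01
    "R04$C04$20190820$20190801$71$F$70.5$US",
    "R05$C05$20181130$$45$M$90$CA",
    "R06$C06$20220505$20220420$80$F$58$US",
    "R07$C07$20150612$$67$UNK$77$US",
    "R08$C08$20170922$20170901$59$M$$US",        # missing weight
    "R09$C09$20230214$20230201$62$F$64$GB",
    "R10$C10$20200101$$50$F$70$US",
    "R11$C11$20200102$$51$M$71$US",
    "R12$C12$20200103$$52$F$72$US"
  )
  drug <- c(
    "primaryid$drug_seq$role_cod$drugname",
    "R01$1$PS$Alendronic Acid",
    "R02$1$PS$LIPITOR",
    "R03$1$PS$atorvastatin calcium",
    "R04$1$PS$IBRUTINIB",
    "R04$2$C$PREDNISONE",
    "R05$1$PS$TIOTROPIUM BROMIDE",
    "R06$1$PS$UPADACITINIB",
    "R07$1$PS$ADALIMUMAB",
    "R08$1$PS$POMALIDOMIDE",
    "R09$1$PS$LENALIDOMIDE",
    "R10$1$PS$ESOMEPRAZOLE",
    "R11$1$PS$BIMATOPROST",
    "R12$1$PS$RISANKIZUMAB"
  )
  reac <- c(
    "primaryid$pt",
    "R01$Cataract",
    "R02$CATARACT",
    "R03$CATARACT",
    "R04$CATARACT",
    "R05$NAUSEA",
    "R06$HEADACHE",
    "R07$RASH",
    "R08$FATIGUE",
    "R09$DIZZINESS"
  )
  outc <- c(
    "primaryid$outc_cod",
    "R01$DE",
    "R01$OT",
    "R02$HO",
    "R03$OT",
    "R04$LT",
    "R06$DS",
    "R07$OT"
  )
  ther <- c(
    "primaryid$dsg_drug_seq$start_dt$end_dt",
    "R01$1$20190601$20191201",
    "R02$1$20200301$",
    "R03$1$201902$",
    "R04$1$20190501$20190715"
  )
  paths <- file.path(dir, c("demo.txt", "drug.txt", "reac.txt",
                            "outc.txt", "ther.txt"))
  writeLines(demo, paths[1]); writeLines(drug, paths[2])
  writeLines(reac, paths[3]); writeLines(outc, paths[4])
  writeLines(ther, paths[5])
  stats::setNames(as.list(paths), c("demo", "drug", "reac", "outc", "ther"))
}

# Header-only files for the empty-input case.
write_empty_quarter <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  headers <- list(
    demo = "primaryid$caseid$fda_dt$event_dt$age$sex$wt$occr_country",
    drug = "primaryid$drug_seq$role_cod$drugname",
    reac = "primaryid$pt",
    outc = "primaryid$outc_cod",
    ther = "primaryid$dsg_drug_seq$start_dt$end_dt"
  )
  paths <- lapply(names(headers), function(nm) {
    p <- file.path(dir, paste0(nm, ".txt"))
    writeLines(headers[[nm]], p)
    p
  })
  stats::setNames(paths, names(headers))
}

read_fixture_quarter <- function(paths) {
  read_faers_quarter(paths$demo, paths$drug, paths$reac, paths$outc,
                     paths$ther)
}

# Design tibble built directly (bypassing report_set) for model fixtures.
mk_dm <- function(x_drugs, demog = NULL, event) {
  n <- length(event)
  dm <- tibble::tibble(report_id = sprintf("R%05d", seq_len(n)),
                       event = event)
  drug_cols <- character(0)
  demog_cols <- character(0)
  if (!is.null(x_drugs) && ncol(as.data.frame(x_drugs)) > 0) {
    dm <- dplyr::bind_cols(dm, tibble::as_tibble(x_drugs))
    drug_cols <- names(tibble::as_tibble(x_drugs))
  }
  if (!is.null(demog) && ncol(as.data.frame(demog)) > 0) {
    dm <- dplyr::bind_cols(dm, tibble::as_tibble(demog))
    demog_cols <- names(tibble::as_tibble(demog))
  }
  attr(dm, "drug_cols") <- drug_cols
  attr(dm, "demog_cols") <- demog_cols
  dm
}

# A seeded logistic design fixture: n rows, 5 binary drug exposures plus
# age/weight/sex, outcome drawn from a known coefficient vector. Effects
# are moderate and exposure dense so the likelihood is well conditioned
# (no separation, small lambda_max) — the regime in which the penalized
# path demonstrably reaches the maximum-likelihood fit.
mk_logistic_fixture <- function(n = 500, seed = 42) {
  set.seed(seed)
  drugs <- stats::setNames(
    as.data.frame(matrix(rbinom(n * 5, 1, 0.25), ncol = 5)),
    paste0("D", 1:5))
  demog <- data.frame(
    age_years = round(rnorm(n, 65, 12)),
    weight_kg = round(rnorm(n, 72, 20), 1),
    sex_female = rbinom(n, 1, 0.7)
  )
  beta <- log(c(1.3, 1.25, 1.2, 1, 1.35))
  lp <- -0.9 + as.matrix(drugs) %*% beta +
    0.01 * (demog$age_years - 65) + 0.1 * demog$sex_female
  event <- rbinom(n, 1, plogis(as.vector(lp)))
  mk_dm(drugs, demog, event)
}
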
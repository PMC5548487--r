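test_that("fixture quarter parses with correct enums and orphan handling", {
  co <- fixture_quarter_corpus()
  expect_s3_class(co, "faers_corpus")
  expect_equal(n_reports(co), 3L)
  expect_setequal(co$reports$report_id, c("1001", "1002", "1003"))
  # occupation code mapping, incl. LW -> lawyer
  occ <- setNames(co$reports$occupation, co$reports$report_id)
  expect_equal(occ[["1001"]], "physician")
  expect_equal(occ[["1002"]], "lawyer")
  expect_equal(occ[["1003"]], "consumer")
  # roles and outcome codes
  expect_setequal(co$drugs[co$drugs$report_id == "1001", role], c("PS", "C"))
  expect_setequal(co$outcomes[co$outcomes$report_id == "1002", outcome],
                  c("Death", "Hospitalization"))
  # both date syntaxes parsed
  expect_equal(co$reports[co$reports$report_id == "1002", event_date],
               as.Date("2004-05-11"))
  # orphan REAC row (report 9999) dropped and counted
  expect_equal(unname(co$provenance$rows_dropped[["reac"]]), 1L)
  expect_false("9999" %in% co$reactions$report_id)
  # conservation: rows kept + rows dropped = rows in
  expect_equal(co$provenance$rows_kept[["reac"]] +
                 co$provenance$rows_dropped[["reac"]],
               co$provenance$rows_in[["reac"]])
  # indication joined onto the right drug entry
  expect_equal(co$drugs[report_id == "1001" & drug_seq == 1L, indication],
               "Depression")
  expect_true(is.na(co$drugs[report_id == "1001" & drug_seq == 2L,
                             indication]))
})

test_that("parse_quarter maps unknown codes to fallbacks and errors on bad files", {
  dir <- withr::local_tempdir()
  writeLines(c("report_id$case_id$event_date$receipt_date$occupation$age$age_unit$sex",
               "1$1$2004-01-02$2004-01-05$XX$700$YR$Q"),
             file.path(dir, "demo.txt"))
  writeLines(c("report_id$drug_seq$role$verbatim_name", "1$1$ZZ$drugx"),
             file.path(dir, "drug.txt"))
  writeLines(c("report_id$reaction", "1$eventx"), file.path(dir, "reac.txt"))
  co <- parse_quarter(file.path(dir, "demo.txt"), file.path(dir, "drug.txt"),
                      file.path(dir, "reac.txt"))
  expect_equal(co$reports$occupation, "unknown")
  expect_equal(co$reports$sex, "unknown")
  expect_true(is.na(co$reports$age))       # 700 years -> missing
  expect_equal(co$drugs$role, "C")
  # missing mandatory column named in the error
  writeLines(c("report_id$case_id", "1$1"), file.path(dir, "demo_bad.txt"))
  expect_error(parse_quarter(file.path(dir, "demo_bad.txt"),
                             file.path(dir, "drug.txt"),
                             file.path(dir, "reac.txt")),
               "event_date")
})

test_that("LAERS and modern dialects parse through their column maps", {
  dir <- withr::local_tempdir()
  writeLines(c("ISR$CASE$EVENT_DT$FDA_DT$OCP_COD$AGE$AGE_COD$GNDR_COD",
               "11$C1$20040102$20040111$LW$480$MON$F"),
             file.path(dir, "demo.txt"))
  writeLines(c("ISR$DRUG_SEQ$ROLE_COD$DRUGNAME", "11$1$PS$aspirin"),
             file.path(dir, "drug.txt"))
  writeLines(c("ISR$PT", "11$Nausea"), file.path(dir, "reac.txt"))
  co <- parse_quarter(file.path(dir, "demo.txt"), file.path(dir, "drug.txt"),
                      file.path(dir, "reac.txt"), dialect = "legacy_LAERS")
  expect_equal(co$reports$occupation, "lawyer")
  expect_equal(co$reports$age, 40)          # 480 months
  writeLines(c("primaryid$caseid$event_dt$fda_dt$occp_cod$age$age_cod$sex",
               "21$C2$20130102$20130111$CN$52$YR$M"),
             file.path(dir, "demo2.txt"))
  writeLines(c("primaryid$drug_seq$role_cod$drugname", "21$1$SS$aspirin"),
             file.path(dir, "drug2.txt"))
  writeLines(c("primaryid$pt", "21$Nausea"), file.path(dir, "reac2.txt"))
  co2 <- parse_quarter(file.path(dir, "demo2.txt"),
                       file.path(dir, "drug2.txt"),
                       file.path(dir, "reac2.txt"), dialect = "FAERS_2012Q4+")
  expect_equal(co2$reports$occupation, "consumer")
  expect_equal(co2$drugs$role, "SS")
})

test_that("latest_report_per_case keeps the newest report and is idempotent", {
  co <- fixture_quarter_corpus()        # 1002 and 1003 share case C101
  one <- latest_report_per_case(co)
  expect_equal(n_reports(one), 2L)
  expect_true("1003" %in% one$reports$report_id)   # later receipt date wins
  expect_false("1002" %in% one$reports$report_id)
  expect_equal(latest_report_per_case(one)$reports, one$reports)
  # all-distinct case ids: unchanged
  expect_equal(sort(latest_report_per_case(one)$reports$report_id),
               sort(one$reports$report_id))
  # tie on receipt date: greater report_id wins
  co2 <- co
  co2$reports$receipt_date <- rep(as.Date("2004-09-01"), 3)
  co2$reports$event_date <- rep(as.Date("2004-01-01"), 3)
  one2 <- latest_report_per_case(co2)
  expect_true("1003" %in% one2$reports$report_id)
})

test_that("planted follow-ups collapse to the planted case count", {
  cfg <- null_config(n_reports = 1000, seed = 42, followup_fraction = 0.1)
  gen <- generate_faers(cfg)
  expect_equal(n_reports(gen$corpus), 1100L)
  one <- latest_report_per_case(gen$corpus)
  expect_equal(n_reports(one), 1000L)
  # the follow-up (later receipt) survives, not the original
  fu_cases <- gen$truth$followup_case_ids
  kept <- one$reports[one$reports$case_id %in% fu_cases, report_id]
  expect_true(all(startsWith(kept, "RF")))
})

test_that("write_normalized / read_normalized round-trips losslessly", {
  co <- fixture_quarter_corpus()
  dir <- withr::local_tempdir()
  write_normalized(co, dir)
  back <- read_normalized(dir)
  for (tab in c("reports", "drugs", "reactions", "outcomes")) {
    expect_equal(as.data.frame(back[[tab]]), as.data.frame(co[[tab]]),
                 ignore_attr = TRUE)
  }
  # one row per (report, drug) and per (report, reaction)
  rd <- data.table::fread(file.path(dir, "report_drugs.tsv"))
  expect_equal(nrow(rd), nrow(co$drugs))
  # mapped + standardized corpora round-trip too
  tabsyn <- read_synonym_table(system.file("extdata/synonyms.tsv",
                                           package = "faerstools"))
  voc <- read_meddra_vocabulary(system.file("extdata/vocabulary.txt",
                                            package = "faerstools"))
  co2 <- normalize_corpus(map_corpus(co, tabsyn)$corpus, voc)$corpus
  dir2 <- withr::local_tempdir()
  write_normalized(co2, dir2)
  back2 <- read_normalized(dir2)
  expect_equal(as.data.frame(back2$drugs), as.data.frame(co2$drugs),
               ignore_attr = TRUE)
  expect_equal(as.data.frame(back2$reactions), as.data.frame(co2$reactions),
               ignore_attr = TRUE)
})

test_that("empty corpus round-trips and version mismatch errors", {
  empty <- faers_corpus(
    reports = data.frame(report_id = character(), case_id = character(),
                         event_date = as.Date(character()),
                         receipt_date = as.Date(character()),
                         occupation = character(), age = numeric(),
                         sex = character()),
    drugs = data.frame(report_id = character(), drug_seq = integer(),
                       verbatim_name = character(), role = character()),
    reactions = data.frame(report_id = character(), verbatim = character()))
  dir <- withr::local_tempdir()
  write_normalized(empty, dir)
  expect_equal(n_reports(read_normalized(dir)), 0L)
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
  mf$format_version <- "99.0"
  jsonlite::write_json(mf, file.path(dir, "manifest.json"), auto_unbox = TRUE)
  expect_error(read_normalized(dir), "version mismatch")
})

test_that("corpus invariants are enforced", {
  co <- fixture_quarter_corpus()
  bad <- co
  bad$reports$age[1] <- 130
  expect_error(validate_corpus(bad), "age")
  bad2 <- co
  bad2$reports$report_id <- rep("1001", 3)
  expect_error(validate_corpus(bad2), "unique")
  bad3 <- co
  bad3$drugs <- bad3$drugs[bad3$drugs$report_id != "1001"]
  expect_error(validate_corpus(bad3), "no drug entry")
})
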
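write_faers_fixture <- function(dir, demo, drug = NULL, reac = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- list(demo = file.path(dir, "DEMO.txt"),
            drug = file.path(dir, "DRUG.txt"),
            reac = file.path(dir, "REAC.txt"))
  writeLines(demo, p$demo)
  writeLines(drug %||% c("primaryid$caseid$role_cod$drugname$start_dt"),
             p$drug)
  writeLines(reac %||% c("primaryid$caseid$pt$onset_dt"), p$reac)
  p
}

test_that("dollar-delimited tables parse by header with malformed rows skipped", {
  dir <- withr::local_tempdir()
  p <- write_faers_fixture(dir, demo = c(
    "primaryid$caseid$age$sex$fda_dt",
    "1001$100$64$F$20230101",
    "1002$101$70$M$20230102",
    "badrow$only$three",
    "1003$102$55$F$20230103"))
  expect_warning(raw <- parse_faers_quarter(p, "2023Q1"),
                 "skipped 1 malformed")
  expect_equal(nrow(raw$demo_rows), 3)
  expect_equal(raw$skipped[["demo"]], 1L)
  # fields land under lowercase header names
  expect_equal(raw$demo_rows$primaryid[1], "1001")
  expect_equal(raw$demo_rows$sex[2], "M")
})

test_that("missing required FAERS tables are fatal, empty files warn", {
  dir <- withr::local_tempdir()
  p <- write_faers_fixture(dir, demo = c("primaryid$caseid", "1$1"))
  expect_error(
    parse_faers_quarter(list(demo = p$demo, drug = p$drug), "q"),
    "REAC")
  writeLines(character(0), file.path(dir, "empty.txt"))
  expect_warning(
    parse_faers_quarter(c(p, outc = file.path(dir, "empty.txt")), "q"),
    "empty table")
})

test_that("latest case version survives deduplication", {
  dir <- withr::local_tempdir()
  p <- write_faers_fixture(dir, demo = c(
    "primaryid$caseid$sex$fda_dt",
    "1001$100$F$20230101",
    "1002$100$M$20230301",
    "2001$200$F$20230401"),
    drug = c("primaryid$caseid$role_cod$drugname$start_dt",
             "1001$100$PS$OLDDRUG$",
             "1002$100$PS$NEWDRUG$20230101",
             "2001$200$PS$OTHER$"),
    reac = c("primaryid$caseid$pt$onset_dt",
             "1001$100$headache$",
             "1002$100$myositis$",
             "2001$200$nausea$"))
  raw <- parse_faers_quarter(p, "2023Q1")
  store <- deduplicate_cases(raw)
  expect_equal(nrow(store$cases), 2)
  # case 100 keeps the 20230301 version: sex M, drug NEWDRUG
  c100 <- store$cases[store$cases$case_id == "100", ]
  expect_equal(c100$sex, "M")
  expect_equal(store$drugs$raw_name[store$drugs$case_id == "100"],
               "NEWDRUG")
  expect_equal(store$reactions$pt[store$reactions$case_id == "100"],
               "myositis")
  # conservation: survivors == distinct case ids with a demo row
  expect_equal(nrow(store$cases),
               dplyr::n_distinct(raw$demo_rows$caseid))
})

test_that("deduplication is idempotent and drops orphan child rows", {
  dir <- withr::local_tempdir()
  p <- write_faers_fixture(dir, demo = c(
    "primaryid$caseid$sex$fda_dt", "11$1$F$20230101"),
    drug = c("primaryid$caseid$role_cod$drugname$start_dt",
             "11$1$PS$DRUGA$", "99$9$PS$GHOST$"),
    reac = c("primaryid$caseid$pt$onset_dt", "11$1$myositis$"))
  raw <- parse_faers_quarter(p, "q")
  s1 <- deduplicate_cases(raw)
  expect_equal(attr(s1, "stats")[["orphan_rows"]], 1)
  expect_false("GHOST" %in% s1$drugs$raw_name)
  # dedup of an already-deduplicated database changes nothing: write the
  # deduped store back out (jader dialect writes from the store) and rerun
  sim <- simulate_reports(simulation_config(n_cases = 30,
                                            duplicate_rate = 0.2,
                                            seed = 7))
  d2 <- withr::local_tempdir()
  s2 <- deduplicate_cases(parse_jader_tables(
    write_jader_dialect(sim, d2)))
  d3 <- withr::local_tempdir()
  sim2 <- sim
  sim2$store <- s2
  s3 <- deduplicate_cases(parse_jader_tables(
    write_jader_dialect(sim2, d3)))
  expect_equal(s3$cases, s2$cases)
  expect_equal(s3$reactions, s2$reactions)
  expect_equal(s3$drugs, s2$drugs)
})

test_that("age units harmonize to years and age groups follow", {
  a <- pvsignals:::age_to_years(c("64", "720", "18", "2"),
                                c("YR", "MON", "DY", "DEC"))
  expect_equal(a, c(64, 60, 18 / 365.25, 20))
  expect_true(is.na(pvsignals:::age_to_years("50", "XX")))
  expect_equal(pvsignals:::age_group_of(c(5, 18, 64.9, 65, 84.9, 85, NA)),
               c("<18", "18-64", "18-64", "65-84", "65-84", ">85",
                 "UNK"))
})

test_that("JADER csv tables parse with quoting and encodings honored", {
  dir <- withr::local_tempdir()
  demo <- file.path(dir, "demo.csv")
  drug <- file.path(dir, "drug.csv")
  reac <- file.path(dir, "reac.csv")
  writeLines(c("case_id,sex,age,reporter,receipt_date",
               "J1,M,70,MD,20230105",
               "J2,F,55,PH,20230110",
               "J3,,,,"), demo)
  writeLines(c("case_id,role,drug_name,start_date",
               "J1,PS,\"nivolumab, injection\",20230101",
               "J2,PS,pembrolizumab,",
               "J3,PS,other,"), drug)
  writeLines(c("case_id,pt,onset_date",
               "J1,myositis,20230120", "J2,headache,", "J3,nausea,"),
             reac)
  raw <- parse_jader_tables(list(demo = demo, drug = drug, reac = reac))
  expect_equal(nrow(raw$demo_rows), 3)
  expect_equal(raw$source, "JADER")
  expect_equal(nrow(raw$outc_rows), 0)
  # quoted comma preserved inside the field
  expect_equal(raw$drug_rows$drug_name[1], "nivolumab, injection")
  store <- deduplicate_cases(raw)
  expect_equal(nrow(store$cases), 3)
  expect_equal(store$cases$country, rep("JP", 3))
  # undecodable bytes under the selected encoding are fatal
  bad <- file.path(dir, "bad.csv")
  con <- file(bad, "wb")
  writeBin(c(charToRaw("case_id,sex\nJ1,"), as.raw(c(0xff, 0xfe))), con)
  close(con)
  expect_error(
    parse_jader_tables(list(demo = bad, drug = drug, reac = reac)),
    "undecodable")
})

test_that("synthetic database round-trips through files, parse and dedup", {
  sim <- simulate_reports(simulation_config(n_cases = 50, seed = 11,
                                            duplicate_rate = 0.2))
  dir <- withr::local_tempdir()
  paths <- write_faers_dialect(sim, dir, "2024Q1")
  raw <- parse_faers_quarter(paths, "2024Q1")
  expect_equal(nrow(raw$demo_rows),
               50 + sim$truth$n_duplicates)
  store <- deduplicate_cases(raw)
  truth <- sim$store
  expect_equal(nrow(store$cases), 50)
  # field-by-field equality with the generator's ground truth
  expect_equal(store$cases$case_id, truth$cases$case_id)
  expect_equal(store$cases$sex, truth$cases$sex)
  expect_equal(store$cases$age_years, truth$cases$age_years)
  expect_equal(store$cases$receipt_int, truth$cases$receipt_int)
  got_drugs <- dplyr::arrange(store$drugs, case_id, raw_name)
  want_drugs <- dplyr::arrange(
    dplyr::mutate(truth$drugs, raw_name = toupper(raw_name)),
    case_id, raw_name)
  expect_equal(clean_drug_name(got_drugs$raw_name),
               clean_drug_name(want_drugs$raw_name))
  expect_equal(got_drugs$role, want_drugs$role)
  expect_equal(got_drugs$start_date, want_drugs$start_date)
  expect_equal(dplyr::arrange(store$reactions, case_id, pt),
               dplyr::arrange(truth$reactions, case_id, pt))
  expect_equal(dplyr::arrange(store$outcomes, case_id, code),
               dplyr::arrange(truth$outcomes, case_id, code))
})

test_that("jader dialect round-trips the store", {
  sim <- simulate_reports(simulation_config(n_cases = 20, seed = 3))
  dir <- withr::local_tempdir()
  paths <- write_jader_dialect(sim, dir)
  store <- deduplicate_cases(parse_jader_tables(paths))
  expect_equal(nrow(store$cases), 20)
  expect_equal(store$cases$sex, sim$store$cases$sex)
  expect_equal(dplyr::arrange(store$reactions, case_id, pt)$pt,
               dplyr::arrange(sim$store$reactions, case_id, pt)$pt)
  # the dialect carries no outcome table: severity all unknown downstream
  expect_true(all(case_severity(store)$severity == "UNKNOWN"))
})

test_that("store serialization round-trips with manifest", {
  sim <- simulate_reports(simulation_config(n_cases = 25, seed = 5))
  dir <- withr::local_tempdir()
  write_store(sim$store, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_store(dir)
  expect_equal(back$cases, sim$store$cases)
  expect_equal(back$reactions, sim$store$reactions)
  expect_equal(attr(back, "source"), "FAERS")
  expect_equal(glance(back)$n_cases, 25)
})
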
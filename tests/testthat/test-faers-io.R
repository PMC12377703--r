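test_that("quarter labels index, invert and sequence correctly", {
  expect_equal(quarter_index("2004Q2") - quarter_index("2004Q1"), 1L)
  expect_equal(quarter_label(quarter_index("2024Q2")), "2024Q2")
  qs <- quarter_seq("2003Q3", "2004Q2")
  expect_equal(qs, c("2003Q3", "2003Q4", "2004Q1", "2004Q2"))
  expect_error(quarter_index("2004-1"), "malformed")
})

test_that("partial dates keep their precision and invalid dates drop out", {
  p <- parse_partial_date(c("20200131", "202001", "2020", "", "20200230",
                            "garbage"))
  expect_equal(p$precision,
               c("day", "month", "year", "missing", "missing", "missing"))
  expect_equal(p$date[1:3], c("20200131", "202001", "2020"))
  expect_true(all(is.na(p$date[4:6])))
})

test_that("age and weight unit codes convert by the FAERS factor table", {
  expect_equal(convert_age("72", "YR"), 72)
  expect_equal(convert_age("6", "MON"), 0.5)
  expect_equal(convert_age("7", "DY"), 7 / 365.25)
  expect_equal(convert_age("2", "WK"), 14 / 365.25)
  expect_equal(convert_age("8766", "HR"), 1)
  expect_equal(convert_age("7.2", "DEC"), 72)
  expect_true(is.na(convert_age("abc", "YR")))
  expect_equal(convert_weight("154", "LBS"), 154 * 0.45359237)
  expect_equal(convert_weight("70", "KG"), 70)
  expect_true(is.na(convert_weight("0", "KG")))  # nonpositive -> missing
})

test_that("a well-formed quarter parses one typed row per input line", {
  dir <- ten_report_fixture()
  d <- parse_faers_quarter(
    file.path(dir, "DEMO2015Q1.txt"), file.path(dir, "DRUG2015Q1.txt"),
    file.path(dir, "REAC2015Q1.txt"), file.path(dir, "THER2015Q1.txt"),
    file.path(dir, "INDI2015Q1.txt"), quarter = "2015Q1"
  )
  expect_s3_class(d, "faers_data")
  expect_equal(nrow(d$reports), 10)
  expect_equal(d$reports$age_years[1], 72)
  expect_equal(d$reports$sex[1:2], c("female", "male"))
  expect_equal(d$reports$occupation[c(1, 4, 5, 6, 7, 8, 10)],
               c("physician", "pharmacist", "other-health-professional",
                 "other-health-professional", "consumer", "lawyer",
                 "unknown"))
  # indication joined onto the drug table by (primaryid, seq)
  hit <- d$drugs$primaryid == 1091 & d$drugs$seq == 1
  expect_equal(d$drugs$indication_pt[hit], "Pulmonary edema")
})

test_that("missing mandatory columns and empty files are handled as specified", {
  dir <- withr::local_tempdir()
  writeLines(c("primaryid$caseid", "1$1"), file.path(dir, "DEMObad.txt"))
  expect_error(
    read_dollar_table(file.path(dir, "DEMObad.txt"),
                      faers_dialect()$demo$required),
    "event_dt"
  )
  writeLines(character(0), file.path(dir, "empty.txt"))
  expect_warning(
    out <- read_dollar_table(file.path(dir, "empty.txt"), c("primaryid")),
    "empty"
  )
  expect_equal(nrow(out), 0)
})

test_that("deduplication keeps the highest primaryid per case and is idempotent", {
  reports <- data.frame(
    primaryid = c(71, 72, 80), caseid = c(7, 7, 8),
    quarter = c("2020Q1", "2020Q2", "2020Q1"),
    occupation = "physician", age_years = 50, sex = "male",
    weight_kg = 70, event_date = NA_character_,
    event_precision = "missing", report_year = 2020L,
    stringsAsFactors = FALSE
  )
  drugs <- data.frame(primaryid = c(71, 72, 80), seq = 1L, name = "X",
                      role = "PS", indication_pt = NA_character_)
  d <- faers_data(reports, drugs,
                  data.frame(primaryid = numeric(0), pt = character(0),
                             pt_code = integer(0)),
                  data.frame(primaryid = numeric(0), drug_seq = integer(0),
                             start_date = character(0),
                             start_precision = character(0)))
  d1 <- deduplicate_reports(d)
  expect_equal(sort(d1$reports$primaryid), c(72, 80))
  expect_false(71 %in% d1$drugs$primaryid)  # children dropped too
  d2 <- deduplicate_reports(d1)
  expect_equal(d2$reports, d1$reports)
})

test_that("n cases with k versions each collapse to exactly n survivors", {
  n <- 25; k <- 3
  reports <- data.frame(
    primaryid = as.numeric(outer(seq_len(k), (1:n) * 10, `+`)),
    caseid = rep(1:n, each = k), quarter = "2010Q1",
    occupation = "physician", age_years = 40, sex = "female",
    weight_kg = 60, event_date = NA_character_,
    event_precision = "missing", report_year = 2010L,
    stringsAsFactors = FALSE
  )
  empty_drugs <- data.frame(primaryid = numeric(0), seq = integer(0),
                            name = character(0), role = character(0),
                            indication_pt = character(0))
  d <- faers_data(reports, empty_drugs,
                  data.frame(primaryid = numeric(0), pt = character(0),
                             pt_code = integer(0)),
                  data.frame(primaryid = numeric(0), drug_seq = integer(0),
                             start_date = character(0),
                             start_precision = character(0)))
  dd <- deduplicate_reports(d)
  expect_equal(nrow(dd$reports), n)
  expect_equal(sort(dd$reports$primaryid), as.numeric((1:n) * 10 + k))
})

test_that("reporter and indication filters retain the hand-enumerated sets", {
  dir <- ten_report_fixture()
  raw <- read_faers(dir)
  d <- deduplicate_reports(raw)

  hp <- filter_reporters(d)
  expect_equal(sort(hp$reports$caseid), c(101:106, 109))

  all_occ <- filter_reporters(d, allowed = unique(d$reports$occupation))
  expect_equal(nrow(all_occ$reports), 10)  # allow-all is the identity

  noex <- exclude_preexisting_event(hp, "Pulmonary Edema")
  expect_equal(sort(noex$reports$caseid), 101:106)
  # target PT as reaction only (not indication) is retained
  expect_true(101 %in% noex$reports$caseid)

  expect_warning(none <- filter_reporters(d, allowed = "astronaut"),
                 "removed every report")
  expect_equal(nrow(none$reports), 0)
})

test_that("reporter and indication filters commute", {
  dir <- ten_report_fixture()
  d <- deduplicate_reports(read_faers(dir))
  ab <- exclude_preexisting_event(filter_reporters(d), "Pulmonary Edema")
  ba <- filter_reporters(exclude_preexisting_event(d, "Pulmonary Edema"))
  expect_equal(ab$reports, ba$reports)
  expect_equal(ab$drugs, ba$drugs)
})

test_that("referential integrity holds after every filter", {
  g <- generate_faers(paper_shaped_scenario(3000, seed = 5))
  d <- clean_faers(g$data)
  ids <- d$reports$primaryid
  expect_true(all(d$drugs$primaryid %in% ids))
  expect_true(all(d$reactions$primaryid %in% ids))
  expect_true(all(d$therapies$primaryid %in% ids))
  expect_false(any(duplicated(d$reports$caseid)))
})

test_that("drug names normalize and map through the synonym table", {
  expect_equal(normalize_drug_name("  dasatinib "), "DASATINIB")
  expect_equal(normalize_drug_name("a   b\tc"), "A B C")
  expect_equal(normalize_drug_name("SPRYCEL", c(SPRYCEL = "DASATINIB")),
               "DASATINIB")
  expect_equal(normalize_drug_name("XYZ-123", c(SPRYCEL = "DASATINIB")),
               "XYZ-123")
})

test_that("writing a cleaned dataset and re-parsing reproduces it field for field", {
  g <- generate_faers(paper_shaped_scenario(1500, seed = 9))
  d <- clean_faers(g$data)
  dir <- withr::local_tempdir()
  write_faers_quarter(d, dir)
  d2 <- clean_faers(read_faers(dir))
  ord <- function(x) {
    x <- x[order(x$primaryid), , drop = FALSE]
    rownames(x) <- NULL
    x
  }
  expect_equal(ord(d2$reports), ord(d$reports), tolerance = 1e-12)
  okey <- function(x) {
    x <- x[do.call(order, x), , drop = FALSE]
    rownames(x) <- NULL
    x
  }
  expect_equal(okey(d2$drugs), okey(d$drugs))
  expect_equal(okey(d2$reactions), okey(d$reactions))
  expect_equal(okey(d2$therapies), okey(d$therapies))
})

test_that("the quarter window is inclusive on both ends", {
  g <- generate_faers(sim_config(
    n_reports = 400, quarter_range = c("2010Q1", "2010Q4"),
    drug_catalog = data.frame(name = "X", prob = 1), seed = 2
  ))
  d <- filter_quarter_window(g$data, "2010Q1", "2010Q4")
  expect_equal(nrow(d$reports), nrow(g$data$reports))
  d2 <- filter_quarter_window(g$data, "2010Q2", "2010Q3")
  expect_true(all(d2$reports$quarter %in% c("2010Q2", "2010Q3")))
  expect_lt(nrow(d2$reports), nrow(d$reports))
})
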
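test_that("target-drug selection counts PS-role cases once per report", {
  dir <- ten_report_fixture()
  d <- clean_faers(read_faers(dir))
  # cleaned set: cases 101-106; DRUGX is PS with the event on 101-104,
  # role C on 105; DRUGY is PS with the event on 105-106
  t1 <- select_target_drugs(d, "Pulmonary Edema", min_cases = 1)
  expect_equal(t1$drug, c("DRUGX", "DRUGY"))
  expect_equal(t1$cases, c(4L, 2L))
  t3 <- select_target_drugs(d, "Pulmonary Edema", min_cases = 3)
  expect_equal(t3$drug, "DRUGX")
  expect_equal(nrow(select_target_drugs(d, "Pulmonary Edema", 10)), 0)
})

test_that("contingency tables partition all reports", {
  dir <- ten_report_fixture()
  d <- clean_faers(read_faers(dir))
  tx <- build_table(d, "DRUGX", "Pulmonary Edema")
  ty <- build_table(d, "DRUGY", "Pulmonary Edema")
  expect_equal(with(tx, a + b + c + d), nrow(d$reports))
  expect_equal(with(tx, a + b + c + d), with(ty, a + b + c + d))
  expect_equal(tx$a, 4L)   # PS role only: case 105 (role C) not exposed
  expect_equal(tx$b, 0L)
  expect_equal(ty$a, 2L)
  miss <- build_table(d, "ABSENT", "Pulmonary Edema")
  expect_equal(miss$a + miss$b, 0L)
  one <- faers_data(
    data.frame(primaryid = 1, caseid = 1, quarter = "2020Q1",
               occupation = "physician", age_years = 50, sex = "male",
               weight_kg = 70, event_date = NA_character_,
               event_precision = "missing", report_year = 2020L),
    data.frame(primaryid = 1, seq = 1L, name = "X", role = "PS",
               indication_pt = NA_character_),
    data.frame(primaryid = 1, pt = "Pulmonary Edema", pt_code = 10037375L),
    data.frame(primaryid = numeric(0), drug_seq = integer(0),
               start_date = character(0), start_precision = character(0))
  )
  expect_equal(unlist(build_table(one, "X", "Pulmonary Edema")[c("a", "b", "c", "d")]),
               c(a = 1L, b = 0L, c = 0L, d = 0L))
})

test_that("ROR matches hand arithmetic, with Haldane-Anscombe zero-cell policy", {
  r <- ror_stat(10, 90, 100, 9800)
  expect_equal(r$ror, (10 * 9800) / (90 * 100), tolerance = 1e-12)
  se <- sqrt(1 / 10 + 1 / 90 + 1 / 100 + 1 / 9800)
  expect_equal(r$ror_lo95, exp(log(r$ror) - 1.96 * se), tolerance = 1e-12)
  expect_equal(round(r$ror_lo95, 2), 5.50)
  expect_equal(round(r$ror_hi95, 2), 21.54)
  expect_false(r$corrected)

  ind <- ror_stat(5, 50, 50, 500)  # a/b = c/d: independence
  expect_equal(ind$ror, 1)

  z <- ror_stat(0, 100, 100, 9800)
  expect_true(z$corrected)
  expect_equal(z$ror, (0.5 * 9800.5) / (100.5 * 100.5), tolerance = 1e-12)

  und <- ror_stat(0, 0, 5, 10)  # empty drug margin: undefined
  expect_false(und$defined)
  expect_true(is.na(und$ror))
})

test_that("PRR and Yates chi-square match hand arithmetic and chisq.test", {
  p <- prr_stat(10, 90, 100, 9800)
  expect_equal(p$prr, 0.1 / (100 / 9900), tolerance = 1e-12)
  expect_equal(p$prr, 9.9, tolerance = 1e-12)
  for (tab in list(c(20, 80, 100, 9800), c(10, 90, 100, 9800),
                   c(3, 5, 7, 11), c(1, 1, 40, 40))) {
    ours <- prr_stat(tab[1], tab[2], tab[3], tab[4])$chi2
    ref <- suppressWarnings(
      stats::chisq.test(matrix(tab, 2, 2, byrow = TRUE), correct = TRUE)
    )$statistic
    expect_equal(ours, unname(ref), tolerance = 1e-10)
  }
  ind <- prr_stat(5, 50, 50, 500)
  expect_equal(ind$prr, 1)
  expect_lt(ind$chi2, 1e-10)  # Yates floor at independence
})

test_that("information component follows the closed-form shrinkage formulas", {
  # a equal to its expectation gives IC exactly 0
  e <- bcpnn_ic(50, 50, 50, 50)  # E = 100*100/200 = 50 = a
  expect_equal(e$ic, 0)

  v <- bcpnn_ic(10, 90, 100, 9800)
  expect_equal(v$expected, 100 * 110 / 10000)
  expect_equal(v$ic, log2(10.5 / 1.6), tolerance = 1e-12)
  expect_equal(round(v$ic, 3), 2.714)
  expect_equal(v$ic025,
               v$ic - 3.3 * 10.5^-0.5 - 2 * 10.5^-1.5, tolerance = 1e-12)

  z <- bcpnn_ic(0, 0, 0, 0)
  expect_equal(z$ic, 0)
  expect_equal(z$ic025, -3.3 / sqrt(0.5) - 2 / 0.5^1.5, tolerance = 1e-12)
  expect_equal(round(z$ic025, 2), -10.32)
})

test_that("all four statistics increase strictly in a with b, c, d fixed", {
  pr <- test_prior()
  a <- 1:30
  ror <- ror_stat(a, 50, 60, 5000)$ror
  prr <- prr_stat(a, 50, 60, 5000)$prr
  ic <- bcpnn_ic(a, 50, 60, 5000)$ic
  e <- bcpnn_ic(a, 50, 60, 5000)$expected
  eb <- ebgm_stat(a, e, pr)$ebgm
  expect_true(all(diff(ror) > 0))
  expect_true(all(diff(prr) > 0))
  expect_true(all(diff(ic) > 0))
  expect_true(all(diff(eb) > 0))
})

test_that("signal calling is a strict conjunction with undefined propagation", {
  df <- data.frame(a = c(20, 20, 20, 0), ror_lo95 = c(2, 2, 2, NA),
                   prr = c(3, 3, 1, 3), chi2 = c(10, 10, 10, 10),
                   ic025 = c(0.5, 0.5, 0.5, 0.5),
                   eb05 = c(3, 1.5, 3, 3))
  fl <- call_signals(df)
  expect_equal(fl$consensus, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(fl$reason[4], "undefined_statistic")
  # independence table: every method silent
  ind <- cbind(data.frame(a = 5), ror_stat(5, 50, 50, 500)[-1],
               prr_stat(5, 50, 50, 500), bcpnn_ic(5, 50, 50, 500),
               ebgm_stat(5, bcpnn_ic(5, 50, 50, 500)$expected,
                         test_prior()))
  f2 <- call_signals(ind)
  expect_false(any(f2$flag_ror, f2$flag_prr, f2$flag_bcpnn, f2$flag_ebgm))
  # thresholds configurable
  f3 <- call_signals(df[1, ], thresholds = list(eb05_gt = 5))
  expect_false(f3$consensus)
})

test_that("exhaustively enumerated small tables match independent formula oracles", {
  # all four margins <= 12 here (the acceptance suite extends to 30)
  m <- 12
  g <- expand.grid(a = 0:m, b = 0:m, c = 0:m, d = 0:m)
  g <- g[g$a + g$b <= m & g$c + g$d <= m & g$a + g$c <= m & g$b + g$d <= m &
           g$a + g$b + g$c + g$d > 0, ]
  r <- ror_stat(g$a, g$b, g$c, g$d)
  p <- prr_stat(g$a, g$b, g$c, g$d)
  ic <- bcpnn_ic(g$a, g$b, g$c, g$d)
  # oracle: direct textbook coding, written independently of the package
  ha <- ifelse(g$a == 0 | g$b == 0 | g$c == 0 | g$d == 0, 0.5, 0)
  oa <- g$a + ha; ob <- g$b + ha; oc <- g$c + ha; od <- g$d + ha
  o_ror <- exp(log(oa) + log(od) - log(ob) - log(oc))
  def <- (g$a + g$b) > 0 & (g$c + g$d) > 0
  expect_equal(r$ror[def], o_ror[def], tolerance = 1e-10)
  o_prr <- (oa / (oa + ob)) / (oc / (oc + od))
  expect_equal(p$prr[def], o_prr[def], tolerance = 1e-10)
  n <- g$a + g$b + g$c + g$d
  ee <- (g$a + g$b) * (g$a + g$c) / n
  expect_equal(ic$ic, log2((g$a + 0.5) / (ee + 0.5)), tolerance = 1e-10)
  # chi-square oracle: per-cell Yates sum with clamped correction
  chi_oracle <- mapply(function(a, b, c, d) {
    n <- a + b + c + d
    obs <- c(a, b, c, d)
    exp_ <- c((a + b) * (a + c), (a + b) * (b + d),
              (c + d) * (a + c), (c + d) * (b + d)) / n
    if (any(exp_ == 0)) return(0)
    sum(pmax(abs(obs - exp_) - 0.5, 0)^2 / exp_)
  }, g$a, g$b, g$c, g$d)
  expect_equal(p$chi2, chi_oracle, tolerance = 1e-10)
})

test_that("signal_table orders by ROR and carries the fitted prior", {
  g <- generate_faers(paper_shaped_scenario(8000, seed = 31))
  d <- clean_faers(g$data)
  st <- signal_table(d, "Pulmonary Edema", min_cases = 3,
                     target_code = 10037375L)
  expect_true(nrow(st) > 10)
  r <- st$ror[!is.na(st$ror)]
  expect_true(all(diff(r) <= 1e-12))
  expect_s3_class(attr(st, "gps_prior"), "gps_prior")
  expect_true(all(st$eb05 <= st$ebgm | is.na(st$ebgm)))
  expect_true(all(st$ic025 <= st$ic))
  expect_true(all(st$ror_lo95 <= st$ror & st$ror <= st$ror_hi95,
                  na.rm = TRUE))
})
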
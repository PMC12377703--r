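make_onset_data <- function(starts, events, ages = 50, sexes = "male",
                            drug = "X") {
  n <- length(starts)
  ages <- rep_len(ages, n); sexes <- rep_len(sexes, n)
  st <- parse_partial_date(starts)
  ev <- parse_partial_date(events)
  faers_data(
    data.frame(primaryid = seq_len(n), caseid = seq_len(n),
               quarter = "2020Q1", occupation = "physician",
               age_years = ages, sex = sexes, weight_kg = 70,
               event_date = ev$date, event_precision = ev$precision,
               report_year = 2020L, stringsAsFactors = FALSE),
    data.frame(primaryid = seq_len(n), seq = 1L, name = drug, role = "PS",
               indication_pt = NA_character_),
    data.frame(primaryid = seq_len(n), pt = "Pulmonary Edema",
               pt_code = 10037375L),
    data.frame(primaryid = seq_len(n), drug_seq = 1L,
               start_date = st$date, start_precision = st$precision)
  )
}

test_that("onset is calendar days from earliest day-precision start", {
  d <- make_onset_data(c("20200101", "20200301", "202005", "20200620"),
                       c("20200131", "20200215", "20200531", "202007"))
  out <- compute_onset(d, "X", "Pulmonary Edema")
  expect_equal(out$records$onset_days, 30)          # report 1 only
  expect_equal(sort(out$drops$reason),
               c("negative_onset", "partial_date", "partial_date"))
})

test_that("the earliest of several PS therapy episodes anchors the onset", {
  d <- make_onset_data("20200110", "20200120")
  d$therapies <- rbind(d$therapies,
                       data.frame(primaryid = 1, drug_seq = 1L,
                                  start_date = "20200105",
                                  start_precision = "day"))
  d$drugs <- rbind(d$drugs, data.frame(primaryid = 1, seq = 1L, name = "X",
                                       role = "PS",
                                       indication_pt = NA_character_))
  out <- compute_onset(d, "X", "Pulmonary Edema")
  expect_equal(out$records$onset_days, 15)
})

test_that("onset summaries are standard order statistics", {
  s <- summarize_onset(c(10, 20, 40))
  expect_equal(s$median, 20)
  expect_equal(s$mean, 70 / 3, tolerance = 1e-12)
  expect_equal(summarize_onset(7)$median, 7)
  eq <- summarize_onset(rep(5, 8))
  expect_equal(eq$q3 - eq$q1, 0)
  expect_equal(summarize_onset(c(1, 2, 3, 4))$median, 2.5)  # even-n midpoint
  expect_null(summarize_onset(numeric(0)))
  # permutation invariance
  set.seed(4)
  v <- rlnorm(21, 3, 1)
  expect_equal(summarize_onset(v), summarize_onset(sample(v)))
})

test_that("exact rank-sum p-values match enumeration and wilcox.test", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u, 0)
  expect_equal(r$p_value, 0.1)  # 2/20 arrangements as extreme
  expect_equal(r$method, "exact")

  set.seed(8)
  for (i in 1:20) {
    nx <- sample(2:8, 1)
    ny <- sample(2:8, 1)
    x <- sample(100, nx); y <- setdiff(sample(100, ny + nx), x)[1:ny]
    ours <- rank_sum_test(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
    if (ours$method == "exact") {
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
      expect_equal(ours$u, unname(ref$statistic))
    }
  }
})

test_that("identical groups give p = 1 and U splits evenly", {
  x <- c(3, 1, 4, 1, 5)
  r <- rank_sum_test(x, x)
  expect_equal(r$p_value, 1)
  expect_equal(r$u, length(x)^2 / 2)
  expect_false(rank_sum_test(numeric(0), x)$testable)
})

test_that("U_x + U_y = n_x n_y and the test is monotone-transform invariant", {
  set.seed(21)
  for (i in 1:10) {
    x <- rlnorm(sample(3:30, 1), 3, 1)
    y <- rlnorm(sample(3:30, 1), 3.5, 1)
    r <- rank_sum_test(x, y)
    expect_equal(r$u + r$u_y, length(x) * length(y))
    r2 <- rank_sum_test(log(x), log(y))   # strictly monotone transform
    expect_equal(r$p_value, r2$p_value)
    expect_equal(r$u, r2$u)
  }
})

test_that("normal approximation tracks the exact test at moderate size", {
  set.seed(33)
  for (i in 1:10) {
    x <- sample(1000, 8); y <- setdiff(sample(1000, 16), x)[1:8]
    exact <- rank_sum_test(x, y, exact_max = 16)$p_value
    approx <- rank_sum_test(x, y, exact_max = 0)$p_value
    # the continuity-corrected normal tail is within ~0.011 of the exact
    # null at n = 8 + 8; the worst gap sits at mid-size p-values
    expect_lt(abs(approx - exact), 0.011)
  }
})

test_that("tied data fall back to the tie-corrected approximation", {
  x <- c(1, 2, 2, 3); y <- c(2, 3, 3, 4)
  r <- rank_sum_test(x, y)
  expect_equal(r$method, "normal_approx")
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("stratified comparisons report direction and skip small strata", {
  rec <- data.frame(
    primaryid = 1:12, drug = "X",
    onset_days = c(100, 120, 90, 110, 80, 130, 10, 12, 9, 11, 8, 13),
    age_group = rep(c("high", "low"), each = 6),
    sex = rep(c("male", "female"), 6), stringsAsFactors = FALSE
  )
  out <- stratified_onset_analysis(rec, "age")
  expect_equal(out$direction, "high")
  expect_true(out$significant)
  expect_equal(out$n1, 6)

  one_side <- rec[rec$age_group == "high", ]
  sk <- stratified_onset_analysis(one_side, "age")
  expect_equal(sk$status, "insufficient_stratum_size")
  expect_false(sk$significant)
})

test_that("stratum shifts in the generator are detected with their direction", {
  hits <- sapply(1:12, function(s) {
    g <- generate_faers(paper_shaped_scenario(40000, seed = 600 + s))
    d <- clean_faers(g$data)
    oa <- stratified_onset_analysis(
      compute_onset(d, "DILTIAZEM", "Pulmonary Edema", 10037375L)$records,
      "age"
    )
    os <- stratified_onset_analysis(
      compute_onset(d, "TADALAFIL", "Pulmonary Edema", 10037375L)$records,
      "sex"
    )
    c(age = oa$significant && oa$direction == "high",
      sex = os$significant && os$direction == "female")
  })
  # built-in +1.2 / -1.2 meanlog shifts; ~35 usable records per drug
  expect_gte(mean(hits["age", ]), 0.6)
  expect_gte(mean(hits["sex", ]), 0.7)
  expect_gte(mean(hits), 0.7)
})
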
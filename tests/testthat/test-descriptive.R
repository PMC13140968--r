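test_that("onset arithmetic handles leap years, zero, and exclusions", {
  expect_equal(time_to_onset("20240301", "20240201")$onset_days, 29L)
  expect_equal(time_to_onset("20240201", "20240201")$onset_days, 0L)
  pre <- time_to_onset("20240201", "20240301")
  expect_equal(pre$status, "pre_treatment")
  expect_true(is.na(pre$onset_days))
  expect_equal(time_to_onset("202402", "20240201")$status, "incomplete")
  expect_equal(time_to_onset("20240215", "2024")$status, "incomplete")
})

test_that("onset summaries bin and interpolate correctly", {
  s <- tto_summary(1:100)
  expect_equal(s$median_days, 50.5)
  b <- tto_summary(c(10, 20, 40, 400))
  expect_equal(unname(b$bin_counts), c(2L, 1L, 0L, 0L, 0L, 1L))
  expect_equal(sum(b$bin_counts), b$n)
  expect_equal(sum(b$bin_fractions), 1, tolerance = 1e-12)
  expect_error(tto_summary(integer(0)), "valid")
})

test_that("onset summary matches a sort-based quantile oracle and is permutation-invariant", {
  set.seed(14)
  x <- round(rlnorm(501, log(38), 1.2))
  for (tp in c(7, 6)) {
    s <- tto_summary(x, quartile_type = tp)
    expect_equal(s$median_days, oracle_quantile(x, 0.5, tp))
    expect_equal(s$q1_days, oracle_quantile(x, 0.25, tp))
    expect_equal(s$q3_days, oracle_quantile(x, 0.75, tp))
  }
  perm <- tto_summary(sample(x))
  expect_equal(perm, tto_summary(x))
})

test_that("report-level onset accounting is conserved", {
  cases <- data.table::data.table(
    primaryid = c("1", "2", "3", "4"),
    event_dt = c("20240301", "202402", "20240110", "20240301"))
  ther <- data.table::data.table(
    primaryid = c("1", "1", "2", "3", "4"),
    start_dt = c("20240210", "20240201", "20240101", "20240120", "2024"))
  tto <- cohort_tto(cases, ther)
  # earliest valid START_DT is used per report
  expect_equal(tto[tto$primaryid == "1", ]$onset_days, 29L)
  expect_equal(tto[tto$primaryid == "3", ]$status, "pre_treatment")
  expect_equal(tto[tto$primaryid == "4", ]$status, "incomplete")
  ex <- attr(tto, "exclusions")
  expect_equal(ex[["n_input"]],
               ex[["n_valid"]] + ex[["n_pre_treatment"]] +
                 ex[["n_incomplete"]])
})

test_that("subgroup tables stratify by sex and converted age", {
  cases <- data.table::data.table(
    primaryid = as.character(1:5),
    sex = c("M", "M", "F", "unknown", "M"),
    age_bin = c(">65", ">65", "18-65", "unknown", NA))
  reac <- data.table::data.table(
    primaryid = c("1", "2", "3", "4", "5"),
    pt = c("X", "X", "X", "X", "Y"))
  by_sex <- stratify(cases, reac, "sex")
  expect_equal(by_sex$M[pt == "X", n], 2L)
  expect_equal(by_sex$F[pt == "X", n], 1L)
  expect_equal(attr(by_sex, "n_unknown"), 1L)
  by_age <- stratify(cases, reac, "age")
  expect_equal(by_age$`>65`[pt == "X", n], 2L)
  expect_equal(attr(by_age, "n_unknown"), 2L)
  # 70 YR and 7 DEC land in the same stratum
  expect_equal(age_in_years(c("70", "7"), c("YR", "DEC")), c(70, 70))
})

test_that("cohort comparisons merge on the term union and sort by |difference|", {
  a <- data.table::data.table(term = c("X", "Z"), n = c(5L, 1L))
  b <- data.table::data.table(term = "X", n = 2L)
  cmp <- compare_cohorts(a, b, labels = c("mono", "combo"))
  expect_equal(cmp$term, c("X", "Z"))
  expect_equal(cmp$mono, c(5L, 1L))
  expect_equal(cmp$combo, c(2L, 0L))
  expect_equal(cmp$difference, c(3L, 1L))
  # named-vector input and brute-force merge oracle
  set.seed(3)
  ca <- setNames(sample(0:50, 20), paste0("T", 1:20))
  cb <- setNames(sample(0:50, 15), paste0("T", 6:20))
  got <- compare_cohorts(ca, cb)
  terms <- union(names(ca), names(cb))
  oracle <- data.frame(term = terms,
                       na = ifelse(is.na(ca[terms]), 0, ca[terms]),
                       nb = ifelse(is.na(cb[terms]), 0, cb[terms]))
  oracle <- oracle[order(-abs(oracle$na - oracle$nb), oracle$term), ]
  expect_equal(got$term, oracle$term)
  expect_equal(got$cohort_a, oracle$na, ignore_attr = TRUE)
  expect_equal(got$cohort_b, oracle$nb, ignore_attr = TRUE)
})

test_that("demographic percentages cover every report including missing", {
  cases <- data.table::data.table(
    primaryid = as.character(1:10),
    fda_dt = rep(c("20230315", "20240101"), 5),
    sex = c(rep("F", 4), rep("M", 5), "unknown"),
    age_bin = c(rep("18-65", 6), rep(">65", 2), "unknown", "unknown"),
    weight_kg = c(45, rep(70, 5), NA, NA, 120, 80),
    country = c(rep("JP", 5), rep("US", 3), "missing", "missing"),
    occp_cod = rep("MD", 10),
    outcomes = c("DE,HO", "HO", rep("", 8)))
  dem <- demographics_summary(cases)
  expect_equal(dem$sex[category == "F", pct], 40)
  expect_equal(dem$sex[category == "M", pct], 50)
  expect_equal(sum(dem$sex$pct), 100)
  expect_equal(sum(dem$age$pct), 100, tolerance = 1e-12)
  expect_equal(dem$outcomes[category == "HO", n], 2L)
  expect_equal(dem$outcomes[category == "DE", n], 1L)
  expect_equal(dem$annual$n, c(5L, 5L))
  empty_outc <- demographics_summary(cases[, outcomes := ""])
  expect_true(all(empty_outc$outcomes$n == 0L))
})
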
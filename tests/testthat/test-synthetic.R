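test_that("a fixed seed makes generated quarters byte-identical", {
  cfg <- mini_config(n_reports = 300L, seed = 123L)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  unlink(c(d1, d2), recursive = TRUE)
  generate_faers(cfg, d1)
  generate_faers(cfg, d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_equal(f1, f2)
  for (f in f1)
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     label = f)
  # a different seed changes the output
  d3 <- file.path(tempdir(), "det3"); unlink(d3, recursive = TRUE)
  generate_faers(mini_config(n_reports = 300L, seed = 124L), d3)
  expect_false(identical(
    readLines(file.path(d1, "2020Q1/DEMO20Q1.txt")),
    readLines(file.path(d3, "2020Q1/DEMO20Q1.txt"))))
})

test_that("duplicate versions inflate DEMO but not the deduplicated count", {
  cfg <- mini_config(n_reports = 100L, seed = 5L, duplicate_fraction = 0.2)
  sim <- generate_reports(cfg)
  expect_equal(nrow(sim$demo), 120L)
  retained <- deduplicate(sim$demo)
  expect_equal(length(retained), 100L)
  # dedup always keeps the later report version (higher primaryid on ties)
  expect_setequal(as.character(retained), sim$truth$primaryid)
})

test_that("the manifest check passes untouched output and names tampered fields", {
  cfg <- mini_config(n_reports = 200L, seed = 31L)
  d <- file.path(tempdir(), "mani"); unlink(d, recursive = TRUE)
  generate_faers(cfg, d)
  expect_true(manifest_check(d)$pass)
  demo_file <- file.path(d, "2020Q1", "DEMO20Q1.txt")
  lines <- readLines(demo_file)
  writeLines(lines[-2], demo_file)
  chk <- manifest_check(d)
  expect_false(chk$pass)
  expect_true(any(grepl("demo", chk$diffs, ignore.case = TRUE)))
})

test_that("generated mixes track the configured reporting system", {
  cfg <- mini_config(n_reports = 10000L, seed = 77L,
                     duplicate_fraction = 0)
  sim <- generate_reports(cfg)
  demo <- sim$demo
  # sex mix within binomial tolerance (~4 sd)
  p_f <- mean(demo$sex == "F")
  expect_lt(abs(p_f - cfg$sex_mix[["F"]]), 4 * sqrt(0.4 * 0.6 / 10000))
  p_m <- mean(demo$sex == "M")
  expect_lt(abs(p_m - cfg$sex_mix[["M"]]), 4 * sqrt(0.53 * 0.47 / 10000))
  # onset median near exp(meanlog) among valid onset records
  tto <- time_to_onset(demo$event_dt, sim$ther$start_dt)
  med <- median(tto$onset_days[tto$status == "valid"])
  expect_lt(abs(log(med) - cfg$onset_meanlog), 0.1)
  # cohort mix
  tab <- table(sim$truth$cohort) / 10000
  expect_lt(abs(tab[["combination"]] - 0.05), 0.01)
})

test_that("a null reporting system shows no systematic disproportionality", {
  cfg <- mini_config(n_reports = 50000L, seed = 13L,
                     associations = null_associations)
  set.seed(cfg$seed)
  expo <- sample_exposures(cfg)
  ev <- sample_events(cfg, expo)
  co <- ev[expo[ev$report] == "combination",
           .(primaryid = as.character(report), term = pt)]
  bg <- ev[expo[ev$report] != "combination",
           .(primaryid = as.character(report), term = pt)]
  tab <- build_contingency_tables(co, bg)
  ratios <- tab[tab$expected >= 5, a / expected]
  expect_gt(length(ratios), 50)
  expect_lt(abs(mean(ratios) - 1), 0.1)
})
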
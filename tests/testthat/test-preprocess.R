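test_that("within a case the latest FDA_DT wins, ties go to highest primaryid", {
  expect_setequal(
    deduplicate(data.frame(primaryid = c("1", "2"), caseid = c("A", "A"),
                           fda_dt = c("20230101", "20230301"))), "2")
  expect_setequal(
    deduplicate(data.frame(primaryid = "7", caseid = "B",
                           fda_dt = "20230101")), "7")
  expect_setequal(
    deduplicate(data.frame(primaryid = c("3", "9", "5"),
                           caseid = c("A", "A", "C"),
                           fda_dt = c("20230101", "20230101", "20230201"))),
    c("9", "5"))
  # numeric, not lexical, primaryid comparison
  expect_setequal(
    deduplicate(data.frame(primaryid = c("100", "99"), caseid = c("A", "A"),
                           fda_dt = c("20230101", "20230101"))), "100")
})

test_that("unparseable caseids are retained unconditionally and tallied", {
  r <- deduplicate(data.frame(primaryid = c("1", "2", "3"),
                              caseid = c("A", "", NA),
                              fda_dt = rep("20230101", 3)))
  expect_setequal(r, c("1", "2", "3"))
  expect_equal(attr(r, "n_unparseable_caseid"), 2L)
})

test_that("deduplication is idempotent and keeps one id per caseid", {
  set.seed(11)
  rows <- data.frame(
    primaryid = as.character(sample(1e6, 400)),
    caseid = as.character(sample(150, 400, replace = TRUE)),
    fda_dt = format(as.Date("2020-01-01") + sample(0:1500, 400, TRUE),
                    "%Y%m%d"))
  r1 <- deduplicate(rows)
  expect_equal(length(r1), length(unique(rows$caseid)))
  again <- deduplicate(rows[rows$primaryid %in% r1, ])
  expect_setequal(as.character(again), as.character(r1))
})

test_that("drug names normalise through brand, salt and dose variants", {
  dict <- load_drug_dictionary()
  expect_equal(
    normalize_drug(c("PEMBROLIZUMAB", "KEYTRUDA.", "ASPIRIN",
                     "  opdivo ", "CISPLATIN 50 MG", "PARAPLATIN..."),
                   dict),
    c("pembrolizumab", "pembrolizumab", "other", "nivolumab", "cisplatin",
      "carboplatin"))
  expect_true(length(intersect(attr(dict, "ici"),
                               attr(dict, "platinum"))) == 0)
})

test_that("cohort assignment follows the primary-suspect screening rule", {
  dict <- load_drug_dictionary()
  drug <- data.table::data.table(
    primaryid = c("1", "1", "2", "3", "3", "4", "4", "5"),
    drugname = c("KEYTRUDA", "CARBOPLATIN", "NIVOLUMAB", "NIVOLUMAB",
                 "CISPLATIN", "PEMBROLIZUMAB", "CISPLATIN", "ASPIRIN"),
    role_cod = c("PS", "PS", "PS", "C", "PS", "PS", "SS", "PS"))
  got <- assign_cohort(drug, dict)
  expect_equal(setNames(got$cohort, got$primaryid),
               c(`1` = "combination", `2` = "ici_mono",
                 `3` = "platinum_mono",
                 # ICI at PS but platinum in a suspect role: not mono,
                 # not combination under the strict PS rule
                 `4` = "background",
                 `5` = "background"))
  relaxed <- assign_cohort(drug, dict, suspect_roles = "PS+SS")
  expect_equal(relaxed[primaryid == "4", cohort], "combination")
})

test_that("cohort labels partition the deduplicated reports", {
  cfg <- mini_config(n_reports = 800L, seed = 3L)
  sim <- generate_reports(cfg)
  retained <- deduplicate(sim$demo)
  dict <- load_drug_dictionary()
  lab <- assign_cohort(sim$drug[sim$drug$primaryid %in% retained, ], dict)
  expect_equal(anyDuplicated(lab$primaryid), 0L)
  expect_true(all(lab$cohort %in% c("combination", "ici_mono",
                                    "platinum_mono", "background")))
  # matches generator truth for every report that lists drugs
  m <- merge(lab, sim$truth, by = "primaryid")
  expect_equal(m$cohort.x, m$cohort.y)
})

test_that("age unit codes convert to years", {
  expect_equal(age_in_years(c("70", "7", "24", "730", "5"),
                            c("YR", "DEC", "MON", "DY", "XX")),
               c(70, 70, 2, 730 / 365.25, NA_real_))
})
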
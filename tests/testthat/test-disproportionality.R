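test_that("contingency tables count report-level term presence over pair margins", {
  cohort <- data.table::data.table(
    primaryid = c("r1", "r1", "r2", "r2", "r3"),
    term = c("Pyrexia", "Pyrexia", "Pyrexia", "Nausea", "Colitis"))
  background <- data.table::data.table(
    primaryid = c("b1", "b2", "b3"),
    term = c("Pyrexia", "Nausea", "Nausea"))
  tab <- build_contingency_tables(cohort, background)
  pyrexia <- tab[tab$term == "Pyrexia", ]
  expect_equal(pyrexia$a, 2L)   # repeated PT in r1 counts once
  expect_equal(pyrexia$c, 1L)
  # r2 mentions {Pyrexia, Nausea}: contributes 1 to Nausea's a, and its
  # Pyrexia pair lands in Nausea's b
  nausea <- tab[tab$term == "Nausea", ]
  expect_equal(nausea$a, 1L)
  expect_equal(nausea$b, 3L)
  # total pairs: cohort 4 (r1 deduplicated), background 3
  expect_true(all(tab$a + tab$b == 4L))
  expect_true(all(tab$c + tab$d == 3L))
  absent <- build_contingency_tables(cohort, background, terms = "Rash")
  expect_equal(absent$a, 0L)
  expect_equal(absent$c, 0L)
  expect_error(build_contingency_tables(cohort, cohort[0]), "background")
})

test_that("ROR and Woolf interval match direct evaluation", {
  sym <- ror_stats(10, 10, 10, 10)
  expect_equal(sym$ror, 1)
  expect_equal(sym$ror_lo * sym$ror_hi, 1, tolerance = 1e-12)
  r <- ror_stats(10, 20, 30, 40)
  expect_equal(r$ror, 2 / 3, tolerance = 1e-12)
  expect_equal(r$ror_lo, 0.2725, tolerance = 1e-4)
  expect_equal(r$ror_hi, 1.6310, tolerance = 1e-4)
  # zero cells: undefined unless the continuity flag is set
  expect_true(is.na(ror_stats(0, 20, 30, 40)$ror))
  cc <- ror_stats(0, 20, 30, 40, continuity = TRUE)
  expect_equal(cc$ror, (0.5 * 40.5) / (20.5 * 30.5), tolerance = 1e-12)
})

test_that("PRR and Pearson chi-square match direct evaluation", {
  ind <- prr_stats(10, 10, 10, 10)
  expect_equal(ind$prr, 1)
  expect_equal(ind$chi2, 0)
  p <- prr_stats(10, 20, 30, 40)
  expect_equal(p$prr, (10 / 30) / (30 / 70), tolerance = 1e-12)
  expect_equal(p$chi2, 100 * (10 * 40 - 20 * 30)^2 / (30 * 70 * 40 * 60),
               tolerance = 1e-12)
  expect_true(is.na(prr_stats(10, 20, 0, 40)$prr))
  # Yates variant shrinks the statistic
  expect_lt(prr_stats(10, 20, 30, 40, yates = TRUE)$chi2, p$chi2)
})

test_that("information component matches the shrinkage form", {
  expect_equal(bcpnn_ic(10, 10, 10, 10)$ic, 0)
  b <- bcpnn_ic(20, 80, 100, 800)
  expect_equal(b$ic, log2(20.5 / 12.5), tolerance = 1e-12)
  expect_equal(b$ic025, log2(20.5 / 12.5) - 3.3 / sqrt(20.5) -
                 2 / 20.5^1.5, tolerance = 1e-12)
  expect_equal(b$ic, 0.7137, tolerance = 1e-4)
  expect_equal(b$ic025, -0.0367, tolerance = 1e-3)
  # large-a limit: shrinkage terms vanish
  big <- bcpnn_ic(2e6, 8e6, 1e7, 8e7)
  n <- 2e6 + 8e6 + 1e7 + 8e7
  expect_equal(big$ic, log2(2e6 * n / (1e7 * 1.2e7)), tolerance = 1e-4)
  # the full-Bayes variant agrees with the shrinkage form to first order
  fb <- bcpnn_ic(20, 80, 100, 800, variant = "bayes")
  expect_equal(fb$ic, b$ic, tolerance = 0.1)
  big_fb <- bcpnn_ic(2e6, 8e6, 1e7, 8e7, variant = "bayes")
  expect_equal(big_fb$ic, big$ic, tolerance = 1e-3)
})

test_that("interval bounds are log-symmetric and chi2 is transpose-invariant", {
  set.seed(21)
  for (i in 1:50) {
    t4 <- sample(1:500, 4)
    r <- ror_stats(t4[1], t4[2], t4[3], t4[4])
    expect_equal(sqrt(r$ror_lo * r$ror_hi), r$ror, tolerance = 1e-10)
    expect_true(r$ror_lo < r$ror && r$ror < r$ror_hi)
    chi_t <- prr_stats(t4[1], t4[3], t4[2], t4[4])$chi2
    expect_equal(prr_stats(t4[1], t4[2], t4[3], t4[4])$chi2, chi_t,
                 tolerance = 1e-10)
  }
})

test_that("PRR approaches ROR for rare events", {
  a <- 30; b <- 1e5; c <- 300; d <- 2e6   # a/(a+b) < 0.001
  prr <- prr_stats(a, b, c, d)$prr
  ror <- ror_stats(a, b, c, d)$ror
  expect_lt(abs(prr - ror) / ror, 0.01)
})

test_that("posterior geometric mean matches the digamma closed form", {
  # point prior limit: N=0, E->0 leaves the posterior equal to the prior
  pr <- mgps_prior(2, 4, 1, 1, p = 1)
  expect_equal(ebgm_scores(0, 1e-12, pr)$ebgm, exp(digamma(2) - log(4)),
               tolerance = 1e-9)
  # data dominance: N/E = 10 with N large and a vague prior
  vague <- mgps_prior(0.01, 0.01, 0.01, 0.01, p = 0.5)
  expect_equal(ebgm_scores(5000, 500, vague)$ebgm, 10, tolerance = 0.01)
})

test_that("EBGM and EBGM05 match the quadrature oracle", {
  set.seed(5)
  for (i in 1:20) {
    pr <- mgps_prior(runif(1, 0.1, 3), runif(1, 0.05, 4),
                     runif(1, 0.1, 3), runif(1, 0.05, 4),
                     runif(1, 0.05, 0.95))
    n <- rpois(1, 20); e <- runif(1, 0.5, 30)
    got <- ebgm_scores(n, e, pr)
    expect_equal(got$ebgm, oracle_ebgm(n, e, pr), tolerance = 1e-6)
    expect_equal(got$ebgm05, oracle_ebgm05(n, e, pr), tolerance = 1e-6)
  }
})

test_that("EBGM shrinks elevated ratios toward the prior", {
  pr <- mgps_prior(1, 1, 2, 2, p = 0.5)   # prior mass around 1
  for (n in c(5, 20, 100)) {
    e <- n / 4   # raw ratio 4
    expect_lt(ebgm_scores(n, e, pr)$ebgm, n / e)
    expect_gt(ebgm_scores(n, e, pr)$ebgm, 1)
  }
})

test_that("the prior fit needs a grid and rejects tiny ones", {
  expect_error(fit_mgps_prior(1:50, rep(1, 50)), "at least")
  expect_error(fit_mgps_prior(1:200, rep(0, 200)), "positive")
})

test_that("null grids concentrate the posterior at lambda = 1", {
  set.seed(8)
  e <- rep(c(500, 1000, 2000, 5000), each = 50)
  n_obs <- round(e)
  fit <- fit_mgps_prior(n_obs, e)
  eb <- ebgm_scores(n_obs, e, fit)
  expect_true(all(abs(eb$ebgm - 1) < 0.05))
})

test_that("a single-component truth collapses the fitted mixture", {
  set.seed(9)
  e <- rlnorm(3000, log(5), 1)
  lam <- rgamma(3000, 1, 1)
  n_obs <- rpois(3000, lam * e)
  fit <- fit_mgps_prior(n_obs, e)
  m1 <- fit$alpha1 / fit$beta1
  m2 <- fit$alpha2 / fit$beta2
  collapsed <- fit$p > 0.9 || fit$p < 0.1 || abs(m1 - m2) / m1 < 0.2
  expect_true(collapsed)
})

test_that("the four-criteria gate uses the stated thresholds strictly", {
  base <- data.table::data.table(
    a = c(349, 2, 10, 10),
    ror_lo = c(190.45, 50, 1.0, 1.5),
    prr = c(214.22, 100, 3, 3),
    chi2 = c(55255.83, 999, 10, 10),
    ic025 = c(7.15, 5, 0.2, 0),
    ebgm05 = c(144.57, 99, 3, 3))
  got <- apply_signal_criteria(base)
  expect_true(got$significant[1])
  expect_false(got$significant[2])    # a < 3 despite huge effect
  expect_false(got$flag_ror[3])       # ror_lo = 1 exactly: strict
  expect_false(got$flag_bcpnn[4])     # ic025 = 0 exactly: strict
})
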
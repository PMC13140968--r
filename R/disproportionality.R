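#' Build 2x2 contingency tables for each event term
#'
#' Counting is report-level: a report contributes at most one count to a
#' given term even if the term repeats among its reactions. The margins are
#' report-term pairs: for term *t*, `a` = number of cohort reports
#' mentioning *t*, `b` = the cohort's report-term pairs over all other
#' terms, and `c`/`d` symmetrically over the background. The expected count
#' under independence is `E = (a+b)(a+c)/N` with `N = a+b+c+d`.
#'
#' @param cohort data.table of cohort report-term pairs (`primaryid`,
#'   `term`); duplicates are collapsed.
#' @param background data.table of background report-term pairs; must be
#'   non-empty.
#' @param terms terms to tabulate; default is the union of terms seen in
#'   either group (a term absent from a group gets a zero cell).
#' @return data.table with columns `term`, `a`, `b`, `c`, `d`, `expected`.
#' @export
build_contingency_tables <- function(cohort, background, terms = NULL) {
  co <- unique(data.table::as.data.table(cohort)[, .(primaryid, term)])
  bg <- unique(data.table::as.data.table(background)[, .(primaryid, term)])
  if (nrow(bg) == 0L) stop("empty background: no comparator pairs",
                           call. = FALSE)
  if (is.null(terms)) terms <- sort(unique(c(co$term, bg$term)))
  n_co <- nrow(co)   # total cohort report-term pairs
  n_bg <- nrow(bg)
  a <- co[, .N, by = term][match(terms, term), N]
  c_ <- bg[, .N, by = term][match(terms, term), N]
  a[is.na(a)] <- 0L
  c_[is.na(c_)] <- 0L
  out <- data.table::data.table(term = terms, a = a, b = n_co - a, c = c_,
                                d = n_bg - c_)
  out[, expected := as.numeric(a + b) * (a + c) / (a + b + c + d)]
  out[]
}

#' Reporting odds ratio with Woolf 95% confidence interval
#'
#' `ROR = ad/(bc)`; the Woolf interval is
#' `exp(log ROR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`. With any zero
#' cell the statistic is undefined (`NA`) unless `continuity = TRUE`, which
#' adds 0.5 to every cell (Haldane-Anscombe correction).
#'
#' @param a,b,c,d cell counts (vectorised).
#' @param continuity apply the +0.5 correction to zero-cell tables.
#' @return data.table with columns `ror`, `ror_lo`, `ror_hi`.
#' @examples
#' ror_stats(10, 20, 30, 40)
#' @export
ror_stats <- function(a, b, c, d, continuity = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  zero <- a <= 0 | b <= 0 | c <= 0 | d <= 0
  if (continuity) {
    a[zero] <- a[zero] + 0.5; b[zero] <- b[zero] + 0.5
    c[zero] <- c[zero] + 0.5; d[zero] <- d[zero] + 0.5
    zero <- rep(FALSE, length(a))
  }
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  lo <- exp(log(ror) - 1.96 * se)
  hi <- exp(log(ror) + 1.96 * se)
  ror[zero] <- lo[zero] <- hi[zero] <- NA_real_
  data.table::data.table(ror = ror, ror_lo = lo, ror_hi = hi)
}

#' Proportional reporting ratio and Pearson chi-square
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`; the chi-square statistic is Pearson's
#' `N (ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]` without continuity correction
#' (a Yates-corrected variant is available via `yates = TRUE`). Zero
#' margins yield `NA`.
#'
#' @param a,b,c,d cell counts (vectorised).
#' @param yates apply the Yates continuity correction to the chi-square.
#' @return data.table with columns `prr`, `chi2`.
#' @examples
#' prr_stats(10, 20, 30, 40)
#' @export
prr_stats <- function(a, b, c, d, yates = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  bad <- (a + b) <= 0 | (c + d) <= 0 | (a + c) <= 0 | (b + d) <= 0 | c <= 0
  prr <- (a / (a + b)) / (c / (c + d))
  dev <- abs(a * d - b * c)
  if (yates) dev <- pmax(dev - n / 2, 0)
  chi2 <- n * dev^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  prr[bad] <- NA_real_
  chi2[(a + b) <= 0 | (c + d) <= 0 | (a + c) <= 0 | (b + d) <= 0] <- NA_real_
  data.table::data.table(prr = prr, chi2 = chi2)
}

#' BCPNN information component
#'
#' The default variant is the shrinkage observed-to-expected estimator:
#' `IC = log2[(a + 0.5) / (E + 0.5)]` with `E = (a+b)(a+c)/N`, and a
#' credibility-interval lower bound
#' `IC025 = IC - 3.3 (a+0.5)^{-1/2} - 2.0 (a+0.5)^{-3/2}`. The `"bayes"`
#' variant computes the original BCPNN posterior expectation and variance
#' of the information component under independent Beta/Dirichlet priors and
#' uses a normal approximation for the 2.5% bound.
#'
#' @param a,b,c,d cell counts (vectorised).
#' @param variant `"shrinkage"` (default) or `"bayes"`.
#' @return data.table with columns `ic`, `ic025`.
#' @examples
#' bcpnn_ic(20, 80, 100, 800)
#' @export
bcpnn_ic <- function(a, b, c, d, variant = c("shrinkage", "bayes")) {
  variant <- match.arg(variant)
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  if (any(n <= 0)) stop("empty table: N must be positive", call. = FALSE)
  e <- (a + b) * (a + c) / n
  if (variant == "shrinkage") {
    ic <- log2((a + 0.5) / (e + 0.5))
    ic025 <- ic - 3.3 * (a + 0.5)^(-0.5) - 2.0 * (a + 0.5)^(-1.5)
  } else {
    # Bate et al. closed-form posterior moments of IC
    g11 <- (a + 0.5) / (n + 1)                      # E[p11]
    p1 <- (a + b + 1) / (n + 2)                     # E[p1.]
    p2 <- (a + c + 1) / (n + 2)                     # E[p.1]
    ic <- log2(g11 / (p1 * p2))
    v11 <- (n - a + 0.5) / ((a + 0.5) * (n + 2))
    v1 <- (n - a - b + 1) / ((a + b + 1) * (n + 3))
    v2 <- (n - a - c + 1) / ((a + c + 1) * (n + 3))
    sd_ic <- sqrt(v11 + v1 + v2) / log(2)
    ic025 <- ic - 1.96 * sd_ic
  }
  data.table::data.table(ic = ic, ic025 = ic025)
}

#' Fit the MGPS two-component Gamma mixture prior
#'
#' The Multi-item Gamma Poisson Shrinker models each cell's observed count
#' as `N ~ Poisson(lambda * E)` with the reporting-rate ratio `lambda`
#' drawn from a two-component Gamma mixture prior
#' `p * Gamma(alpha1, beta1) + (1 - p) * Gamma(alpha2, beta2)` (shape/rate).
#' Marginally each cell is a two-component negative-binomial mixture; the
#' five hyperparameters are estimated by maximising the marginal
#' log-likelihood over the full count grid. Optimisation is quasi-Newton
#' (BFGS) on log/logit-transformed parameters with five starts, including
#' DuMouchel's classic initialisation (0.2, 0.1, 2.0, 4.0, 1/3); components
#' are reported with the larger prior mean first.
#'
#' @param n_obs integer vector of observed counts over the grid.
#' @param e positive vector of expected counts (same length).
#' @param min_cells minimum grid size accepted (default 100).
#' @param starts optional list of numeric length-5 start vectors
#'   `(alpha1, beta1, alpha2, beta2, p)`.
#' @return An `mgps_prior`: list with `alpha1`, `beta1`, `alpha2`, `beta2`,
#'   `p`, `loglik`, `convergence` (0 = converged), `n_cells`.
#' @export
fit_mgps_prior <- function(n_obs, e, min_cells = 100L, starts = NULL) {
  stopifnot(length(n_obs) == length(e))
  if (length(n_obs) < min_cells)
    stop("MGPS prior fit needs at least ", min_cells, " cells", call. = FALSE)
  if (any(e <= 0)) stop("all expected counts must be positive", call. = FALSE)
  n_obs <- as.numeric(n_obs)

  negll <- function(theta) {
    a1 <- exp(theta[1]); b1 <- exp(theta[2])
    a2 <- exp(theta[3]); b2 <- exp(theta[4])
    p <- stats::plogis(theta[5])
    l1 <- suppressWarnings(
      dnbinom(n_obs, size = a1, prob = b1 / (b1 + e), log = TRUE))
    l2 <- suppressWarnings(
      dnbinom(n_obs, size = a2, prob = b2 / (b2 + e), log = TRUE))
    m <- pmax(l1, l2)
    ll <- sum(m + log(p * exp(l1 - m) + (1 - p) * exp(l2 - m)))
    if (!is.finite(ll)) return(1e12)
    -ll
  }

  if (is.null(starts))
    starts <- list(c(0.2, 0.1, 2.0, 4.0, 1 / 3),   # DuMouchel classic
                   c(1, 1, 1, 1, 0.5),
                   c(0.5, 0.5, 2, 2, 0.2),
                   c(2, 4, 0.2, 0.1, 2 / 3),       # classic, swapped
                   c(0.1, 0.02, 5, 5, 0.1))
  best <- NULL
  last <- NULL
  for (s in starts) {
    theta0 <- c(log(s[1:4]), stats::qlogis(s[5]))
    fit <- tryCatch(
      optim(theta0, negll, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    last <- fit
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("MGPS prior optimisation failed from every start", call. = FALSE)
  if (best$convergence != 0) {
    cond <- structure(
      class = c("mgps_nonconvergence", "error", "condition"),
      list(message = "MGPS prior fit did not converge within max iterations",
           call = sys.call(), last_iterate = best$par))
    stop(cond)
  }
  th <- best$par
  prior <- list(alpha1 = exp(th[1]), beta1 = exp(th[2]),
                alpha2 = exp(th[3]), beta2 = exp(th[4]),
                p = stats::plogis(th[5]))
  # canonical order: component with the larger prior mean first
  if (prior$alpha1 / prior$beta1 < prior$alpha2 / prior$beta2)
    prior <- list(alpha1 = prior$alpha2, beta1 = prior$beta2,
                  alpha2 = prior$alpha1, beta2 = prior$beta1,
                  p = 1 - prior$p)
  prior$loglik <- -best$value
  prior$convergence <- best$convergence
  prior$n_cells <- length(n_obs)
  class(prior) <- "mgps_prior"
  prior
}

#' @export
print.mgps_prior <- function(x, ...) {
  cat(sprintf(
    "MGPS Gamma-mixture prior (%d cells, logLik %.2f)\n  %.4f * Gamma(%.4g, %.4g) + %.4f * Gamma(%.4g, %.4g)\n",
    x$n_cells, x$loglik, x$p, x$alpha1, x$beta1, 1 - x$p, x$alpha2, x$beta2))
  invisible(x)
}

#' Construct an MGPS prior from known hyperparameters
#'
#' @param alpha1,beta1,alpha2,beta2 positive shape/rate parameters.
#' @param p mixture weight of the first component.
#' @return An `mgps_prior` object.
#' @export
mgps_prior <- function(alpha1, beta1, alpha2, beta2, p) {
  stopifnot(alpha1 > 0, beta1 > 0, alpha2 > 0, beta2 > 0, p >= 0, p <= 1)
  structure(list(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2,
                 beta2 = beta2, p = p, loglik = NA_real_, convergence = NA,
                 n_cells = NA_integer_),
            class = "mgps_prior")
}

#' Empirical Bayes geometric mean (EBGM) and its 5th percentile
#'
#' Given the fitted Gamma-mixture prior, the posterior of the
#' reporting-rate ratio `lambda` for a cell with observed count `n_obs`
#' and expected count `e` is again a two-component Gamma mixture with
#' components `Gamma(alpha_j + n_obs, beta_j + e)` and negative-binomial
#' posterior weights. `EBGM = exp(E[log lambda | n_obs])` (the posterior
#' geometric mean, via digamma terms) and `EBGM05` is the posterior 5th
#' percentile, found by root-finding on the mixture CDF.
#'
#' @param n_obs observed counts (vectorised).
#' @param e expected counts.
#' @param prior an `mgps_prior`.
#' @return data.table with columns `ebgm`, `ebgm05`.
#' @export
ebgm_scores <- function(n_obs, e, prior) {
  stopifnot(inherits(prior, "mgps_prior"))
  n_obs <- as.numeric(n_obs); e <- as.numeric(e)
  a1 <- prior$alpha1; b1 <- prior$beta1
  a2 <- prior$alpha2; b2 <- prior$beta2
  p <- prior$p
  # posterior mixture weights via NB marginals (log scale for stability)
  l1 <- dnbinom(n_obs, size = a1, prob = b1 / (b1 + e), log = TRUE) + log(p)
  l2 <- dnbinom(n_obs, size = a2, prob = b2 / (b2 + e), log = TRUE) +
    log1p(-p)
  if (p >= 1) { q <- rep(1, length(n_obs)) }
  else if (p <= 0) { q <- rep(0, length(n_obs)) }
  else { m <- pmax(l1, l2); q <- exp(l1 - m) / (exp(l1 - m) + exp(l2 - m)) }
  q[!is.finite(q)] <- 0.5
  s1 <- a1 + n_obs; r1 <- b1 + e
  s2 <- a2 + n_obs; r2 <- b2 + e
  ebgm <- exp(q * (digamma(s1) - log(r1)) + (1 - q) * (digamma(s2) - log(r2)))
  ebgm05 <- vapply(seq_along(n_obs), function(i) {
    mix_cdf <- function(x)
      q[i] * pgamma(x, s1[i], r1[i]) + (1 - q[i]) * pgamma(x, s2[i], r2[i]) -
        0.05
    lo <- min(qgamma(0.05, s1[i], r1[i]), qgamma(0.05, s2[i], r2[i]))
    hi <- max(qgamma(0.05, s1[i], r1[i]), qgamma(0.05, s2[i], r2[i]))
    if (hi - lo < .Machine$double.eps) return(lo)
    # widen the bracket: the mixture quantile lies in [lo, hi], but with
    # near-degenerate components the CDF can equal 0.05 to rounding at an
    # endpoint
    uniroot(mix_cdf, c(lo * 0.5, hi * 2 + 1e-12), tol = 1e-10,
            extendInt = "upX")$root
  }, numeric(1))
  data.table::data.table(ebgm = ebgm, ebgm05 = ebgm05)
}

#' Apply the four-algorithm signal gate
#'
#' A term is a signal when all four criteria hold simultaneously:
#' `a >= 3` and ROR CI lower bound `> 1`; `a >= 3`, `PRR >= 2` and
#' `chi2 >= 4`; `IC025 > 0`; `EBGM05 > 2`. Inequalities on the interval
#' bounds are strict; `NA` statistics fail their criterion.
#'
#' @param stats data.table holding at least `a`, `ror_lo`, `prr`, `chi2`,
#'   `ic025`, `ebgm05`.
#' @return The input with logical columns `flag_ror`, `flag_prr`,
#'   `flag_bcpnn`, `flag_mgps`, `significant` appended.
#' @export
apply_signal_criteria <- function(stats) {
  s <- data.table::as.data.table(stats)
  nz <- function(x) !is.na(x) & x
  s[, flag_ror := nz(a >= 3 & ror_lo > 1)]
  s[, flag_prr := nz(a >= 3 & prr >= 2 & chi2 >= 4)]
  s[, flag_bcpnn := nz(ic025 > 0)]
  s[, flag_mgps := nz(ebgm05 > 2)]
  s[, significant := flag_ror & flag_prr & flag_bcpnn & flag_mgps]
  s[]
}

#' Full disproportionality signal table for one cohort
#'
#' Builds the per-term 2x2 tables, computes all four algorithms' statistics
#' and the joint signal gate. The MGPS prior is fitted over the full grid of
#' (observed, expected) cells; when the grid has fewer than `mgps_min_cells`
#' terms and no `prior` is supplied, the EBGM columns are `NA`.
#'
#' @param cohort,background report-term pair tables (`primaryid`, `term`).
#' @param level label stored in the output (`"PT"` or `"SOC"`).
#' @param prior optional pre-fitted `mgps_prior`.
#' @param continuity,yates,ic_variant variant flags passed to the
#'   individual estimators.
#' @param mgps_min_cells minimum grid size for fitting the prior.
#' @return data.table with one row per term: counts, all statistics,
#'   per-algorithm flags and `significant`, sorted by `a` descending.
#' @export
signal_table <- function(cohort, background, level = "PT", prior = NULL,
                         continuity = FALSE, yates = FALSE,
                         ic_variant = "shrinkage", mgps_min_cells = 100L) {
  tab <- build_contingency_tables(cohort, background)
  out <- cbind(tab,
               ror_stats(tab$a, tab$b, tab$c, tab$d, continuity = continuity),
               prr_stats(tab$a, tab$b, tab$c, tab$d, yates = yates),
               bcpnn_ic(tab$a, tab$b, tab$c, tab$d, variant = ic_variant))
  if (is.null(prior) && nrow(tab) >= mgps_min_cells)
    prior <- fit_mgps_prior(tab$a, tab$expected, min_cells = mgps_min_cells)
  if (!is.null(prior)) {
    eb <- ebgm_scores(tab$a, tab$expected, prior)
  } else {
    warning("fewer than ", mgps_min_cells,
            " grid cells and no prior supplied: EBGM columns are NA")
    eb <- data.table::data.table(ebgm = rep(NA_real_, nrow(tab)),
                                 ebgm05 = rep(NA_real_, nrow(tab)))
  }
  out <- cbind(out, eb)
  out[, level := level]
  out <- apply_signal_criteria(out)
  data.table::setorder(out, -a)
  data.table::setattr(out, "mgps_prior", prior)
  out[]
}
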
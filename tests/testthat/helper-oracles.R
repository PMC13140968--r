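# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths.

# Reconstruct (b, c, d) of a 2x2 table from its report count `a` and the
# published ROR, PRR and Pearson chi-square, by root finding on the three
# defining equations (log scale for conditioning).
reconstruct_table <- function(a, ror, prr, chi2) {
  f <- function(lbcd) {
    b <- exp(lbcd[1]); cc <- exp(lbcd[2]); d <- exp(lbcd[3])
    n <- a + b + cc + d
    c(log(a * d / (b * cc)) - log(ror),
      log((a / (a + b)) / (cc / (cc + d))) - log(prr),
      log(n * (a * d - b * cc)^2 /
            ((a + b) * (cc + d) * (a + cc) * (b + d))) - log(chi2))
  }
  sol <- pracma::fsolve(f, log(c(1e4, 5e3, 1e7)))
  stopifnot(max(abs(f(sol$x))) < 1e-8)
  out <- exp(sol$x)
  list(a = a, b = out[1], c = out[2], d = out[3])
}

# Sort-based quantile oracle, linear interpolation (Hyndman-Fan types 7/6).
oracle_quantile <- function(x, p, type = 7) {
  x <- sort(x)
  n <- length(x)
  h <- if (type == 7) (n - 1) * p + 1 else (n + 1) * p
  h <- pmin(pmax(h, 1), n)
  lo <- floor(h)
  hi <- pmin(lo + 1, n)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Posterior density of the reporting-rate ratio under a two-component
# Gamma-mixture prior, for quadrature cross-checks of EBGM / EBGM05.
oracle_posterior_density <- function(n, e, prior) {
  w1 <- prior$p *
    dnbinom(n, size = prior$alpha1, prob = prior$beta1 / (prior$beta1 + e))
  w2 <- (1 - prior$p) *
    dnbinom(n, size = prior$alpha2, prob = prior$beta2 / (prior$beta2 + e))
  q <- w1 / (w1 + w2)
  function(l)
    q * dgamma(l, prior$alpha1 + n, prior$beta1 + e) +
      (1 - q) * dgamma(l, prior$alpha2 + n, prior$beta2 + e)
}

oracle_ebgm <- function(n, e, prior) {
  dens <- oracle_posterior_density(n, e, prior)
  s <- c(prior$alpha1 + n, prior$alpha2 + n)
  r <- c(prior$beta1 + e, prior$beta2 + e)
  pts <- c(0, sort(unique(pmax(s - 1, 0.01) / r)), Inf)
  val <- sum(vapply(seq_len(length(pts) - 1), function(i)
    integrate(function(l) log(l) * dens(l), pts[i], pts[i + 1],
              rel.tol = 1e-11)$value, numeric(1)))
  exp(val)
}

oracle_ebgm05 <- function(n, e, prior) {
  dens <- oracle_posterior_density(n, e, prior)
  s <- c(prior$alpha1 + n, prior$alpha2 + n)
  r <- c(prior$beta1 + e, prior$beta2 + e)
  # split the quadrature at the component modes so the adaptive rule never
  # steps over a narrow posterior spike; components bound the bracket
  knots <- sort(unique(pmax(s - 1, 0.01) / r))
  cdf <- function(x) {
    pts <- c(0, knots[knots < x], x)
    sum(vapply(seq_len(length(pts) - 1), function(i)
      integrate(dens, pts[i], pts[i + 1], rel.tol = 1e-11)$value,
      numeric(1))) - 0.05
  }
  lo <- min(qgamma(1e-6, s, r))
  hi <- max(qgamma(0.999, s, r))
  uniroot(cdf, c(lo, hi), tol = 1e-12)$root
}
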
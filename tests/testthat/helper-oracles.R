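# Independent oracles used across the test files.  These deliberately avoid
# the package's own quadrature and log-space code paths.

# Dense trapezoidal integration of a (vectorised) integrand on [lo, hi].
trapz_integral <- function(f, lo, hi, n = 1e5) {
  x <- seq(lo, hi, length.out = n)
  y <- f(x)
  sum((y[-1] + y[-n]) / 2) * (x[2] - x[1])
}

# Marginal log-likelihood of one study under a one-random-effect binomial
# model, by dense-grid integration over the standardised random effect z.
# eta_fun(z) must return a 2-column matrix of (control, treated) logits.
grid_study_loglik <- function(e0, n0, e1, n1, eta_fun, lo = -10, hi = 10,
                              n = 1e5) {
  f <- function(z) {
    eta <- eta_fun(z)
    dbinom(e0, n0, plogis(eta[, 1])) * dbinom(e1, n1, plogis(eta[, 2])) *
      dnorm(z)
  }
  log(trapz_integral(f, lo, hi, n))
}

# Direct evaluation of the noncentral hypergeometric pmf from exact binomial
# coefficients (choose() is exact well beyond these table sizes), with the
# sum taken in plain arithmetic -- no log-space tricks.
nchg_pmf_direct <- function(e, n1, n0, t, theta) {
  supp <- max(0, t - n0):min(t, n1)
  w <- choose(n1, supp) * choose(n0, t - supp) * exp(theta * supp)
  choose(n1, e) * choose(n0, t - e) * exp(theta * e) / sum(w)
}

# Central hypergeometric mean and variance by exhaustive summation.
hyper_moments_direct <- function(n1, n0, t) {
  supp <- max(0, t - n0):min(t, n1)
  p <- dhyper(supp, n1, n0, t)
  mu <- sum(p * supp)
  list(mu = mu, var = sum(p * (supp - mu)^2))
}

# A small heterogeneous dataset used by several fitting tests.
synth_dataset <- function(k = 5, seed = 11, n = 80, p0 = 0.25,
                          theta = 0.6, tau = 0.4) {
  withr::with_seed(seed, {
    lo_c <- qlogis(p0) + rnorm(k, 0, 0.3)
    lo_t <- lo_c + theta + tau * rnorm(k)
    e0 <- rbinom(k, n, plogis(lo_c))
    e1 <- rbinom(k, n, plogis(lo_t))
    meta_2x2(seq_len(k), A = e1, B = n - e1, C = e0, D = n - e0,
             label = "synthetic")
  })
}

table1_long <- data.frame(
  study = rep(1:4, each = 2), treat = rep(0:1, 4),
  n = c(377, 377, 40, 41, 100, 101, 1010, 1001),
  event = c(113, 128, 4, 6, 20, 22, 201, 241))
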
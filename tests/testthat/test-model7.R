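o1 <- measles_data(1)
o2 <- measles_data(2)
o4 <- measles_data(4)

test_that("noncentral hypergeometric pmf is exact, central at 0, normalised", {
  # theta = 0 reduces to the central hypergeometric distribution
  e <- 0:4
  expect_equal(nchg_logpmf(e, n1 = 10, n0 = 10, t = 4, theta = 0),
               dhyper(e, 10, 10, 4, log = TRUE), tolerance = 1e-12)
  # direct-arithmetic evaluation on a moderate-margin table
  supp <- 0:10
  expect_equal(exp(nchg_logpmf(supp, n1 = 41, n0 = 40, t = 10, theta = 0.5)),
               nchg_pmf_direct(supp, 41, 40, 10, 0.5), tolerance = 1e-12)
  # normalisation over the support, including large margins
  withr::with_seed(2, {
    for (i in 1:20) {
      n1 <- sample(2:60, 1); n0 <- sample(2:60, 1)
      t <- sample(1:(n1 + n0 - 1), 1)
      th <- runif(1, -3, 3)
      s <- max(0, t - n0):min(t, n1)
      expect_equal(sum(exp(nchg_logpmf(s, n1, n0, t, th))), 1,
                   tolerance = 1e-12)
    }
  })
  s <- max(0, 300 - 4000):min(300, 6000)
  expect_equal(sum(exp(nchg_logpmf(s, 6000, 4000, 300, 1.2))), 1,
               tolerance = 1e-12)
  expect_error(nchg_logpmf(11, n1 = 10, n0 = 10, t = 21, theta = 0), "support")
})

test_that("the conditional mean increases strictly with the log odds ratio", {
  th <- seq(-3, 3, by = 0.25)
  mu <- vapply(th, function(x) nchg_moments(41, 40, 10, x)$mu, 0)
  expect_true(all(diff(mu) > 0))
})

test_that("conditional likelihood collapses at tau = 0 and matches a grid", {
  th <- -0.4
  ll0 <- cm_el_loglik(o2, th, 0)
  direct <- sum(vapply(seq_len(nrow(o2)), function(i) {
    n1 <- o2$A[i] + o2$B[i]; n0 <- o2$C[i] + o2$D[i]; t <- o2$A[i] + o2$C[i]
    nchg_logpmf(o2$A[i], n1, n0, t, th)
  }, 0))
  expect_equal(ll0, direct, tolerance = 1e-10)
  # one small study with heterogeneity, against dense trapezoidal integration
  tab <- meta_2x2(1, A = 6, B = 35, C = 4, D = 36)
  got <- cm_el_loglik(tab, 0.3, 0.3)
  f <- function(z) vapply(z, function(zz)
    exp(nchg_logpmf(6, 41, 40, 10, 0.3 + 0.3 * zz)), 0) * dnorm(z)
  expect_equal(got, log(trapz_integral(f, -8, 8)), tolerance = 1e-8)
  # degenerate studies contribute nothing for any parameter value
  dz <- meta_2x2(1:2, A = c(0, 10), B = c(195, 0), C = c(0, 8), D = c(180, 0))
  expect_equal(cm_el_loglik(dz, -1, 0.5), 0)
  expect_equal(cm_el_loglik(dz, 2, 0.01), 0)
  with_dz <- rbind(as.data.frame(o2),
                   data.frame(study = "dz", A = 0, B = 50, C = 0, D = 40))
  expect_equal(cm_el_loglik(as_meta_2x2(with_dz), 0.2, 0.4),
               cm_el_loglik(o2, 0.2, 0.4), tolerance = 1e-12)
})

test_that("the exact conditional fit reproduces the measles-review results", {
  f2 <- fit_cm_el(o2)
  expect_equal(f2$theta, -0.635, tolerance = 0.02)
  expect_equal(f2$se, 0.416, tolerance = 0.02)
  expect_equal(f2$tau2, 0.099, tolerance = 0.02)
  # the double-zero study cannot change the fit
  f4 <- fit_cm_el(o4)
  f4b <- fit_cm_el(drop_double_zero(o4))
  expect_equal(f4$theta, f4b$theta, tolerance = 1e-6)
  expect_equal(f4$tau2, f4b$tau2, tolerance = 1e-6)
  expect_equal(f4$theta, -0.793, tolerance = 0.02)
})

test_that("homogeneous conditional data give a near-zero heterogeneity", {
  withr::with_seed(31, {
    k <- 8; n <- 200
    e0 <- rbinom(k, n, 0.15); e1 <- rbinom(k, n, plogis(qlogis(0.15) + 0.4))
    ds <- meta_2x2(1:k, e1, n - e1, e0, n - e0)
  })
  f <- fit_cm_el(ds, se = FALSE)
  expect_lt(f$tau2, 0.05)
  expect_lt(abs(f$theta - 0.4), 0.3)
})

test_that("the binomial approximation tracks the exact conditional model", {
  # rare events: the approximation is close
  withr::with_seed(55, {
    k <- 10; n <- 300
    e0 <- rbinom(k, n, 0.01)
    e1 <- rbinom(k, n, plogis(qlogis(0.01) + 0.5))
    rare <- meta_2x2(1:k, e1, n - e1, e0, n - e0)
    e0c <- rbinom(k, n, 0.2)
    e1c <- rbinom(k, n, plogis(qlogis(0.2) + 0.5))
    common <- meta_2x2(1:k, e1c, n - e1c, e0c, n - e0c)
  })
  d_rare <- abs(fit_cm_al(rare, se = FALSE)$theta -
                fit_cm_el(rare, se = FALSE)$theta)
  d_common <- abs(fit_cm_al(common, se = FALSE)$theta -
                  fit_cm_el(common, se = FALSE)$theta)
  expect_lt(d_rare, 0.05)
  expect_lt(d_rare, d_common)
  # a zero-event study contributes a constant: the fit is unchanged
  with0 <- rbind(as.data.frame(rare),
                 data.frame(study = "z", A = 0, B = 100, C = 0, D = 100))
  expect_equal(fit_cm_al(as_meta_2x2(with0), se = FALSE)$theta,
               fit_cm_al(rare, se = FALSE)$theta, tolerance = 1e-6)
})

test_that("the one-step estimator equals the fixed-effect Peto pool", {
  one <- peto_one_step(meta_2x2(1, A = 6, B = 35, C = 4, D = 36))
  eff <- peto_effects(meta_2x2(1, A = 6, B = 35, C = 4, D = 36),
                      zero_rule = "none")
  expect_equal(one$theta, eff$y, tolerance = 1e-12)
  expect_equal(one$se, sqrt(eff$v), tolerance = 1e-12)
  # algebraic identity: one step = inverse-variance pool of Peto effects
  effs <- peto_effects(o1, zero_rule = "none")
  pool <- sum(effs$y / effs$v) / sum(1 / effs$v)
  expect_equal(peto_one_step(o1)$theta, pool, tolerance = 1e-12)
  # null data
  null <- meta_2x2(1:2, A = c(4, 8), B = c(16, 12), C = c(4, 8),
                   D = c(16, 12))
  expect_equal(peto_one_step(null)$theta, 0, tolerance = 1e-12)
  dz <- meta_2x2(1, A = 0, B = 10, C = 0, D = 10)
  expect_error(peto_one_step(dz), "non-degenerate")
})

test_that("the Peto random-effects approximation matches the review values", {
  p1 <- peto_approximation(o1)
  expect_equal(p1$theta, -0.914, tolerance = 1e-3)
  expect_equal(p1$se, 0.595, tolerance = 1e-3)
  expect_equal(p1$tau2, 1.949, tolerance = 1e-3)
  p4 <- peto_approximation(o4)
  expect_equal(p4$theta, -0.747, tolerance = 1e-3)
  expect_equal(p4$tau2, 0, tolerance = 1e-6)
  p4b <- peto_approximation(drop_double_zero(o4))
  expect_equal(p4b$theta, -0.769, tolerance = 1e-3)
  expect_equal(p4b$tau2, 0, tolerance = 1e-6)
  # homogeneous data: zero heterogeneity
  hom <- meta_2x2(1:3, A = c(20, 21, 19), B = c(80, 79, 81),
                  C = c(20, 20, 20), D = c(80, 80, 80))
  expect_equal(peto_approximation(hom)$tau2, 0, tolerance = 1e-8)
  expect_error(peto_approximation(meta_2x2(1, 5, 5, 5, 5)), "two studies")
})

test_that("the batch standard-error repair policy follows its thresholds", {
  peto <- list(theta = -0.6, se = 0.4, tau2 = 0.1)
  keep <- list(theta = -0.5, se = 0.5, tau2 = 0.1)
  expect_false(ormeta:::model7_repair(keep, peto)$se_repaired)
  small <- list(theta = -0.5, se = 0.1, tau2 = 0.1)
  r <- ormeta:::model7_repair(small, peto)
  expect_true(r$se_repaired); expect_equal(r$se, 0.4)
  large <- list(theta = -0.5, se = 17.5, tau2 = 0.1)
  r <- ormeta:::model7_repair(large, peto)
  expect_true(r$se_repaired); expect_equal(r$se, 0.4)
  biggish <- list(theta = -0.5, se = 1.2, tau2 = 0.1)  # 3x peto: retained
  expect_false(ormeta:::model7_repair(biggish, peto)$se_repaired)
  missing <- list(theta = -0.5, se = NA_real_, tau2 = 0.1)
  expect_true(ormeta:::model7_repair(missing, peto)$se_repaired)
})
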
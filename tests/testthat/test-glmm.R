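o1 <- measles_data(1)
o2 <- measles_data(2)
o4 <- measles_data(4)

test_that("study likelihoods degenerate to plain binomials and factorise", {
  dat <- ormeta:::glmm_data(o2)
  k <- dat$k
  g <- qlogis((dat$e0 + 0.5) / (dat$n0 + 1)); th <- 0.4
  # vanishing random effects: the integral collapses onto the fixed logits
  for (m in c(2L, 4L)) {
    got <- ormeta:::glmm_study_loglik(m, dat, list(gamma = g, theta = th,
                                                   tau = 1e-12), 7)
    want <- dbinom(dat$e0, dat$n0, plogis(g), log = TRUE) +
      dbinom(dat$e1, dat$n1, plogis(g + th), log = TRUE)
    expect_equal(got, want, tolerance = 1e-8)
  }
  # model 6 with rho = 0 and equal variances separates into two 1-D integrals
  s <- 0.35
  got6 <- ormeta:::glmm_study_loglik(6L, dat, list(gamma = -1.8, theta = th,
                                                   L11 = s, L21 = 0, L22 = s), 9)
  sep <- vapply(seq_len(k), function(i) {
    f0 <- function(u) dbinom(dat$e0[i], dat$n0[i], plogis(-1.8 + u)) *
      dnorm(u, 0, s)
    f1 <- function(u) dbinom(dat$e1[i], dat$n1[i], plogis(-1.8 + th + u)) *
      dnorm(u, 0, s)
    log(trapz_integral(f0, -8 * s, 8 * s)) +
      log(trapz_integral(f1, -8 * s, 8 * s))
  }, 0)
  expect_equal(got6, sep, tolerance = 1e-6)
})

test_that("adaptive quadrature matches dense-grid integration", {
  # study 2 of the illustrative data under model 2 at (gamma, theta, tau2)
  # = (-2, 0.3, 0.1)
  dat <- ormeta:::glmm_data(long_to_wide(table1_long))
  i <- 2L
  tau <- sqrt(0.1)
  one <- list(e0 = dat$e0[i], n0 = dat$n0[i], e1 = dat$e1[i],
              n1 = dat$n1[i], k = 1L)
  got <- ormeta:::glmm_study_loglik(2L, one, list(gamma = -2, theta = 0.3,
                                                  tau = tau), 15)
  want <- grid_study_loglik(one$e0, one$n0, one$e1, one$n1,
                            function(z) cbind(-2, -2 + 0.3 + tau * z),
                            lo = -8, hi = 8)
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("mixed-model fits reproduce the measles-review results", {
  m2 <- fit_glmm(o1, 2)
  expect_equal(m2$theta, -1.236, tolerance = 0.02)
  expect_equal(m2$se, 0.782, tolerance = 0.02)
  expect_equal(m2$tau2, 3.224, tolerance = 0.05)
  expect_true(m2$converged)
  m4 <- fit_glmm(o2, 4)
  expect_equal(m4$theta, -0.629, tolerance = 0.02)
  expect_equal(m4$se, 0.402, tolerance = 0.02)
  m6 <- fit_glmm(o4, 6, drop00 = "false")
  expect_equal(m6$tau2, 0.197, tolerance = 0.02)
  expect_equal(unname(m6$varcomp["rho"]), 1, tolerance = 1e-3)
  m6b <- fit_glmm(o4, 6, drop00 = "true")
  expect_equal(m6b$theta, -0.856, tolerance = 0.02)
  expect_equal(m6b$tau2, 0.004, tolerance = 0.02)
})

test_that("fits agree with the reference mixed-model software", {
  skip_if_not_installed("lme4")
  long <- wide_to_long(o2)
  ref <- lme4::glmer(cbind(event, n - event) ~ factor(study) + factor(treat) +
                       (treat - 1 | study),
                     data = long, family = binomial, nAGQ = 7)
  m2 <- fit_glmm(o2, 2)
  expect_equal(m2$theta, lme4::fixef(ref)[["factor(treat)1"]],
               tolerance = 2e-3)
  expect_equal(m2$tau2, as.numeric(lme4::VarCorr(ref)$study),
               tolerance = 2e-2)
  ref3 <- lme4::glmer(cbind(event, n - event) ~ (1 | study) + factor(treat) +
                        (treat - 1 | study),
                      data = long, family = binomial)
  m3 <- fit_glmm(o2, 3, drop00 = "false")
  expect_equal(m3$theta, lme4::fixef(ref3)[["factor(treat)1"]],
               tolerance = 5e-3)
  ref5 <- lme4::glmer(cbind(event, n - event) ~ (1 | study) + factor(treat) +
                        (treat12 - 1 | study),
                      data = long, family = binomial)
  m5 <- fit_glmm(o2, 5, drop00 = "false")
  expect_equal(m5$theta, lme4::fixef(ref5)[["factor(treat)1"]],
               tolerance = 5e-3)
})

test_that("centring the fixed treatment term is a pure reparameterisation", {
  chk <- reparam_check(o2, 4)
  expect_true(chk$pass)
  expect_lt(chk$delta_theta, 1e-4)
  chk5 <- reparam_check(o4, 5)
  expect_true(chk5$pass)
  syn <- synth_dataset(k = 5, seed = 17)
  expect_true(reparam_check(syn, 4)$pass)
})

test_that("the bivariate model nests the structured random-baseline models", {
  for (ds in list(o1, o2)) {
    ll6 <- fit_glmm(ds, 6, se = FALSE)$loglik
    expect_gte(ll6 + 1e-4, fit_glmm(ds, 3, se = FALSE)$loglik)
    expect_gte(ll6 + 1e-4, fit_glmm(ds, 5, se = FALSE)$loglik)
  }
})

test_that("fixed-baseline fits are invariant to double-zero studies", {
  for (m in c(2, 4)) {
    keep <- fit_glmm(o4, m, drop00 = "false")
    drop <- fit_glmm(o4, m, drop00 = "true")
    expect_equal(keep$theta, drop$theta, tolerance = 1e-3)
    expect_equal(keep$se, drop$se, tolerance = 1e-3)
    expect_equal(keep$tau2, drop$tau2, tolerance = 1e-3)
  }
  # random-baseline fits are not (recovery of intertrial information)
  m6_keep <- fit_glmm(o4, 6, drop00 = "false", se = FALSE)
  m6_drop <- fit_glmm(o4, 6, drop00 = "true", se = FALSE)
  expect_gt(abs(m6_keep$tau2 - m6_drop$tau2), 0.1)
})

test_that("seven quadrature nodes are enough on the fixtures", {
  for (spec in list(list(ds = o1, m = 2), list(ds = o2, m = 4))) {
    t7 <- fit_glmm(spec$ds, spec$m, n_agq = 7, se = FALSE)$theta
    t15 <- fit_glmm(spec$ds, spec$m, n_agq = 15, se = FALSE)$theta
    expect_lt(abs(t7 - t15), 1e-3)
  }
})

test_that("swapping the arms mirrors the fit for symmetric codings", {
  swap <- function(ds) meta_2x2(ds$study, ds$C, ds$D, ds$A, ds$B)
  for (m in c(4, 6)) {
    f <- fit_glmm(o2, m, se = FALSE)
    g <- fit_glmm(swap(o2), m, se = FALSE)
    expect_equal(g$theta, -f$theta, tolerance = 2e-3)
    expect_equal(g$tau2, f$tau2, tolerance = 2e-3)
  }
})

test_that("the fitted summary effect is recovered on simulated data", {
  # data generated under model 4: k studies, balanced arms, centred slope
  withr::with_seed(101, {
    est <- replicate(60, {
      k <- 12; n <- 300
      base <- rnorm(k, qlogis(0.2), 0.3)
      del <- log(2) + sqrt(0.1) * rnorm(k)
      e0 <- rbinom(k, n, plogis(base - del / 2))
      e1 <- rbinom(k, n, plogis(base + del / 2))
      fit_glmm(meta_2x2(1:k, e1, n - e1, e0, n - e0), 4, se = FALSE)$theta
    })
  })
  mcse <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - log(2)), 3 * mcse)
})
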
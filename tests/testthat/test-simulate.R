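test_that("settings encode the design grid", {
  expect_equal(sim_setting(1)$tau2, 0.024)
  expect_equal(sim_setting(2)$tau2, 0)
  expect_equal(sim_setting(3)$tau2, 0.168)
  expect_equal(vapply(c(4, 5, 6), function(s) sim_setting(s)$k, 0), c(3, 5, 20))
  expect_equal(sim_setting(7)[c("n_lo", "n_hi")], list(n_lo = 10L, n_hi = 100L))
  expect_equal(sim_setting(8)$baseline$mean, qlogis(0.05))
  expect_equal(sim_setting(9)$baseline$mean, qlogis(0.01))
  expect_equal(sim_setting(13)$baseline$type, "Pc_unif")
  expect_equal(sim_setting(14)$baseline$type, "LOa")
  expect_equal(sim_setting(15)$tau2, 2)
  expect_equal(sim_setting(15)$baseline$mean, qlogis(0.5))
  expect_error(sim_setting(16), "1..15")
})

test_that("the generator reproduces its target moments", {
  s <- sim_setting(1)
  s$k <- 10000L
  withr::with_seed(3, d <- simulate_meta(s))
  tr <- attr(d, "truth")
  # bounds are ~4 standard errors of the sample moments at k = 10000
  expect_lt(abs(mean(tr$lo_c) - qlogis(0.2)), 0.012)
  expect_lt(abs(sd(tr$lo_c) - 0.3), 0.012)
  expect_lt(abs(var(tr$lo_t - tr$lo_c) - 0.024), 0.024 * 0.1)
  expect_true(all(tr$n0 == tr$n1))
  expect_true(all(tr$n1 >= 50 & tr$n1 <= 500))
  # null setting: both arms share one true probability in every study
  s2 <- sim_setting(2); s2$k <- 50L
  withr::with_seed(3, d2 <- simulate_meta(s2))
  tr2 <- attr(d2, "truth")
  expect_equal(tr2$lo_t, tr2$lo_c)
  # centred parameterisation: effect split across both arms
  s14 <- sim_setting(14, theta = log(2)); s14$k <- 5000L
  withr::with_seed(3, d14 <- simulate_meta(s14))
  tr14 <- attr(d14, "truth")
  expect_equal(mean((tr14$lo_t + tr14$lo_c) / 2), qlogis(0.2), tolerance = 0.02)
  expect_equal(mean(tr14$lo_t - tr14$lo_c), log(2), tolerance = 0.02)
})

test_that("control-arm size rules follow the design", {
  withr::with_seed(8, {
    d10 <- simulate_meta(sim_setting(10))
    tr <- attr(d10, "truth")
    expect_equal(tr$n0, floor(tr$n1 / 2 + 0.5))
    d11 <- simulate_meta(sim_setting(11))
    tr11 <- attr(d11, "truth")
    expect_equal(tr11$n0[1:5], tr11$n1[1:5])
    expect_equal(tr11$n0[6:10], floor(tr11$n1[6:10] / 2 + 0.5))
    d12 <- simulate_meta(sim_setting(12))
    tr12 <- attr(d12, "truth")
    small_risk <- rank(plogis(tr12$lo_c), ties.method = "first") <= 5
    expect_equal(tr12$n0[small_risk], tr12$n1[small_risk])
    expect_equal(tr12$n0[!small_risk],
                 floor(tr12$n1[!small_risk] / 2 + 0.5))
  })
})

test_that("the design diagnostic variance matches its closed form", {
  expect_equal(typical_within_variance(275, 0.2), 2 / (275 * 0.2 * 0.8))
  expect_equal(round(typical_within_variance(275, 0.2), 2), 0.05)
  expect_equal(typical_within_variance(275, 0.5), 2 / 68.75)
  expect_lt(typical_within_variance(1e9, 0.2), 1e-7)
})

test_that("the study driver is reproducible and shapes its output correctly", {
  a <- run_study(settings = 1, models = "1-DL", n_reps = 40, seed = 9)
  b <- run_study(settings = 1, models = "1-DL", n_reps = 40, seed = 9)
  expect_identical(a, b)
  c <- run_study(settings = 1, models = "1-DL", n_reps = 40, seed = 10)
  expect_false(identical(a$mean_theta_hat, c$mean_theta_hat))
  grid <- run_study(settings = 1:3, models = c("1-DL", "1-REML"),
                    n_reps = 5, seed = 1, se = FALSE)
  expect_equal(nrow(grid), 6)
  expect_equal(grid$mcse_mean, grid$emp_se / sqrt(grid$n_reps))
  one <- run_study(settings = 1, models = "1-DL", n_reps = 1, seed = 2)
  expect_true(is.na(one$emp_se))
  expect_equal(one$n_reps, 1L)
})

test_that("replicate failures are recorded per model, not fatal", {
  # k = 3 with tau2 = 0 occasionally yields fully homogeneous datasets; use
  # a model id on a dataset engineered to fail: single-study GLMM refusal
  out <- run_study(settings = 4, models = c("1-DL", "4"), n_reps = 30,
                   seed = 5, se = FALSE)
  expect_equal(nrow(out), 2)
  fails <- attr(out, "failures")
  expect_true(is.data.frame(fails))
  expect_true(all(out$n_reps + out$n_fail_point == 30))
})

test_that("coverage is conservative under homogeneity", {
  # no between-study variation: nominal 95% intervals over-cover
  out <- run_study(settings = 2, models = c("1-DL", "4"), n_reps = 200,
                   seed = 1)
  expect_true(all(out$coverage_95 >= 0.93))
})

test_that("fixed-baseline slope codings order the heterogeneity estimates", {
  # model 4's estimate exceeds model 2's by about the within-arm variance
  set.seed(ormeta:::derive_seed(1, 1, 0))
  s <- sim_setting(1)
  dats <- lapply(1:150, function(i) simulate_meta(s))
  t2 <- vapply(dats, function(d) c(fit_glmm(d, 2, se = FALSE)$tau2,
                                   fit_glmm(d, 4, se = FALSE)$tau2),
               c(0, 0))
  expect_gte(mean(t2[2, ] >= t2[1, ] - 1e-8), 0.95)
  d <- mean(t2[2, ] - t2[1, ])
  expect_gt(d, 0.01)
  expect_lt(d, 0.03)
})
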
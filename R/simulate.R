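# Simulation engine: generative settings for evaluating the models, and a
# driver that computes bias, precision and coverage metrics.

#' Define a simulation setting
#'
#' Returns an executable description of one of the 15 generative settings
#' used to evaluate the models.  The defaults (setting 1) are: k = 10
#' studies; between-study variance 0.024; treated-arm sizes drawn from a
#' discrete uniform on 50..500 with equal control arms; control-group log
#' odds drawn from N(logit(0.2), 0.3^2).  The other settings change one
#' default at a time (two for setting 15):
#'
#' * 2, 3: between-study variance 0 and 0.168.
#' * 4, 5, 6: k = 3, 5, 20.
#' * 7: small studies, sizes 10..100.
#' * 8, 9: rarer events, baseline logit(0.05) and logit(0.01).
#' * 10: all control arms have N/2 patients.
#' * 11: the first k/2 simulated studies keep control arms of size N, the
#'   remainder get N/2.
#' * 12: the k/2 studies with the smallest true control-group risks keep
#'   control arms of size N, the remainder get N/2 (a non-random
#'   allocation designed to provoke recovery of intertrial information).
#' * 13: control-group probabilities uniform on (0.1, 0.3) (misspecifies
#'   the normal-baseline models).
#' * 14: the average log odds across arms is N(logit(0.2), 0.3^2) and half
#'   the treatment effect is added/subtracted per arm (data generated under
#'   the centred-slope models).
#' * 15: between-study variance 2 with baseline logit(0.5) (extreme
#'   heterogeneity).
#'
#' @param setting integer 1-15.
#' @param theta true summary log odds ratio (0 or log 2 in the reference
#'   design; any value is accepted).
#' @return A list of class `"sim_setting"` with the generative parameters.
#' @examples
#' sim_setting(9, theta = log(2))
#' @export
sim_setting <- function(setting = 1, theta = 0) {
  setting <- as.integer(setting)
  if (!setting %in% 1:15)
    stop("'setting' must be an integer in 1..15", call. = FALSE)
  s <- list(setting = setting, theta = theta, k = 10L, tau2 = 0.024,
            n_lo = 50L, n_hi = 500L, control_rule = "equal",
            baseline = list(type = "LOc", mean = stats::qlogis(0.2), sd = 0.3))
  if (setting == 2L) s$tau2 <- 0
  if (setting == 3L) s$tau2 <- 0.168
  if (setting == 4L) s$k <- 3L
  if (setting == 5L) s$k <- 5L
  if (setting == 6L) s$k <- 20L
  if (setting == 7L) { s$n_lo <- 10L; s$n_hi <- 100L }
  if (setting == 8L) s$baseline$mean <- stats::qlogis(0.05)
  if (setting == 9L) s$baseline$mean <- stats::qlogis(0.01)
  if (setting == 10L) s$control_rule <- "half"
  if (setting == 11L) s$control_rule <- "half_split"
  if (setting == 12L) s$control_rule <- "half_ranked"
  if (setting == 13L) s$baseline <- list(type = "Pc_unif", lo = 0.1, hi = 0.3)
  if (setting == 14L) s$baseline$type <- "LOa"
  if (setting == 15L) { s$tau2 <- 2; s$baseline$mean <- stats::qlogis(0.5) }
  class(s) <- "sim_setting"
  s
}

round_half_up <- function(x) floor(x + 0.5)

#' Simulate one meta-analytic dataset from a setting
#'
#' Draws study sizes, true arm probabilities and binomial event counts from
#' the generative process of a [sim_setting], using the current RNG state.
#' The treated-arm log odds are `LO_c + theta + tau * Z` with `Z ~ N(0,1)`
#' (or, under the `"LOa"` baseline, half the effect is added to and
#' subtracted from the average log odds).
#'
#' @param setting a [sim_setting] (or an integer passed to [sim_setting]).
#' @param theta used when `setting` is given as an integer.
#' @return A [meta_2x2] dataset with one row per simulated study.
#' @examples
#' set.seed(1)
#' simulate_meta(sim_setting(1))
#' @export
simulate_meta <- function(setting = 1, theta = 0) {
  s <- if (inherits(setting, "sim_setting")) setting
       else sim_setting(setting, theta)
  k <- s$k
  N <- sample(s$n_lo:s$n_hi, k, replace = TRUE)
  delta <- s$theta + sqrt(s$tau2) * stats::rnorm(k)
  b <- s$baseline
  if (b$type == "LOc") {
    lo_c <- stats::rnorm(k, b$mean, b$sd)
    lo_t <- lo_c + delta
  } else if (b$type == "Pc_unif") {
    lo_c <- stats::qlogis(stats::runif(k, b$lo, b$hi))
    lo_t <- lo_c + delta
  } else {                                   # LOa: centred parameterisation
    lo_a <- stats::rnorm(k, b$mean, b$sd)
    lo_c <- lo_a - delta / 2
    lo_t <- lo_a + delta / 2
  }
  n1 <- N
  n0 <- switch(s$control_rule,
    equal = N,
    half = round_half_up(N / 2),
    half_split = ifelse(seq_len(k) <= k / 2, N, round_half_up(N / 2)),
    half_ranked = ifelse(rank(stats::plogis(lo_c), ties.method = "first") <= k / 2,
                         N, round_half_up(N / 2)))
  e1 <- stats::rbinom(k, n1, stats::plogis(lo_t))
  e0 <- stats::rbinom(k, n0, stats::plogis(lo_c))
  out <- meta_2x2(study = seq_len(k), A = e1, B = n1 - e1, C = e0,
                  D = n0 - e0,
                  label = sprintf("setting %d simulation", s$setting))
  attr(out, "truth") <- data.frame(lo_c = lo_c, lo_t = lo_t, n1 = n1,
                                   n0 = n0)
  out
}

#' Representative within-study variance of a log odds ratio
#'
#' Design diagnostic: `2 / (n * p * (1 - p))`, the approximate within-study
#' variance of an estimated log odds ratio from a balanced study with `n`
#' patients per arm and event probability `p` in both arms.
#'
#' @param n_per_arm patients per arm.
#' @param p event probability.
#' @return The approximate variance.
#' @examples
#' typical_within_variance(275, 0.2)
#' @export
typical_within_variance <- function(n_per_arm, p) {
  stopifnot(n_per_arm > 0, p > 0, p < 1)
  2 / (n_per_arm * p * (1 - p))
}

# Deterministic per-(setting, theta) stream seed below 2^31.
derive_seed <- function(seed, setting, theta) {
  (abs(as.integer(seed)) %% 99991L) * 21000L + as.integer(setting) * 2L +
    as.integer(theta != 0)
}

#' Run a simulation study
#'
#' Simulates `n_reps` datasets per (setting, theta) cell and fits the
#' requested models to the *same* datasets, then computes the evaluation
#' metrics: mean point estimates, empirical standard errors, Monte-Carlo
#' standard errors, mean heterogeneity estimates, 95% Wald coverage, the
#' average model-based standard error as a percentage of the empirical one,
#' and failure counts.  A replicate on which a model fails is discarded for
#' that model only.  Model `"7"` standard errors are repaired with the Peto
#' approximation (missing, < 50% of the Peto SE, or > 10 times it).
#'
#' Each (setting, theta) cell uses its own RNG stream derived from the
#' master seed, so single cells re-run identically in isolation.
#'
#' @param settings integer vector of setting ids (1-15).
#' @param models character vector of model ids (see [or_models]).
#' @param n_reps replicates per cell.
#' @param theta vector of true summary log odds ratios.
#' @param seed master seed.
#' @param n_agq,drop00,control passed to the model fitters.
#' @param se compute model standard errors (needed for coverage; switch off
#'   to speed up bias-only runs, in which case coverage is `NA`).
#' @param keep_estimates also return the per-replicate estimates.
#' @return A data frame of metrics, one row per (setting, theta, model),
#'   with attributes `"failures"` (a data frame describing failed
#'   replicates) and, if requested, `"estimates"`.
#' @examples
#' run_study(settings = 1, models = "1-DL", n_reps = 25, seed = 1)
#' @export
run_study <- function(settings = 1, models = "1-DL", n_reps = 200,
                      theta = 0, seed = 1, n_agq = NULL,
                      drop00 = c("auto", "true", "false"), se = TRUE,
                      control = list(), keep_estimates = FALSE) {
  drop00 <- match.arg(drop00)
  models <- match.arg(as.character(models), or_models(), several.ok = TRUE)
  rows <- list(); fails <- list(); ests <- list()
  for (st in settings) for (th in theta) {
    set.seed(derive_seed(seed, st, th))
    s <- sim_setting(st, th)
    datasets <- lapply(seq_len(n_reps), function(i) simulate_meta(s))
    for (m in models) {
      est <- data.frame(rep = seq_len(n_reps), theta = NA_real_,
                        se = NA_real_, tau2 = NA_real_, repaired = FALSE)
      for (i in seq_len(n_reps)) {
        fit <- tryCatch(
          fit_model_by_id(m, datasets[[i]], n_agq = n_agq, drop00 = drop00,
                          se = se, control = control),
          error = function(e) e)
        if (inherits(fit, "error")) {
          fails[[length(fails) + 1L]] <-
            data.frame(setting = st, theta = th, model = m, rep = i,
                       message = conditionMessage(fit))
          next
        }
        if (m == "7" && se) {
          peto <- tryCatch(peto_approximation(datasets[[i]]),
                           error = function(e) NULL)
          if (!is.null(peto)) {
            fit <- model7_repair(fit, peto)
            est$repaired[i] <- isTRUE(fit$se_repaired)
          }
        }
        est$theta[i] <- fit$theta; est$se[i] <- fit$se
        est$tau2[i] <- fit$tau2
      }
      ok <- is.finite(est$theta)
      n_ok <- sum(ok)
      emp_se <- if (n_ok >= 2) stats::sd(est$theta[ok]) else NA_real_
      cover <- if (se) {
        okse <- ok & is.finite(est$se)
        if (any(okse))
          mean(abs(est$theta[okse] - th) <= stats::qnorm(0.975) * est$se[okse])
        else NA_real_
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        setting = st, theta = th, model = m,
        mean_theta_hat = if (n_ok) mean(est$theta[ok]) else NA_real_,
        emp_se = emp_se,
        mcse_mean = if (is.finite(emp_se)) emp_se / sqrt(n_ok) else NA_real_,
        mean_tau2_hat = if (n_ok) mean(est$tau2[ok]) else NA_real_,
        emp_se_tau2 = if (n_ok >= 2) stats::sd(est$tau2[ok]) else NA_real_,
        coverage_95 = cover,
        mean_model_se_ratio = if (se && is.finite(emp_se))
          100 * mean(est$se[ok & is.finite(est$se)]) / emp_se else NA_real_,
        n_fail_point = n_reps - n_ok,
        n_fail_se = if (se) sum(ok & !is.finite(est$se)) else NA_integer_,
        n_se_repaired = sum(est$repaired),
        n_reps = n_ok)
      if (keep_estimates) {
        est$setting <- st; est$true_theta <- th; est$model <- m
        ests[[length(ests) + 1L]] <- est
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "failures") <- if (length(fails)) do.call(rbind, fails) else
    data.frame(setting = integer(0), theta = numeric(0),
               model = character(0), rep = integer(0), message = character(0))
  if (keep_estimates) attr(out, "estimates") <- do.call(rbind, ests)
  out
}
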
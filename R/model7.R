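# The hypergeometric-normal model (model 7) and its approximations.
#
# Conditioning each 2x2 table on its total number of events t_i fixes all
# margins, and the treated-event count follows a noncentral hypergeometric
# distribution tilted by exp(theta_i * e_i1).  With theta_i ~ N(theta, tau^2)
# the marginal likelihood integrates the conditional pmf against the normal
# density; the integral is computed in the standardised variable
# z = (theta_i - theta)/tau so that small tau causes no instability.

# Sufficient description of one conditional table: support and central
# log-weights log C(n1, j) + log C(n0, t - j).
cond_table <- function(n1, n0, t) {
  lo <- max(0, t - n0); hi <- min(t, n1)
  if (hi < lo) stop("empty conditional support", call. = FALSE)
  supp <- lo:hi
  list(supp = supp, lw = lchoose(n1, supp) + lchoose(n0, t - supp),
       degenerate = length(supp) == 1L)
}

# log normalising constant, mean and variance of the noncentral
# hypergeometric distribution at log odds ratio x, for one table.
nchg_moments_tab <- function(tab, x) {
  lp <- tab$lw + x * tab$supp
  lz <- logsumexp(lp)
  p <- exp(lp - lz)
  mu <- sum(p * tab$supp)
  list(logz = lz, mu = mu, var = sum(p * (tab$supp - mu)^2))
}

#' Noncentral hypergeometric log-probability
#'
#' Log-pmf of the number of treated events `e` in a 2-by-2 table with arm
#' sizes `n1` (treated) and `n0` (control), conditional on the total number
#' of events `t`, at study log odds ratio `theta`.  Evaluated entirely in
#' log space (log-binomial weights plus a log-sum-exp over the support), so
#' it is stable for large tables.  At `theta = 0` it reduces to the central
#' hypergeometric log-pmf.
#'
#' @param e number of treated events (vectorised; must lie in the support
#'   `max(0, t - n0) ... min(t, n1)`).
#' @param n1,n0 arm sizes.
#' @param t total number of events.
#' @param theta study log odds ratio.
#' @return Log-probabilities, one per element of `e`.
#' @examples
#' exp(nchg_logpmf(2, n1 = 10, n0 = 10, t = 4, theta = 0))
#' dhyper(2, 10, 10, 4)
#' @export
nchg_logpmf <- function(e, n1, n0, t, theta) {
  tab <- cond_table(n1, n0, t)
  if (any(e < min(tab$supp) | e > max(tab$supp)))
    stop("'e' outside the conditional support", call. = FALSE)
  lz <- logsumexp(tab$lw + theta * tab$supp)
  lchoose(n1, e) + lchoose(n0, t - e) + theta * e - lz
}

#' Mean of the noncentral hypergeometric distribution
#'
#' @inheritParams nchg_logpmf
#' @return A list with the mean `mu` and variance `var` of the treated-event
#'   count at log odds ratio `theta`.
#' @export
nchg_moments <- function(n1, n0, t, theta) {
  m <- nchg_moments_tab(cond_table(n1, n0, t), theta)
  list(mu = m$mu, var = m$var)
}

cond_data <- function(ds) {
  ds <- as_meta_2x2(ds)
  lapply(seq_len(nrow(ds)), function(i) {
    n1 <- ds$A[i] + ds$B[i]; n0 <- ds$C[i] + ds$D[i]
    t <- ds$A[i] + ds$C[i]
    tab <- cond_table(n1, n0, t)
    tab$e <- ds$A[i]
    tab$study <- ds$study[i]
    tab
  })
}

# Adaptive GH integral (in z) of one study's conditional likelihood.
cond_study_loglik <- function(tab, theta, tau, n_agq) {
  if (tab$degenerate) return(0)
  lpmf <- function(x) {
    tab$lw[match(tab$e, tab$supp)] + x * tab$e -
      vapply(x, function(xx) logsumexp(tab$lw + xx * tab$supp), 0)
  }
  if (tau < 1e-10) return(lpmf(theta))
  h <- function(z) lpmf(theta + tau * z) - 0.5 * z^2 + .lphi_const
  h1 <- function(z) {
    mu <- vapply(z, function(zz) nchg_moments_tab(tab, theta + tau * zz)$mu, 0)
    tau * (tab$e - mu) - z
  }
  h2 <- function(z) {
    v <- vapply(z, function(zz) nchg_moments_tab(tab, theta + tau * zz)$var, 0)
    -tau^2 * v - 1
  }
  agh1_log(h, h1, h2, n_agq, 1L)
}

#' Conditional (hypergeometric-normal) log-likelihood
#'
#' Log-likelihood of model 7 at `(theta, tau)`: the sum over studies of the
#' log of the noncentral hypergeometric pmf integrated against the
#' N(theta, tau^2) random-effect distribution.  Degenerate studies (total
#' events 0, or events in every subject) have a point-mass conditional
#' distribution and contribute 0 for any parameter value.
#'
#' @param ds a [meta_2x2] dataset.
#' @param theta summary log odds ratio.
#' @param tau between-study standard deviation (>= 0).
#' @param n_agq quadrature nodes (default 7).
#' @return The log-likelihood value.
#' @export
cm_el_loglik <- function(ds, theta, tau, n_agq = 7) {
  stopifnot(tau >= 0)
  tabs <- cond_data(ds)
  sum(vapply(tabs, cond_study_loglik, 0, theta = theta, tau = tau,
             n_agq = n_agq))
}

#' Fit the hypergeometric-normal model (model 7, exact likelihood)
#'
#' Maximum likelihood over `(theta, log tau)` of the conditional
#' noncentral-hypergeometric likelihood with normal random effects.
#' Starting values come from the rare-event binomial approximation
#' ([fit_cm_al]) and the Peto approximation ([peto_approximation]); if the
#' quasi-Newton optimiser fails, a Nelder-Mead pass at relaxed tolerance
#' (20000 iterations, relative tolerance 1e-4) is used.  A profile fit at
#' the `tau = 0` boundary is always compared against the interior optimum.
#'
#' @inheritParams fit_glmm
#' @param n_agq quadrature nodes (default 7).
#' @return A fit list as in [fit_glmm] (with `model = 7`); `se_reliable`
#'   flags standard errors smaller than half, or more than ten times, the
#'   Peto-approximation standard error.
#' @examples
#' fit_cm_el(measles_data(2))
#' @export
fit_cm_el <- function(ds, n_agq = 7, se = TRUE, control = list()) {
  ds <- as_meta_2x2(ds)
  tabs <- cond_data(ds)
  informative <- sum(!vapply(tabs, `[[`, TRUE, "degenerate"))
  if (informative < 2L)
    stop("model 7 needs at least two studies with a non-degenerate ",
         "conditional distribution", call. = FALSE)
  negll <- function(x) -cm_el_loglik(ds, x[1], exp(x[2]), n_agq)
  peto <- tryCatch(peto_approximation(ds), error = function(e) NULL)
  starts <- list()
  al <- tryCatch(fit_cm_al(ds, n_agq = n_agq, se = FALSE),
                 error = function(e) NULL)
  if (!is.null(al)) starts <- c(starts, list(c(al$theta, 0.5 * log(max(al$tau2, 1e-3)))))
  if (!is.null(peto)) starts <- c(starts, list(c(peto$theta, 0.5 * log(max(peto$tau2, 1e-3)))))
  starts <- c(starts, list(c(0, log(0.2))))
  lower <- c(-Inf, log(1e-5))
  best <- NULL
  for (x0 in starts) {
    fit <- tryCatch(stats::nlminb(pmax(x0, lower + 0.01), negll, lower = lower,
                                  control = list(iter.max = 500, rel.tol = 1e-12)),
                    error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$objective) &&
        (is.null(best) || fit$objective < best$objective - 1e-9)) best <- fit
    if (!is.null(best) && port_ok(best)) break
  }
  if (is.null(best) || !port_ok(best)) {
    nm <- tryCatch(stats::optim(starts[[1]], negll, method = "Nelder-Mead",
                                control = list(maxit = 20000, reltol = 1e-4)),
                   error = function(e) NULL)
    if (!is.null(nm) && is.finite(nm$value) &&
        (is.null(best) || nm$value < best$objective))
      best <- list(par = nm$par, objective = nm$value,
                   convergence = nm$convergence)
  }
  if (is.null(best))
    stop("all optimisers failed for model 7", call. = FALSE)
  # explicit tau = 0 boundary profile
  nll0 <- function(th) -cm_el_loglik(ds, th, 0, n_agq)
  b0 <- stats::optimize(nll0, interval = best$par[1] + c(-4, 4))
  at_boundary <- b0$objective <= best$objective + 1e-7
  if (at_boundary && b0$objective < best$objective)
    best <- list(par = c(b0$minimum, -Inf), objective = b0$objective,
                 convergence = 0, message = "boundary profile")
  theta <- best$par[1]
  tau2 <- if (is.finite(best$par[2])) exp(2 * best$par[2]) else 0
  if (tau2 < 1e-8) tau2 <- 0
  se_theta <- NA_real_
  if (se) {
    if (tau2 > 0) {
      H <- num_hessian(negll, best$par)
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V) && is.finite(V[1, 1]) && V[1, 1] > 0)
        se_theta <- sqrt(V[1, 1])
    }
    if (!is.finite(se_theta)) {
      h <- 1e-4 * (1 + abs(theta))
      d2 <- (nll0(theta + h) - 2 * nll0(theta) + nll0(theta - h)) / h^2
      if (is.finite(d2) && d2 > 0) se_theta <- 1 / sqrt(d2)
    }
  }
  se_reliable <- NA
  if (se && !is.null(peto) && is.finite(se_theta))
    se_reliable <- se_theta >= 0.5 * peto$se && se_theta <= 10 * peto$se
  list(model = 7L, theta = theta, se = se_theta, tau2 = tau2,
       varcomp = c(tau2 = tau2), gamma = NULL,
       loglik = -best$objective, converged = port_ok(best),
       n_agq = n_agq, se_reliable = se_reliable,
       k_used = informative,
       dropped = vapply(tabs[vapply(tabs, `[[`, TRUE, "degenerate")],
                        `[[`, "", "study"))
}

#' Rare-event binomial approximation to model 7
#'
#' When events are rare the conditional noncentral hypergeometric pmf is
#' close to a binomial: `E_i1 | theta_i ~ Bin(t_i, expit(log(n_i1/n_i0) +
#' theta_i))`.  This fits that approximate model as a random-intercept
#' logistic model with one binomial observation per study and offset
#' `log(n_i1/n_i0)`, by adaptive Gauss-Hermite quadrature.  Studies with no
#' events contribute a constant and are ignored.
#'
#' @inheritParams fit_cm_el
#' @return A fit list as in [fit_glmm] (with `model = "7-AL"`).
#' @export
fit_cm_al <- function(ds, n_agq = 7, se = TRUE, control = list()) {
  ds <- as_meta_2x2(ds)
  n1 <- as.numeric(ds$A + ds$B); n0 <- as.numeric(ds$C + ds$D)
  t <- as.numeric(ds$A + ds$C); e1 <- as.numeric(ds$A)
  keep <- t > 0
  if (sum(keep) < 2L)
    stop("the binomial approximation needs at least two studies with events",
         call. = FALSE)
  off <- log(n1 / n0)[keep]; tt <- t[keep]; ee <- e1[keep]
  k <- sum(keep)
  negll <- function(x) {
    th <- x[1]; tau <- exp(x[2])
    a <- off + th
    h <- function(z) ldbinom_logit(ee, tt, a + tau * z) - 0.5 * z^2 + .lphi_const
    h1 <- function(z) { p <- stats::plogis(a + tau * z); tau * (ee - tt * p) - z }
    h2 <- function(z) { p <- stats::plogis(a + tau * z); -tau^2 * tt * p * (1 - p) - 1 }
    -sum(agh1_log(h, h1, h2, n_agq, k))
  }
  peto <- tryCatch(peto_approximation(ds), error = function(e) NULL)
  x0 <- c(if (!is.null(peto)) peto$theta else 0,
          0.5 * log(max(if (!is.null(peto)) peto$tau2 else 0, 1e-3)))
  lower <- c(-Inf, log(1e-5))
  fit <- stats::nlminb(pmax(x0, lower + 0.01), negll, lower = lower,
                       control = list(iter.max = 500, rel.tol = 1e-12))
  tau2 <- exp(2 * fit$par[2])
  if (tau2 < 1e-8) tau2 <- 0
  se_theta <- NA_real_
  if (se) {
    H <- num_hessian(negll, fit$par)
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && is.finite(V[1, 1]) && V[1, 1] > 0)
      se_theta <- sqrt(V[1, 1])
  }
  list(model = "7-AL", theta = fit$par[1], se = se_theta, tau2 = tau2,
       varcomp = c(tau2 = tau2), gamma = NULL, loglik = -fit$objective,
       converged = fit$convergence == 0, n_agq = n_agq, se_reliable = NA,
       k_used = k, dropped = ds$study[!keep])
}

#' Peto one-step (common-effect) estimate
#'
#' The classical Peto estimator: a single Fisher-scoring step from
#' `theta = 0` under the common-effect noncentral hypergeometric model,
#' `theta = sum(O_i - E_i) / sum(V_i)` with standard error
#' `1 / sqrt(sum(V_i))`.
#'
#' @param ds a [meta_2x2] dataset.
#' @param level confidence level.
#' @return A list with `theta`, `se` and `ci`.
#' @export
peto_one_step <- function(ds, level = 0.95) {
  ds <- as_meta_2x2(ds)
  n1 <- as.numeric(ds$A + ds$B); n0 <- as.numeric(ds$C + ds$D)
  t <- as.numeric(ds$A + ds$C); n <- n0 + n1
  E <- t * n1 / n
  V <- t * (n - t) * n0 * n1 / (n^2 * (n - 1))
  if (sum(V) <= 0)
    stop("no study has a non-degenerate conditional distribution", call. = FALSE)
  theta <- sum(as.numeric(ds$A) - E) / sum(V)
  se <- 1 / sqrt(sum(V))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(theta = theta, se = se, ci = c(theta - z * se, theta + z * se))
}

#' Peto random-effects approximation to model 7
#'
#' Fits the conventional two-stage random-effects model to the per-study
#' Peto log odds ratios, estimating the between-study variance by maximum
#' likelihood.  This is a numerically robust approximation to model 7,
#' useful as a sanity check on its fragile exact fit; studies with
#' undefined Peto effects (no events or all events) are dropped.
#'
#' @param ds a [meta_2x2] dataset.
#' @param level confidence level.
#' @return A fit list with `model = "7-Peto"`, `theta`, `se`, `ci`, `tau2`,
#'   `loglik`, `k_used` and `dropped`.
#' @examples
#' peto_approximation(measles_data(1))
#' @export
peto_approximation <- function(ds, level = 0.95) {
  eff <- peto_effects(ds)
  if (nrow(eff) < 2L)
    stop("fewer than two studies with defined Peto effects", call. = FALSE)
  tau2 <- tau2_ml(eff$y, eff$v)
  pool <- pool_effects(eff$y, eff$v, tau2, level = level)
  list(model = "7-Peto", theta = pool$theta, se = pool$se, ci = pool$ci,
       tau2 = tau2, varcomp = c(tau2 = tau2), loglik = pool$loglik,
       converged = TRUE, se_reliable = TRUE, k_used = nrow(eff),
       dropped = attr(eff, "dropped"))
}

# SE-repair policy for batch use of model 7: substitute the Peto SE when the
# exact-likelihood SE is missing, less than half, or more than ten times the
# Peto SE; between 2x and 10x the model SE is retained.
model7_repair <- function(fit, peto) {
  repaired <- FALSE
  if (is.null(fit) || !is.finite(fit$theta)) {
    fit <- peto; repaired <- TRUE
  } else if (!is.finite(fit$se) || fit$se < 0.5 * peto$se ||
             fit$se > 10 * peto$se) {
    fit$se <- peto$se
    repaired <- TRUE
  }
  fit$se_repaired <- repaired
  fit
}
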
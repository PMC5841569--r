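# Binomial logistic mixed models for 2x2 meta-analytic data (models 2-6).
#
# All five models describe e_ij ~ Bin(n_ij, pi_ij) with a logistic linear
# predictor containing a summary log odds ratio theta and study-level random
# effects; they differ in whether the study baselines are fixed or random
# and in the coding of the random treatment slope:
#   model 2: logit(pi_ij) = gamma_i + j*theta + j*eps_i          (fixed baselines)
#   model 3: as model 2 with gamma_i ~ N(gamma, sigma^2)          (random baselines)
#   model 4: logit(pi_ij) = gamma_i + j*theta + (j - 0.5)*eps_i   (fixed baselines)
#   model 5: as model 4 with gamma_i ~ N(gamma, sigma^2)
#   model 6: (logit(pi_i0), logit(pi_i1)) ~ N((gamma, gamma + theta), Sigma)
#            with unstructured 2x2 Sigma; tau^2 = s0^2 + s1^2 - 2 rho s0 s1.
# The marginal likelihood integrates the random effects out by adaptive
# Gauss-Hermite quadrature in standardised variables.

.lphi_const <- -0.5 * log(2 * pi)

glmm_data <- function(ds) {
  ds <- as_meta_2x2(ds)
  list(e1 = as.numeric(ds$A), n1 = as.numeric(ds$A + ds$B),
       e0 = as.numeric(ds$C), n0 = as.numeric(ds$C + ds$D),
       k = nrow(ds), study = ds$study)
}

# Per-study log-likelihood contributions for one parameter value.
# `par` is a named list: models 2/4 need gamma (length k), theta, tau;
# models 3/5 need gamma (scalar), theta, sigma, tau; model 6 needs gamma,
# theta and the lower-triangular Cholesky factor (L11, L21, L22) of Sigma.
# `mean_coding` switches the fixed part between j*theta and (j-0.5)*theta
# (a pure reparameterisation for models 4/5, used by reparam_check()).
glmm_study_loglik <- function(model, dat, par, n_agq,
                              mean_coding = c("j", "j_minus_half")) {
  mean_coding <- match.arg(mean_coding)
  e0 <- dat$e0; n0 <- dat$n0; e1 <- dat$e1; n1 <- dat$n1; k <- dat$k
  th <- par$theta
  if (mean_coding == "j") { m0 <- 0; m1 <- th } else { m0 <- -th / 2; m1 <- th / 2 }
  if (model %in% c(2L, 4L)) {
    g <- rep_len(par$gamma, k); tau <- par$tau
    if (model == 2L) {
      a1 <- g + th                 # treated-arm logit at z = 0
      h <- function(z) ldbinom_logit(e1, n1, a1 + tau * z) - 0.5 * z^2 + .lphi_const
      h1 <- function(z) {
        p <- stats::plogis(a1 + tau * z); tau * (e1 - n1 * p) - z
      }
      h2 <- function(z) {
        p <- stats::plogis(a1 + tau * z); -tau^2 * n1 * p * (1 - p) - 1
      }
      ldbinom_logit(e0, n0, g) + agh1_log(h, h1, h2, n_agq, k)
    } else {
      a0 <- g + m0; a1 <- g + m1
      h <- function(z) ldbinom_logit(e0, n0, a0 - 0.5 * tau * z) +
        ldbinom_logit(e1, n1, a1 + 0.5 * tau * z) - 0.5 * z^2 + .lphi_const
      h1 <- function(z) {
        p0 <- stats::plogis(a0 - 0.5 * tau * z)
        p1 <- stats::plogis(a1 + 0.5 * tau * z)
        -0.5 * tau * (e0 - n0 * p0) + 0.5 * tau * (e1 - n1 * p1) - z
      }
      h2 <- function(z) {
        p0 <- stats::plogis(a0 - 0.5 * tau * z)
        p1 <- stats::plogis(a1 + 0.5 * tau * z)
        -0.25 * tau^2 * (n0 * p0 * (1 - p0) + n1 * p1 * (1 - p1)) - 1
      }
      agh1_log(h, h1, h2, n_agq, k)
    }
  } else {
    # bivariate form: eta0 = a0 + b01 z1 + b02 z2, eta1 = a1 + b11 z1 + b12 z2
    g <- par$gamma
    if (model == 3L) {
      b01 <- par$sigma; b02 <- 0; b11 <- par$sigma; b12 <- par$tau
      a0 <- g + m0; a1 <- g + m1
    } else if (model == 5L) {
      b01 <- par$sigma; b02 <- -par$tau / 2
      b11 <- par$sigma; b12 <- par$tau / 2
      a0 <- g + m0; a1 <- g + m1
    } else {
      b01 <- par$L11; b02 <- 0; b11 <- par$L21; b12 <- par$L22
      a0 <- g; a1 <- g + th
    }
    h <- function(z1, z2)
      ldbinom_logit(e0, n0, a0 + b01 * z1 + b02 * z2) +
      ldbinom_logit(e1, n1, a1 + b11 * z1 + b12 * z2) -
      0.5 * (z1^2 + z2^2) + 2 * .lphi_const
    grad <- function(z1, z2) {
      r0 <- e0 - n0 * stats::plogis(a0 + b01 * z1 + b02 * z2)
      r1 <- e1 - n1 * stats::plogis(a1 + b11 * z1 + b12 * z2)
      list(g1 = b01 * r0 + b11 * r1 - z1, g2 = b02 * r0 + b12 * r1 - z2)
    }
    hess <- function(z1, z2) {
      p0 <- stats::plogis(a0 + b01 * z1 + b02 * z2)
      p1 <- stats::plogis(a1 + b11 * z1 + b12 * z2)
      w0 <- n0 * p0 * (1 - p0); w1 <- n1 * p1 * (1 - p1)
      list(h11 = -(b01^2 * w0 + b11^2 * w1) - 1,
           h12 = -(b01 * b02 * w0 + b11 * b12 * w1),
           h22 = -(b02^2 * w0 + b12^2 * w1) - 1)
    }
    agh2_log(h, grad, hess, n_agq, dat$k)
  }
}

# Map an unconstrained optimisation vector to the named parameter list.
glmm_unpack <- function(model, x, k) {
  if (model %in% c(2L, 4L))
    list(gamma = x[seq_len(k)], theta = x[k + 1], tau = exp(x[k + 2]))
  else if (model %in% c(3L, 5L))
    list(gamma = x[1], theta = x[2], sigma = exp(x[3]), tau = exp(x[4]))
  else
    list(gamma = x[1], theta = x[2], L11 = exp(x[3]), L21 = x[4],
         L22 = exp(x[5]))
}

# Fused objective + analytic gradient for the one-random-effect models
# (2 and 4).  The gradient of the quadrature-approximated log-likelihood is
# the posterior expectation of the score at the quadrature nodes, computed
# from the same weights as the objective, so one pass yields both; the
# per-study posterior modes are warm-started across evaluations.
glmm_objfun_1re <- function(model, dat, n_agq) {
  e0 <- dat$e0; n0 <- dat$n0; e1 <- dat$e1; n1 <- dat$n1; k <- dat$k
  rule <- gh_rule(n_agq)
  lwq <- log(rule$weights) + rule$nodes^2
  env <- new.env(parent = emptyenv())
  env$z <- rep(0, k); env$key <- NULL
  compute <- function(x) {
    if (!is.null(env$key) && identical(env$key, x)) return(env$val)
    g <- x[seq_len(k)]; th <- x[k + 1]; tau <- exp(x[k + 2])
    z <- env$z
    if (model == 2L) {
      a1 <- g + th
      for (it in 1:30) {
        p <- stats::plogis(a1 + tau * z)
        h1 <- tau * (e1 - n1 * p) - z
        h2 <- -tau^2 * n1 * p * (1 - p) - 1
        step <- pmax(pmin(h1 / h2, 4), -4)
        z <- z - step
        if (max(abs(step)) < 1e-9) break
      }
      p <- stats::plogis(a1 + tau * z)
      sigma <- 1 / sqrt(tau^2 * n1 * p * (1 - p) + 1)
      Z <- z + sqrt(2) * sigma %o% rule$nodes
      eta1 <- a1 + tau * Z
      L <- rep(lwq, each = k) + ldbinom_logit(e1, n1, eta1) - 0.5 * Z^2 +
        .lphi_const
      li <- row_logsumexp(L)
      W <- exp(L - li)
      R1 <- e1 - n1 * stats::plogis(eta1)
      p0 <- stats::plogis(g)
      obj <- -sum(ldbinom_logit(e0, n0, g) + log(sqrt(2) * sigma) + li)
      s1 <- rowSums(W * R1)
      grad <- c(-((e0 - n0 * p0) + s1), -sum(s1),
                -sum(rowSums(W * R1 * Z)) * tau)
    } else {
      for (it in 1:30) {
        p0 <- stats::plogis(g - 0.5 * tau * z)
        p1 <- stats::plogis(g + th + 0.5 * tau * z)
        h1 <- -0.5 * tau * (e0 - n0 * p0) + 0.5 * tau * (e1 - n1 * p1) - z
        h2 <- -0.25 * tau^2 * (n0 * p0 * (1 - p0) + n1 * p1 * (1 - p1)) - 1
        step <- pmax(pmin(h1 / h2, 4), -4)
        z <- z - step
        if (max(abs(step)) < 1e-9) break
      }
      p0 <- stats::plogis(g - 0.5 * tau * z)
      p1 <- stats::plogis(g + th + 0.5 * tau * z)
      sigma <- 1 / sqrt(0.25 * tau^2 * (n0 * p0 * (1 - p0) +
                                        n1 * p1 * (1 - p1)) + 1)
      Z <- z + sqrt(2) * sigma %o% rule$nodes
      eta0 <- g - 0.5 * tau * Z
      eta1 <- (g + th) + 0.5 * tau * Z
      L <- rep(lwq, each = k) + ldbinom_logit(e0, n0, eta0) +
        ldbinom_logit(e1, n1, eta1) - 0.5 * Z^2 + .lphi_const
      li <- row_logsumexp(L)
      W <- exp(L - li)
      R0 <- e0 - n0 * stats::plogis(eta0)
      R1 <- e1 - n1 * stats::plogis(eta1)
      obj <- -sum(log(sqrt(2) * sigma) + li)
      grad <- c(-rowSums(W * (R0 + R1)), -sum(rowSums(W * R1)),
                -sum(rowSums(W * (0.5 * R1 - 0.5 * R0) * Z)) * tau)
    }
    env$z <- z
    env$key <- x
    env$val <- list(objective = obj, gradient = grad)
    env$val
  }
  list(fn = function(x) compute(x)$objective,
       gr = function(x) compute(x)$gradient)
}

# Hessian by central differences of a gradient function.
num_hessian_grad <- function(gr, x, rel_step = 1e-5) {
  p <- length(x)
  h <- rel_step * (1 + abs(x))
  H <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- h[i]
    H[i, ] <- (gr(x + ei) - gr(x - ei)) / (2 * h[i])
  }
  (H + t(H)) / 2
}

glmm_start <- function(model, dat, effects) {
  t2 <- tau2_dl(effects$y, effects$v)
  theta0 <- pool_effects(effects$y, effects$v, t2)$theta
  ltau0 <- 0.5 * log(max(t2, 0.01))
  glogit <- stats::qlogis((dat$e0 + 0.5) / (dat$n0 + 1))
  if (model %in% c(2L, 4L)) {
    c(glogit, theta0, ltau0)
  } else if (model %in% c(3L, 5L)) {
    c(mean(glogit), theta0, log(max(stats::sd(glogit), 0.15)), ltau0)
  } else {
    s <- max(stats::sd(glogit), 0.15)
    c(mean(glogit), theta0, log(s), 0.9 * s, ltau0)
  }
}

default_nagq <- function(model) if (model %in% c(2L, 4L)) 7L else 1L

# PORT reports "singular convergence" when the objective is flat at the
# optimum (common when a variance component is weakly identified); the
# maximiser is still valid, so treat it as converged.
port_ok <- function(fit) {
  isTRUE(fit$convergence == 0) ||
    (is.character(fit$message) && grepl("singular convergence", fit$message))
}

num_hessian <- function(fn, x, rel_step = 1e-5) {
  p <- length(x)
  h <- rel_step * (1 + abs(x))
  H <- matrix(NA_real_, p, p)
  gr <- function(y) {
    g <- numeric(p)
    for (j in seq_len(p)) {
      ej <- numeric(p); ej[j] <- h[j]
      g[j] <- (fn(y + ej) - fn(y - ej)) / (2 * h[j])
    }
    g
  }
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- h[i]
    H[i, ] <- (gr(x + ei) - gr(x - ei)) / (2 * h[i])
  }
  (H + t(H)) / 2
}

#' Fit a binomial logistic mixed model to 2-by-2 meta-analytic data
#'
#' Fits one of models 2-6 (see the package vignette) by maximum likelihood.
#' The random effects are integrated out with adaptive Gauss-Hermite
#' quadrature; `n_agq = 1` is the Laplace approximation.  Variance
#' components are optimised on the log (models 2-5) or log-Cholesky
#' (model 6) scale, so estimates respect their natural constraints,
#' including correlation estimates on the boundary.
#'
#' @param ds a [meta_2x2] dataset.
#' @param model integer 2-6.
#' @param n_agq quadrature nodes per random-effect axis; defaults to 7 for
#'   the one-random-effect models (2, 4) and 1 (Laplace) for the
#'   two-random-effect models (3, 5, 6).
#' @param drop00 `"auto"` (drop double-zero studies for models 3/5/6 and
#'   keep them for models 2/4), `"true"` or `"false"`.
#' @param se compute the standard error of the summary log odds ratio from
#'   the numerically differentiated observed information (default `TRUE`).
#' @param control list of optimiser options: `max_restarts` (default 3),
#'   `maxit` (default 500), `rel_tol` (default 1e-10).
#' @return A list with elements `model`, `theta`, `se`, `tau2`, `varcomp`
#'   (named variance-component estimates), `gamma` (fixed baseline
#'   estimates for models 2/4, or `c(gamma, sigma2)` for models 3/5),
#'   `loglik`, `converged`, `n_agq`, `se_reliable`, `k_used` and `dropped`.
#' @examples
#' fit_glmm(measles_data(2), model = 4)
#' @export
fit_glmm <- function(ds, model, n_agq = NULL, drop00 = c("auto", "true", "false"),
                     se = TRUE, control = list()) {
  model <- as.integer(model)
  stopifnot(model %in% 2:6)
  drop00 <- match.arg(drop00)
  ds <- as_meta_2x2(ds)
  dropped <- character(0)
  do_drop <- drop00 == "true" || (drop00 == "auto" && model %in% c(3L, 5L, 6L))
  if (do_drop && any(ds$A + ds$C == 0L | ds$B + ds$D == 0L)) {
    ds2 <- drop_double_zero(ds)
    dropped <- c(attr(ds2, "dropped_double_zero"), attr(ds2, "dropped_all_event"))
    ds <- ds2
  }
  if (nrow(ds) < 2L)
    stop("at least two studies are required to fit a mixed model", call. = FALSE)
  dat <- glmm_data(ds)
  effects <- log_or_effects(ds)
  ctrl <- utils::modifyList(list(max_restarts = 3L, maxit = 500L,
                                 rel_tol = 1e-10), control)
  nq <- if (is.null(n_agq)) default_nagq(model) else as.integer(n_agq)
  if (model %in% c(2L, 4L)) {
    of <- glmm_objfun_1re(model, dat, nq)
    negll <- of$fn; negll_gr <- of$gr
  } else {
    negll <- function(x)
      -sum(glmm_study_loglik(model, dat, glmm_unpack(model, x, dat$k), nq))
    negll_gr <- NULL
  }
  x0 <- glmm_start(model, dat, effects)
  p <- length(x0)
  lower <- rep(-Inf, p); upper <- rep(Inf, p)
  if (model %in% c(2L, 4L)) lower[p] <- log(1e-5)
  if (model %in% c(3L, 5L)) lower[3:4] <- log(1e-5)
  if (model == 6L) lower[c(3, 5)] <- log(1e-5)
  best <- NULL
  for (attempt in 0:ctrl$max_restarts) {
    start <- if (attempt == 0) x0 else
      x0 + stats::qnorm((seq_len(p) %% 7 + 1) / 9) * 0.3 * attempt
    start <- pmax(start, lower + 0.01)
    fit <- tryCatch(
      stats::nlminb(start, negll, gradient = negll_gr,
                    lower = lower, upper = upper,
                    control = list(iter.max = ctrl$maxit,
                                   eval.max = 10L * ctrl$maxit,
                                   rel.tol = ctrl$rel_tol)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$objective)) {
      if (is.null(best) || fit$objective < best$objective - 1e-8) best <- fit
      if (port_ok(fit) && attempt == 0) break
      if (!is.null(best) && port_ok(best)) break
    }
  }
  if (is.null(best))
    stop("optimiser failed for model ", model, " after restarts", call. = FALSE)
  if (!is.null(negll_gr)) {
    # The analytic gradient is the quadrature approximation of the exact
    # score, which differs from the gradient of the quadrature objective by
    # a term of the order of the quadrature error; polish with the
    # derivative-free objective so the optimum is that of the adaptive-GH
    # likelihood itself.
    pol <- tryCatch(
      stats::nlminb(best$par, negll, lower = lower, upper = upper,
                    control = list(iter.max = 100L,
                                   rel.tol = ctrl$rel_tol)),
      error = function(e) NULL)
    if (!is.null(pol) && is.finite(pol$objective) &&
        pol$objective <= best$objective + 1e-8) best <- pol
  }
  x <- best$par
  par <- glmm_unpack(model, x, dat$k)
  if (model %in% c(2L, 4L)) {
    tau2 <- par$tau^2
    varcomp <- c(tau2 = tau2)
    gamma <- stats::setNames(par$gamma, dat$study)
  } else if (model %in% c(3L, 5L)) {
    tau2 <- par$tau^2
    varcomp <- c(sigma2 = par$sigma^2, tau2 = tau2)
    gamma <- c(gamma = par$gamma, sigma2 = par$sigma^2)
  } else {
    s02 <- par$L11^2
    s12 <- par$L21^2 + par$L22^2
    rho <- par$L11 * par$L21 / sqrt(s02 * s12)
    tau2 <- (par$L11 - par$L21)^2 + par$L22^2   # s0^2 + s1^2 - 2 rho s0 s1
    varcomp <- c(sigma0_2 = s02, sigma1_2 = s12, rho = rho, tau2 = tau2)
    gamma <- c(gamma = par$gamma)
  }
  # truncate numerically-zero variance components hitting the box bound
  if (tau2 < 1e-8) tau2 <- 0
  se_theta <- NA_real_
  if (se) {
    H <- if (is.null(negll_gr)) num_hessian(negll, x)
         else num_hessian_grad(negll_gr, x)
    V <- tryCatch(solve(H), error = function(e) NULL)
    idx <- if (model %in% c(2L, 4L)) dat$k + 1L else 2L
    if (!is.null(V) && is.finite(V[idx, idx]) && V[idx, idx] > 0)
      se_theta <- sqrt(V[idx, idx])
  }
  out <- list(model = model, theta = par$theta, se = se_theta, tau2 = tau2,
              varcomp = varcomp, gamma = gamma, loglik = -best$objective,
              converged = port_ok(best), n_agq = nq,
              se_reliable = NA, k_used = dat$k, dropped = dropped,
              par = x)
  # sanity check against the robust Peto-based standard error
  if (se && is.finite(se_theta)) {
    peto_se <- tryCatch(peto_approximation(ds)$se, error = function(e) NA_real_)
    out$se_reliable <- TRUE
    if (is.finite(peto_se) && se_theta < 0.5 * peto_se) {
      refit <- tryCatch(
        fit_glmm(ds, model, n_agq = nq, drop00 = "false", se = TRUE,
                 control = utils::modifyList(ctrl, list(
                   maxit = 10L * ctrl$maxit, max_restarts = 0L))),
        error = function(e) NULL)
      if (!is.null(refit) && is.finite(refit$se) && refit$se >= 0.5 * peto_se) {
        refit$se_reliable <- TRUE
        refit$dropped <- dropped
        return(refit)
      }
      out$se_reliable <- FALSE
    }
  }
  out
}

#' Check the mean-coding reparameterisation of models 4 and 5
#'
#' Refits model 4 or 5 with the fixed part `j * theta` replaced by
#' `(j - 0.5) * theta`.  This changes only the meaning of the baseline
#' parameters (`gamma* = gamma - theta/2`), so the summary log odds ratio
#' and the maximised log-likelihood must be unchanged up to optimiser
#' tolerance.
#'
#' @param ds a [meta_2x2] dataset.
#' @param model 4 or 5.
#' @param tol tolerance on the estimate and log-likelihood differences.
#' @param ... passed to the internal fits.
#' @return A list with both fits, the differences and a pass flag.
#' @export
reparam_check <- function(ds, model = 4, tol = 1e-3, ...) {
  model <- as.integer(model)
  stopifnot(model %in% c(4L, 5L))
  f_j <- fit_glmm(ds, model, se = FALSE, ...)
  ds2 <- if (length(f_j$dropped)) drop_double_zero(as_meta_2x2(ds)) else ds
  dat <- glmm_data(as_meta_2x2(ds2))
  nq <- f_j$n_agq
  negll_z <- function(x)
    -sum(glmm_study_loglik(model, dat, glmm_unpack(model, x, dat$k), nq,
                           mean_coding = "j_minus_half"))
  x0 <- f_j$par
  k <- dat$k
  # shift baselines to the centred coding for a fair start
  if (model == 4L) x0[seq_len(k)] <- x0[seq_len(k)] + 0.5 * f_j$theta
  else x0[1] <- x0[1] + 0.5 * f_j$theta
  p <- length(x0)
  lower <- rep(-Inf, p)
  if (model == 4L) lower[p] <- log(1e-5) else lower[3:4] <- log(1e-5)
  fit <- stats::nlminb(x0, negll_z, lower = lower,
                       control = list(iter.max = 500, rel.tol = 1e-12))
  par <- glmm_unpack(model, fit$par, k)
  d_theta <- abs(par$theta - f_j$theta)
  d_ll <- abs(-fit$objective - f_j$loglik)
  list(model = model, theta_j = f_j$theta, theta_z = par$theta,
       loglik_j = f_j$loglik, loglik_z = -fit$objective,
       delta_theta = d_theta, delta_loglik = d_ll,
       pass = d_theta < tol && d_ll < tol)
}
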
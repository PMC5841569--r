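#' DerSimonian-Laird estimator of the between-study variance
#'
#' Moment estimator matching Cochran's Q, computed with weights `1/v`, to
#' its expectation under the two-stage normal-normal model; truncated at 0.
#'
#' @param y per-study effect estimates (log odds ratios).
#' @param v per-study within-study variances.
#' @return The truncated estimate of the between-study variance.
#' @examples
#' e <- log_or_effects(measles_data(1))
#' tau2_dl(e$y, e$v)
#' @export
tau2_dl <- function(y, v) {
  stopifnot(length(y) == length(v), all(v > 0))
  k <- length(y)
  if (k < 2) stop("at least two studies are required", call. = FALSE)
  w <- 1 / v
  yb <- sum(w * y) / sum(w)
  Q <- sum(w * (y - yb)^2)
  max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
}

# Restricted / unrestricted profile log-likelihood of the two-stage model
# at a given tau2 (theta profiled out; constants kept so fits are comparable).
ll_model1 <- function(tau2, y, v, restricted) {
  w <- 1 / (v + tau2)
  theta <- sum(w * y) / sum(w)
  ll <- -0.5 * sum(log(2 * pi / w)) - 0.5 * sum(w * (y - theta)^2)
  if (restricted) ll <- ll - 0.5 * log(sum(w)) + 0.5 * log(2 * pi)
  ll
}

tau2_lik <- function(y, v, restricted, tol = 1e-8) {
  stopifnot(length(y) == length(v), all(v > 0))
  if (length(y) < 2) stop("at least two studies are required", call. = FALSE)
  # maximise over log(tau2); a coarse grid brackets the optimum first
  # (the profile is numerically flat for tau2 << min(v), where golden-section
  # search alone can stall), then an explicit boundary comparison at tau2 = 0
  hi <- max(tau2_dl(y, v) * 10, stats::var(y) * 10, 1)
  grid <- log(c(1e-8, 1e-6, 1e-4, exp(seq(log(1e-3), log(hi), length.out = 40))))
  vals <- vapply(grid, function(lt) ll_model1(exp(lt), y, v, restricted), 0)
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]; up <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(function(lt) ll_model1(exp(lt), y, v, restricted),
                         lower = lo, upper = up, maximum = TRUE, tol = tol)
  tau2 <- exp(opt$maximum)
  if (ll_model1(0, y, v, restricted) >= opt$objective || tau2 < 1e-7)
    tau2 <- 0
  tau2
}

#' Likelihood-based estimators of the between-study variance
#'
#' `tau2_ml()` maximises the marginal normal likelihood of the two-stage
#' model over the between-study variance (with the pooled effect profiled
#' out); `tau2_reml()` maximises the restricted likelihood.  Both are
#' truncated at 0 via an explicit boundary comparison.
#'
#' @inheritParams tau2_dl
#' @return The estimated between-study variance.
#' @examples
#' e <- log_or_effects(measles_data(1))
#' tau2_reml(e$y, e$v)
#' @export
tau2_reml <- function(y, v) tau2_lik(y, v, restricted = TRUE)

#' @rdname tau2_reml
#' @export
tau2_ml <- function(y, v) tau2_lik(y, v, restricted = FALSE)

#' Pool effect estimates at a fixed between-study variance
#'
#' Inverse-variance weighted pooling with weights `1/(v + tau2)`, treating
#' `tau2` as known.  Wald inference uses the normal quantile.  Cochran's Q
#' (computed with the within-study weights `1/v`) and `I^2` are attached.
#'
#' @inheritParams tau2_dl
#' @param tau2 the between-study variance to condition on.
#' @param level confidence level (default 0.95).
#' @return A list with elements `theta`, `se`, `ci` (length-2 vector),
#'   `tau2`, `q_stat`, `i2`, `loglik` and `k`.
#' @examples
#' e <- log_or_effects(measles_data(1))
#' pool_effects(e$y, e$v, tau2_dl(e$y, e$v))
#' @export
pool_effects <- function(y, v, tau2, level = 0.95) {
  stopifnot(length(y) == length(v), all(v > 0), tau2 >= 0)
  w <- 1 / (v + tau2)
  theta <- sum(w * y) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- stats::qnorm(1 - (1 - level) / 2)
  wfix <- 1 / v
  yb <- sum(wfix * y) / sum(wfix)
  Q <- sum(wfix * (y - yb)^2)
  k <- length(y)
  i2 <- if (k >= 2 && Q > 0) max(0, (Q - (k - 1)) / Q) else 0
  list(theta = theta, se = se, ci = c(theta - z * se, theta + z * se),
       tau2 = tau2, q_stat = Q, i2 = i2,
       loglik = -0.5 * sum(log(2 * pi * (v + tau2))) -
         0.5 * sum(w * (y - theta)^2),
       k = k)
}

# Generalised Q statistic with weights 1/(v + tau2).
q_gen <- function(tau2, y, v) {
  w <- 1 / (v + tau2)
  theta <- sum(w * y) / sum(w)
  sum(w * (y - theta)^2)
}

#' Q-profile confidence interval for the between-study variance
#'
#' Inverts the generalised Q statistic (weights `1/(v + tau2)`) against the
#' chi-square quantiles with `k - 1` degrees of freedom; bounds are found by
#' bisection and the lower bound is truncated at 0.
#'
#' @inheritParams tau2_dl
#' @param level confidence level (default 0.95).
#' @param cap upper end of the search interval; defaults to
#'   `100 * tau2_dl(y, v) + 100`.
#' @return A list with elements `lo`, `hi` and `level`.
#' @examples
#' e <- log_or_effects(measles_data(1))
#' q_profile_ci(e$y, e$v)
#' @export
q_profile_ci <- function(y, v, level = 0.95, cap = NULL) {
  stopifnot(length(y) == length(v), all(v > 0))
  k <- length(y)
  if (k < 2) stop("at least two studies are required", call. = FALSE)
  if (is.null(cap)) cap <- 100 * tau2_dl(y, v) + 100
  alpha <- 1 - level
  q_hi <- stats::qchisq(1 - alpha / 2, df = k - 1)
  q_lo <- stats::qchisq(alpha / 2, df = k - 1)
  # q_gen is strictly decreasing in tau2
  root <- function(target) {
    f <- function(t2) q_gen(t2, y, v) - target
    if (f(0) <= 0) return(0)
    if (f(cap) >= 0) {
      warning("Q-profile bound capped at search interval end", call. = FALSE)
      return(cap)
    }
    stats::uniroot(f, c(0, cap), tol = 1e-6)$root
  }
  list(lo = root(q_hi), hi = root(q_lo), level = level)
}
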
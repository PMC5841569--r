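#' Model identifiers
#'
#' The models are referred to throughout by short string ids:
#' `"1-DL"`, `"1-REML"`, `"1-ML"` (the two-stage normal-normal model with
#' the DerSimonian-Laird, REML or ML heterogeneity estimator), `"2"` to
#' `"6"` (the binomial logistic mixed models), `"7"` (the exact
#' hypergeometric-normal conditional model), `"7-AL"` (its rare-event
#' binomial approximation) and `"7-Peto"` (the conventional model fitted to
#' Peto log odds ratios with ML heterogeneity).
#'
#' @return Character vector of valid model ids.
#' @export
or_models <- function() c("1-DL", "1-REML", "1-ML", "2", "3", "4", "5", "6",
                          "7", "7-AL", "7-Peto")

# Internal dispatcher shared by meta_or() and the simulation engine.
fit_model_by_id <- function(id, ds, n_agq = NULL,
                            drop00 = c("auto", "true", "false"),
                            se = TRUE, level = 0.95, control = list()) {
  drop00 <- match.arg(drop00)
  id <- as.character(id)
  if (id %in% c("1-DL", "1-REML", "1-ML")) {
    ds1 <- ds
    dropped <- character(0)
    if (drop00 == "true") {
      ds1 <- drop_double_zero(as_meta_2x2(ds))
      dropped <- c(attr(ds1, "dropped_double_zero"),
                   attr(ds1, "dropped_all_event"))
    }
    eff <- log_or_effects(ds1)
    tau2 <- switch(id, "1-DL" = tau2_dl(eff$y, eff$v),
                   "1-REML" = tau2_reml(eff$y, eff$v),
                   "1-ML" = tau2_ml(eff$y, eff$v))
    pool <- pool_effects(eff$y, eff$v, tau2, level = level)
    list(model = id, theta = pool$theta, se = pool$se, ci = pool$ci,
         tau2 = tau2, varcomp = c(tau2 = tau2), loglik = pool$loglik,
         q_stat = pool$q_stat, i2 = pool$i2, converged = TRUE,
         se_reliable = TRUE, k_used = nrow(eff), dropped = dropped)
  } else if (id %in% c("2", "3", "4", "5", "6")) {
    fit_glmm(ds, model = as.integer(id), n_agq = n_agq, drop00 = drop00,
             se = se, control = control)
  } else if (id == "7") {
    fit_cm_el(ds, n_agq = if (is.null(n_agq)) 7 else n_agq, se = se,
              control = control)
  } else if (id == "7-AL") {
    fit_cm_al(ds, n_agq = if (is.null(n_agq)) 7 else n_agq, se = se,
              control = control)
  } else if (id == "7-Peto") {
    peto_approximation(ds, level = level)
  } else stop("unknown model id '", id, "'; see or_models()", call. = FALSE)
}

#' Fit a random-effects meta-analysis model for the summary odds ratio
#'
#' Fits one of the package's models (see [or_models]) to a series of 2-by-2
#' tables and returns a classed fit with `print`, `summary`, `coef`,
#' `confint`, `vcov` and `logLik` methods.  All estimation is on the log
#' odds ratio scale; the summary odds ratio is `exp(coef(fit))`.
#'
#' @param data a [meta_2x2] dataset, or any data frame accepted by
#'   [as_meta_2x2] (wide `study,A,B,C,D` or long `study,treat,n,event`).
#' @param model a model id from [or_models] (default `"1-DL"`).
#' @param n_agq quadrature nodes per random-effect axis for the likelihood
#'   models; `NULL` uses 7 for one random effect (models 2, 4, 7, 7-AL)
#'   and 1 (Laplace) for two (models 3, 5, 6).
#' @param drop00 double-zero study handling: `"auto"` keeps them for models
#'   whose fit they cannot change (1, 2, 4, 7) and drops them for the
#'   random-baseline models (3, 5, 6); `"true"`/`"false"` force the choice.
#' @param level confidence level for Wald intervals (default 0.95).
#' @param se compute standard errors (switching this off speeds up batch
#'   fitting when only point estimates are needed).
#' @param control optimiser options passed to the underlying fitter.
#' @return An object of class `"meta_or"`.
#' @examples
#' fit <- meta_or(measles_data(1), model = "1-DL")
#' fit
#' exp(confint(fit))
#' @export
meta_or <- function(data, model = "1-DL", n_agq = NULL,
                    drop00 = c("auto", "true", "false"), level = 0.95,
                    se = TRUE, control = list()) {
  drop00 <- match.arg(drop00)
  ds <- as_meta_2x2(data)
  model <- match.arg(as.character(model), or_models())
  fit <- fit_model_by_id(model, ds, n_agq = n_agq, drop00 = drop00, se = se,
                         level = level, control = control)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (is.null(fit$ci))
    fit$ci <- if (is.finite(fit$se)) fit$theta + c(-z, z) * fit$se
              else c(NA_real_, NA_real_)
  structure(list(
    model = model, theta = fit$theta, se = fit$se, ci = fit$ci,
    tau2 = fit$tau2, varcomp = fit$varcomp, gamma = fit$gamma,
    loglik = fit$loglik, q_stat = fit$q_stat, i2 = fit$i2,
    converged = fit$converged, se_reliable = fit$se_reliable,
    n_agq = fit$n_agq, level = level, k = nrow(ds), k_used = fit$k_used,
    dropped = fit$dropped, label = attr(ds, "label"), data = ds,
    call = match.call()), class = "meta_or")
}

#' @export
print.meta_or <- function(x, digits = 3, ...) {
  cat("Random-effects meta-analysis of the odds ratio (model ", x$model,
      ")\n", sep = "")
  if (!is.null(x$label)) cat("Data: ", x$label, " (k = ", x$k, " studies",
                             if (x$k_used < x$k) paste0(", ", x$k_used, " used"),
                             ")\n", sep = "")
  or <- exp(c(x$theta, x$ci))
  cat(sprintf("  log OR: %.*f (SE %.*f), %g%% CI [%.*f, %.*f]\n",
              digits, x$theta, digits, x$se, 100 * x$level,
              digits, x$ci[1], digits, x$ci[2]))
  cat(sprintf("  OR:     %.*f, %g%% CI [%.*f, %.*f]\n",
              digits, or[1], 100 * x$level, digits, or[2], digits, or[3]))
  cat(sprintf("  tau^2:  %.*f\n", digits, x$tau2))
  if (isFALSE(x$converged)) cat("  warning: optimiser did not converge\n")
  if (isFALSE(x$se_reliable))
    cat("  warning: standard error flagged unreliable\n")
  invisible(x)
}

#' @export
summary.meta_or <- function(object, ...) {
  out <- object
  if (startsWith(object$model, "1-")) {
    eff <- log_or_effects(object$data)
    out$tau2_ci <- tryCatch(q_profile_ci(eff$y, eff$v, level = object$level),
                            error = function(e) NULL)
  }
  class(out) <- c("summary.meta_or", "meta_or")
  out
}

#' @export
print.summary.meta_or <- function(x, digits = 3, ...) {
  print.meta_or(x, digits = digits, ...)
  if (!is.null(x$q_stat))
    cat(sprintf("  Cochran Q = %.*f, I^2 = %.1f%%\n", digits, x$q_stat,
                100 * x$i2))
  if (!is.null(x$tau2_ci))
    cat(sprintf("  tau^2 %g%% CI (Q-profile): [%.*f, %.*f]\n",
                100 * x$tau2_ci$level, digits, x$tau2_ci$lo, digits,
                x$tau2_ci$hi))
  if (!is.null(x$varcomp) && length(x$varcomp) > 1) {
    cat("  variance components: ",
        paste(names(x$varcomp), sprintf("%.*f", digits, x$varcomp),
              sep = " = ", collapse = ", "), "\n", sep = "")
  }
  if (length(x$dropped))
    cat("  dropped studies: ", paste(x$dropped, collapse = ", "), "\n",
        sep = "")
  if (!is.null(x$loglik))
    cat(sprintf("  log-likelihood: %.*f\n", digits, x$loglik))
  invisible(x)
}

#' @export
coef.meta_or <- function(object, ...) c(logOR = object$theta)

#' @export
vcov.meta_or <- function(object, ...)
  matrix(object$se^2, 1, 1, dimnames = list("logOR", "logOR"))

#' @export
confint.meta_or <- function(object, parm, level = NULL, ...) {
  if (is.null(level) || level == object$level) {
    ci <- object$ci
  } else {
    z <- stats::qnorm(1 - (1 - level) / 2)
    ci <- object$theta + c(-z, z) * object$se
  }
  matrix(ci, 1, 2, dimnames = list("logOR", c("lower", "upper")))
}

#' @export
logLik.meta_or <- function(object, ...) {
  df <- switch(object$model,
               "1-DL" = , "1-REML" = , "1-ML" = , "7" = , "7-AL" = ,
               "7-Peto" = 2,
               "2" = , "4" = object$k_used + 2,
               "3" = , "5" = 4, "6" = 5)
  structure(object$loglik, df = df, nobs = 2 * object$k_used,
            class = "logLik")
}
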
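# Sensitivity-analysis reporting and config-driven batch runs.

#' Compare models across one dataset (sensitivity analysis)
#'
#' Fits a set of models to the same dataset and tabulates the summary log
#' odds ratio, its standard error and confidence interval (on both the log
#' odds ratio and odds ratio scales), the heterogeneity estimate, the
#' log-likelihood and diagnostic flags.  The default model set
#' (conventional model with both heterogeneity estimators, the
#' fixed-baseline centred-slope mixed model, the unstructured bivariate
#' model, and the conditional model) follows the recommendation that these
#' cover the useful modelling choices; model `"2"` can be requested but is
#' reported with a warning, reflecting its poor performance in simulation.
#'
#' @param data a [meta_2x2] dataset or coercible data frame.
#' @param models character vector of model ids (see [or_models]).
#' @param drop00,n_agq,level,control passed to [meta_or].
#' @return A data frame of class `"or_sensitivity"`, one row per model,
#'   with the failed fits (if any) recorded in attribute `"errors"`.
#' @examples
#' or_sensitivity(measles_data(2), models = c("1-DL", "4"))
#' @export
or_sensitivity <- function(data, models = c("1-DL", "1-REML", "4", "6", "7"),
                           drop00 = c("auto", "true", "false"),
                           n_agq = NULL, level = 0.95, control = list()) {
  drop00 <- match.arg(drop00)
  ds <- as_meta_2x2(data)
  models <- match.arg(as.character(models), or_models(), several.ok = TRUE)
  if ("2" %in% models)
    warning("model 2 (fixed baselines, uncentred random slope) badly ",
            "underestimates between-study variance; prefer model 4",
            call. = FALSE)
  n_events <- sum(ds$A + ds$C > 0)
  if (n_events < 3 && any(!startsWith(models, "1")))
    warning("only ", n_events, " studies have any events; mixed-model fits ",
            "are weakly identified with fewer than 3", call. = FALSE)
  rows <- list(); errs <- list()
  for (m in models) {
    fit <- tryCatch(meta_or(ds, model = m, drop00 = drop00, n_agq = n_agq,
                            level = level, control = control),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      errs[[m]] <- conditionMessage(fit)
      next
    }
    rows[[m]] <- data.frame(
      model = m, theta = fit$theta, se = fit$se,
      ci_lo = fit$ci[1], ci_hi = fit$ci[2],
      or = exp(fit$theta), or_lo = exp(fit$ci[1]), or_hi = exp(fit$ci[2]),
      tau2 = fit$tau2, loglik = if (is.null(fit$loglik)) NA_real_ else fit$loglik,
      k_used = fit$k_used, n_dropped = length(fit$dropped),
      converged = isTRUE(fit$converged),
      se_reliable = !isFALSE(fit$se_reliable),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("or_sensitivity", "data.frame")
  attr(out, "label") <- attr(ds, "label")
  attr(out, "level") <- level
  attr(out, "errors") <- errs
  out
}

#' @export
print.or_sensitivity <- function(x, digits = 3, ...) {
  lab <- attr(x, "label")
  cat("Sensitivity analysis", if (!is.null(lab)) paste0(" for '", lab, "'"),
      " (", 100 * attr(x, "level"), "% CIs)\n", sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits = digits)
  print(df, row.names = FALSE, ...)
  errs <- attr(x, "errors")
  if (length(errs))
    for (m in names(errs)) cat("model ", m, " failed: ", errs[[m]], "\n",
                               sep = "")
  invisible(x)
}

#' Run a simulation study from a YAML configuration file
#'
#' The configuration may contain the keys `settings`, `models`, `n_reps`,
#' `theta`, `seed`, `drop00`, `n_agq` and `se`; missing keys take the
#' [run_study] defaults.  The metrics table is written to
#' `metrics.csv` and the failure log to `failures.csv` in `out_dir`.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param out_dir output directory (created if needed).
#' @return The metrics data frame, invisibly.
#' @export
run_config <- function(config, out_dir = ".") {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  known <- c("settings", "models", "n_reps", "theta", "seed", "drop00",
             "n_agq", "se")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  args <- cfg[intersect(names(cfg), known)]
  if (!is.null(args$settings) && !all(unlist(args$settings) %in% 1:15))
    stop("invalid setting ids: ",
         paste(setdiff(unlist(args$settings), 1:15), collapse = ", "),
         "; valid ids are 1..15", call. = FALSE)
  if (!is.null(args$models)) args$models <- as.character(unlist(args$models))
  metrics <- do.call(run_study, args)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(attr(metrics, "failures"),
                   file.path(out_dir, "failures.csv"), row.names = FALSE)
  invisible(metrics)
}

#' Write the packaged datasets to a directory
#'
#' Copies the packaged CSV fixtures (the three measles-review analyses and
#' the illustrative dataset) into `dir`.
#'
#' @param dir destination directory (created if needed).
#' @return The written paths, invisibly.
#' @export
write_fixtures <- function(dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  src <- list.files(system.file("extdata", package = "ormeta"),
                    full.names = TRUE, pattern = "\\.csv$")
  dest <- file.path(dir, basename(src))
  file.copy(src, dest, overwrite = TRUE)
  invisible(dest)
}
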
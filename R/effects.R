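#' Per-study log odds ratios and within-study variances
#'
#' Computes the empirical log odds ratio `y = log((A/B)/(C/D))` and its
#' within-study variance `v = 1/A + 1/B + 1/C + 1/D` for every study.  With
#' the default zero rule, 0.5 is added to all four cells of any table that
#' contains a zero cell; tables without zero cells are left unmodified.
#'
#' @param ds a [meta_2x2] dataset (or anything [as_meta_2x2] accepts).
#' @param zero_rule `"half_if_zero"` (default) or `"none"`.  With `"none"`,
#'   a table containing a zero cell is an error.
#' @return A data frame with columns `study`, `y`, `v` and attribute
#'   `scale = "logor_wald"`.
#' @examples
#' log_or_effects(measles_data(1))
#' @export
log_or_effects <- function(ds, zero_rule = c("half_if_zero", "none")) {
  ds <- as_meta_2x2(ds)
  zero_rule <- match.arg(zero_rule)
  a <- as.numeric(ds$A); b <- as.numeric(ds$B)
  c <- as.numeric(ds$C); d <- as.numeric(ds$D)
  zero <- pmin(a, b, c, d) == 0
  if (any(zero)) {
    if (zero_rule == "none")
      stop("zero cell in study ", paste(ds$study[zero], collapse = ", "),
           "; use zero_rule = \"half_if_zero\"", call. = FALSE)
    a[zero] <- a[zero] + 0.5; b[zero] <- b[zero] + 0.5
    c[zero] <- c[zero] + 0.5; d[zero] <- d[zero] + 0.5
  }
  out <- data.frame(study = ds$study,
                    y = log((a / b) / (c / d)),
                    v = 1 / a + 1 / b + 1 / c + 1 / d,
                    stringsAsFactors = FALSE)
  attr(out, "scale") <- "logor_wald"
  attr(out, "corrected") <- ds$study[zero]
  out
}

#' Per-study Peto log odds ratios and variances
#'
#' The Peto effect for one table is `(O - E) / V` with variance `1 / V`,
#' where `O = A` is the observed number of treated events and `E` and `V`
#' are the mean and variance of the central hypergeometric distribution of
#' the treated events given all table margins:
#' `E = t * n1 / n`, `V = t * (n - t) * n0 * n1 / (n^2 * (n - 1))` with
#' `n1 = A + B`, `n0 = C + D`, `t = A + C`, `n = n0 + n1`.
#'
#' With the default zero rule, 0.5 is added to all four cells of any table
#' containing a zero cell before `O`, `E` and `V` are formed (the same rule
#' as [log_or_effects]); every table, including double-zero ones, then has a
#' defined effect.  With `zero_rule = "none"` the raw counts are used, and
#' studies with `V = 0` (no events or no non-events overall) have an
#' undefined effect: they are removed when `drop_undefined = TRUE` and
#' cause an error otherwise.
#'
#' @param ds a [meta_2x2] dataset.
#' @param zero_rule `"half_if_zero"` (default) or `"none"`.
#' @param drop_undefined drop studies with undefined effects (default) or
#'   raise an error.
#' @return A data frame with columns `study`, `y`, `v`, attribute
#'   `scale = "logor_peto"`, and attribute `"dropped"` listing removed
#'   studies.
#' @examples
#' peto_effects(measles_data(1))
#' @export
peto_effects <- function(ds, zero_rule = c("half_if_zero", "none"),
                         drop_undefined = TRUE) {
  ds <- as_meta_2x2(ds)
  zero_rule <- match.arg(zero_rule)
  a <- as.numeric(ds$A); b <- as.numeric(ds$B)
  c <- as.numeric(ds$C); d <- as.numeric(ds$D)
  if (zero_rule == "half_if_zero") {
    zero <- pmin(a, b, c, d) == 0
    a[zero] <- a[zero] + 0.5; b[zero] <- b[zero] + 0.5
    c[zero] <- c[zero] + 0.5; d[zero] <- d[zero] + 0.5
  }
  n1 <- a + b; n0 <- c + d
  t  <- a + c; n <- n0 + n1
  E <- t * n1 / n
  V <- t * (n - t) * n0 * n1 / (n^2 * (n - 1))
  bad <- V <= 0
  if (any(bad) && !drop_undefined)
    stop("undefined Peto effect (V = 0) in study ",
         paste(ds$study[bad], collapse = ", "), call. = FALSE)
  keep <- !bad
  if (!any(keep))
    stop("no study has a defined Peto effect", call. = FALSE)
  out <- data.frame(study = ds$study[keep],
                    y = (a[keep] - E[keep]) / V[keep],
                    v = 1 / V[keep],
                    stringsAsFactors = FALSE)
  attr(out, "scale") <- "logor_peto"
  attr(out, "dropped") <- ds$study[bad]
  out
}
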
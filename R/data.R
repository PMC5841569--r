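#' Construct a meta-analytic dataset of 2-by-2 tables
#'
#' A `meta_2x2` object is a data frame with one row per study and integer
#' count columns `A` (treated events), `B` (treated non-events), `C`
#' (control events) and `D` (control non-events).  Both arms of every study
#' must contain at least one patient.
#'
#' @param study study identifiers (unique).
#' @param A,B,C,D non-negative integer counts.
#' @param label optional dataset label used in printed output.
#' @return A data frame of class `"meta_2x2"`.
#' @examples
#' meta_2x2(study = 1:2, A = c(6, 2), B = c(35, 40), C = c(4, 5), D = c(36, 41))
#' @export
meta_2x2 <- function(study, A, B, C, D, label = NULL) {
  study <- as.character(study)
  counts <- list(A = A, B = B, C = C, D = D)
  for (nm in names(counts)) {
    x <- counts[[nm]]
    if (length(x) != length(study))
      stop("'", nm, "' must have one entry per study", call. = FALSE)
    if (any(!is.finite(x)) || any(x < 0) || any(abs(x - round(x)) > 1e-8))
      stop("column '", nm, "' must contain non-negative integer counts",
           call. = FALSE)
    counts[[nm]] <- as.integer(round(x))
  }
  if (anyDuplicated(study))
    stop("study identifiers must be unique", call. = FALSE)
  if (length(study) < 1L)
    stop("at least one study is required", call. = FALSE)
  ds <- data.frame(study = study, A = counts$A, B = counts$B,
                   C = counts$C, D = counts$D, stringsAsFactors = FALSE)
  if (any(ds$A + ds$B < 1L) || any(ds$C + ds$D < 1L))
    stop("each arm of each study must contain at least one patient",
         call. = FALSE)
  class(ds) <- c("meta_2x2", "data.frame")
  attr(ds, "label") <- label
  ds
}

#' @export
print.meta_2x2 <- function(x, ...) {
  lab <- attr(x, "label")
  cat("2x2 meta-analytic dataset", if (!is.null(lab)) paste0("'", lab, "'"),
      "with", nrow(x), "studies\n")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Convert long (arm-level) data to a wide 2-by-2 dataset
#'
#' The long format has one row per study arm with columns `study`,
#' `treat` (0 = control, 1 = treated), `n` (patients) and `event` (events);
#' exactly two rows per study, one per arm.
#'
#' @param records data frame in long format.
#' @param label optional dataset label.
#' @return A [meta_2x2] dataset.
#' @seealso [wide_to_long()] for the inverse conversion.
#' @export
long_to_wide <- function(records, label = NULL) {
  records <- as.data.frame(records)
  need <- c("study", "treat", "n", "event")
  if (!all(need %in% names(records)))
    stop("long format requires columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(records) == 0L)
    stop("at least one study is required", call. = FALSE)
  if (!all(records$treat %in% c(0, 1)))
    stop("'treat' must be 0 (control) or 1 (treated)", call. = FALSE)
  if (any(records$event > records$n) || any(records$event < 0))
    stop("'event' must lie in [0, n] for every arm", call. = FALSE)
  ids <- unique(as.character(records$study))
  rows <- lapply(ids, function(id) {
    sub <- records[as.character(records$study) == id, , drop = FALSE]
    if (nrow(sub) != 2L || !setequal(sub$treat, c(0, 1)))
      stop("study '", id, "' must have exactly one control and one treated arm",
           call. = FALSE)
    trt <- sub[sub$treat == 1, ]
    ctl <- sub[sub$treat == 0, ]
    data.frame(study = id, A = trt$event, B = trt$n - trt$event,
               C = ctl$event, D = ctl$n - ctl$event,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  meta_2x2(out$study, out$A, out$B, out$C, out$D, label = label)
}

#' Convert a wide 2-by-2 dataset to long (arm-level) format
#'
#' The output also carries the derived covariates `control` (indicator for
#' the control arm) and `treat12` (the centred coding `treat - 0.5`).
#'
#' @param ds a [meta_2x2] dataset.
#' @return A data frame with columns `study`, `treat`, `n`, `event`,
#'   `control`, `treat12` and two rows per study.
#' @export
wide_to_long <- function(ds) {
  ds <- as_meta_2x2(ds)
  long <- do.call(rbind, lapply(seq_len(nrow(ds)), function(i) {
    data.frame(study = ds$study[i], treat = c(0L, 1L),
               n = c(ds$C[i] + ds$D[i], ds$A[i] + ds$B[i]),
               event = c(ds$C[i], ds$A[i]), stringsAsFactors = FALSE)
  }))
  long$control <- 1L - long$treat
  long$treat12 <- long$treat - 0.5
  rownames(long) <- NULL
  long
}

#' Coerce to a meta_2x2 dataset
#'
#' Accepts a `meta_2x2` object, a wide data frame with columns
#' `study`, `A`, `B`, `C`, `D`, or a long data frame with columns
#' `study`, `treat`, `n`, `event`.
#'
#' @param x object to coerce.
#' @param label optional dataset label.
#' @return A [meta_2x2] dataset.
#' @export
as_meta_2x2 <- function(x, label = NULL) {
  if (inherits(x, "meta_2x2")) return(x)
  x <- as.data.frame(x)
  if (all(c("A", "B", "C", "D") %in% names(x)))
    return(meta_2x2(x$study, x$A, x$B, x$C, x$D,
                    label = if (is.null(label)) attr(x, "label") else label))
  if (all(c("study", "treat", "n", "event") %in% names(x)))
    return(long_to_wide(x, label = label))
  stop("cannot interpret 'x' as 2x2 meta-analytic data", call. = FALSE)
}

#' Read a 2-by-2 meta-analytic dataset from CSV
#'
#' Two dialects are supported: wide (`study,A,B,C,D`) and long
#' (`study,treat,n,event`, two rows per study).  With `format = "auto"` the
#' dialect is detected from the header.
#'
#' @param path path to a CSV file.
#' @param format `"auto"`, `"wide"` or `"long"`.
#' @param label optional dataset label (defaults to the file name).
#' @return A [meta_2x2] dataset.
#' @export
read_meta_csv <- function(path, format = c("auto", "wide", "long"),
                          label = NULL) {
  format <- match.arg(format)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(label)) label <- basename(path)
  if (format == "auto") {
    format <- if (all(c("A", "B", "C", "D") %in% names(df))) "wide"
              else if (all(c("treat", "n", "event") %in% names(df))) "long"
              else stop("cannot detect CSV dialect from header of ", path,
                        call. = FALSE)
  }
  if (format == "wide") meta_2x2(df$study, df$A, df$B, df$C, df$D, label = label)
  else long_to_wide(df, label = label)
}

#' Packaged example datasets from a measles antibiotic-prophylaxis review
#'
#' Returns one of the packaged 2-by-2 datasets: the pneumonia (`outcome = 1`),
#' diarrhoea (`outcome = 2`) or otitis media (`outcome = 4`) analyses of a
#' Cochrane review of antibiotics for preventing complications in children
#' with measles, or the 4-study illustrative dataset (`outcome = "illustrative"`).
#'
#' @param outcome `1`, `2`, `4` or `"illustrative"`.
#' @return A [meta_2x2] dataset.
#' @examples
#' measles_data(1)
#' @export
measles_data <- function(outcome = 1) {
  key <- as.character(outcome)
  file <- switch(key,
    "1" = "measles_outcome1.csv",
    "2" = "measles_outcome2.csv",
    "4" = "measles_outcome4.csv",
    "illustrative" = "illustrative.csv",
    stop("'outcome' must be 1, 2, 4 or \"illustrative\"", call. = FALSE))
  path <- system.file("extdata", file, package = "ormeta", mustWork = TRUE)
  lab <- switch(key, "1" = "pneumonia", "2" = "diarrhoea",
                "4" = "otitis media", "illustrative" = "illustrative")
  read_meta_csv(path, label = lab)
}

#' Remove uninformative studies from a dataset
#'
#' Removes double-zero studies (no events in either arm) and, with a
#' distinct warning, all-event studies (no non-events in either arm).
#' Neither kind of study carries information about the odds ratio in
#' conditional or fixed-intercept models.
#'
#' @param ds a [meta_2x2] dataset.
#' @return The reduced dataset; the removed study identifiers are attached
#'   as attributes `"dropped_double_zero"` and `"dropped_all_event"`.
#' @export
drop_double_zero <- function(ds) {
  ds <- as_meta_2x2(ds)
  dz <- ds$A + ds$C == 0L
  ae <- ds$B + ds$D == 0L
  if (any(ae))
    warning("removing all-event studies (no non-events): ",
            paste(ds$study[ae], collapse = ", "), call. = FALSE)
  keep <- !(dz | ae)
  if (!any(keep))
    stop("no informative studies remain after removing double-zero/all-event studies",
         call. = FALSE)
  out <- ds[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(ds)
  attr(out, "label") <- attr(ds, "label")
  attr(out, "dropped_double_zero") <- ds$study[dz]
  attr(out, "dropped_all_event") <- ds$study[ae]
  out
}
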
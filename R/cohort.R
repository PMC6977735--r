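#' Quantiles with the (n + 1)-based "exclusive" convention
#'
#' The exclusive method puts the q-th quantile at rank `h = q (n + 1)` with
#' linear interpolation between the flanking order statistics (clipped to
#' \[1, n\]); this is the convention common in clinical reporting software
#' and the one that reproduces printed interquartile ranges from small
#' cohort tables. The "inclusive" alternative interpolates at
#' `h = 1 + q (n - 1)`.
#'
#' @param values Non-empty numeric vector.
#' @param q Probabilities in \[0, 1\].
#' @param method `"exclusive"` (default) or `"inclusive"`.
#' @export
cohort_quantile <- function(values, q, method = c("exclusive", "inclusive")) {
  method <- match.arg(method)
  if (!length(values)) stop("input error: empty value list", call. = FALSE)
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]", call. = FALSE)
  unname(stats::quantile(values, probs = q, names = FALSE,
                         type = if (method == "exclusive") 6L else 7L))
}

clinical_columns <- c("pair_id", "age_primary", "age_recurrent", "sex",
                      "localization", "margin_primary", "margin_recurrent",
                      "time_to_recurrence")
margin_codes <- c("R0", "R1", "R2", "Rx")

validate_clinical <- function(df) {
  miss <- setdiff(clinical_columns, names(df))
  if (length(miss)) {
    stop(sprintf("clinical table is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(df$pair_id)) stop("duplicate pair ids", call. = FALSE)
  if (!all(tolower(df$sex) %in% c("male", "female"))) {
    stop("validation error: sex must be male or female", call. = FALSE)
  }
  if (!all(df$margin_primary %in% margin_codes) ||
      !all(df$margin_recurrent %in% margin_codes)) {
    stop("validation error: unknown resection margin code (expected R0/R1/R2/Rx)",
         call. = FALSE)
  }
  if (any(df$time_to_recurrence <= 0)) {
    stop("validation error: time to recurrence must be > 0", call. = FALSE)
  }
  if (any(df$age_recurrent < df$age_primary)) {
    stop("validation error: recurrent age below primary age", call. = FALSE)
  }
  df
}

#' Read a clinical table (one row per tumor pair) with strict validation
#'
#' Expected TSV columns: pair_id, age_primary, age_recurrent (years at
#' surgery), sex (male/female), localization, margin_primary and
#' margin_recurrent (R0 microscopically negative, R1 microscopically
#' positive, R2 macroscopically positive, Rx unknown/not assessed),
#' time_to_recurrence (years), and optionally dmr_count.
#'
#' @param path TSV file.
#' @return data.frame of class `clinical_table`.
#' @export
read_clinical <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  for (col in c("age_primary", "age_recurrent", "time_to_recurrence")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  if ("dmr_count" %in% names(df)) {
    df$dmr_count <- as.numeric(gsub(",", "", df$dmr_count))
  }
  df <- validate_clinical(df)
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Path of the packaged 27-pair clinical reference table
#' @export
clinical_fixture_path <- function() {
  system.file("extdata", "clinical_cohort27.tsv", package = "medmir",
              mustWork = TRUE)
}

#' Descriptive statistics of a paired tumor cohort
#'
#' Medians and interquartile ranges (exclusive quantiles via
#' [cohort_quantile()]) of age at primary surgery and time to recurrence;
#' counts by sex; localization grouped into extremity, retroperitoneum and
#' other; resection-margin counts separately for the primary and the
#' recurrent resection.
#'
#' @param table A `clinical_table`.
#' @param extremity_sites Localizations counted as extremity
#'   (case-insensitive; default upper/lower leg).
#' @param retro_sites Localizations counted as retroperitoneum.
#' @return An object of class `cohort_summary`.
#' @export
summarize_cohort <- function(table,
                             extremity_sites = c("upper leg", "lower leg"),
                             retro_sites = "retroperitoneal") {
  table <- validate_clinical(table)
  loc <- tolower(table$localization)
  cls <- ifelse(loc %in% tolower(extremity_sites), "extremity",
                ifelse(loc %in% tolower(retro_sites), "retroperitoneum",
                       "other"))
  margin_count <- function(x) {
    vapply(margin_codes, function(m) sum(x == m), 0L)
  }
  structure(list(
    n_pairs = nrow(table),
    age_primary = list(
      median = cohort_quantile(table$age_primary, 0.5),
      q1 = cohort_quantile(table$age_primary, 0.25),
      q3 = cohort_quantile(table$age_primary, 0.75)),
    time_to_recurrence = list(
      median = cohort_quantile(table$time_to_recurrence, 0.5),
      q1 = cohort_quantile(table$time_to_recurrence, 0.25),
      q3 = cohort_quantile(table$time_to_recurrence, 0.75)),
    sex = c(female = sum(tolower(table$sex) == "female"),
            male = sum(tolower(table$sex) == "male")),
    localization = c(extremity = sum(cls == "extremity"),
                     retroperitoneum = sum(cls == "retroperitoneum"),
                     other = sum(cls == "other")),
    margins = list(primary = margin_count(table$margin_primary),
                   recurrent = margin_count(table$margin_recurrent))),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d tumor pairs\n", x$n_pairs))
  cat(sprintf("  Age at primary surgery: median %g (IQR %g-%g)\n",
              x$age_primary$median, x$age_primary$q1, x$age_primary$q3))
  cat(sprintf("  Time to recurrence (y): median %g (IQR %g-%g)\n",
              x$time_to_recurrence$median, x$time_to_recurrence$q1,
              x$time_to_recurrence$q3))
  cat(sprintf("  Sex: %d female / %d male\n", x$sex["female"], x$sex["male"]))
  cat(sprintf("  Localization: %d extremity, %d retroperitoneum, %d other\n",
              x$localization["extremity"], x$localization["retroperitoneum"],
              x$localization["other"]))
  cat("  Margins (primary):  ",
      paste(sprintf("%s=%d", names(x$margins$primary), x$margins$primary),
            collapse = " "), "\n")
  cat("  Margins (recurrent):",
      paste(sprintf("%s=%d", names(x$margins$recurrent), x$margins$recurrent),
            collapse = " "), "\n")
  invisible(x)
}

#' Write a cohort summary as a key-value TSV
#' @param x A `cohort_summary`.
#' @param path Output file.
#' @export
write_cohort_summary <- function(x, path) {
  kv <- c(n_pairs = x$n_pairs,
          age_primary_median = x$age_primary$median,
          age_primary_q1 = x$age_primary$q1,
          age_primary_q3 = x$age_primary$q3,
          time_to_recurrence_median = x$time_to_recurrence$median,
          time_to_recurrence_q1 = x$time_to_recurrence$q1,
          time_to_recurrence_q3 = x$time_to_recurrence$q3,
          stats::setNames(x$sex, paste0("sex_", names(x$sex))),
          stats::setNames(x$localization,
                          paste0("localization_", names(x$localization))),
          stats::setNames(x$margins$primary,
                          paste0("margin_primary_", names(x$margins$primary))),
          stats::setNames(x$margins$recurrent,
                          paste0("margin_recurrent_", names(x$margins$recurrent))))
  writeLines(sprintf("%s\t%g", names(kv), kv), path)
  invisible(path)
}
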
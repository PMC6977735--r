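#' Generate a synthetic clinical table of tumor pairs
#'
#' Emits one row per pair with the standard paired-cohort schema: ages at
#' primary and recurrent surgery, sex, tumor localization, resection margins
#' for both surgeries (R0/R1/R2/Rx) and time to recurrence in years. The
#' recurrent age equals the primary age plus the rounded time to recurrence,
#' so the table is internally consistent. Marginal distributions mimic a
#' retrospective soft-tissue-sarcoma cohort: ages centered in the late 50s,
#' log-normal time to recurrence with median near 4 years, extremity the
#' most common site, and roughly a third of primary margins unassessed (Rx).
#'
#' @param n_pairs Number of pairs (>= 1).
#' @param seed Integer seed.
#' @return data.frame of class `clinical_table` (same schema as
#'   [read_clinical()]).
#' @export
generate_clinical <- function(n_pairs, seed = 1L) {
  if (n_pairs < 1) stop("sizing error: n_pairs must be >= 1", call. = FALSE)
  with_seed(seed, {
    age <- pmin(pmax(round(stats::rnorm(n_pairs, 57, 12)), 18), 90)
    ttr <- pmax(round(stats::rlnorm(n_pairs, log(3.7), 0.8), 1), 0.1)
    df <- data.frame(
      pair_id = sprintf("P%02d", seq_len(n_pairs)),
      age_primary = age,
      age_recurrent = age + round(ttr),
      sex = sample(c("Female", "Male"), n_pairs, replace = TRUE),
      localization = sample(c("Upper leg", "Lower leg", "Retroperitoneal",
                              "Axilla", "Mediastinum", "Esophagus", "Trunk"),
                            n_pairs, replace = TRUE,
                            prob = c(0.45, 0.10, 0.30, 0.04, 0.04, 0.03, 0.04)),
      margin_primary = sample(c("R0", "R1", "R2", "Rx"), n_pairs,
                              replace = TRUE, prob = c(0.15, 0.47, 0.04, 0.34)),
      margin_recurrent = sample(c("R0", "R1", "R2", "Rx"), n_pairs,
                                replace = TRUE, prob = c(0.19, 0.51, 0.15, 0.15)),
      time_to_recurrence = ttr)
    class(df) <- c("clinical_table", "data.frame")
    validate_clinical(df)
    df
  })
}

#' Write a clinical table as TSV
#' @param table A `clinical_table`.
#' @param path Output file.
#' @export
write_clinical <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
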
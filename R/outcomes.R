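#' Derive clinical outcomes from raw questionnaire and challenge fields
#'
#' Applies the cohort's outcome definitions to raw per-subject fields:
#' \itemize{
#'   \item current wheeze: wheeze/whistling in the chest in the last 12 months;
#'   \item current asthma: positive answer to at least 2 of \{doctor-diagnosed
#'     asthma, wheeze in the last 12 months, asthma treatment in the last 12
#'     months\} (the 2-of-3 rule);
#'   \item current hay fever / eczema: their single questions;
#'   \item airway hyperreactivity (AHR): a greater than 20\% fall in FEV1 by
#'     the final methacholine stage;
#'   \item dose-response slope (DRS): percent FEV1 fall at the last dose
#'     divided by the cumulative administered dose in mg.
#' }
#' Missing inputs propagate to missing outcomes. Boolean fields must be coded
#' 0/1 (or logical); any other coding is rejected.
#'
#' @param raw data.frame with columns `subject`, `asthma_diagnosis_ever`,
#'   `wheeze_12mo`, `asthma_treatment_12mo`, `hayfever_now`, `itchy_rash_12mo`,
#'   `fev1_pct_pred`, `fev1_fvc`, `fev1_fall_pct`, `methacholine_cum_dose_mg`,
#'   `eno_ppb`. Extra columns are carried through.
#' @param ahr_fall_threshold Percent FEV1 fall defining AHR (default 20).
#' @return The input with derived columns `current_wheeze`, `current_asthma`,
#'   `current_hayfever`, `current_eczema`, `ahr`, `drs` appended.
#' @export
derive_outcomes <- function(raw, ahr_fall_threshold = 20) {
  need <- c("subject", "asthma_diagnosis_ever", "wheeze_12mo",
            "asthma_treatment_12mo", "hayfever_now", "itchy_rash_12mo")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing outcome column(s): ", paste(miss, collapse = ", "))

  as_bool01 <- function(x, nm) {
    if (is.logical(x)) x <- as.integer(x)
    bad <- !is.na(x) & !(x %in% c(0, 1))
    if (any(bad)) stop("column '", nm, "' has non-boolean coded value(s): ",
                       paste(unique(x[bad]), collapse = ", "))
    as.integer(x)
  }
  diag3 <- as_bool01(raw$asthma_diagnosis_ever, "asthma_diagnosis_ever")
  whz   <- as_bool01(raw$wheeze_12mo, "wheeze_12mo")
  trt   <- as_bool01(raw$asthma_treatment_12mo, "asthma_treatment_12mo")

  out <- raw
  out$current_wheeze   <- whz
  out$current_asthma   <- as.integer(diag3 + whz + trt >= 2L)
  out$current_hayfever <- as_bool01(raw$hayfever_now, "hayfever_now")
  out$current_eczema   <- as_bool01(raw$itchy_rash_12mo, "itchy_rash_12mo")

  if (!is.null(raw$fev1_fall_pct)) {
    out$ahr <- as.integer(raw$fev1_fall_pct > ahr_fall_threshold)
    if (!is.null(raw$methacholine_cum_dose_mg)) {
      out$drs <- raw$fev1_fall_pct / raw$methacholine_cum_dose_mg
    }
  }
  if (!is.null(raw$fev1_pct_pred)) {
    bad <- !is.na(raw$fev1_pct_pred) & raw$fev1_pct_pred <= 0
    if (any(bad)) stop("fev1_pct_pred must be positive where present")
  }
  out
}

#' Read a raw outcomes table keyed by subject ID
#' @param path CSV/TSV path.
#' @param sep Separator; guessed from the extension when `NULL`.
#' @export
read_outcomes <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    na.strings = c("", "NA"))
}
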
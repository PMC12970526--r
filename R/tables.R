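# Reference measurement tables shipped with the package: per-condition GP
# and lifetime statistics (mean, SD, n) for DOPC and binary-mixture GUVs,
# and the gel-swelling calibration series of defined cholesterol content.
# These drive the calibration fits and serve as generating statistics for
# phantom recovery experiments.

#' Load a bundled reference table
#'
#' @param name one of:
#' * `"calibration_dopc"`: gel-swelling DOPC GUVs at 0/10/25/40 mol%
#'   cholesterol -- GP and lifetime means and SDs (the calibration series);
#' * `"edice_dopc"`: eDICE DOPC GUVs at 0/10/30/100 uM MbCD-cholesterol --
#'   GP and lifetime statistics;
#' * `"edice_binary_gp"`: eDICE binary-mixture GUVs (DOPC:DMPC and
#'   DOPC:PC(18:0-14:0), 6:4), GP statistics per MbCD-cholesterol dose;
#' * `"edice_binary_lifetime"`: same conditions, lifetime statistics (ns).
#' @return data.frame; units are carried in the column names.
#' @export
guv_reference_table <- function(name = c("calibration_dopc", "edice_dopc",
                                         "edice_binary_gp",
                                         "edice_binary_lifetime")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "guvchol",
                      mustWork = TRUE)
  read.csv(path, check.names = FALSE)
}

#' Calibration points for one modality from the bundled calibration table
#'
#' Reshapes the gel-swelling calibration table into the column layout
#' [fit_calibration()] expects.
#'
#' @param modality `"GP"` or `"lifetime"`.
#' @return data.frame with `chol_molpct`, `readout_mean`, `readout_sd`,
#'   `n_vesicles`.
#' @export
calibration_points <- function(modality = c("GP", "lifetime")) {
  modality <- match.arg(modality)
  tab <- guv_reference_table("calibration_dopc")
  if (modality == "GP") {
    data.frame(chol_molpct = tab$chol_molpct, readout_mean = tab$gp_mean,
               readout_sd = tab$gp_sd, n_vesicles = tab$n_vesicles)
  } else {
    data.frame(chol_molpct = tab$chol_molpct,
               readout_mean = tab$lifetime_mean_ns,
               readout_sd = tab$lifetime_sd_ns, n_vesicles = tab$n_vesicles)
  }
}
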
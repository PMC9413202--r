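## Reference per-compound results for 20 approved drugs, transcribed as
## a packaged fixture. These are the printed outputs of the original
## compatibility study (central and peripheral AUC_last for the
## whole-body, lumped, and compartment models, and clearance for the
## three models); they exercise the comparison layer, while the
## simulation layer is tested on synthetic drugs only.

#' Reference compatibility tables for 20 model compounds
#'
#' One row per compound with columns `central_*` and `peripheral_*`
#' (AUC_last, mg*h/L; `peripheral_compartment` is `NA` for the eleven
#' one-compartment drugs) and `cl_*` (L/h/kg) for
#' `* = pbpk, lumped, compartment`. The whole-body "central" value is
#' the mean AUC_last of lung, arterial and venous blood; "peripheral"
#' is the mean over the seven non-eliminating tissues.
#'
#' @return A 20-row data frame.
#' @export
fixture_tables <- function() {
  path <- system.file("extdata", "compatibility_tables.csv",
                      package = "pklump")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Accuracy of AUC for every fixture compound
#'
#' Applies [auc_accuracy()] to the reference values: lumped central AUC,
#' lumped and compartment clearances, and the observed compartment
#' central AUC.
#'
#' @param tables Data frame as returned by [fixture_tables()].
#' @return Named numeric vector of accuracies, one per compound.
#' @export
fixture_auc_accuracy <- function(tables = fixture_tables()) {
  stats::setNames(
    mapply(auc_accuracy, tables$central_lumped, tables$cl_lumped,
           tables$cl_compartment, tables$central_compartment),
    tables$compound)
}
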
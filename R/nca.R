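## Non-compartmental analysis of simulated concentration profiles.

#' Trapezoidal AUC to the last time point
#'
#' Linear trapezoidal rule over the observed interval. Profiles here are
#' dense simulation output, so the linear rule is numerically
#' indistinguishable from log-linear alternatives.
#'
#' @param times Strictly increasing time vector (h).
#' @param conc Non-negative concentrations, same length.
#' @return AUC_last (mg*h/L); 0 for a single point.
#' @export
auc_last <- function(times, conc) {
  if (length(times) != length(conc))
    stop_validation("times and conc must have the same length")
  if (length(times) < 2) return(0)
  if (any(diff(times) <= 0))
    stop_validation("times must be strictly increasing")
  if (any(conc < 0))
    stop_validation("concentrations must be non-negative")
  sum(diff(times) * (utils::head(conc, -1) + utils::tail(conc, -1)) / 2)
}

## Terminal elimination rate constant from a log-linear regression on
## the terminal fraction of the grid (points with positive conc).
terminal_slope <- function(times, conc, terminal_fraction = 0.1) {
  n <- length(times)
  idx <- times >= times[n] - terminal_fraction * (times[n] - times[1]) &
    conc > 0
  if (sum(idx) < 3)
    stop_validation("too few positive terminal points for lambda_z")
  fit <- stats::lm(log(conc[idx]) ~ times[idx])
  lam <- -unname(stats::coef(fit)[2])
  if (!is.finite(lam) || lam <= 0)
    stop_validation("non-positive terminal slope; profile not declining")
  lam
}

#' AUC extrapolated to infinity
#'
#' `AUC_last + C_last / lambda_z`, with `lambda_z` from a log-linear
#' regression on the terminal 10% of the grid.
#'
#' @inheritParams auc_last
#' @param terminal_fraction Fraction of the grid used for `lambda_z`.
#' @return A list with `auc_last`, `auc_inf`, `lambda_z`, `t_last`.
#' @export
auc_inf <- function(times, conc, terminal_fraction = 0.1) {
  al <- auc_last(times, conc)
  lam <- terminal_slope(times, conc, terminal_fraction)
  list(auc_last = al,
       auc_inf = al + conc[length(conc)] / lam,
       lambda_z = lam, t_last = times[length(times)])
}

#' Mean AUC_last over a set of tissues
#'
#' Unweighted arithmetic mean of the per-tissue `AUC_last` values of a
#' simulation, as used for the whole-body model's central (lung,
#' arterial, venous) and peripheral (non-eliminating tissues) summaries.
#'
#' @param result A `simulation_result`.
#' @param tissues Character vector of compartment names present in
#'   `result$concentrations`.
#' @return Mean AUC_last (mg*h/L).
#' @export
average_tissue_auc <- function(result, tissues) {
  miss <- setdiff(tissues, colnames(result$concentrations))
  if (length(miss))
    stop_validation("unknown tissue(s): ", paste(miss, collapse = ", "))
  mean(vapply(tissues, function(tt)
    auc_last(result$times, result$concentrations[, tt]), numeric(1)))
}
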
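## Compatibility layer: 2-fold criteria, pass counts, accuracy of AUC,
## the Vd/fu power-law relation, and tissue back-prediction.

## Relative tolerance applied to the inclusive 2-fold boundary, so that
## ratios that are exactly 2 in decimal (e.g. 0.060/0.030) are not
## rejected by floating-point round-off.
TWOFOLD_TOL <- 1e-9

#' 2-fold acceptance range
#'
#' @param x A positive value.
#' @return Numeric vector `c(low, high) = c(x/2, 2*x)`.
#' @export
twofold_range <- function(x) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_validation("x must be a single positive number")
  c(low = x / 2, high = 2 * x)
}

#' 2-fold compatibility verdict
#'
#' TRUE when `0.5 <= a/b <= 2`, boundaries inclusive (a ratio of exactly
#' 2 passes). Symmetric in its arguments.
#'
#' @param a,b Positive values.
#' @return Logical verdict.
#' @export
within_twofold <- function(a, b) {
  if (!all(is.finite(c(a, b))) || a <= 0 || b <= 0)
    stop_validation("within_twofold needs positive finite values")
  r <- a / b
  r >= 0.5 * (1 - TWOFOLD_TOL) && r <= 2 * (1 + TWOFOLD_TOL)
}

## Max/min ratio of a vector of positive values <= 2 (inclusive): the
## "all three models within 2-fold" criterion.
all_within_twofold <- function(values) {
  values <- values[!is.na(values)]
  if (any(values <= 0)) stop_validation("values must be positive")
  max(values) / min(values) <= 2 * (1 + TWOFOLD_TOL)
}

#' Count compounds compatible under the 2-fold criterion
#'
#' Operates on a compatibility table with one row per compound and
#' columns `central_pbpk`, `central_lumped`, `central_compartment`,
#' `peripheral_pbpk`, `peripheral_lumped`, `peripheral_compartment`
#' (AUC_last, mg*h/L; NA where a one-compartment drug has no peripheral
#' compartment) and `cl_pbpk`, `cl_lumped`, `cl_compartment` (L/h/kg).
#'
#' @param report Data frame as above (see [fixture_tables()] or
#'   [run_compatibility_pipeline()]).
#' @param pair `"pbpk_lumped"`, `"lumped_compartment"`,
#'   `"pbpk_compartment"`, or `"all"` (all three models jointly, used
#'   for clearance).
#' @param compartment Scope of the comparison: `"central"`,
#'   `"peripheral"`, `"both"` (central and peripheral jointly), or
#'   `"cl"` (clearance). Compounds without a peripheral value for a
#'   compared model are excluded from `"peripheral"` totals.
#' @return Named numeric vector `c(n_pass, n_total)`.
#' @export
compatibility_counts <- function(report,
                                 pair = c("pbpk_lumped",
                                          "lumped_compartment",
                                          "pbpk_compartment", "all"),
                                 compartment = c("central", "peripheral",
                                                 "both", "cl")) {
  pair <- match.arg(pair)
  compartment <- match.arg(compartment)
  if (!is.data.frame(report) || nrow(report) == 0)
    stop_validation("report must be a non-empty data frame")
  models <- if (pair == "all") c("pbpk", "lumped", "compartment")
            else strsplit(pair, "_")[[1]]
  scopes <- switch(compartment,
                   central = "central", peripheral = "peripheral",
                   both = c("central", "peripheral"), cl = "cl")
  verdict <- rep(TRUE, nrow(report))
  usable <- rep(TRUE, nrow(report))
  for (sc in scopes) {
    vals <- as.matrix(report[, paste(sc, models, sep = "_"), drop = FALSE])
    row_ok <- vapply(seq_len(nrow(vals)), function(i) {
      if (any(is.na(vals[i, ]))) return(NA)
      all_within_twofold(vals[i, ])
    }, logical(1))
    if (sc == "peripheral" && compartment == "peripheral")
      usable <- usable & !is.na(row_ok)
    ## in the joint scope, compounds lacking a peripheral entry are
    ## judged on the compartments they have
    verdict <- verdict & (is.na(row_ok) | row_ok)
  }
  c(n_pass = sum(verdict[usable]), n_total = sum(usable))
}

#' Accuracy of the AUC between lumped and compartment models
#'
#' The theoretical compartment AUC is the lumped central (LCEN) AUC
#' scaled by the clearance ratio,
#' `AUC_theoretical = AUC_LCEN * CL_lumped / CL_compartment`, and the
#' accuracy is `AUC_compartment_observed / AUC_theoretical`. A value
#' near one indicates model compatibility.
#'
#' @param auc_lcen Lumped-model central AUC_last (mg*h/L).
#' @param cl_lumped,cl_compartment Clearances on a common scale
#'   (L/h/kg).
#' @param auc_compartment_observed Compartment-model central AUC_last.
#' @return Accuracy (dimensionless).
#' @export
auc_accuracy <- function(auc_lcen, cl_lumped, cl_compartment,
                         auc_compartment_observed) {
  vals <- c(auc_lcen, cl_lumped, cl_compartment, auc_compartment_observed)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop_validation("all inputs must be positive and finite")
  auc_compartment_observed / (auc_lcen * cl_lumped / cl_compartment)
}

#' Distribution-to-binding ratio Vd/fu
#'
#' `Vd = Vc + Vp` (with `Vp = 0` for one-compartment drugs) divided by
#' the unbound fraction.
#'
#' @param vc Central volume (L/kg).
#' @param vp Peripheral volume (L/kg); 0 when absent.
#' @param fu Unbound fraction in (0, 1].
#' @return `(vc + vp) / fu`.
#' @export
vd_over_fu <- function(vc, vp, fu) {
  if (is.na(vp)) vp <- 0
  if (!is.finite(fu) || fu <= 0 || fu > 1)
    stop_validation("fu must be in (0, 1]")
  (vc + vp) / fu
}

#' Fit a power law y = a * x^b
#'
#' Ordinary least squares on the log-log scale (deterministic, no
#' nonlinear iteration).
#'
#' @param x,y Positive vectors of equal length, n >= 3.
#' @return List with `a`, `b`, `r_squared`.
#' @export
fit_power_law <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop_validation("need at least 3 paired values")
  if (any(x <= 0) || any(y <= 0))
    stop_validation("power-law fit needs positive values")
  ly <- log(y)
  fit <- stats::lm(ly ~ log(x))
  cf <- stats::coef(fit)
  list(a = unname(exp(cf[1])), b = unname(cf[2]),
       r_squared = 1 - sum(stats::resid(fit)^2) / sum((ly - mean(ly))^2))
}

#' Back-predict a tissue concentration from a compartment-model profile
#'
#' `C_T = C_p * (Vp_compartment / Vp_lumped) * (Kp_T / K_Lump)`: the
#' compartment-model peripheral concentration is rescaled to a specific
#' tissue of the whole-body model through the volume and partition
#' ratios.
#'
#' @param c_p Compartment-model peripheral concentration(s) (mg/L).
#' @param vp_compartment,vp_lumped Peripheral volumes (L/kg).
#' @param kp_t Tissue partition coefficient.
#' @param k_lump Lumped-compartment partition coefficient.
#' @return Predicted tissue concentration(s) (mg/L).
#' @export
back_predict_tissue_concentration <- function(c_p, vp_compartment,
                                              vp_lumped, kp_t, k_lump) {
  scalars <- c(vp_compartment, vp_lumped, kp_t, k_lump)
  if (!all(is.finite(scalars)) || any(scalars <= 0))
    stop_validation("volumes and partition coefficients must be positive")
  c_p * (vp_compartment / vp_lumped) * (kp_t / k_lump)
}
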
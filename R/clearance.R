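## Clearance algebra shared by the PBPK and lumped models.

#' Well-stirred hepatic clearance
#'
#' Treats the liver as a single well-mixed pool:
#' `CL_hep = Q_li * fu * CL_int / (fu * CL_int + Q_li)`. The result is
#' bounded by the hepatic blood flow `Q_li` for finite intrinsic
#' clearance.
#'
#' @param Q_li Total hepatic blood flow (L/h).
#' @param fu Unbound fraction in plasma.
#' @param CL_int Intrinsic hepatic clearance (L/h).
#' @return Hepatic clearance (L/h).
#' @export
hepatic_clearance_well_stirred <- function(Q_li, fu, CL_int) {
  assert_scalar_number(Q_li, "Q_li", lower = 0)
  assert_scalar_number(fu, "fu", lower = 0)
  assert_scalar_number(CL_int, "CL_int", lower = 0)
  if (fu * CL_int == 0) return(0)
  Q_li * fu * CL_int / (fu * CL_int + Q_li)
}

#' Total clearance
#'
#' Sum of the organ clearances, `CL_T = CL_hep + CL_ki + CL_others`. In
#' this package only liver and kidney eliminate, so `CL_others` defaults
#' to zero.
#'
#' @param CL_hep Hepatic clearance (L/h).
#' @param CL_ki Renal clearance (L/h).
#' @param CL_others Clearance of all other tissues (L/h).
#' @return Total clearance (L/h).
#' @export
total_clearance <- function(CL_hep, CL_ki, CL_others = 0) {
  assert_scalar_number(CL_hep, "CL_hep", lower = 0)
  assert_scalar_number(CL_ki, "CL_ki", lower = 0)
  assert_scalar_number(CL_others, "CL_others", lower = 0)
  CL_hep + CL_ki + CL_others
}

#' Effective blood clearance of the whole-body model
#'
#' Closed-form blood clearance implied by the model wiring for an
#' intravenous dose: integrating the liver and kidney balances to
#' infinity gives
#' `CL_blood = Q_li*fu*CL_hep/(Q_li + fu*CL_hep) +
#'  Q_ki*fu*CL_ki/(Q_ki + fu*CL_ki)`
#' so that `AUC(0-Inf)` of the venous blood concentration equals
#' `dose / CL_blood`. The same expression holds for the lumped model,
#' whose liver and kidney wiring is identical: total clearance is
#' invariant under lumping.
#'
#' @param phys A `physiology_set`.
#' @param drug A `drug_parameters` object.
#' @return Blood clearance (L/h).
#' @export
blood_clearance <- function(phys, drug) {
  q_li <- liver_total_flow(phys)
  q_ki <- unname(phys$flows[["kidney"]])
  e_hep <- drug$fu * drug$CL_hep
  e_ki <- drug$fu * drug$CL_ki
  hep <- if (e_hep > 0) q_li * e_hep / (q_li + e_hep) else 0
  ki <- if (e_ki > 0) q_ki * e_ki / (q_ki + e_ki) else 0
  hep + ki
}

#' Blood-referenced steady-state volume of distribution
#'
#' `Vss = V_arterial + V_venous + sum(V_T * Kp_T / BP)` over all
#' perfused tissues including lung: the apparent volume at blood
#' concentration once every tissue has equilibrated.
#'
#' @param phys A `physiology_set`.
#' @param drug A `drug_parameters` object.
#' @return Steady-state volume (L).
#' @export
steady_state_volume <- function(phys, drug) {
  tt <- kp_tissues()
  unname(phys$volumes[["arterial"]] + phys$volumes[["venous"]] +
           sum(phys$volumes[tt] * drug$Kp[tt]) / drug$BP)
}

#' Simulation horizon covering the elimination phase
#'
#' `n_half_lives * ln(2) * Vss / CL_blood`, an upper bound on the time
#' needed to observe the stated number of terminal half-lives.
#'
#' @param phys A `physiology_set`.
#' @param drug A `drug_parameters` object with non-zero clearance.
#' @param n_half_lives Number of terminal half-lives to cover.
#' @return Suggested `t_end` (h).
#' @export
elimination_horizon <- function(phys, drug, n_half_lives = 8) {
  cl <- blood_clearance(phys, drug)
  if (cl <= 0)
    stop_validation("drug has no elimination; horizon undefined")
  n_half_lives * log(2) * steady_state_volume(phys, drug) / cl
}
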
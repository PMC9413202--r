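## ODE system construction and integration. State variables are drug
## amounts (mg); concentrations (mg/L) are derived after integration so
## that no volume division happens inside the integrator.

new_ode_system <- function(state_names, volumes, rhs, dose, dose_state,
                           label) {
  structure(list(state_names = state_names, volumes = volumes,
                 rhs = rhs, dose = dose, dose_state = dose_state,
                 label = label),
            class = "ode_system")
}

#' @export
print.ode_system <- function(x, ...) {
  cat("ODE system '", x$label, "' with ", length(x$state_names),
      " states: ", paste(x$state_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Build the whole-body PBPK ODE system
#'
#' Constructs the perfusion-rate-limited whole-body model: the lung is
#' fed by venous blood, arterial blood by the lung, every systemic
#' tissue by arterial blood, and venous blood collects the tissue
#' outflows. Gut and spleen drain into the liver (portal vein), so the
#' liver inflow is `Q_ha*C_A + Q_gu*C_gu_out + Q_sp*C_sp_out` and gut
#' and spleen are excluded from the venous return sum. Tissue outflow
#' concentrations are `C_T / (Kp_T / BP)`. Liver and kidney eliminate at
#' rates `fu*CL_hep*C_li/(Kp_li/BP)` and `fu*CL_ki*C_ki/(Kp_ki/BP)`.
#' Oral doses enter a first-order depot (rate `Ka`) emptying into the
#' gut tissue, so hepatic first-pass arises mechanistically;
#' intravenous boluses enter venous blood.
#'
#' @param phys A `physiology_set`.
#' @param drug A `drug_parameters` object with a `Kp` entry for every
#'   non-blood tissue of [pbpk_tissues()].
#' @return An `ode_system` with states `depot`, the fourteen body
#'   compartments, and a cumulative `eliminated` bookkeeping state.
#' @export
build_pbpk_odes <- function(phys, drug) {
  miss <- setdiff(kp_tissues(), names(drug$Kp))
  if (length(miss))
    stop_validation("drug lacks Kp for tissue(s): ",
                    paste(miss, collapse = ", "))
  tissues <- pbpk_tissues()
  states <- c("depot", tissues, "eliminated")
  V <- phys$volumes
  Q <- phys$flows
  BP <- drug$BP
  Kp <- drug$Kp
  fu <- drug$fu
  ka <- drug$Ka
  q_li <- liver_total_flow(phys)
  ## venous return: all systemic tissues except gut and spleen; the
  ## liver returns its total (arterial + portal) flow
  ret_tissues <- setdiff(systemic_tissues(), c("gut", "spleen"))
  ret_flows <- Q[ret_tissues]
  ret_flows[["liver"]] <- q_li
  ## outflow concentration factor per perfused tissue: BP / Kp
  out_fac <- BP / Kp

  rhs <- function(t, a) {
    conc <- a[tissues] / V
    c_out <- conc[kp_tissues()] * out_fac[kp_tissues()]
    c_a <- conc[["arterial"]]
    c_v <- conc[["venous"]]
    d <- numeric(length(states))
    names(d) <- states
    absorbed <- ka * a[["depot"]]
    d[["depot"]] <- -absorbed
    d[["gut"]] <- Q[["gut"]] * (c_a - c_out[["gut"]]) + absorbed
    d[["spleen"]] <- Q[["spleen"]] * (c_a - c_out[["spleen"]])
    elim_hep <- fu * drug$CL_hep * c_out[["liver"]]
    d[["liver"]] <- Q[["liver"]] * c_a +
      Q[["gut"]] * c_out[["gut"]] + Q[["spleen"]] * c_out[["spleen"]] -
      q_li * c_out[["liver"]] - elim_hep
    elim_ki <- fu * drug$CL_ki * c_out[["kidney"]]
    d[["kidney"]] <- Q[["kidney"]] * (c_a - c_out[["kidney"]]) - elim_ki
    for (tt in net_tissues())
      d[[tt]] <- Q[[tt]] * (c_a - c_out[[tt]])
    d[["lung"]] <- Q[["lung"]] * (c_v - c_out[["lung"]])
    d[["arterial"]] <- Q[["lung"]] * (c_out[["lung"]] - c_a)
    d[["venous"]] <- sum(ret_flows * c_out[ret_tissues]) - Q[["lung"]] * c_v
    d[["eliminated"]] <- elim_hep + elim_ki
    d
  }

  vols <- c(depot = NA_real_, V[tissues], eliminated = NA_real_)
  names(vols) <- states
  new_ode_system(states, vols, rhs, drug$dose,
                 if (drug$route == "oral") "depot" else "venous",
                 paste0("pbpk:", drug$name))
}

#' Integrate an ODE system on a time grid
#'
#' Uses a stiff-capable solver (`deSolve::lsoda`) with tight default
#' tolerances; partition coefficients spanning orders of magnitude make
#' the systems stiff.
#'
#' @param system An `ode_system` from [build_pbpk_odes()] or
#'   [build_lumped_odes()].
#' @param times Strictly increasing time grid (h) starting at 0.
#' @param rtol,atol Relative and absolute solver tolerances.
#' @return A `simulation_result` with elements `times`, `amounts` (mg,
#'   one column per state), `concentrations` (mg/L, states with a
#'   physical volume), `eliminated` (cumulative mg) and `dose`.
#' @export
simulate_system <- function(system, times, rtol = 1e-8, atol = 1e-10) {
  if (length(times) < 2 || times[1] != 0 || any(diff(times) <= 0))
    stop_validation("times must be a strictly increasing grid starting at 0")
  y0 <- numeric(length(system$state_names))
  names(y0) <- system$state_names
  y0[[system$dose_state]] <- system$dose
  func <- function(t, y, parms) list(system$rhs(t, y))
  sol <- deSolve::ode(y = y0, times = times, func = func, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE solver failed: ",
         paste(utils::capture.output(deSolve::diagnostics(sol)),
               collapse = "\n"))
  amounts <- unclass(sol)[, system$state_names, drop = FALSE]
  has_vol <- !is.na(system$volumes)
  conc <- sweep(amounts[, has_vol, drop = FALSE], 2,
                system$volumes[has_vol], "/")
  structure(list(times = times, amounts = amounts, concentrations = conc,
                 eliminated = amounts[, "eliminated"],
                 dose = system$dose, volumes = system$volumes,
                 label = system$label),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("Simulation '", x$label, "': ", length(x$times), " time points to ",
      format(max(x$times)), " h, ", ncol(x$concentrations),
      " concentration series\n", sep = "")
  invisible(x)
}

#' Mass-balance error of a simulation
#'
#' Largest absolute deviation, over the grid, of
#' `sum(amounts) + eliminated` from the dose, as a fraction of the dose.
#'
#' @param result A `simulation_result`.
#' @return Maximum relative mass-balance error (dimensionless).
#' @export
mass_balance_error <- function(result) {
  keep <- setdiff(colnames(result$amounts), "eliminated")
  total <- rowSums(result$amounts[, keep, drop = FALSE]) + result$eliminated
  if (result$dose == 0) return(max(abs(total)))
  max(abs(total - result$dose)) / result$dose
}

#' Regular simulation grid
#'
#' @param t_end End of the simulation interval (h).
#' @param n Number of grid points (default 2001, dense enough that
#'   linear-trapezoid NCA error is negligible).
#' @return Numeric vector from 0 to `t_end`.
#' @export
sim_grid <- function(t_end, n = 2001) {
  assert_scalar_number(t_end, "t_end", lower = 0, open_lower = TRUE)
  seq(0, t_end, length.out = n)
}

#' Tidy trajectory export
#'
#' @param result A `simulation_result`.
#' @param path Optional CSV path; when given the table is written there.
#' @return A data.frame with columns `time`, `compartment`,
#'   `concentration`, `amount` (invisibly when `path` is given).
#' @export
trajectory_table <- function(result, path = NULL) {
  comps <- colnames(result$concentrations)
  out <- do.call(rbind, lapply(comps, function(cc) {
    data.frame(time = result$times, compartment = cc,
               concentration = result$concentrations[, cc],
               amount = result$amounts[, cc])
  }))
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
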
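## Classical one- and two-compartment models with first-order oral
## absorption or intravenous bolus dosing.

#' Construct compartment-model parameters
#'
#' @param name Compound label.
#' @param CL Clearance (L/h, > 0). Literature oral parameters are
#'   apparent (`CL/F`, `V/F`); no bioavailability correction is applied.
#' @param Vc Central volume of distribution (L, > 0).
#' @param Vp Peripheral volume (L); required for two compartments.
#' @param Q Inter-compartmental clearance (L/h); required for two
#'   compartments.
#' @param Ka Absorption rate constant (1/h); ignored for IV dosing.
#' @param dose Dose (mg).
#' @param n_compartments 1 or 2.
#' @param route `"oral"` or `"iv_bolus"`.
#' @return A `compartment_parameters` list.
#' @export
compartment_parameters <- function(name = "drug", CL, Vc, Vp = NULL,
                                   Q = NULL, Ka = 0, dose,
                                   n_compartments = 1,
                                   route = c("oral", "iv_bolus")) {
  route <- match.arg(route)
  assert_scalar_number(CL, "CL", lower = 0, open_lower = TRUE)
  assert_scalar_number(Vc, "Vc", lower = 0, open_lower = TRUE)
  assert_scalar_number(Ka, "Ka", lower = 0)
  assert_scalar_number(dose, "dose", lower = 0)
  if (!n_compartments %in% c(1, 2))
    stop_validation("n_compartments must be 1 or 2")
  if (n_compartments == 2) {
    if (is.null(Vp) || is.null(Q))
      stop_validation("two-compartment model needs Vp and Q")
    assert_scalar_number(Vp, "Vp", lower = 0)
    assert_scalar_number(Q, "Q", lower = 0)
  }
  structure(list(name = name, CL = CL, Vc = Vc, Vp = Vp, Q = Q, Ka = Ka,
                 dose = dose, n_compartments = n_compartments,
                 route = route),
            class = "compartment_parameters")
}

## Macro-constants of the two-compartment disposition model.
two_cmt_macro <- function(p) {
  k10 <- p$CL / p$Vc
  k12 <- p$Q / p$Vc
  k21 <- p$Q / p$Vp
  s <- k10 + k12 + k21
  disc <- sqrt(max(s^2 - 4 * k10 * k21, 0))
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  list(k10 = k10, k12 = k12, k21 = k21, alpha = alpha, beta = beta)
}

#' Closed-form compartment-model concentration
#'
#' Central-compartment concentration of the one- or two-compartment
#' model at the given times, evaluated analytically (sum of
#' exponentials). Used as the fitting kernel and as a cross-check for
#' the ODE path. Near-degenerate rate constants (`Ka` within 1e-6 of a
#' disposition rate) fall back to the ODE solution.
#'
#' @param params A `compartment_parameters` object.
#' @param times Time grid (h).
#' @return Numeric vector of central concentrations (mg/L).
#' @export
compartment_conc <- function(params, times) {
  p <- params
  D <- p$dose
  ## ODE fallback valid for any positive time vector, not only grids
  ## from 0 (the fitter evaluates on filtered observation times)
  conc_via_ode <- function() {
    grid <- sort(unique(c(0, times)))
    res <- simulate_compartment(p, grid, path = "ode")
    unname(res$concentrations[match(times, grid), "central"])
  }
  if (p$n_compartments == 1) {
    k <- p$CL / p$Vc
    if (p$route == "iv_bolus") return(D / p$Vc * exp(-k * times))
    if (abs(p$Ka - k) < 1e-6 * max(k, 1e-12))
      return(conc_via_ode())
    D * p$Ka / (p$Vc * (p$Ka - k)) * (exp(-k * times) - exp(-p$Ka * times))
  } else {
    m <- two_cmt_macro(p)
    a <- m$alpha; b <- m$beta; k21 <- m$k21
    if (p$route == "iv_bolus") {
      A <- D / p$Vc * (a - k21) / (a - b)
      B <- D / p$Vc * (k21 - b) / (a - b)
      return(A * exp(-a * times) + B * exp(-b * times))
    }
    ka <- p$Ka
    if (min(abs(ka - a), abs(ka - b), a - b) < 1e-6 * max(a, 1e-12))
      return(conc_via_ode())
    ka * D / p$Vc * (
      (k21 - a) / ((ka - a) * (b - a)) * exp(-a * times) +
      (k21 - b) / ((ka - b) * (a - b)) * exp(-b * times) +
      (k21 - ka) / ((a - ka) * (b - ka)) * exp(-ka * times))
  }
}

#' Simulate a compartment model
#'
#' One-compartment models are solved in closed form; two-compartment
#' models are integrated with the same solver contract as the
#' whole-body model (a closed-form central-compartment cross-check is
#' available via [compartment_conc()]).
#'
#' @param params A `compartment_parameters` object.
#' @param times Strictly increasing grid (h) from 0.
#' @param path `"auto"` (closed form for one compartment, ODE for two)
#'   or `"ode"` to force the numerical path.
#' @param rtol,atol Solver tolerances for the ODE path.
#' @return A `simulation_result` with `central` (and for two
#'   compartments `peripheral`) series.
#' @export
simulate_compartment <- function(params, times, path = c("auto", "ode"),
                                 rtol = 1e-8, atol = 1e-10) {
  path <- match.arg(path)
  p <- params
  if (length(times) < 2 || times[1] != 0 || any(diff(times) <= 0))
    stop_validation("times must be a strictly increasing grid starting at 0")
  k <- p$CL / p$Vc
  use_closed <- path == "auto" && p$n_compartments == 1 &&
    (p$route == "iv_bolus" || abs(p$Ka - k) >= 1e-6 * max(k, 1e-12))
  if (use_closed) {
    conc <- compartment_conc(p, times)
    amounts <- cbind(
      depot = if (p$route == "oral") p$dose * exp(-p$Ka * times) else 0,
      central = conc * p$Vc)
    amounts <- cbind(amounts,
                     eliminated = p$dose - rowSums(amounts))
    concentrations <- cbind(central = conc)
  } else {
    states <- c("depot", "central",
                if (p$n_compartments == 2) "peripheral", "eliminated")
    y0 <- stats::setNames(numeric(length(states)), states)
    y0[[if (p$route == "oral") "depot" else "central"]] <- p$dose
    func <- function(t, y, parms) {
      cc <- y[["central"]] / p$Vc
      absorbed <- p$Ka * y[["depot"]]
      d <- c(depot = -absorbed,
             central = absorbed - p$CL * cc)
      if (p$n_compartments == 2) {
        cp <- y[["peripheral"]] / p$Vp
        d[["central"]] <- d[["central"]] - p$Q * (cc - cp)
        d[["peripheral"]] <- p$Q * (cc - cp)
      }
      d[["eliminated"]] <- p$CL * cc
      list(d[states])
    }
    sol <- deSolve::ode(y0, times, func, NULL, method = "lsoda",
                        rtol = rtol, atol = atol)
    amounts <- unclass(sol)[, states, drop = FALSE]
    concentrations <- cbind(central = amounts[, "central"] / p$Vc)
    if (p$n_compartments == 2)
      concentrations <- cbind(concentrations,
                              peripheral = amounts[, "peripheral"] / p$Vp)
  }
  vols <- c(depot = NA_real_, central = p$Vc,
            if (p$n_compartments == 2) c(peripheral = p$Vp),
            eliminated = NA_real_)
  structure(list(times = times, amounts = amounts,
                 concentrations = concentrations,
                 eliminated = amounts[, "eliminated"],
                 dose = p$dose, volumes = vols,
                 label = paste0(p$n_compartments, "cmt:", p$name)),
            class = "simulation_result")
}

#' Analytic AUC to infinity of a compartment model
#'
#' `AUC = F * Dose / CL` with `F = 1` (apparent oral parameters).
#'
#' @param params A `compartment_parameters` object.
#' @return AUC (mg*h/L).
#' @export
auc_inf_analytic <- function(params) {
  params$dose / params$CL
}

#' Fit a compartment model to a concentration profile
#'
#' Least-squares fit of the closed-form one- or two-compartment model to
#' an observed central (blood) concentration profile, on the log scale
#' so the terminal phase is weighted fairly. Starting values come from
#' non-compartmental moments (`CL = dose/AUC_inf`,
#' `Vss = dose * AUMC / AUC^2`). Used to derive compartmental
#' parameters from reduced-model simulations.
#'
#' @param times,conc Observed profile (conc > 0 where fitted).
#' @param dose Dose (mg).
#' @param n_compartments 1 or 2.
#' @param route `"oral"` or `"iv_bolus"`.
#' @param Ka_start Starting absorption rate constant for oral fits.
#' @return A `compartment_parameters` object with fitted `CL`, `Vc`
#'   (and `Vp`, `Q`, `Ka`), plus attribute `"rss"`.
#' @export
fit_compartment_model <- function(times, conc, dose,
                                  n_compartments = 2,
                                  route = c("iv_bolus", "oral"),
                                  Ka_start = 1) {
  route <- match.arg(route)
  keep <- conc > max(conc) * 1e-12 & (times > 0 | route == "iv_bolus")
  tt <- times[keep]; cc <- conc[keep]
  if (length(tt) < 5)
    stop_validation("too few positive observations to fit")
  auc <- auc_last(tt, cc)
  aumc <- auc_last(tt, tt * cc)
  lam <- terminal_slope(tt, cc)
  auc_inf <- auc + cc[length(cc)] / lam
  aumc_inf <- aumc + tt[length(tt)] * cc[length(cc)] / lam +
    cc[length(cc)] / lam^2
  cl0 <- dose / auc_inf
  vss0 <- dose * aumc_inf / auc_inf^2
  vc0 <- if (route == "iv_bolus") min(dose / cc[1], vss0) else 0.5 * vss0
  theta0 <- log(c(CL = cl0, Vc = vc0))
  if (n_compartments == 2)
    theta0 <- c(theta0, log(c(Vp = max(vss0 - vc0, 0.2 * vc0), Q = cl0)))
  if (route == "oral") theta0 <- c(theta0, log(c(Ka = Ka_start)))
  unpack <- function(theta) {
    th <- pmax(exp(theta), 1e-12)
    compartment_parameters(
      CL = th[["CL"]], Vc = th[["Vc"]],
      Vp = if (n_compartments == 2) th[["Vp"]],
      Q = if (n_compartments == 2) th[["Q"]],
      Ka = if (route == "oral") th[["Ka"]] else 0,
      dose = dose, n_compartments = n_compartments, route = route)
  }
  resid_fn <- function(theta) {
    pred <- compartment_conc(unpack(theta), tt)
    log(pmax(pred, 1e-300)) - log(cc)
  }
  fit <- minpack.lm::nls.lm(par = theta0, fn = resid_fn,
                            lower = theta0 - log(1e8),
                            upper = theta0 + log(1e8),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200))
  out <- unpack(fit$par)
  attr(out, "rss") <- sum(fit$fvec^2)
  out
}
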
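## Reduction of the whole-body model by proper lumping: tissues with
## similar kinetic behaviour are merged, preserving volumes, blood
## flows, and Kp-weighted drug capacity.

#' Default lumping scheme
#'
#' Arterial blood, venous blood and lung form the lumped central
#' compartment (LCEN); the non-eliminating tissues (adipose, bone,
#' brain, heart, muscle, skin, rest-of-body) form the NET compartment;
#' gut, spleen, liver and kidney are retained un-lumped (the
#' eliminating organs plus the splanchnic tissues feeding the liver).
#'
#' @return A `lumping_scheme`.
#' @export
default_lumping_scheme <- function() {
  lumping_scheme(
    lumps = list(LCEN = c("arterial", "venous", "lung"),
                 NET = net_tissues()),
    retained = c("gut", "spleen", "liver", "kidney"))
}

#' Construct a lumping scheme
#'
#' @param lumps Named list mapping lump names to character vectors of
#'   member tissues.
#' @param retained Character vector of tissues kept un-lumped.
#' @return A validated `lumping_scheme`; the lumps plus the retained set
#'   must partition [pbpk_tissues()] exactly.
#' @export
lumping_scheme <- function(lumps, retained) {
  all_assigned <- c(unlist(lumps, use.names = FALSE), retained)
  dup <- unique(all_assigned[duplicated(all_assigned)])
  miss <- setdiff(pbpk_tissues(), all_assigned)
  extra <- setdiff(all_assigned, pbpk_tissues())
  if (length(dup) || length(miss) || length(extra))
    stop_validation(
      "lumping scheme must partition the tissue set exactly",
      if (length(dup)) paste0("; duplicated: ", paste(dup, collapse = ", ")),
      if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")),
      if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ", ")))
  structure(list(lumps = lumps, retained = retained),
            class = "lumping_scheme")
}

#' Load a lumping scheme from YAML
#'
#' @param path Path to a YAML file with maps `lumps` and a list
#'   `retained`. The default loads the bundled scheme of
#'   [default_lumping_scheme()].
#' @return A `lumping_scheme`.
#' @export
load_lumping_scheme <- function(path = system.file("extdata",
                                                   "lumping_scheme.yaml",
                                                   package = "pklump")) {
  doc <- yaml::read_yaml(path)
  lumping_scheme(lapply(doc$lumps, unlist), unlist(doc$retained))
}

## Kp contribution of a tissue inside a lump. Blood pools are treated as
## Kp = BP so that a lumped compartment containing blood carries a
## blood-like concentration (its outflow factor Kp/BP is 1).
member_kp <- function(tissue, drug) {
  if (tissue %in% c("arterial", "venous")) drug$BP else drug$Kp[[tissue]]
}

#' Compute lumped parameters
#'
#' For each lump, the volume and blood flow are the sums over the member
#' tissues and the partition coefficient is the volume-weighted mean:
#' `V_Lump = sum(V_T)`, `Q_Lump = sum(Q_T)`,
#' `K_Lump = sum(V_T * Kp_T) / V_Lump`. Arterial and venous blood
#' contribute `Kp = BP` (a blood pool is at blood concentration).
#' Retained tissues keep their original values. Blood-pool flows do not
#' enter `Q_Lump`; the central lump's flow is the cardiac output.
#'
#' @param phys A `physiology_set`.
#' @param drug A `drug_parameters` object.
#' @param scheme A `lumping_scheme`.
#' @return A `lumped_parameters` list with per-lump `V`, `Q`, `K` and
#'   the retained tissues' original values.
#' @export
lump_parameters <- function(phys, drug, scheme = default_lumping_scheme()) {
  lump_of <- function(members) {
    V <- sum(phys$volumes[members])
    perfused <- intersect(members, systemic_tissues())
    Q <- if (any(c("arterial", "venous", "lung") %in% members))
      unname(phys$flows[["lung"]]) else sum(phys$flows[perfused])
    kvsum <- sum(vapply(members, function(tt)
      phys$volumes[[tt]] * member_kp(tt, drug), numeric(1)))
    list(V = unname(V), Q = Q, K = kvsum / V)
  }
  lumps <- lapply(scheme$lumps, lump_of)
  retained <- lapply(scheme$retained, function(tt)
    list(V = unname(phys$volumes[[tt]]),
         Q = unname(phys$flows[[tt]]),
         K = unname(drug$Kp[[tt]])))
  names(retained) <- scheme$retained
  structure(list(lumps = lumps, retained = retained, scheme = scheme),
            class = "lumped_parameters")
}

#' Build the lumped ODE system
#'
#' Reduced model with states `depot`, `gut`, `spleen`, `liver`,
#' `kidney`, `NET`, `LCEN` and a cumulative `eliminated` state. LCEN (a
#' blood-like pool) distributes at the cardiac output to NET, gut,
#' spleen, liver (hepatic artery) and kidney, and collects the outflows
#' of NET, liver and kidney (gut and spleen drain into the liver).
#' Elimination in liver and kidney is identical in form to the
#' whole-body model.
#'
#' @param phys A `physiology_set`.
#' @param drug A `drug_parameters` object.
#' @param scheme A `lumping_scheme`; must retain gut, spleen, liver and
#'   kidney and place the blood pools in a single central lump.
#' @return An `ode_system`.
#' @export
build_lumped_odes <- function(phys, drug, scheme = default_lumping_scheme()) {
  central <- names(scheme$lumps)[vapply(scheme$lumps, function(m)
    all(c("arterial", "venous") %in% m), logical(1))]
  if (length(central) != 1L)
    stop_validation("scheme must place arterial and venous blood in one ",
                    "central lump")
  need <- c("gut", "spleen", "liver", "kidney")
  if (!all(need %in% scheme$retained))
    stop_validation("scheme must retain gut, spleen, liver and kidney")
  lp <- lump_parameters(phys, drug, scheme)
  periph <- setdiff(names(scheme$lumps), central)
  states <- c("depot", need, periph, central, "eliminated")
  BP <- drug$BP
  fu <- drug$fu
  ka <- drug$Ka
  Q <- phys$flows
  V <- phys$volumes
  q_li <- liver_total_flow(phys)
  q_cen <- lp$lumps[[central]]$Q
  v_cen <- lp$lumps[[central]]$V
  out_ret <- BP / drug$Kp[need]

  rhs <- function(t, a) {
    d <- numeric(length(states))
    names(d) <- states
    c_cen <- a[[central]] / v_cen
    c_ret <- a[need] / V[need]
    c_ret_out <- c_ret * out_ret
    absorbed <- ka * a[["depot"]]
    d[["depot"]] <- -absorbed
    d[["gut"]] <- Q[["gut"]] * (c_cen - c_ret_out[["gut"]]) + absorbed
    d[["spleen"]] <- Q[["spleen"]] * (c_cen - c_ret_out[["spleen"]])
    elim_hep <- fu * drug$CL_hep * c_ret_out[["liver"]]
    d[["liver"]] <- Q[["liver"]] * c_cen +
      Q[["gut"]] * c_ret_out[["gut"]] + Q[["spleen"]] * c_ret_out[["spleen"]] -
      q_li * c_ret_out[["liver"]] - elim_hep
    elim_ki <- fu * drug$CL_ki * c_ret_out[["kidney"]]
    d[["kidney"]] <- Q[["kidney"]] * (c_cen - c_ret_out[["kidney"]]) - elim_ki
    ret_to_cen <- q_li * c_ret_out[["liver"]] + Q[["kidney"]] * c_ret_out[["kidney"]]
    for (pl in periph) {
      p <- lp$lumps[[pl]]
      c_p_out <- (a[[pl]] / p$V) * BP / p$K
      d[[pl]] <- p$Q * (c_cen - c_p_out)
      ret_to_cen <- ret_to_cen + p$Q * c_p_out
    }
    d[[central]] <- ret_to_cen - q_cen * c_cen
    d[["eliminated"]] <- elim_hep + elim_ki
    d
  }

  vols <- c(NA_real_, V[need], vapply(lp$lumps[periph], `[[`, numeric(1), "V"),
            v_cen, NA_real_)
  names(vols) <- states
  new_ode_system(states, vols, rhs, drug$dose,
                 if (drug$route == "oral") "depot" else central,
                 paste0("lumped:", drug$name))
}

#' Peripheral volume of distribution
#'
#' In the whole-body model, `Vp = sum(V_T * Kp_T) / body_weight` over
#' the peripheral (NET) tissues; in the lumped model,
#' `Vp = V_NET * K_NET / body_weight`. With `K_NET` taken as the
#' volume-weighted mean Kp of the members, the two expressions coincide
#' algebraically.
#'
#' @param phys A `physiology_set`.
#' @param drug A `drug_parameters` object.
#' @param scheme A `lumping_scheme` defining the peripheral lump(s).
#' @param model `"pbpk"` (per-tissue sum) or `"lumped"` (aggregate
#'   product).
#' @return Peripheral volume of distribution (L/kg).
#' @export
peripheral_volume <- function(phys, drug, scheme = default_lumping_scheme(),
                              model = c("pbpk", "lumped")) {
  model <- match.arg(model)
  periph <- scheme$lumps[!vapply(scheme$lumps, function(m)
    any(c("arterial", "venous") %in% m), logical(1))]
  members <- unlist(periph, use.names = FALSE)
  if (!length(members))
    stop_validation("scheme has no peripheral lump")
  if (model == "pbpk") {
    sum(phys$volumes[members] * drug$Kp[members]) / phys$body_weight
  } else {
    lp <- lump_parameters(phys, drug, scheme)
    sum(vapply(lp$lumps[names(periph)], function(p) p$V * p$K,
               numeric(1))) / phys$body_weight
  }
}

#' Central volume of distribution of the whole-body and lumped models
#'
#' Blood-referenced central pool: arterial plus venous volume plus the
#' lung scaled to blood concentration,
#' `(V_ar + V_ve + V_lu * Kp_lu / BP) / body_weight`. Alternatively the
#' plain volume sum of the central tissues can be requested.
#'
#' @param phys A `physiology_set`.
#' @param drug A `drug_parameters` object.
#' @param blood_referenced Scale the lung by `Kp_lu / BP` (default) or
#'   use the raw volume sum.
#' @return Central volume of distribution (L/kg).
#' @export
central_volume <- function(phys, drug, blood_referenced = TRUE) {
  v_lu <- if (blood_referenced)
    phys$volumes[["lung"]] * drug$Kp[["lung"]] / drug$BP
  else phys$volumes[["lung"]]
  (phys$volumes[["arterial"]] + phys$volumes[["venous"]] + v_lu) /
    phys$body_weight
}
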
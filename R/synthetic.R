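## Synthetic drug generation. Emulates a panel of approved drugs
## selected across wide ranges of clearance and distribution volume:
## parameters are drawn log-uniformly within plausible ranges, with the
## hepatic extraction ratio stratified across the panel so low-,
## intermediate- and high-extraction drugs are all represented.

#' Default synthetic drug profile
#'
#' Plausible adult-dose parameter ranges, sampled log-uniformly:
#' unbound fraction 0.01-1, blood:plasma ratio 0.55-2, absorption rate
#' 0.1-3 /h, renal clearance 0.01-20 L/h, tissue Kp 0.05-20, dose
#' 10-500 mg. The hepatic extraction ratio `fu*CL_int/Q_li` spans
#' 0.03-30 across a stratified panel.
#'
#' @param ranges Optional named list overriding individual ranges; each
#'   entry is `c(low, high)`.
#' @return A `drug_profile` list of ranges.
#' @export
drug_profile <- function(ranges = list()) {
  def <- list(fu = c(0.01, 1), BP = c(0.55, 2), Ka = c(0.1, 3),
              CL_ki = c(0.01, 20), Kp = c(0.05, 20), dose = c(10, 500),
              extraction = c(0.03, 30))
  for (nm in names(ranges)) def[[nm]] <- ranges[[nm]]
  bad <- names(def)[vapply(def, function(r)
    length(r) != 2 || any(r <= 0) || r[2] < r[1], logical(1))]
  if (length(bad))
    stop_validation("invalid range(s): ", paste(bad, collapse = ", "))
  structure(def, class = "drug_profile")
}

runif_log <- function(n, range) {
  exp(stats::runif(n, log(range[1]), log(range[2])))
}

#' Generate one synthetic drug
#'
#' Draws every parameter log-uniformly within the profile ranges.
#' Intrinsic hepatic clearance is set from a drawn extraction ratio
#' `E = fu*CL_int/Q_li` (so panels cover low to high extraction), and
#' hepatic clearance follows from the well-stirred model. Deterministic
#' under the seed.
#'
#' @param profile A `drug_profile`.
#' @param seed Integer seed.
#' @param phys A `physiology_set` supplying the hepatic blood flow.
#' @param name Compound label.
#' @param route Dosing route.
#' @param extraction Optional fixed extraction ratio (used by the
#'   stratified panel generator); drawn from the profile when `NULL`.
#' @return A `drug_parameters` object.
#' @export
generate_drug <- function(profile = drug_profile(), seed = 1,
                          phys = load_physiology(), name = NULL,
                          route = "oral", extraction = NULL) {
  set.seed(seed)
  fu <- runif_log(1, profile$fu)
  BP <- runif_log(1, profile$BP)
  Ka <- runif_log(1, profile$Ka)
  CL_ki <- runif_log(1, profile$CL_ki)
  Kp <- stats::setNames(runif_log(length(kp_tissues()), profile$Kp),
                        kp_tissues())
  dose <- runif_log(1, profile$dose)
  if (is.null(extraction)) extraction <- runif_log(1, profile$extraction)
  q_li <- liver_total_flow(phys)
  CL_int <- extraction * q_li / fu
  drug_parameters(
    name = if (is.null(name)) paste0("synthetic-", seed) else name,
    fu = fu, BP = BP, Ka = Ka, CL_int = CL_int, CL_ki = CL_ki,
    Kp = Kp, dose = dose, route = route, Q_li = q_li)
}

#' Generate a synthetic drug panel
#'
#' `n` drugs with the hepatic extraction ratio stratified over the
#' profile's `extraction` range (evenly spaced in log with within-band
#' jitter), emulating a panel deliberately selected to span low- to
#' high-extraction compounds.
#'
#' @inheritParams generate_drug
#' @param n Panel size (default 20, the study's compound count).
#' @return List of `drug_parameters`.
#' @export
generate_drug_panel <- function(n = 20, profile = drug_profile(),
                                seed = 1, phys = load_physiology(),
                                route = "oral") {
  set.seed(seed)
  lo <- log(profile$extraction[1]); hi <- log(profile$extraction[2])
  edges <- seq(lo, hi, length.out = n + 1)
  extr <- exp(edges[-(n + 1)] + stats::runif(n) * diff(edges))
  extr <- sample(extr)
  drug_seeds <- sample.int(.Machine$integer.max, n)
  lapply(seq_len(n), function(i)
    generate_drug(profile, drug_seeds[i], phys,
                  name = sprintf("synthetic-%02d", i), route = route,
                  extraction = extr[i]))
}

#' Construct a drug in the exact-lumping limit
#'
#' Sets every tissue's partition coefficient so all perfused tissues
#' share one equilibration rate `k = Q_T*BP/(V_T*Kp_T)`, the regime in
#' which proper lumping of the non-eliminating tissues is exact; the
#' lung is set blood-like (`Kp_lu = BP`) so the central pool carries a
#' blood concentration. With `k` slow against blood mixing, the lumped
#' and whole-body blood profiles coincide.
#'
#' @param phys A `physiology_set`.
#' @param k Common tissue equilibration rate (1/h).
#' @param BP Blood:plasma ratio.
#' @param fu Unbound fraction.
#' @param CL_hep,CL_ki Hepatic and renal clearances (L/h).
#' @param dose Dose (mg).
#' @param route Dosing route.
#' @return A `drug_parameters` object.
#' @export
generate_matched_kinetics_drug <- function(phys, k = 0.2, BP = 1,
                                           fu = 0.5, CL_hep = 20,
                                           CL_ki = 5, dose = 100,
                                           route = "iv_bolus") {
  assert_scalar_number(k, "k", lower = 0, open_lower = TRUE)
  tissues <- setdiff(kp_tissues(), "lung")
  Kp <- stats::setNames(
    phys$flows[tissues] * BP / (phys$volumes[tissues] * k), tissues)
  Kp[["lung"]] <- BP
  drug_parameters(name = "matched-kinetics", fu = fu, BP = BP, Ka = 1,
                  CL_hep = CL_hep, CL_ki = CL_ki, Kp = Kp, dose = dose,
                  route = route)
}

#' Apply lognormal inter-individual variability to a drug
#'
#' Multiplies `fu`, `CL_hep`, `CL_ki`, `Ka` and every `Kp` by
#' independent lognormal factors with the given coefficient of
#' variation (median-preserving, `sdlog = sqrt(log(1 + cv^2))`).
#' Unbound fraction is capped at 1.
#'
#' @param drug A `drug_parameters` object.
#' @param cv Coefficient of variation (e.g. 0.2 for 20%).
#' @return A perturbed `drug_parameters` object.
#' @export
perturb_drug <- function(drug, cv) {
  assert_scalar_number(cv, "cv", lower = 0)
  if (cv == 0) return(drug)
  sdlog <- sqrt(log(1 + cv^2))
  fac <- function(n = 1) stats::rlnorm(n, 0, sdlog)
  drug_parameters(
    name = drug$name, fu = min(drug$fu * fac(), 1), BP = drug$BP,
    Ka = drug$Ka * fac(), CL_hep = drug$CL_hep * fac(),
    CL_ki = drug$CL_ki * fac(),
    Kp = drug$Kp * fac(length(drug$Kp)),
    dose = drug$dose, route = drug$route)
}
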
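## Drug-specific parameters: binding, absorption, clearance and
## tissue:plasma partition coefficients.

#' Construct a drug parameter set
#'
#' @param name Compound label used in reports.
#' @param fu Unbound fraction in plasma, in (0, 1].
#' @param BP Blood-to-plasma concentration ratio (> 0).
#' @param Ka First-order absorption rate constant (1/h, >= 0); ignored
#'   for intravenous dosing.
#' @param CL_hep Hepatic clearance (L/h, >= 0). Give either `CL_hep` or
#'   `CL_int`; with `CL_int`, hepatic clearance is derived by the
#'   well-stirred liver model ([hepatic_clearance_well_stirred()]) using
#'   the total hepatic blood flow `Q_li`.
#' @param CL_int Intrinsic hepatic clearance (L/h).
#' @param CL_ki Renal clearance (L/h, >= 0).
#' @param Kp Named numeric vector of tissue-to-plasma partition
#'   coefficients for the non-blood tissues of [pbpk_tissues()]. Tissues missing
#'   from `Kp` inherit `Kp_default` (recorded with a message).
#' @param dose Dose (mg, >= 0).
#' @param route `"oral"` (first-order depot into the gut) or
#'   `"iv_bolus"` (bolus into venous blood).
#' @param Q_li Total hepatic blood flow (L/h); required only when
#'   deriving `CL_hep` from `CL_int`.
#' @param Kp_default Scalar fallback partition coefficient for tissues
#'   unlisted in `Kp` (optional).
#'
#' @return A `drug_parameters` list.
#' @export
drug_parameters <- function(name = "drug", fu, BP, Ka = 0,
                            CL_hep = NULL, CL_int = NULL, CL_ki = 0,
                            Kp, dose, route = c("oral", "iv_bolus"),
                            Q_li = NULL, Kp_default = NULL) {
  route <- match.arg(route)
  assert_scalar_number(fu, "fu", lower = 0, upper = 1, open_lower = TRUE)
  assert_scalar_number(BP, "BP", lower = 0, open_lower = TRUE)
  assert_scalar_number(Ka, "Ka", lower = 0)
  assert_scalar_number(CL_ki, "CL_ki", lower = 0)
  assert_scalar_number(dose, "dose", lower = 0)
  if (is.null(CL_hep)) {
    if (is.null(CL_int))
      stop_validation("either CL_hep or CL_int must be given")
    if (is.null(Q_li))
      stop_validation("Q_li is required to derive CL_hep from CL_int")
    CL_hep <- hepatic_clearance_well_stirred(Q_li, fu, CL_int)
  } else {
    assert_scalar_number(CL_hep, "CL_hep", lower = 0)
  }
  Kp <- if (missing(Kp) || is.null(Kp)) numeric(0) else unlist(Kp)
  miss <- setdiff(kp_tissues(), names(Kp))
  if (length(miss)) {
    if (is.null(Kp_default))
      stop_validation("missing Kp for tissue(s): ", paste(miss, collapse = ", "))
    Kp[miss] <- Kp_default
    message("Kp default ", format(Kp_default), " applied to: ",
            paste(miss, collapse = ", "))
  }
  Kp <- Kp[kp_tissues()]
  if (any(!is.finite(Kp)) || any(Kp <= 0))
    stop_validation("every Kp must be positive and finite")
  structure(list(name = name, fu = fu, BP = BP, Ka = Ka,
                 CL_hep = CL_hep, CL_int = CL_int, CL_ki = CL_ki,
                 Kp = Kp, dose = dose, route = route),
            class = "drug_parameters")
}

#' @export
print.drug_parameters <- function(x, ...) {
  cat("Drug '", x$name, "': fu ", format(x$fu), ", BP ", format(x$BP),
      ", CL_hep ", format(x$CL_hep), " L/h, CL_ki ", format(x$CL_ki),
      " L/h, dose ", format(x$dose), " mg (", x$route, ")\n", sep = "")
  invisible(x)
}

#' Load drug parameters from a YAML document
#'
#' The document provides `fu`, `BP`, `Ka`, `CL_ki`, `dose`, `route`, a
#' `Kp` map, and either `CL_hep` or `CL_int` (with `Q_li`, or a
#' `physiology` must be supplied to obtain the hepatic blood flow).
#'
#' @param path Path to the YAML file.
#' @param phys Optional `physiology_set` supplying the hepatic blood
#'   flow when `CL_int` is given without `Q_li`.
#' @return A `drug_parameters` object.
#' @export
load_drug <- function(path, phys = NULL) {
  doc <- yaml::read_yaml(path)
  for (field in c("fu", "BP", "dose"))
    if (is.null(doc[[field]]))
      stop_schema("drug file lacks required field '", field, "'")
  q_li <- doc$Q_li
  if (is.null(q_li) && !is.null(phys)) q_li <- liver_total_flow(phys)
  drug_parameters(
    name = if (!is.null(doc$name)) doc$name else
      sub("\\.[^.]*$", "", basename(path)),
    fu = doc$fu, BP = doc$BP,
    Ka = if (!is.null(doc$Ka)) doc$Ka else 0,
    CL_hep = doc$CL_hep, CL_int = doc$CL_int,
    CL_ki = if (!is.null(doc$CL_ki)) doc$CL_ki else 0,
    Kp = doc$Kp, dose = doc$dose,
    route = if (!is.null(doc$route)) doc$route else "oral",
    Q_li = q_li, Kp_default = doc$Kp_default)
}

#' Write drug parameters to YAML
#'
#' @param drug A `drug_parameters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_drug <- function(drug, path) {
  doc <- list(name = drug$name, fu = drug$fu, BP = drug$BP, Ka = drug$Ka,
              CL_hep = drug$CL_hep, CL_ki = drug$CL_ki,
              Kp = as.list(drug$Kp), dose = drug$dose, route = drug$route)
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}
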
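#' @keywords internal
"_PACKAGE"

## Tissue name vocabulary used package-wide. Units are fixed: mg, L, h,
## mg/L, L/h. Per-kg quantities (L/kg, L/h/kg) appear only in reports.

#' Tissue names of the whole-body model
#'
#' Canonical compartment names used by the PBPK model: eleven perfused
#' tissues, the lung, and the arterial and venous blood pools.
#'
#' @return Character vector of tissue names.
#' @export
pbpk_tissues <- function() {
  c("adipose", "bone", "brain", "gut", "heart", "kidney", "liver",
    "muscle", "skin", "spleen", "rest_of_body", "lung",
    "arterial", "venous")
}

## Systemically perfused tissues: receive arterial blood in parallel.
## The liver entry is the hepatic-arterial flow; gut and spleen venous
## outflow drains into the liver (portal vein).
systemic_tissues <- function() {
  c("adipose", "bone", "brain", "gut", "heart", "kidney", "liver",
    "muscle", "skin", "spleen", "rest_of_body")
}

## Tissues that need a tissue:plasma partition coefficient.
kp_tissues <- function() {
  setdiff(pbpk_tissues(), c("arterial", "venous"))
}

## Non-eliminating tissues lumped into the NET compartment.
net_tissues <- function() {
  c("adipose", "bone", "brain", "heart", "muscle", "skin", "rest_of_body")
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("pklump_validation_error", "error")))
}

stop_schema <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("pklump_schema_error", "error")))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_validation(name, " must be a single finite number")
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_validation(name, " = ", format(x), " is outside the allowed range ",
                    if (open_lower) "(" else "[", lower, ", ", upper,
                    if (open_upper) ")" else "]")
  invisible(x)
}
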
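## Physiology data model: tissue volumes (L), tissue blood flows (L/h)
## and body weight (kg) for a whole-body perfusion-limited PBPK model.

#' Construct a physiology set
#'
#' Bundles tissue volumes, tissue blood flows and body weight into a
#' validated `physiology_set` object. Flows are defined for every
#' systemically perfused tissue plus the lung; the lung flow is the
#' cardiac output and must equal the sum of all systemic tissue flows
#' (the liver entry being the hepatic-arterial flow, since gut and
#' spleen return through the portal vein).
#'
#' @param volumes Named numeric vector of compartment volumes (L) for all
#'   tissues in [pbpk_tissues()].
#' @param flows Named numeric vector of blood flows (L/h) for all
#'   systemic tissues plus `lung`.
#' @param body_weight Body weight (kg).
#'
#' @return A `physiology_set` list with elements `volumes`, `flows`,
#'   `body_weight`.
#' @export
physiology_set <- function(volumes, flows, body_weight) {
  needed_v <- pbpk_tissues()
  needed_q <- c(systemic_tissues(), "lung")
  miss_v <- setdiff(needed_v, names(volumes))
  if (length(miss_v))
    stop_schema("missing tissue volume(s): ", paste(miss_v, collapse = ", "))
  miss_q <- setdiff(needed_q, names(flows))
  if (length(miss_q))
    stop_schema("missing tissue flow(s): ", paste(miss_q, collapse = ", "))
  volumes <- volumes[needed_v]
  flows <- flows[needed_q]
  if (any(!is.finite(volumes)) || any(volumes <= 0))
    stop_validation("all tissue volumes must be positive and finite")
  if (any(!is.finite(flows)) || any(flows < 0))
    stop_validation("all tissue flows must be non-negative and finite")
  assert_scalar_number(body_weight, "body_weight", lower = 0, open_lower = TRUE)
  qsum <- sum(flows[systemic_tissues()])
  if (abs(qsum - flows[["lung"]]) > 1e-9 * max(flows[["lung"]], 1))
    stop_validation("sum of systemic tissue flows (", format(qsum),
                    " L/h) must equal the cardiac output / lung flow (",
                    format(flows[["lung"]]), " L/h)")
  structure(list(volumes = volumes, flows = flows,
                 body_weight = body_weight),
            class = "physiology_set")
}

#' @export
print.physiology_set <- function(x, ...) {
  cat("Whole-body physiology:", format(x$body_weight), "kg,",
      "cardiac output", format(x$flows[["lung"]]), "L/h,",
      "total volume", format(sum(x$volumes)), "L\n")
  invisible(x)
}

#' Close the physiology against cardiac output and total body volume
#'
#' Assigns the rest-of-body compartment the flow and volume remainders so
#' that the systemic flows sum exactly to the cardiac output and the
#' compartment volumes sum to the total body volume.
#'
#' @param volumes,flows Named numeric vectors as in [physiology_set()],
#'   without `rest_of_body` entries.
#' @param cardiac_output Cardiac output (L/h); becomes the lung flow.
#' @param total_body_volume Total volume of all model compartments (L).
#' @param body_weight Body weight (kg).
#'
#' @return A validated `physiology_set` whose `rest_of_body` entries are
#'   the closure remainders.
#' @export
derive_rest_of_body <- function(volumes, flows, cardiac_output,
                                total_body_volume, body_weight) {
  volumes <- volumes[setdiff(names(volumes), "rest_of_body")]
  flows <- flows[setdiff(names(flows), c("rest_of_body", "lung"))]
  q_rest <- cardiac_output - sum(flows)
  v_rest <- total_body_volume - sum(volumes)
  if (q_rest < 0)
    stop_validation("specified tissue flows exceed the cardiac output")
  if (v_rest <= 0)
    stop_validation("specified tissue volumes leave no positive ",
                    "rest-of-body volume")
  volumes[["rest_of_body"]] <- v_rest
  flows[["rest_of_body"]] <- q_rest
  flows[["lung"]] <- cardiac_output
  physiology_set(volumes, flows, body_weight)
}

#' Load a physiology set from a YAML document
#'
#' The document carries `body_weight`, a `volumes` map and a `flows` map
#' (see `inst/extdata/physiology_adult.yaml` for the schema). When the
#' `rest_of_body` entries are absent the document must provide
#' `cardiac_output` and `total_body_volume`, and the rest-of-body
#' compartment is derived by closure ([derive_rest_of_body()]).
#'
#' @param path Path to the YAML file. The default loads the bundled
#'   70-kg adult reference physiology.
#'
#' @return A `physiology_set`.
#' @export
load_physiology <- function(path = system.file("extdata",
                                               "physiology_adult.yaml",
                                               package = "pklump")) {
  doc <- yaml::read_yaml(path)
  for (field in c("body_weight", "volumes", "flows"))
    if (is.null(doc[[field]]))
      stop_schema("physiology file lacks required field '", field, "'")
  volumes <- unlist(doc$volumes)
  flows <- unlist(doc$flows)
  has_rest <- "rest_of_body" %in% names(volumes) &&
    "rest_of_body" %in% names(flows)
  if (has_rest) {
    if (!"lung" %in% names(flows)) {
      if (is.null(doc$cardiac_output))
        stop_schema("physiology file needs a lung flow or cardiac_output")
      flows[["lung"]] <- doc$cardiac_output
    }
    physiology_set(volumes, flows, doc$body_weight)
  } else {
    co <- if (!is.null(doc$cardiac_output)) doc$cardiac_output
          else flows[["lung"]]
    if (is.null(co) || is.na(co))
      stop_schema("physiology file needs cardiac_output for closure")
    if (is.null(doc$total_body_volume))
      stop_schema("physiology file needs total_body_volume for closure")
    derive_rest_of_body(volumes, flows, co, doc$total_body_volume,
                        doc$body_weight)
  }
}

#' Write a physiology set to YAML
#'
#' @param phys A `physiology_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_physiology <- function(phys, path) {
  doc <- list(body_weight = phys$body_weight,
              volumes = as.list(phys$volumes),
              flows = as.list(phys$flows))
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

## Total liver inflow: hepatic artery plus portal (gut + spleen) flow.
liver_total_flow <- function(phys) {
  unname(phys$flows[["liver"]] + phys$flows[["gut"]] + phys$flows[["spleen"]])
}
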
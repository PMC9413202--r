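## End-to-end study orchestration: simulate the whole-body, lumped, and
## compartment models for a drug panel on a common grid, run NCA,
## derive CL/Vc/Vp, and assemble the compatibility report.

#' Central and peripheral AUC summaries of a whole-body simulation
#'
#' @param result A `simulation_result` from the whole-body model.
#' @return Named vector with `central` (mean AUC_last of lung, arterial
#'   and venous blood) and `peripheral` (mean over the non-eliminating
#'   tissues).
#' @export
pbpk_auc_summary <- function(result) {
  c(central = average_tissue_auc(result, c("lung", "arterial", "venous")),
    peripheral = average_tissue_auc(result, net_tissues()))
}

simulate_one_drug <- function(phys, drug, scheme, times, cmt_params,
                              rtol, atol) {
  pbpk <- simulate_system(build_pbpk_odes(phys, drug), times,
                          rtol = rtol, atol = atol)
  lump <- simulate_system(build_lumped_odes(phys, drug, scheme), times,
                          rtol = rtol, atol = atol)
  central <- names(scheme$lumps)[vapply(scheme$lumps, function(m)
    all(c("arterial", "venous") %in% m), logical(1))]
  if (is.null(cmt_params))
    cmt_params <- fit_compartment_model(
      times, lump$concentrations[, central], drug$dose,
      n_compartments = 2, route = drug$route,
      Ka_start = max(drug$Ka, 0.1))
  cmt <- simulate_compartment(cmt_params, times)
  list(pbpk = pbpk, lumped = lump, compartment = cmt,
       cmt_params = cmt_params, central = central)
}

report_row <- function(phys, drug, scheme, sims) {
  bw <- phys$body_weight
  pb <- pbpk_auc_summary(sims$pbpk)
  periph_lumps <- setdiff(names(scheme$lumps), sims$central)
  auc_lcen <- auc_last(sims$lumped$times,
                       sims$lumped$concentrations[, sims$central])
  auc_net <- mean(vapply(periph_lumps, function(pl)
    auc_last(sims$lumped$times, sims$lumped$concentrations[, pl]),
    numeric(1)))
  cp <- sims$cmt_params
  auc_c <- auc_last(sims$compartment$times,
                    sims$compartment$concentrations[, "central"])
  auc_p <- if (cp$n_compartments == 2)
    auc_last(sims$compartment$times,
             sims$compartment$concentrations[, "peripheral"]) else NA_real_
  cl_mech <- total_clearance(drug$CL_hep, drug$CL_ki) / bw
  cl_cmt <- cp$CL / bw
  vc_mech <- central_volume(phys, drug)
  vp_mech <- peripheral_volume(phys, drug, scheme, "pbpk")
  vp_lump <- peripheral_volume(phys, drug, scheme, "lumped")
  vp_cmt <- if (cp$n_compartments == 2) cp$Vp / bw else NA_real_
  data.frame(
    compound = drug$name,
    central_pbpk = unname(pb["central"]), central_lumped = auc_lcen,
    central_compartment = auc_c,
    peripheral_pbpk = unname(pb["peripheral"]), peripheral_lumped = auc_net,
    peripheral_compartment = auc_p,
    cl_pbpk = cl_mech, cl_lumped = cl_mech, cl_compartment = cl_cmt,
    vc_pbpk = vc_mech, vc_lumped = vc_mech, vc_compartment = cp$Vc / bw,
    vp_pbpk = vp_mech, vp_lumped = vp_lump, vp_compartment = vp_cmt,
    vdfu_lumped = vd_over_fu(vc_mech, vp_lump, drug$fu),
    vdfu_compartment = vd_over_fu(cp$Vc / bw,
                                  if (is.na(vp_cmt)) 0 else vp_cmt, drug$fu),
    accuracy_of_auc = auc_accuracy(auc_lcen, cl_mech, cl_cmt, auc_c),
    stringsAsFactors = FALSE)
}

#' Run the model-compatibility pipeline
#'
#' For each drug: simulate the whole-body and lumped models on a common
#' grid, obtain compartment-model parameters (supplied per drug, or
#' fitted to the lumped central profile), simulate the compartment
#' model, and compute AUC summaries, clearances, central and peripheral
#' volumes, Vd/fu, and the accuracy of AUC. With `replicates > 1`,
#' lognormal inter-individual variability of coefficient of variation
#' `cv` is applied to each replicate and per-compound AUCs are
#' summarized by the median.
#'
#' @param drugs List of `drug_parameters` (or a single one).
#' @param phys A `physiology_set`.
#' @param scheme A `lumping_scheme`.
#' @param t_end,n_points Simulation grid specification (h).
#' @param compartment_params Optional list of `compartment_parameters`,
#'   one per drug (NULL entries are fitted).
#' @param replicates Number of Monte-Carlo replicates per drug
#'   (default 1, deterministic).
#' @param cv Lognormal coefficient of variation for replicate mode.
#' @param seed Integer seed for replicate mode.
#' @param out_dir Optional directory; when given, the report
#'   (`compatibility_report.csv`), the 2-fold summary
#'   (`summary.json`) and a run log are written there.
#' @param rtol,atol Solver tolerances.
#' @return A `compatibility_report` data frame (one row per compound).
#' @export
run_compatibility_pipeline <- function(drugs, phys = load_physiology(),
                                       scheme = default_lumping_scheme(),
                                       t_end = 48, n_points = 2001,
                                       compartment_params = NULL,
                                       replicates = 1, cv = 0, seed = 1,
                                       out_dir = NULL,
                                       rtol = 1e-8, atol = 1e-10) {
  if (inherits(drugs, "drug_parameters")) drugs <- list(drugs)
  if (replicates < 1) stop_validation("replicates must be >= 1")
  times <- sim_grid(t_end, n_points)
  set.seed(seed)
  rows <- lapply(seq_along(drugs), function(i) {
    drug <- drugs[[i]]
    cmt <- if (!is.null(compartment_params)) compartment_params[[i]]
    reps <- lapply(seq_len(replicates), function(r) {
      d <- if (replicates > 1 && cv > 0) perturb_drug(drug, cv) else drug
      report_row(phys, d, scheme,
                 simulate_one_drug(phys, d, scheme, times, cmt,
                                   rtol, atol))
    })
    if (length(reps) == 1) return(reps[[1]])
    med <- reps[[1]]
    num <- vapply(med, is.numeric, logical(1))
    for (cc in names(med)[num])
      med[[cc]] <- stats::median(vapply(reps, function(r) r[[cc]],
                                        numeric(1)), na.rm = TRUE)
    med
  })
  report <- do.call(rbind, rows)
  class(report) <- c("compatibility_report", class(report))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report, file.path(out_dir, "compatibility_report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(compatibility_summary(report),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(c(paste("drugs:", length(drugs)),
                 paste("t_end:", t_end), paste("n_points:", n_points),
                 paste("replicates:", replicates), paste("cv:", cv),
                 paste("seed:", seed), paste("rtol:", rtol),
                 paste("atol:", atol),
                 "replicate summary: median AUC"),
               file.path(out_dir, "run_log.txt"))
  }
  report
}

#' 2-fold compatibility summary of a report
#'
#' Pass counts for the standard comparisons: whole-body vs lumped
#' (central, peripheral, both), lumped vs compartment (central,
#' peripheral), clearance across all three models, and (when the report
#' carries `accuracy_of_auc`) the number of compounds with accuracy of
#' AUC within 2-fold of one.
#'
#' @param report A compatibility table (pipeline output or
#'   [fixture_tables()]).
#' @return Named list of `c(n_pass, n_total)` vectors.
#' @export
compatibility_summary <- function(report) {
  out <- list(
    pbpk_lumped_central = compatibility_counts(report, "pbpk_lumped",
                                               "central"),
    pbpk_lumped_peripheral = compatibility_counts(report, "pbpk_lumped",
                                                  "peripheral"),
    pbpk_lumped_both = compatibility_counts(report, "pbpk_lumped", "both"),
    lumped_compartment_central = compatibility_counts(
      report, "lumped_compartment", "central"),
    lumped_compartment_peripheral = compatibility_counts(
      report, "lumped_compartment", "peripheral"),
    cl_three_models = compatibility_counts(report, "all", "cl"))
  acc <- if ("accuracy_of_auc" %in% names(report)) report$accuracy_of_auc
         else fixture_auc_accuracy(report)
  out$accuracy_within_twofold <- c(
    n_pass = sum(vapply(acc, function(a) within_twofold(a, 1), logical(1))),
    n_total = length(acc))
  out
}
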
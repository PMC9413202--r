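test_that("lumped parameters preserve volume, flow and Kp-weighted mass", {
  set.seed(101)
  scheme <- default_lumping_scheme()
  for (i in 1:5) {
    kp <- exp(stats::runif(length(pklump:::kp_tissues()), log(0.05), log(20)))
    names(kp) <- pklump:::kp_tissues()
    drug <- fixed_test_drug(kp = kp)
    lp <- lump_parameters(ref_phys, drug, scheme)
    net <- pklump:::net_tissues()
    expect_equal(lp$lumps$NET$V, sum(ref_phys$volumes[net]))
    expect_equal(lp$lumps$NET$Q, sum(ref_phys$flows[net]))
    expect_equal(lp$lumps$NET$V * lp$lumps$NET$K,
                 sum(ref_phys$volumes[net] * kp[net]))
    ## central lump: flow is the cardiac output, blood pools count Kp = BP
    expect_equal(lp$lumps$LCEN$Q, unname(ref_phys$flows[["lung"]]))
    expect_equal(lp$lumps$LCEN$V * lp$lumps$LCEN$K,
                 (ref_phys$volumes[["arterial"]] +
                    ref_phys$volumes[["venous"]]) * drug$BP +
                   ref_phys$volumes[["lung"]] * kp[["lung"]])
    ## volume conservation across lumps + retained tissues
    expect_equal(lp$lumps$NET$V + lp$lumps$LCEN$V +
                   sum(vapply(lp$retained, `[[`, numeric(1), "V")),
                 sum(ref_phys$volumes))
  }
})

test_that("conservation identities hold on random partitions", {
  set.seed(202)
  for (i in 1:10) {
    kp <- exp(stats::runif(length(pklump:::kp_tissues()), log(0.05), log(20)))
    names(kp) <- pklump:::kp_tissues()
    drug <- fixed_test_drug(kp = kp)
    ## random partition of the non-retained tissues into two lumps, with
    ## the blood pool always central
    free <- setdiff(pklump:::pbpk_tissues(),
                    c("gut", "spleen", "liver", "kidney",
                      "arterial", "venous", "lung"))
    pick <- sample(free, sample(1:(length(free) - 1), 1))
    scheme <- lumping_scheme(
      lumps = list(CEN = c("arterial", "venous", "lung"),
                   P1 = pick, P2 = setdiff(free, pick)),
      retained = c("gut", "spleen", "liver", "kidney"))
    lp <- lump_parameters(ref_phys, drug, scheme)
    for (lump in c("P1", "P2")) {
      members <- scheme$lumps[[lump]]
      expect_equal(lp$lumps[[lump]]$V, sum(ref_phys$volumes[members]))
      expect_equal(lp$lumps[[lump]]$Q, sum(ref_phys$flows[members]))
      expect_equal(lp$lumps[[lump]]$V * lp$lumps[[lump]]$K,
                   sum(ref_phys$volumes[members] * kp[members]))
    }
  }
  ## uniform Kp: the volume-weighted mean of a constant is the constant
  kp2 <- rep(2, length(pklump:::kp_tissues()))
  names(kp2) <- pklump:::kp_tissues()
  lp <- lump_parameters(ref_phys, fixed_test_drug(kp = kp2))
  expect_equal(lp$lumps$NET$K, 2)
})

test_that("invalid schemes are rejected with the offending tissues", {
  expect_error(
    lumping_scheme(lumps = list(A = c("muscle", "skin"),
                                B = c("skin", "adipose")),
                   retained = setdiff(pklump:::pbpk_tissues(),
                                      c("muscle", "skin", "adipose"))),
    "skin", class = "pklump_validation_error")
  expect_error(
    lumping_scheme(lumps = list(A = "muscle"),
                   retained = setdiff(pklump:::pbpk_tissues(),
                                      c("muscle", "brain"))),
    "brain", class = "pklump_validation_error")
  drug <- fixed_test_drug()
  bad <- lumping_scheme(
    lumps = list(X = c("arterial", "venous", "lung"),
                 NET = pklump:::net_tissues(),
                 K = "kidney"),
    retained = c("gut", "spleen", "liver"))
  expect_error(build_lumped_odes(ref_phys, drug, bad),
               class = "pklump_validation_error")
})

test_that("peripheral volume is identical between the two formulations", {
  set.seed(303)
  for (i in 1:5) {
    kp <- exp(stats::runif(length(pklump:::kp_tissues()), log(0.05), log(20)))
    names(kp) <- pklump:::kp_tissues()
    drug <- fixed_test_drug(kp = kp)
    expect_equal(peripheral_volume(ref_phys, drug, model = "pbpk"),
                 peripheral_volume(ref_phys, drug, model = "lumped"),
                 tolerance = 1e-12)
  }
  ## unit partition coefficients: Vp is just the volume fraction
  kp1 <- rep(1, length(pklump:::kp_tissues()))
  names(kp1) <- pklump:::kp_tissues()
  drug1 <- fixed_test_drug(kp = kp1)
  expect_equal(peripheral_volume(ref_phys, drug1, model = "pbpk"),
               sum(ref_phys$volumes[pklump:::net_tissues()]) /
                 ref_phys$body_weight)
})

test_that("zero dose propagates to a zero lumped simulation", {
  drug <- fixed_test_drug(dose = 0)
  res <- simulate_system(build_lumped_odes(ref_phys, drug),
                         sim_grid(24, 101))
  expect_true(all(res$concentrations == 0))
})

test_that("total clearance is invariant under lumping", {
  set.seed(404)
  panel <- generate_drug_panel(n = 4, seed = 404, phys = ref_phys,
                               route = "iv_bolus")
  for (drug in panel) {
    t_end <- elimination_horizon(ref_phys, drug, n_half_lives = 12)
    grid <- log_grid(t_end, 900)
    auc_p <- auc_inf(grid, simulate_system(
      build_pbpk_odes(ref_phys, drug), grid)$concentrations[, "venous"])
    auc_l <- auc_inf(grid, simulate_system(
      build_lumped_odes(ref_phys, drug), grid)$concentrations[, "LCEN"])
    cl_pbpk <- drug$dose / auc_p$auc_inf
    cl_lump <- drug$dose / auc_l$auc_inf
    expect_equal(cl_lump / cl_pbpk, 1, tolerance = 5e-3)
    ## and both agree with the closed-form blood clearance
    expect_equal(cl_pbpk / blood_clearance(ref_phys, drug), 1,
                 tolerance = 1e-2)
  }
})

test_that("lumping is exact when tissues share one equilibration rate", {
  drug <- generate_matched_kinetics_drug(ref_phys, k = 0.2, route = "oral")
  ## construction: every perfused tissue equilibrates at rate k
  tt <- setdiff(pklump:::kp_tissues(), "lung")
  rates <- ref_phys$flows[tt] * drug$BP / (ref_phys$volumes[tt] * drug$Kp[tt])
  expect_equal(unname(rates), rep(0.2, length(tt)), tolerance = 1e-12)

  times <- sim_grid(48, 801)
  cv <- simulate_system(build_pbpk_odes(ref_phys, drug),
                        times)$concentrations[, "venous"]
  cl <- simulate_system(build_lumped_odes(ref_phys, drug),
                        times)$concentrations[, "LCEN"]
  expect_lt(max(abs(cv - cl)) / max(cv), 5e-3)

  ## negative control: one perturbed Kp breaks the agreement
  drug2 <- drug
  drug2$Kp[["muscle"]] <- drug2$Kp[["muscle"]] * 10
  cv2 <- simulate_system(build_pbpk_odes(ref_phys, drug2),
                         times)$concentrations[, "venous"]
  cl2 <- simulate_system(build_lumped_odes(ref_phys, drug2),
                         times)$concentrations[, "LCEN"]
  expect_gt(max(abs(cv2 - cl2)) / max(cv2), 5e-3)
})
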
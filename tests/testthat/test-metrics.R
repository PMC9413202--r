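test_that("2-fold ranges and verdicts follow the inclusive criterion", {
  expect_equal(unname(twofold_range(0.348)), c(0.174, 0.696))
  expect_equal(unname(twofold_range(1)), c(0.5, 2))
  expect_equal(unname(twofold_range(3.250)), c(1.625, 6.5))
  expect_error(twofold_range(0), class = "pklump_validation_error")
  expect_error(twofold_range(-1), class = "pklump_validation_error")

  expect_true(within_twofold(0.060, 0.030))   # ratio exactly 2: inclusive
  expect_false(within_twofold(5.476, 2.644))  # ratio 2.071
  expect_true(within_twofold(7.1, 7.1))
  expect_error(within_twofold(0, 1), class = "pklump_validation_error")

  set.seed(5)
  for (i in 1:20) {
    a <- exp(stats::rnorm(1)); b <- exp(stats::rnorm(1))
    expect_identical(within_twofold(a, b), within_twofold(b, a))
  }
})

test_that("pass counts on an all-identical report are total", {
  toy <- data.frame(compound = letters[1:4],
                    central_pbpk = 1:4, central_lumped = 1:4,
                    central_compartment = 1:4,
                    peripheral_pbpk = 1:4, peripheral_lumped = 1:4,
                    peripheral_compartment = c(1, 2, NA, 4),
                    cl_pbpk = 1:4, cl_lumped = 1:4, cl_compartment = 1:4)
  expect_equal(unname(compatibility_counts(toy, "pbpk_lumped", "central")),
               c(4, 4))
  expect_equal(unname(compatibility_counts(toy, "lumped_compartment",
                                           "peripheral")), c(3, 3))
  expect_equal(unname(compatibility_counts(toy, "all", "cl")), c(4, 4))
  expect_error(compatibility_counts(toy[0, ], "all", "cl"),
               class = "pklump_validation_error")
})

test_that("accuracy of AUC reproduces hand-evaluated compounds", {
  ## alfentanil: 0.585 / (0.351 * 0.555 / 0.209)
  expect_equal(auc_accuracy(0.351, 0.555, 0.209, 0.585), 0.62757,
               tolerance = 1e-4)
  ## thiopental: compatible, accuracy ~ 1
  expect_equal(auc_accuracy(1819.869, 0.189, 0.114, 3015.313), 0.99937,
               tolerance = 1e-4)
  expect_equal(auc_accuracy(3, 0.5, 0.5, 3), 1)
  ## scale invariance to a common rescaling of both AUCs
  expect_equal(auc_accuracy(10 * 0.351, 0.555, 0.209, 10 * 0.585),
               auc_accuracy(0.351, 0.555, 0.209, 0.585))
  expect_error(auc_accuracy(1, 0, 1, 1), class = "pklump_validation_error")
})

test_that("Vd/fu combines volumes and binding", {
  expect_equal(vd_over_fu(0.5, 0.5, 0.5), 2)
  expect_equal(vd_over_fu(3.2, 0, 1), 3.2)
  expect_equal(vd_over_fu(3.2, NA, 1), 3.2)  # one-compartment drugs
  expect_error(vd_over_fu(1, 1, 0), class = "pklump_validation_error")

  ## lumped-model Vd/fu equals the brute-force tissue sum
  drug <- fixed_test_drug()
  vc <- central_volume(ref_phys, drug)
  vp <- peripheral_volume(ref_phys, drug, model = "lumped")
  net <- pklump:::net_tissues()
  brute <- (vc + sum(ref_phys$volumes[net] * drug$Kp[net]) /
              ref_phys$body_weight) / drug$fu
  expect_equal(vd_over_fu(vc, vp, drug$fu), brute, tolerance = 1e-12)
})

test_that("power-law fitting recovers exact and noisy relationships", {
  x <- exp(seq(log(0.1), log(50), length.out = 12))
  fit <- fit_power_law(x, 2 * x^0.9)
  expect_equal(fit$a, 2, tolerance = 1e-10)
  expect_equal(fit$b, 0.9, tolerance = 1e-10)
  fit_id <- fit_power_law(x, x)
  expect_equal(fit_id$a, 1, tolerance = 1e-10)
  expect_equal(fit_id$b, 1, tolerance = 1e-10)
  expect_error(fit_power_law(c(1, 2), c(1, 2)),
               class = "pklump_validation_error")
  expect_error(fit_power_law(c(1, -2, 3), c(1, 2, 3)),
               class = "pklump_validation_error")

  set.seed(77)
  x20 <- exp(stats::runif(20, log(0.5), log(200)))
  y20 <- 1.5 * x20^0.85 * stats::rlnorm(20, 0, sqrt(log(1 + 0.2^2)))
  fitn <- fit_power_law(x20, y20)
  expect_lt(abs(fitn$b - 0.85), 0.1)
})

test_that("tissue back-prediction scales the peripheral concentration", {
  expect_equal(back_predict_tissue_concentration(2.5, 1, 1, 3, 3), 2.5)
  expect_equal(back_predict_tissue_concentration(2.5, 1, 1, 6, 3),
               2 * back_predict_tissue_concentration(2.5, 1, 1, 3, 3))
  expect_error(back_predict_tissue_concentration(1, 0, 1, 1, 1),
               class = "pklump_validation_error")
})

test_that("back-predicted tissue AUCs bracket the whole-body values", {
  ## a kinetically homogeneous (compatible) drug end to end
  drug <- generate_matched_kinetics_drug(ref_phys, k = 0.2, route = "oral")
  times <- sim_grid(72, 721)
  pbpk <- simulate_system(build_pbpk_odes(ref_phys, drug), times)
  lump <- simulate_system(build_lumped_odes(ref_phys, drug), times)
  fit <- fit_compartment_model(times, lump$concentrations[, "LCEN"],
                               drug$dose, 2, "oral", Ka_start = drug$Ka)
  cmt <- simulate_compartment(fit, times)
  lp <- lump_parameters(ref_phys, drug)
  vp_cmt <- fit$Vp / ref_phys$body_weight
  vp_lump <- peripheral_volume(ref_phys, drug, model = "lumped")
  ## peripheral concentration referenced to the anatomical lumped-tissue
  ## volume (amount per litre of real tissue), the scale on which the
  ## back-prediction identity closes
  c_p <- cmt$amounts[, "peripheral"] / lp$lumps$NET$V
  auc_cp <- auc_last(times, c_p)
  for (tt in pklump:::net_tissues()) {
    pred <- back_predict_tissue_concentration(
      auc_cp, vp_cmt, vp_lump, drug$Kp[[tt]], lp$lumps$NET$K)
    obs <- auc_last(times, pbpk$concentrations[, tt])
    expect_true(within_twofold(pred, obs), info = tt)
  }
})
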
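test_that("one-compartment oral profile matches the closed form", {
  p <- compartment_parameters(CL = 5, Vc = 50, Ka = 1, dose = 100,
                              n_compartments = 1, route = "oral")
  res <- simulate_compartment(p, sim_grid(24, 241))
  ## hand evaluation of D*Ka/(Vc*(Ka-k))*(exp(-k t)-exp(-Ka t)) at t = 1
  expect_equal(unname(res$concentrations[11, "central"]), 1.1932399,
               tolerance = 1e-6)
  ## full-profile agreement with an in-test evaluation
  k <- 5 / 50
  expect_equal(unname(res$concentrations[, "central"]),
               100 * 1 / (50 * (1 - k)) *
                 (exp(-k * res$times) - exp(-res$times)),
               tolerance = 1e-10)
})

test_that("zero dose and decoupled peripheral limits behave", {
  p0 <- compartment_parameters(CL = 5, Vc = 50, Ka = 1, dose = 0,
                               n_compartments = 1, route = "oral")
  expect_true(all(simulate_compartment(p0, sim_grid(10, 51))
                  $concentrations == 0))

  ## Q = 0 decouples the peripheral compartment
  p2 <- compartment_parameters(CL = 5, Vc = 50, Vp = 40, Q = 0, Ka = 1,
                               dose = 100, n_compartments = 2,
                               route = "oral")
  p1 <- compartment_parameters(CL = 5, Vc = 50, Ka = 1, dose = 100,
                               n_compartments = 1, route = "oral")
  times <- sim_grid(24, 97)
  expect_equal(simulate_compartment(p2, times)$concentrations[, "central"],
               simulate_compartment(p1, times)$concentrations[, "central"],
               tolerance = 1e-7)
})

test_that("ODE and closed-form paths agree", {
  p1 <- compartment_parameters(CL = 5, Vc = 50, Ka = 1, dose = 100,
                               n_compartments = 1, route = "oral")
  times <- sim_grid(24, 97)
  ode <- simulate_compartment(p1, times, path = "ode",
                              rtol = 1e-10, atol = 1e-12)
  expect_equal(ode$concentrations[, "central"],
               compartment_conc(p1, times), tolerance = 1e-8)

  p2 <- compartment_parameters(CL = 8, Vc = 30, Vp = 120, Q = 15,
                               Ka = 0.7, dose = 250, n_compartments = 2,
                               route = "oral")
  ode2 <- simulate_compartment(p2, times, rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(ode2$concentrations[, "central"]),
               unname(compartment_conc(p2, times)), tolerance = 1e-7)

  p2iv <- compartment_parameters(CL = 8, Vc = 30, Vp = 120, Q = 15,
                                 dose = 250, n_compartments = 2,
                                 route = "iv_bolus")
  ode3 <- simulate_compartment(p2iv, times, rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(ode3$concentrations[, "central"]),
               unname(compartment_conc(p2iv, times)), tolerance = 1e-7)
})

test_that("the absorption-equals-elimination singularity is removable", {
  p <- compartment_parameters(CL = 5, Vc = 50, Ka = 0.1, dose = 100,
                              n_compartments = 1, route = "oral")
  times <- sim_grid(24, 97)
  res <- simulate_compartment(p, times)
  ## limit form: C = D*k*t*exp(-k t)/Vc when Ka == k
  expect_equal(unname(res$concentrations[, "central"]),
               100 * 0.1 * times * exp(-0.1 * times) / 50,
               tolerance = 1e-6)
})

test_that("analytic AUC agrees with NCA on a dense grid", {
  p <- compartment_parameters(CL = 5, Vc = 50, Ka = 1, dose = 100,
                              n_compartments = 1, route = "oral")
  expect_equal(auc_inf_analytic(p), 20)
  p0 <- compartment_parameters(CL = 5, Vc = 50, Ka = 1, dose = 0,
                               n_compartments = 1, route = "oral")
  expect_equal(auc_inf_analytic(p0), 0)
  times <- sim_grid(200, 4001)
  res <- simulate_compartment(p, times)
  nca <- auc_inf(times, res$concentrations[, "central"])
  expect_equal(nca$auc_inf / auc_inf_analytic(p), 1, tolerance = 1e-2)
})

test_that("fitting recovers the generating two-compartment parameters", {
  p <- compartment_parameters(CL = 6, Vc = 40, Vp = 90, Q = 12,
                              dose = 200, n_compartments = 2,
                              route = "iv_bolus")
  times <- sim_grid(120, 601)
  cc <- compartment_conc(p, times)
  fit <- fit_compartment_model(times, cc, 200, 2, "iv_bolus")
  expect_equal(fit$CL, 6, tolerance = 1e-4)
  expect_equal(fit$Vc, 40, tolerance = 1e-3)
  expect_equal(fit$Vp, 90, tolerance = 1e-2)
  expect_equal(fit$Q, 12, tolerance = 1e-2)
})

test_that("invalid compartment parameters are rejected", {
  expect_error(compartment_parameters(CL = 0, Vc = 50, dose = 1),
               class = "pklump_validation_error")
  expect_error(compartment_parameters(CL = 5, Vc = 50, dose = 1,
                                      n_compartments = 2),
               class = "pklump_validation_error")
})
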
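## Shared builders for the test suite. Fixtures are constructed in code.

ref_phys <- load_physiology()

## Log-spaced grid: resolves the post-bolus mixing transient and the
## slow terminal phase simultaneously.
log_grid <- function(t_end, n = 1500, t_min = 1e-4) {
  c(0, 10^seq(log10(t_min), log10(t_end), length.out = n))
}

## A drug with every parameter fixed (no randomness) for deterministic
## simulation tests.
fixed_test_drug <- function(dose = 100, route = "oral", fu = 0.3,
                            BP = 1.1, Ka = 1.2, CL_hep = 30, CL_ki = 8,
                            kp = NULL) {
  if (is.null(kp)) {
    kp <- seq(0.4, 8, length.out = length(pklump:::kp_tissues()))
    names(kp) <- pklump:::kp_tissues()
  }
  drug_parameters(name = "fixed-test", fu = fu, BP = BP, Ka = Ka,
                  CL_hep = CL_hep, CL_ki = CL_ki, Kp = kp, dose = dose,
                  route = route)
}

## Physiology in which only the muscle is perfused: the whole-body
## model then reduces dynamically to a 4-state loop
## venous -> lung -> arterial -> muscle -> venous, used against the
## hand-coded matrix-exponential oracle.
single_tissue_phys <- function() {
  vols <- c(adipose = 0.1, bone = 0.1, brain = 0.1, gut = 0.1,
            heart = 0.1, kidney = 0.1, liver = 0.1, muscle = 30,
            skin = 0.1, spleen = 0.1, rest_of_body = 0.1, lung = 0.5,
            arterial = 1.8, venous = 3.6)
  flows <- c(adipose = 0, bone = 0, brain = 0, gut = 0, heart = 0,
             kidney = 0, liver = 0, muscle = 390, skin = 0, spleen = 0,
             rest_of_body = 0, lung = 390)
  physiology_set(vols, flows, 70)
}
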
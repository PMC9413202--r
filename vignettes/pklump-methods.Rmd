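---
title: "Methods: whole-body, lumped, and compartment model compatibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-body, lumped, and compartment model compatibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pklump)
```

## Overview

`pklump` implements a three-model pharmacokinetic compatibility study.
For each drug it simulates

1. a **whole-body perfusion-rate-limited PBPK model** — fourteen
   anatomical compartments (adipose, bone, brain, gut, heart, kidney,
   liver, lung, muscle, skin, spleen, rest-of-body, arterial and venous
   blood) connected by blood flows;
2. a **lumped model** obtained by proper lumping — a lumped central
   compartment (LCEN: arterial blood, venous blood, lung), a
   non-eliminating tissues compartment (NET: adipose, bone, brain,
   heart, muscle, skin, rest-of-body), and the retained gut, spleen,
   liver, and kidney;
3. a **classical one- or two-compartment model**, either supplied or
   fitted to the lumped central profile;

and then quantifies their compatibility through non-compartmental AUC,
clearance, central and peripheral volumes, an inclusive 2-fold
criterion, an accuracy-of-AUC statistic, a Vd/fu power-law relation,
and tissue concentration back-prediction.

## The whole-body model

States are drug **amounts** (mg), so mass balance is a direct sum.
Each perfusion-limited tissue obeys

$$V_T \frac{dC_T}{dt} = Q_T \left( C_{in} - \frac{C_T \cdot BP}{K_{p,T}} \right) - \text{elimination},$$

with tissue outflow referenced to blood via the blood-to-plasma ratio
$BP$ and the tissue-to-plasma partition coefficient $K_{p,T}$.  The
lung is fed by venous blood and feeds arterial blood; gut and spleen
drain through the portal vein into the liver, whose total inflow is
the hepatic arterial flow plus the portal contributions
($Q_{li} = Q_{ha} + Q_{gu} + Q_{sp}$).  Elimination is first order in
the unbound tissue concentration, $fu \cdot CL \cdot C_T \cdot BP / K_{p,T}$,
in liver and kidney.  Hepatic clearance follows the well-stirred
model, $CL_{hep} = Q_{li} \, fu \, CL_{int} / (fu \, CL_{int} + Q_{li})$.
Oral dosing enters a depot that empties into the gut at rate $K_a$;
intravenous bolus dosing initializes the venous pool.

A cumulative `eliminated` state makes conservation checkable on every
run: depot + tissues + eliminated must equal the dose to solver
precision (`mass_balance_error()`).

## Proper lumping

A lump with members $T \in L$ has

$$V_L = \sum_T V_T, \qquad Q_L = \sum_T Q_T, \qquad
  K_L = \frac{\sum_T V_T K_{p,T}}{V_L},$$

with blood pools contributing $K_p \equiv BP$.  The central lump's
flow is the cardiac output.  These identities conserve total volume,
total flow, and $K_p$-weighted drug mass exactly, for any partition of
the tissues (`lump_parameters()` is tested on random partitions).

Two consequences the package exploits as oracles:

* **Clearance invariance.**  The eliminating organs are retained
  unchanged, so total blood clearance — a function of organ flows,
  $fu$, and organ clearances only — is identical in the full and
  lumped models.  In closed form,
  $CL_{blood} = \frac{Q_{li} \, fu \, CL_{hep}}{Q_{li} + fu \, CL_{hep}} + \frac{Q_{ki} \, fu \, CL_{ki}}{Q_{ki} + fu \, CL_{ki}}$,
  and the IV venous $AUC_{0-\infty} = D / CL_{blood}$ in both models.
* **Exactness limit.**  Lumping is exact when all lumped tissues share
  one equilibration rate $k_T = Q_T BP / (V_T K_{p,T})$.
  `generate_matched_kinetics_drug()` constructs such a drug by
  inverting this relation ($K_{p,T} = Q_T BP / (V_T k)$, lung at
  $K_p = BP$).  The default rate $k = 0.2\,h^{-1}$ is deliberately
  slow compared with blood mixing (cardiac output over blood volume,
  roughly $65\,h^{-1}$), which is the time-scale separation the limit
  requires; the comparison uses oral dosing because an intravenous
  bolus probes the sub-minute blood mixing transient that the single
  central pool cannot represent.  A ten-fold perturbation of one
  $K_p$ serves as the negative control.

## Compartment models and fitting

One- and two-compartment models with IV-bolus or first-order oral
input are evaluated in closed form (macro-constants
$\alpha, \beta, k_{21}$), with an ODE fallback near the removable
absorption-rate degeneracies.  `fit_compartment_model()` minimizes
log-concentration residuals over log-parameters with
`minpack.lm::nls.lm`, started from non-compartmental moment estimates
($CL = D/AUC_\infty$, $V_{ss} = D \cdot AUMC / AUC^2$).  Fitting
horizons are set per drug as eight terminal half-lives
($8 \ln 2 \cdot V_{ss} / CL$); with a fixed horizon, long half-life
drugs are truncated and clearance recovery degrades.

## Comparison metrics

* **2-fold criterion** — two positive values are compatible when
  their ratio lies in $[0.5, 2]$, boundary inclusive (a small relative
  tolerance guards against decimal-rounding artefacts at exactly 2.0);
  the three-model clearance comparison requires the max/min ratio
  $\le 2$.
* **Accuracy of AUC** — observed compartment AUC divided by the
  lumped AUC rescaled by the clearance ratio,
  $AUC_{obs} / (AUC_{LCEN} \cdot CL_{lump} / CL_{cmt})$.
* **Central volume** — $(V_{ar} + V_{ve} + V_{lu} K_{p,lu}/BP)/BW$;
  the peripheral volume is $\sum_{T \in NET} V_T K_{p,T} / BW$, which
  is algebraically identical between the tissue-wise and lumped
  ($V_{NET} K_{NET} / BW$) formulations.
* **Vd/fu power law** — $Vd/fu$ of the compartment model against the
  lumped model on log-log axes, fitted by `fit_power_law()`.
* **Back-prediction** — per-tissue concentrations from the
  compartment-model peripheral profile,
  $C_T = C_p \cdot (V_{p,cmt}/V_{p,lump}) \cdot (K_{p,T}/K_{Lump})$,
  where $C_p$ is referenced to the anatomical lumped-tissue volume.

## Bundled result tables

`fixture_tables()` returns per-compound central/peripheral AUC and CL
point values for twenty compounds under the three models.  They
exercise only the comparison layer; the simulation layer is verified
on synthetic drugs, keeping the two test surfaces independent:

```{r fixtures}
str(compatibility_summary(fixture_tables()), give.attr = FALSE)
```

## The synthetic drug generator

`generate_drug_panel()` draws log-uniform $fu$, $BP$, $K_a$, $K_p$,
renal clearance, and dose, and stratifies the hepatic extraction ratio
$E = fu \, CL_{int} / Q_{li}$ log-evenly across the panel so that both
flow-limited and restrictively cleared drugs always appear.  The
generator's ranges are study conditions, fixed in
`drug_profile()`; `perturb_drug()` adds median-preserving lognormal
inter-individual variability for replicate (Monte-Carlo) mode, which
`run_compatibility_pipeline()` summarizes by the per-compound median.

## A complete run

```{r pipeline}
phys <- load_physiology()
panel <- generate_drug_panel(n = 3, seed = 1, phys = phys)
report <- run_compatibility_pipeline(panel, phys, t_end = 48,
                                     n_points = 801)
report[, c("compound", "central_pbpk", "central_lumped",
           "central_compartment", "accuracy_of_auc")]
```

Typical problem sizes: a 17-state whole-body simulation over 2001
time points takes well under a second; a full 20-drug three-model run
with fitting completes in a few seconds on one CPU.

## Limitations

Only perfusion-rate-limited tissue models are implemented
(no permeability-limited tissues), single doses, and oral or IV-bolus
routes.  The compartment model's fitted clearance is an apparent
blood clearance of the simulated profile and therefore reflects the
unbound-fraction scaling of organ elimination; it is not expected to
equal the sum of the mechanistic organ-clearance inputs for highly
bound drugs.
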
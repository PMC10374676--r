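---
title: "A mechanistic model of hematopoiesis under chemotherapy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanistic model of hematopoiesis under chemotherapy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hematotox)
```

## Purpose

`hematotox` predicts individual chemotherapy-induced hematotoxicity. Given a
patient's blood counts (platelets, neutrophils, leukocytes) measured densely
during the *first* cycle of FLOT, FLO/mFOLFOX or FOLFIRINOX chemotherapy, the
package learns that patient's parameters of a mechanistic
hematopoiesis model and forward-simulates the remaining treatment cycles to
predict the per-cycle CTCAE toxicity grade of each cell line. A synthetic
cohort generator emulating the clinical sampling design makes every pipeline
stage testable without patient-level data.

## The model

The model tracks bone-marrow and blood compartments on a normalized scale
(homeostatic value 1) with blood counts in 10⁹/L:

* **Stem cells** `S` proliferate logistically and are activated into the
  myeloid flux at a rate stimulated by G-CSF (sensitivity `b_S_act`) and by
  depletion of the megakaryocyte mass (compensatory feedback, exponent
  `b_MKC_S`).
* **Osteoblast niche** `O` and **dormant precursors** `D`: chemotherapy
  slowly erodes osteoblast activity (`f_kill_O`); lacking osteoblast support,
  dormant precursors are lost at rate `d_Osteo_loss`, which damps the stem
  outflux. This is the mechanism carrying *long-term* (multi-cycle)
  cumulative toxicity: it makes the pre-cycle platelet baseline drift
  downward over cycles.
* **Granulopoiesis**: common myeloid progenitors `CMP` (G-CSF-amplified
  influx, sensitivity `b_A_CM`), a proliferating precursor pool, a 4-stage
  post-mitotic maturation chain (3.6 days) and circulating neutrophils `ANC`.
* **Thrombopoiesis**: megakaryocyte precursors `CM`, an endoreduplication
  ladder over ploidy classes 2–64, a TPO-modulated ploidy-64 → proplatelet
  transition (sensitivity `b_MKC64`), and a 10-stage Erlang platelet age
  chain (lifespan `tau_PLT` = 9 days). The Erlang chain gives the platelet
  survival curve its characteristic shoulder — survival at half the mean
  lifespan far exceeds the exponential `exp(-0.5)`.
* **Lymphocytes** (two-stage) and **monocytes** (first-order) complete the
  leukocyte observable `WBC = ANC + LYM + MON`.
* **Cytokines**: G-CSF with renal plus neutrophil-mediated saturable
  clearance (falling ANC raises G-CSF, which amplifies production); TPO with
  renal clearance plus saturable clearance by the platelet/megakaryocyte
  mass, maximum rate `w_PLC`. TPO stimulates megakaryopoiesis biphasically:
  `f(u) = (1+s)·u^h / (1+s·u^{2h})` rises from 0, passes 1 at the normal
  level, peaks at `u* = s^{-1/(2h)}` and falls at supra-physiological levels.
* **Feedback functional form**: all cytokine actions use the clamped power
  law `Z(x) = clamp(x^b, z_min, z_max)`, normalized so `Z(1) = 1`; the single
  exponent `b` is the "sensitivity parameter" that is learned per patient.

Every compartment is written in *normalized relaxation form*
(`dX/dt = k_X (input − X)` plus kill terms), so the drug-free steady state is
exactly the all-normal state for any admissible parameters — the homeostasis
contract `steady_state()` enforces (derivative max-norm < 1e-8) holds by
construction, not by numerical root finding.

### Pharmacokinetics and pharmacodynamics

Each cytotoxic drug has a linear compartmental PK model (3 compartments for
oxaliplatin, irinotecan and the docetaxel placeholder; 2 for 5-fluorouracil)
with first-order elimination `k10` from a central volume. Doses are
per-BSA (`build_dosing_events()` converts regimen definitions plus the
patient's body surface area into absolute infusion events on the study
clock). Leucovorin is scheduled but myelotoxically inert. The cytotoxic
effect is a first-order kill of cycling cells,
`kill(t) = Σ_d PD_d · C_d(t)`, additive across drugs and linear in the
per-drug coefficients `PD_d` (L/mg/day). Shared compartments (stem cells,
CMP, lymphoid progenitors, osteoblasts) see the unweighted sum scaled by a
class vulnerability; the granulopoietic and thrombopoietic branches see
lineage-weighted sums with fixed per-drug weights. The weights encode the
clinically distinct toxicity profiles — oxaliplatin predominantly
thrombotoxic, docetaxel and 5-FU predominantly neutropenic — and, equally
important, they make the per-drug `PD` coefficients of co-administered drugs
separable from first-cycle data: with a single shared scaling the `PD`s of
drugs given on the same day are nearly collinear (we measured relative
standard errors of 3–6 for `PD_oxali`/`PD_5FU` in noise-free fits), which
would defeat individual PD estimation outright.

### Rate constants

The population constants (normal counts, transit and clearance rates,
clamps) live in `inst/extdata/model.yaml`. They were calibrated once so that
a standard FLOT cycle at BSA 1.8 m² produces: an ANC nadir of ≈1.4×10⁹/L
(grade 2) between days 3 and 14, recovery to ≥90% of baseline by day 28, a
platelet nadir ≈135×10⁹/L near day 8, damped (non-oscillatory) return to
homeostasis after perturbations, and a monotonically non-increasing
pre-cycle platelet baseline over four cycles. PK constants
(`inst/extdata/pk.yaml`) use literature-plausible central half-lives of
hours; the docetaxel entry is an explicitly flagged generic placeholder.

## Learning individual parameters: virtual participation

A patient's free parameters (default: `b_S_act`, `b_A_CM`, `b_MKC64`,
`w_PLC`, `d_Osteo_loss` and the `PD` coefficients of the drugs in their
regimen) are learned from cycle-1 observations only, by minimizing

```
J(θ) = Σ_obs ((log y_obs − log y_model(θ)) / σ_ind)²        (individual term)
     + Σ_exp Σ_points ((mean − y_model,pop(θ)) / sd)²       (population term)
```

The individual residuals are lognormal (`σ_ind` = 0.15 by default; blood
counts are positive with multiplicative error). The population terms are
"virtual experiments": the patient virtually participates in population
datasets, and deviations of their model from the population means are
penalized by the population SDs. The packaged synthetic bank
(`make_virtual_experiments()`) holds six datasets: the recovery of ANC, PLT
and TPO after a standardized 1-day exogenous kill pulse (11 time points
each — the large cytokine excursions inform the sensitivity parameters and
the TPO clearance capacity), and the ANC/PLT/WBC course of a standard FLOT
cycle at reference BSA (13 daily points each — this is what gives the
per-drug kill coefficients population-level curvature). Population SDs
default to 1.8× the individual residual scale on a relative footing (a 27%
relative SD, typical of hematologic recovery data), so each population
point carries about 1/3 of an individual point's weight — considerably
smaller per point, while the dense sampling gives the bank a meaningful
total weight. This balance is what the identifiability report relies on:
individually, the 18 cycle-1 points cannot pin the sensitivity parameters
(their marginal RSEs are 0.8–2.3); jointly with the bank, all free
parameters reach RSEs near or below 0.5.

Optimization is bounded multistart Nelder-Mead in log-parameter space: the
first start is the population centre, further starts come from a seeded
Latin hypercube, the best objective wins (ties to the first start index),
and the simplex is restarted at the incumbent until it reports convergence
("polish" rounds). Parameters are bounded to [0.25, 4]× the population value
(≈±4.6 lognormal SD at the default between-patient CV of 0.3): with noisy
data the unbounded likelihood can prefer implausible compensating
combinations (e.g. a 5× kill coefficient offset by a 4× stem-cell
sensitivity) that match cycle 1 but destroy multi-cycle predictions.
A failed simulation inside the objective returns a large finite penalty, so
the search remains total. Identifiability is reported as relative standard
errors: the square root of the diagonal of the inverse finite-difference
Hessian of the objective in log space (so the SE of `log θ` approximates the
relative SE of `θ`); values above 0.5 are flagged non-identifiable.

## Prediction and evaluation

`predict_grades()` simulates the full treatment with the fitted parameters
and grades the per-cycle minimum *over the scheduled sampling days*, so that
predicted and observed grades are compared on the same information grid
(a `continuous = TRUE` flag grades the continuous minimum instead).
Observed grades come from `grade_per_cycle()`: the nadir of the observations
in each half-open 14-day cycle window, graded by the CTCAE v5 thresholds in
`inst/extdata/ctcae.yaml` (boundary values take the milder grade; grade 0 at
or above the LLN). `deviation_summary()` reports the mean absolute grade
deviation with its standard error (sample SD/√n) per cycle and analyte,
flagging cycle 1 as fitted-for-comparison-only. `covariate_screen()`
correlates estimates with age, BMI and BSA by Spearman's rank correlation
(average ranks; exact permutation p-values for n ≤ 7, t-approximation
otherwise — full exact enumeration beyond n = 7 is quadratically expensive
for no inferential gain at this cohort size). `summarize_adverse_events()`
tabulates worst grades per regimen and derives high-grade (≥3) fractions.

## The synthetic cohort

`sample_cohort()` emulates the study design: 28 patients by default
(20 FLOT, 3 FLO/mFOLFOX, 5 FOLFIRINOX by largest-remainder apportionment),
ages 43–83, BMI 17.8–44.9, BSA ≈ N(1.85, 0.18²) m², 4 cycles for
FLOT/FLO and 8 for FOLFIRINOX, blood draws on days 1, 3, 5, 8, 10, 12 of
cycles 1–2 and days 1, 10 from cycle 3 on, multiplicative lognormal
measurement noise with CV 0.15, and independent lognormal between-patient
parameter heterogeneity with CV 0.3. An optional planted association writes
`log b_S_act = log(pop) + 0.5·z(BSA) + N(0, σ)` with residual CV 0.1 — the
slope/residual ratio gives a Spearman ρ near 0.95 at n = 30, a clean test
bed for the covariate screen. True parameters are kept in a separate table
so fitting can run blind.

What the generator does *not* emulate: site-to-site assay differences,
informative missingness (dropout is independent thinning), dose reductions
or delays in response to toxicity, G-CSF rescue medication, and surgery
effects. Passing tests on synthetic cohorts therefore demonstrate internal
consistency of the machinery — that the estimator recovers the generating
process and the prediction pipeline is unbiased under the model — not
clinical validity on real patients.

## Numerical choices

* Stiff-capable integrator (`lsoda`) with relative tolerance 1e-8 and
  absolute tolerance 1e-10 on the normalized scale; the time axis is split
  at every infusion on/off breakpoint and the integrator restarted, so the
  piecewise-constant inputs are handled exactly (no forcing interpolation).
  Inside the fitting objective the relative tolerance is relaxed to 1e-6.
* Tiny negative undershoots of fast-decaying states (notably 5-FU amounts,
  eliminated at 50/day) are clamped to zero within a 1e-3 band; larger
  negatives are real errors and surface in tests.
* Nadir ties break to the earliest time; cycle windows are half-open
  `[start, start+14)`; a cycle without observations propagates as an absent
  entry, not an error.
* All randomness flows through explicit seeds (cohort, per-patient noise,
  multistart draws), so every pipeline output is bit-reproducible.
* Test-suite problem sizes: recovery studies use 10 patients per arm with 3
  multistarts; the end-to-end noise-free check uses a 6-patient mixed-regimen
  cohort; the noisy end-to-end check uses the full default 28-patient cohort
  with a single population-centred start (the penalized surface is
  well-conditioned, so the multistart mainly guards the recovery studies).

## Identifiability: what first-cycle data can and cannot estimate

The Fisher information of the 18 cycle-1 observations (6 sampling days × 3
analytes, σ_ind = 0.15) is strongly anisotropic. At the population point the
eigenvalues of the log-parameter information matrix for the set
{`b_S_act`, `b_A_CM`, `PD_oxali`, `PD_5FU`, `w_PLC`} span 23 down to 0.15:
the kill coefficients are well determined (nadir depths respond directly),
but the combination "raise `b_S_act`, lower `b_A_CM` and `w_PLC`" changes
the predicted first cycle almost imperceptibly, because G-CSF and TPO only
rise ~1.3–1.6-fold during a moderate cycle and the feedback sensitivities
enter through `b·log(regulator)`. Three consequences, all visible in the
acceptance suite:

1. *Noise-free* data identify everything in principle (the objective has a
   unique zero), and individual-only fits recover generating parameters to
   well under 1%, which is why the end-to-end noise-free cohort is predicted
   with zero grade deviation.
2. The penalty bank restores curvature along the weak directions (reported
   RSEs drop from 0.8–2.3 to ≈0.4–0.5), but any penalty strong enough to do
   that necessarily shrinks those directions toward the population centre;
   for a patient whose truth deviates along a weak direction this appears as
   a recovery bias that can reach tens of percent even with noise-free data.
   A 5% recovery guarantee and a 50% RSE guarantee from one penalized fit
   are therefore mathematically in tension for patients drawn at CV 0.3,
   and the corresponding acceptance assertions fail for individual
   parameter instances — by design, not by defect: the virtual-participation
   estimator is a shrinkage estimator.
3. With 15% measurement noise the maximum-likelihood errors along weak
   directions reach the Fisher bound (≈0.8–2.3 on the log scale): we
   verified with exhaustive optimization that the noisy objective's global
   minimum genuinely sits 3–6 χ² units below the truth at parameter errors
   of 30–100%, the statistically expected displacement for five free
   parameters. Median recovery errors under noise are therefore dominated by
   this information limit, not by the optimizer. In practice this matters
   little for *prediction* — cycle-2 grade predictions on the noisy default
   cohort agree with observation to well under one grade on average, because
   the weakly identified directions are exactly the ones the trajectory is
   insensitive to — but it bounds what per-parameter recovery statements can
   honestly be made. Real applications should read individual estimates of
   `b_S_act`, `b_A_CM` and `w_PLC` as regularized (shrunken) quantities.

## Known limitations

* Erythropoiesis/hemoglobin and anemia grading are out of scope; so are
  non-hematologic toxicities, surgery effects and drug–drug PK interactions.
* PK rate constants and the docetaxel model are structural placeholders with
  plausible magnitudes, not fitted to concentration data.
* The model supports exogenous G-CSF input events (`drug = "gcsf"`), but the
  default cohort uses none.
* Updating fits with later cycles (fit cycles 1–3, predict cycle 4) is not
  implemented.
* The platelet age chain length (10 stages) is fixed in the compiled model;
  the lifespan `tau_PLT` is configurable.

## A worked example

```{r example, eval = FALSE}
library(hematotox)

# simulate one FLOT cycle for an average patient
params <- default_parameters()
events <- build_dosing_events("FLOT", bsa = 1.8, n_cycles = 1)
trajectory <- simulate_hematopoiesis(params, events, t_grid = seq(0, 28, 0.5))
autoplot(trajectory)

# a small synthetic study, end to end
cfg <- study_config(
  synthetic = cohort_config(n_patients = 6, seed = 1),
  fit = fit_settings(n_starts = 2, maxit = 300, rtol = 1e-6),
  seed = 1
)
res <- run_study(cfg)
res$deviations
autoplot(res$deviations)
```
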
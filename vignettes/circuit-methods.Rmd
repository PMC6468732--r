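---
title: "Modelling the extracellular proteasome-OPN circuit: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the extracellular proteasome-OPN circuit: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opncircuit)
```

This vignette explains the models implemented in `opncircuit`, the
assumptions behind them, the numerical machinery, and the design
decisions taken where the problem was genuinely open. It states no
empirical result beyond what the package's test suite and
`scripts/acceptance.R` themselves compute.

## The circuit model and its assumptions

The circuit couples serum osteopontin (OPN) to extracellular 20S
proteasomes in relapsing-remitting multiple sclerosis (RRMS).
Proteasomes enter the blood at a constant release rate `k_in` (nM/h),
are cleared at `k_deg` (1/h), and their release is inhibited by total
OPN through the factor `1/(1 + k_i * OPN_tot)`. Release is split
`x_i : (1 - x_i)` between the immuno- and standard isoform, which
differ only through their Michaelis-Menten constants (`kcut`, `KM`)
for degrading the three OPN species. OPN is produced at `k_1` (nM/h),
apportioned `x_t` to full-length OPN and `(1 - x_t)/2` to each
thrombin-cleaved half; this symmetric split is forced by the definition
of `x_t` as the OPN-FL fraction and is the only parsimonious reading of
the production terms -- thrombin cleavage of one OPN-FL yields one
OPN-N and one OPN-C. Each (isoform, parent) pair feeds its own fragment
pool, cleared at `k_deg3`; fragment concentration is expressed as moles
of parent consumed, so in vitro `OPN(t) + F(t)` is conserved.

Key assumptions, all load-bearing for the closed-form identification:

* **Remission is a steady state.** Serum levels of healthy donors are
  stable over months, and RRMS remission is treated the same way. This
  turns the remission measurements into algebraic constraints that
  yield `k_in`, `k_i` and the non-proteasomal clearances exactly.
* **Relapse is a quasi-steady state for OPN.** The relapse multiplier
  `gamma` on `k_1` is derived from the OPN-FL balance at the measured
  relapse levels. Whether the sampled relapse concentrations sit at a
  transient peak or near a plateau is unknowable from two-phase
  sampling; the quasi-steady-state reading is self-consistent (it
  returns `gamma = 1` exactly when relapse equals remission) and
  round-trips through the simulator to better than 1% (verified in the
  tests by simulating each phase to equilibrium and re-deriving).
* **Relapse forcing shape.** `k_1` rises linearly over a 2-week ramp,
  holds a 2-week plateau, and returns instantly: a 4-week window
  (672 h). The shape is conventional, not inferred; a step relapse is
  available via `ramp_duration = 0`.
* **Forcing multiplies `k_1` only.** Whether inflammation also shifts
  `x_t` (thrombin activity) during relapse is unmeasured; here the
  species mix of production is held fixed.

Units are hours and nM throughout. ELISA inputs in ng/mL convert with
configurable molecular masses (35 kDa for OPN constructs, 700 kDa for
the 20S barrel). The fixed constants default to
`k_deg = k_deg3 = 2e-4 /h` and `k_1 = 1e-4 nM/h`; they are
overridable, and everything downstream is derived relative to them.

Because the assays measure only totals (and only OPN-FL reacts in the
OPN ELISA), measured totals are apportioned by the assumed fractions:
`x_t : (1-x_t)/2 : (1-x_t)/2` across OPN species and `x_i : (1-x_i)`
across isoforms. Per-patient analyses assume `x_i = x_t = 0.5`, the
maximally non-committal split.

## Numerical choices

* **Integration.** `simulate_circuit()` uses LSODA (`deSolve`) with
  `rtol = 1e-8`, `atol = 1e-10`. Negative excursions above `-1e-6` are
  clipped to zero; anything worse raises an error rather than being
  hidden. The test suite pins the solver against an independent
  fixed-step classical Runge-Kutta oracle at `dt = 0.01 h`.
* **Steady states** are solved algebraically (`circuit_equilibrium()`):
  proteasome levels are closed-form in total OPN, each OPN species then
  solves a scalar monotone balance by `uniroot`, and one outer root
  find closes total OPN. This avoids burn-in simulation entirely.
* **Digestion curves.** The substrate depletion ODE
  `dS/dt = -p kcut S/(KM + S)` has an exact implicit solution
  `KM log(S0/S) + (S0 - S) = p kcut t`, evaluated by a vectorised
  damped Newton iteration on `log S` with a bisection fallback
  (~1e-12 relative). Exposure integrals over the migration window use
  composite Simpson on 4001 nodes: fast kinetics make the curve
  near-step, where adaptive quadrature can fail but a fixed fine rule
  cannot.
* **MCMC.** `metropolis_hastings()` is a plain Gaussian random-walk
  sampler with an optional symmetric wide-jump mixture component
  (10% of proposals at 8x scale) that lets chains hop between the
  zero-order and first-order basins of weakly decaying digestion
  curves. For the kinetic inference the chain runs in
  `(log rate0, log KM)` with `rate0 = kcut p/(KM + S0)`: data that only
  constrain `kcut/KM` produce an axis-aligned flat direction instead of
  a diagonal ridge, so the chain mixes across the full identifiable
  set; the map back to `(kcut, KM)` has unit Jacobian, leaving the
  log-uniform priors flat. Priors: `kcut` in [1e-4, 1e2] /h per nM,
  `KM` in [1e-2, 1e4] nM, noise SD inferred by default under a
  log-uniform prior on [1e-3, 1] (Gaussian likelihood on relative
  substrate, replicates pooled). Proposal scales are tuned toward ~30%
  acceptance by short pilot runs. The `kcut`-`KM` ridge correlation is
  computed and reported per chain, not hidden; credible intervals are
  honest about it (they widen along the ridge).
* **Ties and degenerate inputs.** MSSS resolves EDSS ties by mid-rank
  within the query-augmented bin; exact phase ties classify a patient
  as group B (strict inequalities define group A); constant outcomes
  make cross-validated R-squared undefined and raise an error;
  rank-deficient severity designs (duplicated features) are tolerated
  through pivoted least squares.

## Chemotactic indices

Unprocessed indices divide net migration (percent of control minus the
100% baseline) by the stimulus exposure `opn0 * window`. The baseline
subtraction is a deliberate calibration choice: without it, plain
medium would carry a nonzero chemotactic index. Fragment indices solve
`net = ci_parent * int(OPN dt) + ci_F * int(F dt)` over the migration
window, attributing residual migration to the fragment pool. The
window is [2, 22] h: digestion starts when enzyme and substrate are
mixed (t = 0), cells migrate from the 2 h pre-incubation mark for
20 h. The 3 h short-protocol readouts are qualitative only; the window
is configurable. Applied per posterior kinetic draw, the indices come
out as distributions. The relapse "peak" used by scenario grids is the
maximum of total chemotaxis inside the relapse window.

## Severity modelling

MSSS ranks a patient's EDSS within the whole-year duration bin of a
reference population, with the query counted in the bin: mid-rank of
the query's EDSS divided by (augmented bin size + 1), times 10. The
published normative table is not redistributable, so the module accepts
any reference table and the generator synthesises one (a synthetic
stand-in, labelled as such). `delta_msss = msss_relapse -
msss_remission` is implemented with the printed sign convention, so
positive values mean a worse relapse; `msss_prime` multiplies by the
relapse MSSS to up-weight worsening at high severity.

The severity models are Gaussian linear models evaluated by k-fold
cross-validation on pooled out-of-fold predictions. Out-of-fold
R-squared is the primary metric (in-sample R-squared is exposed as a
secondary output) because with ~6-50 patients in-sample fit is
uninformative. Folds are a seeded random partition, clamped to the
sample size -- a six-patient cohort with `k_folds = 10` silently
becomes leave-one-out, which is the only sensible reading of 10-fold
CV at that scale -- and the identical fold assignment is reused across
nested feature sets so differences reflect the features. Group-B
patients (inverted phase ordering) are never used for training; the
fitted group-A model is applied to them out-of-group.

## What the synthetic generator emulates -- and what it does not

The generators encode the statistical structure the analysis assumes:
a 16-patient cohort with 1-4 remission withdrawals each and a ~20%
group-B minority; remission OPN log-normal between patients
(log-SD 0.15) with 5% multiplicative measurement noise (ELISA-scale);
proteasome levels tied to OPN through the steady-state release balance,
producing the inverse OPN-proteasome correlation; relapse levels at the
`gamma`-equilibrium uplift; digestions at the in vitro concentrations
(571 nM OPN, 250 nM proteasome -- 0.4 µg and 3.5 µg in 20 µL) over
0-4 h in duplicate experiments; migration at 10 µg/mL OPN with a 20:1
proteasome:OPN mass ratio and control counts 87 ± 7.9; immuno `kcut`
above standard for every species; fragment indices above parent for
OPN-FL/-C and below for OPN-N; and severity outcomes linear in the
proteasome/fragment features with positive remission and negative
relapse coefficients.

Two generator choices deserve emphasis. First, the serum scale
(6 ng/mL OPN, 10 ng/mL proteasome) was fixed a priori so that, with
`k_1 = 1e-4 nM/h` and in-vitro-scale kinetic constants, the derived
non-proteasomal clearances are positive with comfortable margin: no
published unit system connects the serum and in vitro concentration
scales, and a much larger serum OPN scale makes every patient's
derivation inadmissible, which the existence of derivable group-A
patients rules out. Second, the ground-truth `KM = 300 nM` sits below
the in vitro substrate concentration, so digestion curves traverse the
saturation transition and the posterior genuinely constrains `KM`; the
coverage tests additionally probe the deliberately weaker 5-point
design.

What passing tests therefore show about real data is limited: the
generator has one latent dimension of patient heterogeneity (the OPN
level), multiplicative log-normal noise, no assay drift, no
batch/centre effects, no treatment effects (corticosteroids), and
relapse levels exactly at the model's own quasi-steady state. Recovery
and coverage results certify the *procedures* under the model's
assumptions, not the model's adequacy for any particular cohort.

## Problem sizes

Default study conditions: 1000 cohort bootstrap draws for parameter
ensembles (200 in the pipeline stage), 50,000-iteration reference
chains for focused inference with 20,000 as the `infer_kinetics()`
default (4000 with 1000 burn-in per curve inside the pipeline, where
six curves are fitted), 50 posterior kinetic draws carried into index
distributions, 1000-fold ensemble simulation in focused analyses (50
in the pipeline), 1000 bootstrap resamples for correlation intervals,
and an 11 x 11 scenario grid. The acceptance script uses 50 seeded
datasets for credible-interval coverage and 100 seeded cohorts for
bootstrap coverage. These sizes leave Monte Carlo error well below
every tolerance tested while keeping a full run fast on one CPU.

## Known limitations

* Serum is treated as the compartment; CSF and CNS lesion
  concentrations, where the circuit presumably acts, are unmodelled.
* Autoantibodies against OPN or proteasomes, and any other sequestering
  species, are absent.
* The in vitro digestion data identify `kcut/KM` far better than either
  constant separately when substrate sits below `KM`; the reported
  ridge correlation makes this visible, and dilute-regime
  extrapolations inherit the full ridge uncertainty.
* `gamma` derivation assumes the measured relapse is at quasi-steady
  state; blood drawn 2-7 days after onset may sit on the transient.
* Group-B patients are handled descriptively (measured-value features,
  out-of-group prediction); the package offers no mechanism for their
  inverted dynamics.
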
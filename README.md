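# opncircuit

Dynamics of the extracellular proteasome–osteopontin circuit in
relapsing-remitting multiple sclerosis (RRMS).

Osteopontin (OPN) is a pro-inflammatory cytokine whose serum
concentration rises during RRMS relapses. It circulates as full-length
OPN (OPN-FL) and as thrombin-cleaved N-/C-terminal halves (OPN-N,
OPN-C), and all three are degraded in the blood by extracellular 20S
proteasomes — faster by the inflammation-induced immunoproteasome than
by the standard isoform. The resulting fragments of OPN-FL and OPN-C
are *more* chemotactic than their parents, while proteasomal processing
blunts OPN-N. OPN in turn inhibits proteasome release, closing a
negative-feedback circuit whose state shifts between remission and
relapse. `opncircuit` implements this circuit as a quantitative
pipeline for systems-biology and clinical-modelling work: ODE
simulation, parameter identification from paired serum measurements,
Bayesian kinetic inference, chemotactic-index estimation, and severity
prediction.

## The model

Eleven species: proteasome isoforms `p_i`, `p_s`; OPN species
`OPN_F`, `OPN_N`, `OPN_C`; and six fragment pools `F_{x,y}` per
(isoform x, parent y). With `OPN_tot = OPN_F + OPN_N + OPN_C`:

    dp_i/dt   = k_in X_i / (1 + k_i OPN_tot) − k_deg p_i
    dp_s/dt   = k_in (1−X_i) / (1 + k_i OPN_tot) − k_deg p_s
    dOPN_x/dt = γ(t) k_1 s_x − Σ_j kcut_{x,j} p_j OPN_x/(KM_{x,j}+OPN_x)
                − k_deg,x OPN_x
    dF_{x,j}/dt = kcut_{x,j} p_j OPN_x/(KM_{x,j}+OPN_x) − k_deg3 F_{x,j}

where `s_F = X_t`, `s_N = s_C = (1−X_t)/2` split OPN production between
the full-length and cleaved forms, and `γ(t)` ramps from 1 to γ over a
2-week onset, holds a 2-week plateau, and returns to 1 (the 4-week
relapse window). Remission is treated as a steady state, which gives
`k_in`, `k_i`, the non-proteasomal clearances and γ in closed form from
paired remission/relapse serum measurements. The `kcut`/`KM` constants
are inferred from 0–4 h in vitro digestions by random-walk
Metropolis–Hastings; chemotactic indices `ci` (relative migration per
nM per h) are solved from Boyden-chamber readouts via the exposure
integrals of parent and fragments over the 2–22 h migration window;
total chemotaxis is `C_tot(t) = Σ ci_x · x(t)`. Severity uses the MSSS
(EDSS ranked within a duration-matched reference population, as a
decile × 10), `ΔMSSS = MSSS_relapse − MSSS_remission` and
`MSSS′ = ΔMSSS × MSSS_relapse`, predicted from simulated circuit
components by cross-validated linear models.

Seeded generators (`generate_cohort()`, `generate_digestion()`,
`generate_migration()`, `generate_msss_reference()`,
`generate_severity()`) emulate every input table with the structure the
analysis assumes, so the whole pipeline runs and is tested without any
patient data.

## Worked example

Derive a patient's circuit from paired serum measurements (ng/mL,
converted at 35 kDa for OPN and 700 kDa for the 20S proteasome) and
simulate a relapse:

```r
library(opncircuit)

kin <- kinetic_params(
  kcut = cbind(standard = c(0.4, 0.6, 0.5), immuno = c(1.2, 0.8, 1.5)),
  km = matrix(300, 3, 2))

pars <- derive_circuit_params(
  p_rem = ng_ml_to_nM(10, 700), p_rel = ng_ml_to_nM(6, 700),
  opn_rem = ng_ml_to_nM(6, 35), opn_rel = ng_ml_to_nM(18, 35),
  kinetics = kin)
pars
#> Extracellular proteasome-OPN circuit parameters
#>   k_in = 4.286e-06 nM/h, k_i = 2.917 1/nM, k_deg = 0.0002 1/h
#>   k_1 = 0.0001 nM/h, gamma = 2.922, x_i = 0.5, x_t = 0.5
#>   OPN clearance (FL/N/C): 0.0005452 / 0.00055 / 0.0005357 1/h; k_deg3 = 0.0002

eq   <- circuit_equilibrium(pars)
sch  <- relapse_schedule(onset_time = 336, t_end = 1680)
traj <- simulate_circuit(pars, eq, sch, seq(0, 1680, by = 24))
ct   <- total_chemotaxis(traj, default_ci_truth()$HUVEC)
win  <- relapse_window(sch)
max(ct$c_tot[ct$time_h >= win[1] & ct$time_h <= win[2]]) / ct$c_tot[1]
#> 1.386
```

The derived `k_i = 2.92 /nM` quantifies how strongly OPN suppresses
proteasome release, `gamma = 2.92` is the relapse fold-increase of OPN
production consistent with the measured relapse levels, and total
HUVEC chemotaxis rises ~39% from the remission baseline to the relapse
peak. `run_pipeline(outdir)` chains all stages (synthetic data →
kinetic inference → parameter ensemble → ensemble simulation →
chemotaxis → severity models) and writes CSV artifacts plus a
checksummed `manifest.json`.

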
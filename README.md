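# pkpdlink

Sequential pharmacokinetic-pharmacodynamic (PK-PD) modelling of antipyretic
drug response with an effect-compartment link, for pharmacologists analysing
single-dose concentration and temperature time courses.

Fever suppression typically lags plasma concentration: the drug peak arrives
in minutes, the effect peak an hour later, producing an anticlockwise
concentration-effect hysteresis loop. The package implements the standard
modelling chain for such data:

* **NCA** — Cmax, Tmax, terminal slope λz (best adjusted-R² window), t½,
  AUC/AUMC by linear-up/log-down trapezoid, MRT, CL/F;
* **Compartmental PK** — closed-form 1- and 2-compartment extravascular
  models with first-order absorption and optional lag time
  (C(τ) = (ka·D/Vc)·[c₁e^(−ατ) + c₂e^(−βτ) + c₃e^(−ka·τ)], τ = t − t_lag),
  weighted least squares over log-parameters with Latin-hypercube
  multistart, model ranking by AIC = n·ln(SSR/n) + 2p;
* **Effect-compartment link** — Ce solving dCe/dt = ke0·(Cp − Ce),
  evaluated analytically, with the Sigmoid Emax (Hill) response
  E = Emax·Ce^γ / (EC50^γ + Ce^γ) fitted jointly in (ke0, Emax, EC50, γ)
  against control-corrected temperature change ΔT;
* **Diagnostics and derived metrics** — shoelace hysteresis area,
  Emax/maximal-fever-increment and EC50/Cmax ratios;
* **A virtual-trial simulator** — forward simulation from known truths with
  proportional/additive noise and log-normal between-subject variability,
  plus parameter-recovery and model-selection experiments.

The mean baicalin and geniposide profiles of a single-dose antipyresis study
in pyrexia-model rats (13 samples over 2.5 h, doses 23.04 and 2.38 mg/kg)
ship as a built-in fixture.

## Worked example

```r
library(pkpdlink)
report <- run_fixture_analysis(seed = 17)
report
```

```
<pkpd_report> seed 17, pkpdlink 0.1.0

== baicalin ==
  NCA: Cmax 56117.2 ng/mL at 0.17 h; AUC0-t 22755.9 h*ng/mL
  PK model (AIC): 2-compartment+lag, AIC -51.37
  PD: Emax 1.02 degC, EC50 7049.07 ng/mL, gamma 4.33, ke0 0.907 1/h
  derived: Emax fraction 74.0%, EC50/Cmax 11.9%
  hysteresis loop area: 2.889e+04 (positive = anticlockwise)

== geniposide ==
  NCA: Cmax 6921.36 ng/mL at 0.1 h; AUC0-t 2600.23 h*ng/mL
  PK model (AIC): 2-compartment+lag, AIC -61.2
  PD: Emax 1.38 degC, EC50 1040.97 ng/mL, gamma 2.39, ke0 0.833 1/h
  derived: Emax fraction 100.0%, EC50/Cmax 14.7%
  hysteresis loop area: 3842 (positive = anticlockwise)
```

Reading the output: both analytes are best described (minimum AIC) by a
two-compartment model with an absorption lag; the positive loop areas
confirm the anticlockwise hysteresis that motivates the effect compartment;
baicalin reaches half its maximal antipyretic effect at an effect-site
concentration of ~7 µg/mL, about 12% of its observed Cmax. The geniposide
Emax sits at the supplied physiological ceiling (the 1.38 °C maximal fever
increment of untreated controls), flagging that its saturation level is not
identified from these 13 mean points alone. The fitted Hill exponent for
baicalin (γ ≈ 4.3) is steeper than originally reported for this dataset
(γ 2.03); the methods vignette analyses why the printed mean profiles force
this and why per-animal data would not.

Individual stages are available directly:

```r
fx <- qkl_fixture()
run_nca(fx$conc_baicalin)                        # model-free summary
fits <- fit_pk_candidates(fx$conc_baicalin)      # all four candidate models
pk <- select_model(fits)                         # minimum-AIC fit
pd <- fit_pd(pk, fx$delta_t, emax_upper = 1.38)  # link + Sigmoid Emax
```

And the simulator:

```r
cfg <- sim_config(seed = 1)                      # study-design defaults
trial <- simulate_trial(cfg)
rec <- recovery_experiment(cfg, n_replicates = 200)
```

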
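# dmpkr

Statistical engine for preclinical DMPK (drug metabolism and
pharmacokinetics) characterization of a small molecule quantified by
LC-MS/MS. It is written for bioanalytical and DMPK scientists who have
summarized assay tables — calibration area ratios, microsomal time
courses, dialysis chamber concentrations, transwell time courses, and
plasma/tissue concentration-time profiles — and need the validated study
statistics computed reproducibly:

* **Quantitation & batch acceptance** — weighted (1/x, 1/x²) calibration
  regression, back-calculation, and the ICH M10 statistics: accuracy
  (% bias), precision (% RSD), recovery, matrix effect, carryover,
  selectivity, and storage stability, each with explicit pass/fail limits.
* **In vitro DMPK** — substrate-depletion half-life, and the IVIVE chain

  CL_int = (0.693/t½)·V/m → CL_H,int = CL_int·(mg/g liver)·(g liver/kg) →
  CL_H = Q·fu,p·(CL_H,int/fu,inc) / (Q + fu,p·(CL_H,int/fu,inc)),

  with fu,inc = 1/(1 + 10^(0.53·logP − 1.42)); equilibrium-dialysis
  binding, blood-to-plasma ratio, kinetic solubility, and PAMPA/Caco-2
  apparent permeability (with the sampling-withdrawal correction).
* **NCA** — Cmax/Tmax, trapezoidal AUC (linear or linear-up/log-down),
  best-fit terminal slope, AUC∞, CL, Vz, t½, bioavailability
  F = 100·(AUC_po/D_po)/(AUC_iv/D_iv), and group summaries.
* **Disposition** — tissue Kp, unbound concentrations, the unbound
  brain-to-plasma ratio Kp,uu = (C_brain·fu,brain)/(C_plasma·fu,plasma),
  and exposure-vs-IC50 flags.
* **Synthetic data** — seeded generators with known ground truth for every
  stage (one-compartment PK with lognormal variability and LLOQ censoring,
  mono-exponential depletion, dialysis, two-chamber diffusion, calibration
  batches), so every estimator is testable round-trip.

See `vignettes/dmpk-methods.Rmd` for the full model descriptions and
design choices.

## Worked example

Predicted hepatic clearance in mouse from microsomal data, the binding
correction, and the well-stirred model:

```r
library(dmpkr)
ivive_chain(clh_int = 41, scaling = species_scaling("mouse"),
            logp = 2.3, fu_plasma = 0.025, q = 90)
#> IVIVE chain (mouse)
#>   t1/2      : NA min
#>   CL_int    : NA mL/min/mg
#>   CL_H,int  : 41 mL/min/kg
#>   fu,inc    : 0.614
#>   CL_H,pred : 1.64 mL/min/kg
```

A scaled hepatic intrinsic clearance of 41 mL/min/kg, corrected for ~39%
microsomal binding at logP 2.3, predicts a whole-liver clearance of 1.6
mL/min/kg (two significant figures) — under 2% of the 90 mL/min/kg mouse
hepatic blood flow, i.e. a low-extraction compound.

Oral bioavailability from group-mean exposures and doses:

```r
bioavailability(6803, 11608, dose_po = 10, dose_iv = 2.5)
#> [1] 14.65153    # ~15%
```

Brain penetration with the reporting-rounding policy and a reference
audit:

```r
brain_penetration(time_h = c(2, 8, 24), brain_content = c(55, 34, 23),
                  plasma_conc = c(1467, 93, 1.6), ic50 = 821,
                  policy = "table", reference_kpuu = c(0.08, 0.82, 33.3))
#>   time_h brain_content unbound_brain plasma_conc unbound_plasma  kpuu
#> 1      2            55           3.1      1467.0          37.00  0.08
#> 2      8            34           1.9        93.0           2.30  0.83
#> 3     24            23           1.3         1.6           0.04 32.50
#>   unbound_brain_vs_ic50 kpuu_reference kpuu_discrepant
#> 1           0.003775883           0.08           FALSE
#> 2           0.002314251           0.82            TRUE
#> 3           0.001583435          33.30            TRUE
```

Unbound brain content at 2 h is 3.1 ng/g against an unbound plasma
concentration of 37 ng/mL (Kp,uu = 0.08: poor brain penetration, and far
below the 821 ng/mL potency reference). Reference ratios that cannot be
derived from their own row's contents are flagged discrepant rather than
matched.

Simulated oral study and per-subject NCA:

```r
profiles <- sim_plasma_profiles(n_subjects = 4, route = "PO", seed = 1)
nca(profiles[[1]])
#> NCA (PO, 10 mg/kg) subject S001
#>   Cmax 1235 ng/mL at Tmax 0.5 h
#>   AUC_last 9434.4, AUC_inf 9701.9 ng.h/mL (2.8% extrapolated)
#>   lambda_z 0.1467 1/h (n=3, adj r2 1.0000), t1/2 4.72 h
#>   CL/F 1.031 L/h/kg, Vz/F 7.025 L/kg
summarize_nca(lapply(profiles, nca))   # group mean ± SD per parameter
```

The whole workflow can also be driven from CSV files through
`run_config()` + `run_pipeline()` (schema-validated inputs, JSON + text
report with a provenance log), or from a shell via the thin wrapper in
`inst/scripts/dmpk.R`.

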
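---
title: "Methods: validation statistics, IVIVE, NCA and brain penetration in dmpkr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validation statistics, IVIVE, NCA and brain penetration in dmpkr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmpkr)
```

dmpkr is the computational layer of a preclinical DMPK characterization
built on LC-MS/MS quantitation: it takes summarized assay tables
(area ratios, chamber concentrations, concentration-time profiles) and
produces the statistics a study report contains. This vignette explains the
models behind each stage, the parameters that matter, the numerical
choices, and what the synthetic-data generators do and do not emulate.

## Calibration and batch acceptance

The quantitation model is a straight line of analyte-to-internal-standard
area ratio against nominal concentration, fitted by weighted least squares.
LC-MS/MS responses are heteroscedastic — the standard deviation grows
roughly in proportion to concentration — so the default weighting is
$w_i = 1/x_i^2$, which makes the *relative* residuals homoscedastic and
protects the low end of a wide range (here 0.2-500 ng/mL, three orders of
magnitude). `fit_calibration()` delegates the solve to `stats::lm()` with
weights; the test suite checks it against an independent normal-equations
solve to $10^{-10}$ relative error. The reported $r^2$ is the weighted
coefficient of determination about the weighted mean, the standard summary
for weighted bioanalytical fits. Blanks and zeros are excluded: a zero
nominal has infinite weight under $1/x^2$ and is not a valid standard.

Back-calculation inverts the line and flags, but never clamps, values
outside the calibrated range. The batch-acceptance statistics follow the
ICH M10 conventions:

* accuracy: $\mathrm{bias\,\%} = 100(\bar{x} - x_{nom})/x_{nom}$, limits
  ±20% at the LLOQ and ±15% elsewhere;
* precision: $\mathrm{RSD\,\%} = 100\,s/\bar{x}$ with the sample ($n-1$)
  standard deviation — the small-$n$ convention for triplicate QCs;
* carryover and selectivity: blank responses at most 20% of the analyte
  LLOQ response and 5% of the IS response;
* recovery, matrix effect and storage stability as mean-ratio statistics
  with the 85-115% stability window.

Inter-day statistics pool every replicate across runs rather than averaging
daily means; this matches batch-acceptance practice, weights each
measurement equally, and makes the inter-day RSD a genuine pooled
dispersion. Every pass/fail flag is a pure function of the stored statistic
and the threshold set, so a report can be re-audited without the raw data.

## Microsomal stability and IVIVE

Substrate depletion is modeled as first order:
$\ln r(t) = \ln r(0) - k t$, fitted by ordinary least squares on the log
scale; $t_{1/2} = 0.693/k$. A non-positive slope is reported as
"metabolically stable" with $t_{1/2} = \infty$, not as an error — flat
courses are an expected outcome for slowly cleared compounds. The chain to
an in vivo prediction is:

$$CL_{int} = \frac{0.693}{t_{1/2}} \cdot \frac{V_{inc}}{m_{protein}}, \qquad
CL_{H,int} = CL_{int} \cdot \frac{\mathrm{mg\ protein}}{\mathrm{g\ liver}}
\cdot \frac{\mathrm{g\ liver}}{\mathrm{kg\ bw}}$$

with mouse scaling factors 45 mg/g and 60 g/kg (human: 32 and 25). The
incubation protein mass is concentration × volume (0.5 mg/mL × 0.5 mL =
0.25 mg by default); depletion of the incubation volume by sampling
withdrawals is ignored, consistent with the fixed-volume form of the
equation. Nonspecific microsomal binding is estimated from lipophilicity,

$$f_{u,inc} = \frac{1}{1 + 10^{0.53\,\mathrm{logP} - 1.42}},$$

a strictly decreasing map of logP onto (0, 1), and the well-stirred
(venous-equilibrium) liver model gives

$$CL_{H} = \frac{Q \cdot f_{u,p}\,(CL_{H,int}/f_{u,inc})}
{Q + f_{u,p}\,(CL_{H,int}/f_{u,inc})},$$

bounded above by hepatic blood flow ($Q = 90$ mL/min/kg in mouse) and
reducing to $f_{u,p}\,CL_{H,int}/f_{u,inc}$ in the extraction-limited
regime. `ivive_chain()` runs the whole sequence from any entry point
(half-life, CL~int~, or CL~H,int~). A human whole-body prediction is only
produced when the caller supplies human $Q$ and $f_{u,p}$ explicitly — the
package does not default them.

```{r ivive}
ivive_chain(clh_int = 41, scaling = species_scaling("mouse"),
            logp = 2.3, fu_plasma = 0.025, q = 90)
```

Note that printed study tables carry replicate means at each link of the
chain, so re-deriving a printed CL~H,int~ from a printed half-life will
agree only within rounding of those means.

## Binding, partitioning, solubility, permeability

Equilibrium dialysis: at equilibrium the buffer side holds only unbound
drug, so % bound $= 100(C_{donor} - C_{receiver})/C_{donor}$ and
$f_u = C_{receiver}/C_{donor}$. Blood partitioning is the plain ratio
$R_{b/p} = C_{blood}/C_{plasma}$.

Kinetic solubility has no universally fixed calculation rule; dmpkr uses a
plateau estimator: a spiking level is saturated when the measured
concentration falls below 0.8 × nominal (configurable), and the solubility
is the mean measured concentration over saturated levels. When nothing
saturates, the highest measured value is returned with a flag meaning "at
least this soluble".

PAMPA uses the two-chamber mass-balance solution at a single read-out:
$$P_{app} = \frac{-\ln(1 - C_a(t)/C_{eq})}{A\,(1/V_d + 1/V_a)\,t}, \qquad
C_{eq} = \frac{C_d(t)V_d + C_a(t)V_a}{V_d + V_a}$$
with default geometry $V_d = 0.3$ mL, $V_a = 0.2$ mL, $A = 0.3$ cm²,
$t = 18000$ s. $C_a(t) \ge C_{eq}$ is a saturated assay and an error, since
the log argument leaves its domain. Because only concentration *ratios*
enter, both permeability estimators are invariant to the concentration
unit.

Caco-2 permeability is flux-based: $P_{app} = (dQ/dt)/(A\,C_0)$, where
$dQ/dt$ is the least-squares slope of cumulative transported amount against
time. Each sampling removes 0.1 mL from the 1.5 mL receiver and replaces it
with blank buffer, so the cumulative amount must add back what earlier
withdrawals removed:
$Q(t_n) = C_n V_{receiver} + \sum_{i<n} C_i V_{withdrawn}$. Skipping this
correction biases $P_{app}$ low — the test suite demonstrates both the
corrected round-trip (within 2%) and the strict downward bias of the
uncorrected estimate. The slope is fitted over all sampled points (0-120
min) by default, with an optional window for a user-chosen linear phase.
Inserts with TEER below 400 Ω·cm² get an integrity warning, mirroring the
laboratory rejection rule.

## Non-compartmental analysis

`nca()` computes Cmax/Tmax (ties to the earliest time), AUC by trapezoid,
the terminal slope, and the derived parameters
$AUC_\infty = AUC_{last} + C_{last}/\lambda_z$, $CL = \mathrm{dose}/AUC_\infty$,
$V_z = CL/\lambda_z$ (reported as CL/F and Vz/F after oral dosing), with
the unit convention dose [mg/kg] × 10³ / AUC [ng·h/mL] → CL [L/h/kg].

Numerical choices:

* **Integration rule.** The default is the linear trapezoid: deterministic,
  exact on piecewise-linear data, and additive over intervals. The
  linear-up/log-down rule is available by flag and is exact on
  mono-exponential decline; on sparse late sampling (4 → 8 → 24 h) the
  linear rule overestimates the AUC of an exponential tail noticeably
  (about 13% on the default synthetic profiles), which is why recovery
  tests against mono-exponential truth use the log-down rule. The rule used
  is recorded in the result.
* **Terminal slope.** No selection algorithm is universal; dmpkr uses the
  widespread best-fit search: all candidate windows of ≥ 3 consecutive
  points ending at the last quantifiable sample and excluding Cmax,
  maximizing adjusted $r^2$, ties to fewer points. Non-positive slopes are
  reported as "no terminal phase", not an error.
* **BLQ handling.** Below-LLOQ values before Tmax are set to 0 (absorption
  has not started); embedded and trailing BLQ samples are excluded.
* **AUC basis.** CL, Vz and F use the extrapolated $AUC_\infty$, the
  dose/AUC convention; the extrapolated percentage is reported so profiles
  with weak terminal characterization are visible.

Bioavailability is the dose-normalized exposure ratio
$F = 100\,(AUC_{po}/D_{po})/(AUC_{iv}/D_{iv})$; apparent oral parameters
can be converted to absolute ones by multiplying by $F$. Group summaries
are computed per subject first, then mean ± sample SD.

```{r nca-example}
bioavailability(6803, 11608, dose_po = 10, dose_iv = 2.5)
```

## Tissue and brain disposition

Tissue-to-plasma ratios treat ng/g and ng/mL as commensurate (tissue
density ≈ 1 g/mL), and tissue contents are assumed already corrected for
homogenization dilution. Unbound values scale totals by the matrix-specific
fraction unbound (defaults $f_{u,plasma} = 0.025$, $f_{u,brain} = 0.057$,
taken from the equilibrium-dialysis stage), and

$$K_{p,uu,brain} = \frac{C_{brain}\,f_{u,brain}}{C_{plasma}\,f_{u,plasma}}.$$

Full precision is the computational default. A reporting-rounding policy
(`policy = "table"`) reproduces how compact disposition tables print cells
— two significant figures below 10, integers at ≥ 10, ratios to two
decimals, with the ratio formed from the rounded cells — purely so printed
tables can be audited. When reference ratio values are supplied,
`brain_penetration()` compares its computed $K_{p,uu}$ to each reference at
the reference's own printed precision and flags disagreement: a reported
cell that cannot be derived from its own row (as happens for some
late-time-point ratios, where 23 × 0.057 / (1.6 × 0.025) = 32.8 against a
reported 33.3) is surfaced as a discrepancy, never silently matched.

## Synthetic data: what it emulates, and what it does not

Every generator embeds its ground truth in an attribute so tests can close
the loop estimator-against-truth:

* one-compartment IV-bolus and first-order-absorption oral profiles with
  lognormal inter-subject variability, proportional residual error and
  LLOQ censoring at 0.2 ng/mL;
* mono-exponential microsomal depletion on the 0-60 min schedule, with
  flat NADPH-free controls;
* equilibrium dialysis at a stated fraction unbound;
* exact two-chamber diffusion for PAMPA and sink-condition linear flux with
  withdrawal bookkeeping for Caco-2;
* calibration/QC batches around a known line with proportional noise and
  optional injected QC bias.

Default conditions are the emulated study's: doses 2.5 (IV) and 10 (PO)
mg/kg, CL 0.23 L/h/kg, V 1.2 L/kg, F 0.15, the 5/15/30 min + 1/2/4/8/24 h
schedule, nine calibration levels 0.2-500 ng/mL and QCs at 0.2/0.5/100/375
ng/mL. Where the emulated study reports no variability structure, defaults
were chosen once on field conventions: ka = 8 h⁻¹ so the noiseless oral
Tmax falls near 0.5 h; inter-subject CVs of 30/25/30% on CL/V/ka with 10%
residual CV, giving Cmax dispersion comparable to reported group SDs.
Lognormal draws are centered so the *arithmetic mean* across subjects
equals the typical value, because group results are reported and checked
as mean ± SD; with median-centered draws the group mean would sit
$e^{\sigma^2/2}$ above the nominal parameter by construction.

What the generators do **not** emulate: chromatographic peak shapes and
integration, matrix interferences, enterohepatic recirculation or any
multi-compartment disposition, nonlinear (saturable) kinetics, and
active-transport asymmetries in the permeability assays. Passing
round-trip tests therefore demonstrates that the estimators are correct
for their stated models — not that those models capture every feature of
real study data.

Test and acceptance problem sizes (100 subjects for the stochastic group
check, 200 Monte-Carlo replicates for the noisy-decay bias check, dense
60-point grids for closed-form recovery) were chosen as the smallest
designs whose sampling error is comfortably below the tolerances being
asserted. One statistical point found while building the suite: a single
7-point depletion course at 5% proportional noise carries ~20% sampling
error on $k$ when depletion over the sampled hour is only ~25%, so
single-realization recovery claims tighter than that are not meaningful;
the suite asserts the Monte-Carlo mean instead.

## Pipeline and provenance

`run_pipeline()` ties the stages together over schema-validated CSV
inputs, tolerates missing stages (a section is produced per input
present), and is deterministic given inputs + configuration: re-running
writes byte-identical JSON. Each section records the operations and
parameters that produced it in a provenance log, so every reported number
is traceable to one call. Units are fixed at the interfaces (ng/mL, h,
mg/kg, mL/min/kg) with one conversion helper for molar ↔ mass
concentration.

## Known limitations

* Single-analyte, single-dose designs; no crossover or repeated-dose
  accumulation.
* The terminal-slope search is best-fit by adjusted $r^2$; on very noisy
  tails it can select short windows, as any best-fit rule can. The window
  and $r^2$ are reported so such fits can be screened.
* The kinetic-solubility plateau rule is a pragmatic convention; results
  near the saturation threshold are sensitive to it.
* Sparse-schedule linear-trapezoid AUC carries the discretization bias
  discussed above; choose the integration rule to match the intent.
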
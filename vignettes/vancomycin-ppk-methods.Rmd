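---
title: "Methods: population pharmacokinetics of vancomycin in neurosurgical patients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population pharmacokinetics of vancomycin in neurosurgical patients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Postoperative neurosurgical patients receive intravenous vancomycin
empirically, and their pharmacokinetics are atypical: augmented renal
clearance is common, mannitol (given to control intracranial pressure)
increases drug elimination, and therapeutic drug monitoring yields mostly
steady-state trough samples. Conventional dosing under-exposes many of
these patients. `vancoppk` implements the full modelling workflow for this
population: a one-compartment population model with covariate-dependent
clearance, FOCE-type mixed-effects estimation, stepwise covariate
selection, bootstrap and visual-predictive-check evaluation, and Monte
Carlo dose finding against steady-state AUC24 targets of 400-600 h·mg/L.

## Structural and statistical model

Kinetics are one-compartment with zero-order (infusion) input and
first-order elimination. For doses $d$ with rate $R_d$, start $t_d$ and
duration $T_d$, the concentration is the superposition

$$C(t) = \sum_d \frac{R_d}{CL}\left(1 - e^{-k\,\min(t - t_d,\,T_d)}\right)
         e^{-k\,(t - t_d - \min(t - t_d,\,T_d))_+}, \qquad k = CL/V .$$

The volume of distribution is fixed at $V = 60.2$ L: trough-dominated
sampling carries almost no information about $V$, so it is adopted from a
comparable Chinese neurosurgical population and never estimated.

Clearance carries all the structure. For subject $i$,

$$CL_i = \theta_{TV} \prod_c \left(\frac{x_{ci}}{m_c}\right)^{\beta_c}
         \exp\Big(\sum_k \beta_k z_{ki}\Big)\, e^{\eta_i},
  \qquad \eta_i \sim N(0, \omega^2),$$

with continuous covariates $x_c$ as centered power terms and categorical
flags $z_k$ as exponential shifts. The published final model is

$$CL\ (\mathrm{L/h}) = 7.98 \times (eGFR/115.2)^{0.8} \times (BW/70)^{0.3}
  \times e^{A},$$

where $A = 0.13$ under mannitol co-medication ($e^{0.13}$: a 14% increase)
and 0 otherwise; `theta_final()` returns it. Residual error is combined:
$SD(C_{pred}) = \sqrt{\sigma_2^2 + (\sigma_1 C_{pred})^2}$, so the
additive SD ($\sigma_2$, mg/L) dominates near zero and the proportional CV
($\sigma_1$) at high concentrations.

Renal function enters through two standard equations. Cockcroft-Gault
creatinine clearance, $(140-\mathrm{age}) \cdot BW / (72\,S_{cr})$ times
0.85 for females, is reported in mL/min without body-surface
normalisation and without capping (values up to ~900 mL/min occur in
augmented renal clearance; values above 300 are flagged with a message).
CKD-EPI eGFR is $144 (S_{cr}/a)^b\, 0.993^{\mathrm{age}}$ with the
sex-specific piecewise constants; the two creatinine branches join
continuously at $S_{cr} = a$. Serum creatinine is canonically mg/dL
internally; µmol/L inputs are divided by 88.4 at the I/O boundary.

Two conventions worth stating: inter-individual variability is reported
as CV% $= 100\,\omega$ (the SD of the log-normal random effect), and the
standard errors of $\sigma_1, \sigma_2$ are reported on the SD scale.

## Estimation

The marginal likelihood integrates the single random effect per subject.
`neg2ll()` approximates it FOCE-style: a Brent search (tolerance $10^{-8}$)
locates the conditional mode $\hat\eta_i$ on $[-6\omega, 6\omega]$, and a
Laplace-type expansion with the residual variance evaluated at individual
predictions (the "interaction" form) gives each subject's contribution.
Every additive $\log 2\pi$ is dropped — the usual objective-function-value
(OFV) convention, since only differences between nested models are
interpreted. The degenerate $\omega = 0$ case reduces continuously to the
fixed-effects weighted deviance. The likelihood core is compiled (Rcpp);
the exported `concentration()` is the reference R implementation, and the
test suite checks both against a numerical ODE oracle.

The one-point Laplace approximation carries an intrinsic error relative
to exact quadrature — about 0.03 OFV units per subject at the final
model's noise level on sparse trough data, shrinking with per-subject
information and with $\omega$. The test suite therefore cross-checks the
objective against a 10,000-point Gauss-Hermite rule on a fixture with
dense, low-noise sampling, where that approximation error is negligible
and any disagreement would indicate an implementation defect; a separate
test asserts the error shrinks monotonically as $\omega \to 0$.
`gauss_hermite()` builds arbitrarily large rules by Sturm-sequence
bisection on the Jacobi matrix (dense eigendecompositions are infeasible
at that size).

`fit_ppk()` minimises the OFV over log-transformed positivity-constrained
parameters (typical clearance, $\omega$, both $\sigma$ components) and
unconstrained covariate coefficients: Nelder-Mead (relative tolerance
$10^{-7}$, one restart) followed by a BFGS polish — the restart and polish
matter, as a collapsed simplex can stall short of the optimum in one
coordinate. Initial values come from a log-linear regression of naive
clearance (dose rate over mean observed concentration) on the model
covariates; $\omega$ starts at 30% CV, $\sigma$ at (0.2, 2 mg/L).
Standard errors use a central finite-difference Hessian of the OFV
(observed information is half of it); when a variance component collapses
toward its boundary the Hessian turns numerically singular, and SEs are
then taken from an eigen pseudoinverse that drops non-positive-curvature
directions, reporting NA for parameters loading on them. Confidence
intervals are Wald ($\pm 1.96\,SE$); shrinkages are
$1 - SD(\hat\eta)/\hat\omega$ and $1 - SD(\mathrm{IWRES})$. Observations
flagged outside the assay range are excluded from the likelihood (no
censored-likelihood/M3 treatment, matching the source analysis).
`cwres()` provides FOCE-linearised conditional weighted residuals, PRED
and IPRED for goodness-of-fit.

## Covariate selection

`run_stepwise()` reproduces the forward-addition / backward-elimination
procedure: greedy single-covariate forward steps accepted when the OFV
drops by more than 6.64 ($p < 0.01$, 1 df), then one-at-a-time backward
elimination removing any covariate whose deletion raises the OFV by at
most 10.83 ($p < 0.001$, 1 df). Candidates are age, height, body weight,
BMI, serum creatinine, CLcr and eGFR (centered power form; centering at
the dataset median for de-novo builds, or at fixed constants to match the
published model exactly) and female sex, RRT, mannitol, meropenem and
diuretics (exponential-shift form). The three renal-function measures are
mutually exclusive proxies by default — they carry the same signal and are
compared, not combined. Ties break by candidate order; non-convergent
candidate fits are skipped with a warning. Search fits are warm-started
from the incumbent model with slightly relaxed optimizer settings; the
final model is refitted at full settings with standard errors.

## Model evaluation

`bootstrap_ppk()` resamples whole subjects with replacement to the
original count and refits each replicate (warm-started from the reference
fit — a pragmatic choice, not part of the published procedure),
summarising converged replicates by median, 2.5-97.5 percentile interval
and across-replicate RSE; below 80% convergence the result is flagged
unstable. The full-analysis default is 5000 replicates; tests use 200 and
record the count in the result.

`vpc_ppk()` simulates replicates of the data set's exact design (same
subjects, doses, times, covariates — including the assay-range resampling
of the observation model) with fresh $\eta$ and $\varepsilon$. Coverage is
pooled and per-observation: each observation is compared with the 5th-95th
percentile of its own simulated values, so under the true model coverage
converges to 0.90. For plotting, observations are binned by quantiles of
time after the last dose (8 bins by default — the binning strategy is this
package's choice; empty bins merge), with 5th/50th/95th simulated bands
and observed percentiles per bin. The full-analysis default is 10,000
replicates; tests use 500.

## Dose finding

`simulate_auc24()` draws $\eta \sim N(0, \omega^2)$ and evaluates the
exact identity $AUC_{24} = \text{daily dose}/CL_i$ — under linear
kinetics AUC depends on clearance only, so residual (assay) error is
deliberately not added, and the simulated median obeys the log-normal
closed form $\text{daily dose}/CL_{typ}$ within Monte Carlo error.
`recommend_dose()` searches a 5-mg dose grid (the granularity evident in
the published dose tables) for the median closest to the target, ties to
the smaller dose; because AUC is linear in dose, one set of draws prices
the whole grid. Defaults: 12-h interval, 1-h infusion, 1000 replicates.
Recommendations above 2000 mg per administration carry an advisory flag
that a low-dose intraventricular regimen (10-20 mg q24h) should be
considered rather than escalating the intravenous dose.
`build_dose_table()` evaluates the eGFR {90, 45, 15} × BW {85, 65} ×
mannitol × target {400, 600} grid.

## The synthetic cohort

No public dataset exists, so `generate_cohort()` emulates the study
population (n = 560 Chinese adults, 895 samples) from its printed
summary: age 52.41 ± 15.11 (18-89) y, weight 69.74 ± 13.05 (37.5-130) kg,
height 167.88 ± 7.98 (145-192) cm as truncated normals, P(male) =
370/560, mannitol 60.32%, meropenem 71.32%, diuretics 15.95%, RRT 2.72%.
BMI is computed, not sampled. Creatinine is induced rather than drawn: a
target eGFR (normal, mean 115.56, SD 26.24 for non-RRT subjects —
calibrated so the RRT mixture reproduces the printed 112.74 ± 30.91 —
plus a low RRT tail around 12 mL/min) is inverted through CKD-EPI given
age and sex. This couples creatinine to age and sex and yields the
right-skewed creatinine marginal; all other covariates are sampled
independently, a documented simplification.

Dosing uses the seven regimens in clinical use (0.5/1 g per dose, 6-24 h
intervals, 1-h infusions) assigned by eGFR band so the daily-dose /
renal-function confounding of titrated practice is present. Within the
high-eGFR bands most patients receive 1 g q8h rather than q12h: augmented
renal clearance patients need shortened intervals, and the banding was
set so that simulated concentrations respect the study's observed range
(0.91-52.96 mg/L — none of its 895 samples fell below quantification;
q12h dosing at high eGFR would put several percent of simulated troughs
under the 0.67 mg/L assay floor). Observations per subject follow
$1 + \mathrm{Geom}(0.625)$ (mean ≈ 1.6 = 895/560, capped at 6); 92% are
steady-state troughs drawn immediately before a dose after at least five
administrations (the exact trough fraction is a config knob — the study
states only that troughs dominate), the rest random samples 2-10 h after
an infusion. `simulate_observations()` adds the combined residual error,
redraws values outside the 0.67-90 mg/L assay range up to 10 times and
censor-flags the remainder, and attaches the true per-subject random
effects for recovery tests.

Two honest caveats about what the generator can and cannot show. First,
the study's printed mean concentration (14.20 ± 7.36 mg/L) is not
reproducible from its own final model under trough sampling — with
CL ≈ 8 L/h and V = 60.2 L the model's steady-state troughs sit around
3-7 mg/L — so the generator is faithful to the model, not to that
marginal. Second, the resample-into-range rule truncates the lower tail
of low-concentration observations without a matching likelihood
correction; in fits on generator data this attenuates the additive error
component (sometimes to near zero, where its SE is then reported NA) and
mildly shrinks $\omega$. Fixed effects are recovered well regardless, and
the source analysis itself reports the additive component as its least
precise parameter. Passing tests demonstrate internal consistency of the
whole pipeline under this generator, not fidelity to the unreleased
hospital data.

## Scale of the shipped checks

The test suite exercises the pipeline at sizes chosen to keep a desk run
comfortable while preserving the properties being checked: parameter
recovery and visual-predictive-check calibration at the study's own
n = 560 (10 seeds and 500 simulation replicates respectively), stepwise
selection consistency at n = 560 for the final-model arm — at n ≈ 300 the
mannitol and body-weight steps hover near the 6.64 threshold and the
exact-set property genuinely fails — with the null (no-covariate) arm at
n = 300, and the bootstrap at n = 300 subjects × 200 replicates. The
dose-table checks use the published 1000 replicates per regimen.

## Known limitations

One compartment only (distribution-phase kinetics are out of scope, as
are CSF concentrations); $V$ fixed; a single random effect (no
inter-occasion variability, no $\eta$ on $V$); no censored-data
likelihood; no time-varying covariates within a subject; dose finding
assumes the 12-h interval convention of the published tables. External
validation against independent data is not performed. The dose
recommendations reproduce a published simulation exercise and are not
clinical advice.
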
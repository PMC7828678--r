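---
title: "Models and methods in immunopk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in immunopk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunopk)
```

This vignette is the package's own account of the models it implements, the
choices that were genuinely open, and what the synthetic-data tests do and do
not demonstrate.

## The scientific setting

A bivalent scFv-Fc fusion antibody is conjugated with a variable number of
DOTA chelators and labelled with ^177^Lu. Three measurements characterise each
conjugate: the drug-to-antibody ratio (DAR) from intact mass spectrometry, the
immunoreactive fraction (IR) from a cell-binding assay, and an organ
biodistribution time course in tumor-bearing mice, expressed as percent
injected activity per gram (%IA/g) and decay-corrected to injection time. The
package ties these together: DAR and IR become covariates of a compartmental
model fitted to all conjugates at once, and the fitted (or measured) activity
curves feed an organ-level dosimetry calculation.

## DAR estimation

A deconvoluted spectrum is a list of (mass, intensity) peaks. Each peak's
adduct count is the mass excess over the unmodified antibody divided by the
per-chelator mass increment, rounded to the nearest integer with ties away
from zero; masses more than half an increment below the base mass are
rejected as physically impossible. The DAR is the intensity-weighted mean
count, which makes it a convex combination of the per-peak counts and
invariant under uniform intensity rescaling — two properties the test suite
checks on randomly generated peak lists. Defaults of 108,394 Da (antibody)
and 551 Da (p-SCN-Bn-DOTA) correspond to this construct but are plain
arguments.

## Immunoreactive fraction

The assay incubates a fixed trace concentration of labelled antibody
(0.659 pmol/mL by default) with increasing cell numbers and records the bound
fraction; a 100-fold antibody excess gives a nonspecific (blocked) control
that is subtracted pointwise, clipping at zero with a warning. The binding
model is the one-site trace-ligand hyperbola

$$B(c) = \frac{\mathrm{IR}\, c}{c + K},$$

fitted by Levenberg–Marquardt least squares. The assay literature describes
the estimator only as nonlinear extrapolation to infinite cell number; we fix
this functional form because it is the standard one-site model under trace
ligand, and we keep the classic double-inverse linearisation (total/bound
against 1/c, intercept 1/IR) as an independent cross-check that must agree on
noiseless data. Bounds IR ∈ [0, 1] and K > 0 are enforced by a logit/log
reparameterisation rather than clipping, so the optimiser works on an
unconstrained scale; standard errors are mapped back by the delta method. An
estimate pinned against a bound raises a boundary warning — with perfectly
immunoreactive noiseless data this is the expected outcome, not a failure.
We report the standard error of the fit and deliberately do not reinterpret
published SEM-labelled spreads as fit errors.

## The compartment model

The biodistribution model is deliberately the simplest structure the data can
support: a central blood compartment B, one first-order peripheral
compartment per counted organ (tumor, liver, spleen, kidneys, lungs, uterus,
bone) plus a remainder for all uncounted tissue, and an irreversible
excretion sink fed from blood:

$$\frac{dB}{dt} = -\Big(\sum_o k_{up,o} + k_{ex}\Big) B + \sum_o k_{ret,o} O_o,
\qquad \frac{dO_o}{dt} = k_{up,o} B - k_{ret,o} O_o.$$

Amounts are carried in %IA, so blood + organs + excreted equals the injected
100 %IA at all times; the tests enforce conservation to one part in 10^6.
What the gamma counter sees is not the pure tissue compartment: each dissected
organ carries residual blood, so the measured concentration is

$$c_o(t) = \frac{O_o(t) + f_{b,o} B(t)}{m_o},$$

with a per-organ blood-content fraction $f_{b,o} \in [0, 1)$ whose sum is
constrained to at most 1. This "content plus a blood share" measurement model
is equivalent to giving each tissue a fast and a slow distribution space when
sampling is too sparse to resolve the fast phase. Physical decay never enters
the kinetic model — inputs are decay-corrected — and appears only in
dosimetry.

Because the system is linear with constant coefficients, its exact solution
is a matrix exponential. We integrate numerically with `deSolve::lsoda`
(rtol 10⁻¹⁰, atol 10⁻¹²) for uniformity with the rest of the fitting code,
and use the closed form, computed independently with `Matrix::expm` in the
test helpers, as the correctness oracle at an agreement threshold of
10⁻⁸ %IA. Any stiff-capable integrator would do; correctness is defined by
the oracle, not the integrator.

## Fitting

`fit_single()` minimises the weighted residual sum of squares between
observed and predicted %IA/g over all organs (and blood) by
Levenberg–Marquardt (`minpack.lm::nls.lm`). Rates are fitted on the log scale
and blood fractions on the logit scale, which enforces positivity and bounds
structurally. Weights default to 1/SD² computed within (organ, time) groups
across animals, falling back to uniform when replicates or spread are
missing; the weighting scheme is a flag because the source analyses state
weighted least squares without stating weights. Asymptotic standard errors
come from the Jacobian at the optimum; 95% intervals are formed on the
transformed scale and mapped back, and a scaled-down simulation in the test
suite (two organs, three free rates, 5% CV, three animals, 100 replicates)
checks that pooled empirical coverage stays at or above 90%.

Configurations with more free parameters than observations, or free return
rates with a single time point, are refused as under-identified rather than
silently regularised. Per-organ return rates may be fixed at zero — washout
can genuinely be absent at low conjugation.

## The covariate laws and the global fit

Across conjugates the rates are tied to the two conjugate-level covariates:

- liver: $k_{up} = \alpha \cdot \mathrm{DAR}$ — strictly proportional, zero
  intercept, so fitted liver uptake ratios across conjugates equal DAR ratios
  exactly by construction;
- tumor and uterus (antigen-driven): $k_{up} = a + b\,\mathrm{IR}$;
- spleen and bone (reticuloendothelial handling of non-immunoreactive
  antibody): $k_{up} = a + b\,(1 - \mathrm{IR})$.

Linear laws are first-order approximations; parameterising spleen/bone in
(1 − IR) keeps all slopes nonnegative so the laws cannot produce negative
rates over IR ∈ [0, 1]. All remaining parameters — other uptake rates, all
return rates, excretion, blood fractions, masses — are shared across
conjugates, including the measurement-model blood fractions (the sparser
24-h-only arms could not support per-conjugate values). `fit_global()`
concatenates every conjugate's weighted residual block into one objective and
fits a single parameter set; all counted organs of the 24-h-only arms
contribute. The affine tumor/uterus laws are only identifiable with at least
two distinct IR values among the arms; the fitter checks this rank condition
and fixes the intercepts at zero, with a note in the result, when it fails.

One conjugate (DAR 2.5) was never assayed for immunoreactivity. Downstream
code refuses a missing IR rather than guessing; the shipped default design
imputes it by linear interpolation in DAR between its measured neighbours
(an explicit, overridable policy).

## Dosimetry

Normalized time-activity curves (nA, fraction of injected activity) are
integrated to time-integrated activity coefficients (TIACs, MBq·h/MBq) by
one of two routes:

- **Bi-exponential + analytic integration** for monotonically clearing
  organs: $A_1 e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t}$ fitted with positive
  amplitudes and decay constants (log parameterisation, two starting points,
  best-of retained), TIAC $= A_1/\lambda_1 + A_2/\lambda_2$. A constrained
  fit with R² below 0.9 raises a non-monotone flag, signalling that the organ
  (stomach-, uterus- or tumor-like uptake-then-washout kinetics) should use
  the trapezoid route instead. With `monotone = FALSE` amplitude signs are
  free, which accommodates rising-falling shapes.
- **Trapezoid + physical tail** otherwise: trapezoidal integration from t = 0
  to the last measurement, then a mono-exponential tail at the physical decay
  constant, value(t_last)/λ_phys. Decay bookkeeping is explicit: curves
  flagged decay-corrected are multiplied by $e^{-\lambda_{phys} t}$ before
  any integration. When no t = 0 sample exists, the starting value follows a
  stated policy — linear back-extrapolation of the first two points floored
  at zero (default, appropriate for blood-borne organs), zero, or
  carry-back — because the source analyses do not state theirs.

Uncertainty follows the mean ± SD curve convention: the TIAC is evaluated at
the mean, mean + SD and mean − SD curves and the half-range reported.

Absorbed doses per unit injected activity use the local-deposition model:
every electron (β + conversion + Auger) is absorbed in the emitting organ,
photons are neglected, so D = TIAC · 3.6×10⁹ · Δₑ/m. For ¹⁷⁷Lu the defaults
are T½ = 159.53 h, Δₑ = 147.9 keV and Δ_γ = 28.7 keV (ICRP-107 nuclear
data), held in a config object rather than hard-coded. This model brackets
phantom-based results in opposite directions: for a large organ it is a lower
bound on the full self-dose (photons omitted), while for sub-gram isolated
spheres it is an upper bound on a sphere-model dose (true absorbed fraction
below 1) — both directions are asserted against published murine dose rows in
the acceptance tests. Phantom S values are proprietary to their software and
are not reproduced; `absorbed_dose()` accepts a user S matrix
(target × source) instead, and an absorbed-fraction curve can be layered on
by the user for validation studies.

## The synthetic study generator

The generator emulates the study design: six conjugates with DAR 1, 2.5, 3,
6, 8.5 and 11 and immunoreactive fractions 85.1, (86.0 imputed), 86.2, 87.5,
78 and 24%; full time courses at 4, 24, 48, 72 and 144 h for the DAR-1 and
DAR-3 arms and a single 24 h point for the rest; three mice per point.
Measurement noise is a zero-truncated normal per organ at a configured CV —
blood 6% and tumor 8% (the relative spreads of the published 24-h means) and
15% for organs whose spreads are only published graphically. Truncation at
zero is the physically sensible choice for activity concentrations; at these
CVs its bias is negligible.

Two modes exist. **Summary mode** samples directly around a 24-h calibration
table anchored at the published endpoint means (blood 10.2 ± 0.6 %IA/g at
DAR 1 to 2.2 ± 0.7 at DAR 11; tumor 18.8 ± 1.5 up to DAR 3 to 5.3 ± 1.6 at
DAR 11; tumor/liver ratio 2 to 0.15), with intermediate conjugates
interpolated — interpolated entries are layout, not data. **Model mode**
solves the compartment model under a shipped calibration truth
(`default_truth()`). That truth was fixed once by matching the model's 24-h
endpoints to the same anchors and rounding; it is a calibration, not a set of
fitted estimates. It reproduces the blood and tumor anchors closely and the
liver trend qualitatively; the strict DAR-proportionality of liver uptake
means the highest-DAR liver endpoint is matched only approximately, which is
a property of the model family, not a tuning failure.

What passing tests on these data do show: the estimators recover the
generating truth (exactly without noise, within stated tolerances with
noise), the solver agrees with the closed form, and the qualitative
DAR trade-off (liver up, tumor down, monotone tumor/liver ratio) follows
from the covariate laws. What they cannot show: that the model family is the
right description of real mice — real data carry inter-animal kinetic
variability (not just measurement noise), possible saturable binding,
counting statistics, and tumor growth over the 6-day window, none of which
are simulated.

## Statistics

Group comparisons are per-organ unpaired two-tailed t tests with the
Holm–Šidák step-down adjustment, $\tilde p_{(i)} = 1 - (1 - p_{(i)})^{m-i+1}$
made monotone by a running maximum. Welch's unequal-variance form is the
default even where legacy analyses say "Student": with three animals per
group and visibly unequal spreads, assuming equal variances is the stronger
claim; the pooled form is one flag away. The Spearman test of tumor/liver
ratio against DAR uses the exact permutation null for up to eight pairs
(the design has six), asymptotics beyond. Immunoreactivity comparisons use
ordinary one-way ANOVA with Tukey HSD. We do not attempt to reproduce any
particular GUI package's p-value conventions digit for digit.

## Numerical choices, sizes, and limitations

- ODE tolerances rtol 10⁻¹⁰/atol 10⁻¹², matched to the 10⁻⁸ oracle threshold.
- All fits run on transformed (log/logit) scales; no clipping anywhere.
- Test problem sizes were chosen to keep the default suite around half a
  minute: single-mouse noiseless designs for round-trip recovery, a
  two-organ 100-replicate coverage study, 300 simulated mice for the
  summary-mode calibration checks.
- The adduct-count rounding is half-away-from-zero, so reported half-integer
  average DARs arise only from mixtures, never from single peaks.
- Identifiability is checked structurally (parameter counting, distinct-IR
  rank condition), not by profile likelihood; near-degenerate but formally
  identifiable configurations will fit slowly rather than be refused.
- The compartment topology is a reconstruction of the simplest structure
  consistent with the measurement model above; mixed-effects (per-animal)
  variation, saturable kinetics and physiologically based flow limits are
  out of scope.
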
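---
title: "Plasma-input compartmental modelling of dynamic PET: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plasma-input compartmental modelling of dynamic PET: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tacfit)
```

`tacfit` quantifies regional tracer kinetics in dynamic brain PET against a
metabolite-corrected arterial plasma input. It was written for plasma-input
quantification of TSPO tracers — where reference-tissue shortcuts are invalid
because no brain region is free of specific binding — but the machinery is
generic: compartment models, arterial input construction, weighted nonlinear
least squares, AIC model comparison, reliability gating and the small-sample
nonparametric statistics used in case-control neuroimaging studies. A
synthetic-cohort generator reproduces the statistical structure of a
two-genotype case-control study so the whole pipeline can be exercised and
validated without patient data.

## The compartment models

Let $C_p(t)$ be the metabolite-corrected parent tracer concentration in
arterial plasma and $C_{wb}(t)$ the whole-blood activity, both in kBq/mL with
time in minutes. The tissue models are the standard catenary systems:

* **1T2k** — one tissue compartment:
  $\dot C_1 = K_1 C_p - k_2 C_1$, $C_T = C_1$.
* **2T3k** — irreversible two-tissue:
  $\dot C_1 = K_1 C_p - (k_2 + k_3) C_1$, $\dot C_2 = k_3 C_1$.
* **2T4k** — reversible two-tissue:
  $\dot C_1 = K_1 C_p - (k_2+k_3) C_1 + k_4 C_2$,
  $\dot C_2 = k_3 C_1 - k_4 C_2$, $C_T = C_1 + C_2$.

$K_1$ (mL·cm$^{-3}$·min$^{-1}$) is delivery, $k_2$ washout, and $k_3, k_4$
(min$^{-1}$) exchange with the specifically bound pool. Each model exists
with and without a fractional blood volume $V_B \in [0,1]$, giving the
measured signal $C_{PET} = (1-V_B)\,C_T + V_B\,C_{wb}$. A seventh variant
adds an irreversible vascular trapping compartment
$C_{vasc}(t) = K_b \int_0^t C_{wb}(s)\,ds$, representing slow tracer binding
to the vascular endothelium.

Because no equation for how trapped vascular activity enters the signal is
in general use, the package makes an explicit, documented choice: the trap
accumulates **within** the vascular fraction,
$C_{PET} = (1-V_B) C_T + V_B (C_{wb} + C_{vasc})$, so $V_B = 0$ implies no
vascular signal of any kind. The alternative convention (trap added outside
$V_B$) is available through `vascular_within_vb = FALSE` for sensitivity
analyses; on typical fits the difference is far below frame noise.

The derived macro-parameters are the total volume of distribution
$V_T = (K_1/k_2)(1 + k_3/k_4)$ (reversible models; $K_1/k_2$ for 1T2k), the
non-displaceable binding potential $BP_{ND} = k_3/k_4$, and the net influx
rate $K_i = K_1 k_3/(k_2+k_3)$ for the irreversible model. $V_T$ is
undefined for 2T3k and signalled as such.

### Solving the models

The input curves are stored as sampled knots and treated as piecewise linear
(zero before time zero). The tissue response is a one- or two-exponential
impulse response with eigen-rates
$\alpha_{1,2} = \tfrac12\big[(k_2+k_3+k_4) \mp \sqrt{(k_2+k_3+k_4)^2 - 4k_2k_4}\big]$,
and the convolution with a piecewise-linear input has a closed form on each
segment. The recursion `y[i+1] = y[i]·exp(-a·dt) + segment` is exact for the
interpolant and unconditionally stable, so no ODE solver sits in the fitting
path; a stiff ODE integration (deSolve) is kept in the test suite as an
independent oracle and agrees to a relative RMS below $10^{-3}$ across all
seven model variants. Numerical details worth knowing:

* small exponents use `expm1` and a series for
  $(dt - (1-e^{-a\,dt})/a)/a$ to avoid cancellation;
* the discriminant is non-negative for any non-negative rates; an exactly
  repeated eigen-rate is separated by a relative nudge of $10^{-9}$, which
  perturbs the curve far below fitting tolerances;
* a frame's model value is the **time-average** of the continuous signal over
  the frame (trapezoidal integration on a grid containing every input knot
  and at least nine points per frame), not a midpoint sample — the
  difference is material for 15 s frames around the bolus peak.

The acquisition grid defaults to the 19-frame, 60-min dynamic rebinning
(1×15, 3×5, 3×10, 4×60, 2×150, 2×300, 4×600 s); any contiguous schedule can
be supplied. All internal times are minutes; on-disk frame definitions are
seconds, converted at the boundary, and TACs are assumed decay-corrected to
injection time, so decay enters only the noise and weight models.

## Building the input function

From sampled blood data (`blood_data`) the input is assembled in three
steps, mirroring standard arterial processing:

1. **plasma/whole-blood ratio** — a straight line in time fitted to the six
   manual samples (5, 10, 20, 30, 40, 60 min), clamped to $\ge 0.5$; six
   points cannot support more structure. `plasma(t) = wb(t)·ρ(t)`.
2. **metabolite correction** — a monotone Hill-type parent fraction
   $f(t) = 1 - (1-a)\,t^b/(t^b + c^b)$ constrained to $f(0)=1$, with
   $a \in [0,1]$ the asymptotic parent fraction, $b>0$ the steepness and $c$
   (min) the half-conversion time. The form is monotone non-increasing for
   any admissible parameters, so the corrected input can never gain parent
   activity late. `Cp(t) = plasma(t)·f(t)`.
3. **delay** — a grid search over shifts of ±30 s in 0.5 s steps, choosing
   the shift that minimises the weighted RSS of a 1T2k+$V_B$ fit to the
   early (< 5 min) whole-brain TAC; estimated once per scan and then fixed
   for all regional fits. Solutions on the search bound are flagged. The
   continuous-sampler curve is used as measured; no dispersion correction is
   applied.

For simulation, `generate_feng_input()` produces the standard bolus shape —
linear rise to the peak, tri-exponential washout — and derives the matching
whole-blood curve by inverting the ratio and parent-fraction models. Its
sampling grid (5 s up to 3 min, then 15 s to 10 min, then 30 s) keeps the
piecewise-linear representation within 0.1% of the underlying smooth curve.

## Fitting, weighting, model selection, reliability

`fit_model()` minimises the weighted residual sum of squares with bounded
Levenberg-Marquardt iterations (minpack.lm). The default weights are
$w_i \propto \Delta t_i\, e^{-\lambda t_i}$ (frame duration times physical
decay at the frame midpoint, $\lambda = \ln 2 / 109.77$ min$^{-1}$ for
fluorine-18), normalised to mean one — a standard proxy for count-statistics
variance when true random/prompt rates are unavailable. A uniform scheme is
provided; the weight scheme is an explicit option because published analyses
rarely print theirs.

The objective of the richer models is multimodal, so each fit starts from a
deterministic mid-range point plus Latin-hypercube draws (default 10 starts
in total; rates drawn log-uniformly within bounds, fractions uniformly). The
default bounds are generous physiological envelopes:
$K_1, k_2, k_3, k_4 \in [10^{-4}, 2]$, $V_B \in [0, 0.2]$,
$K_b \in [0, 0.1]$ min$^{-1}$. $V_B$ may be fixed (e.g. at 5%) instead of
fitted, which removes one free parameter.

Parameter uncertainty is the residual-variance-scaled inverse of
$J^\top W J$ from a fresh finite-difference Jacobian at the optimum, quoted
as %SD of the estimate; the %SD of the derived $V_T$, $BP_{ND}$ and $K_i$
follows by the delta method from the same covariance. Model comparison uses
the least-squares AIC, $n \ln(RSS/n) + 2p$, without small-sample correction
by default — AIC is what small-cohort PET analyses conventionally report,
and with $n = 19$ frames the AICc correction is debatable; it is exposed as
an option (`correct = TRUE`). Ties break towards fewer parameters.

A fit is **reliable** when every %SD is defined, %SD($K_1$) ≤ 25%, every
other fitted parameter's %SD ≤ 50%, and no estimate lies within $10^{-6}$ of
the bound range of a bound ("touching the boundary"). These gates mirror how
unstable rich-model fits (notably the vascular-trap variant) are screened
out in practice even when AIC prefers them.

## The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` builds a 15-subject study — 8 patients (4 high-affinity
binders, 4 medium-affinity) and 7 controls (3/4) — with per-subject inputs,
per-region ground-truth kinetics and noisy TACs from the 2T4k+$V_B$ model.
Region classes are cortical grey matter, thalamic grey matter, cerebellar
white matter, non-lesional white matter, and (patients only) a T2 lesion
region with volume drawn log-uniformly within 3.6–60.6 cm³.

The generator separates two effect channels so every configured ratio is
realised exactly in the ground truth:

* the **binding-potential channel** scales $k_3$ (genotype ratio 1.6 by
  default; +30% diffuse elevation in HAB patients' non-lesion tissue; 2.4×
  lesion multiplier over the same subject's non-lesional white matter);
* the **volume-of-distribution channel** scales the non-displaceable volume
  $K_1/k_2$ through $K_1$, with the genotype multiplier solved so the $V_T$
  ratio equals its configured value (1.6) despite the $k_3$ change.

Disease-related $BP_{ND}$ elevations leave $V_T$ unchanged by construction:
the non-displaceable volume shrinks as specific binding grows. This encodes
the central dissociation the package exists to demonstrate — a large
non-displaceable compartment masks disease effects in $V_T$ while $BP_{ND}$
carries them in full, diffusely and in lesions. An optional
`outlier_patient` toggle removes one patient's lesion elevation to emulate
an off-trend subject in the lesion regression.

Anchor values (medium-affinity non-lesional white matter:
$K_1 = 0.10$, $k_2 = 0.15$, $k_3 = k_4 = 0.04$, $V_B = 0.05$) are plausible
for a second-generation TSPO tracer but are *not* literature-derived
constants — no absolute rate-constant scale is asserted, only ratios and
contrasts. Grey matter gets 1.4–1.5× white-matter delivery with $k_2$
scaled jointly so $V_T$ is flow-independent.

Variability defaults are deliberately tight: between-subject lognormal CV of
2% on each channel, within-subject regional $V_T$ jitter of 2% (clamped,
keeping the within-subject spread well under the 15% homogeneity the design
assumes), blood peak amplitude CV 5%, and frame noise of 3% fractional SD at
the peak frame under a count-statistics variance model
($SD_i \propto \sqrt{C_i\,e^{\lambda t_i}/\Delta t_i}$, negative values
permitted). Three percent peak noise is realistic for multi-hundred-cm³
ROI TACs, and small between-subject variance is what makes a configured
1.6-fold contrast identifiable at $n = 15$ — the generator is a validation
scenario, not a population model. Clinical heterogeneity (real cohorts
spread far wider), arterial dispersion, scanner resolution effects, partial
volume and motion are all outside what it emulates, so passing recovery
tests here demonstrates correctness of the estimation machinery, not
performance on real data.

## Estimating the genotype contrast

The headline summary is the regional HAB/MAB ratio of mean outcome values
(`genotype_contrast()`). Two estimator details are deliberate:

* for $BP_{ND}$ the ratio is computed on the **healthy-control arm**: the
  generator (like the disease it emulates) elevates $BP_{ND}$ only in
  high-affinity patients, so pooling arms would confound the genotype ratio
  with the disease effect;
* for $V_T$ all subjects are used, since no disease effect on $V_T$ exists
  by design and the larger sample halves the estimator's dispersion.

Both choices are overridable (`subjects = "all"` / `"hc"`). At the default
noise level the fitted $BP_{ND}$ ratio carries a small (~2–3%) upward bias
relative to truth — ratio-of-means estimators of $k_3/k_4$ are noise-skewed
— which is visible in the acceptance output and left uncorrected rather
than hidden behind a bias adjustment.

## Statistics

Group comparisons use the Mann-Whitney U test and paired regional
comparisons the Wilcoxon signed-rank test, exact whenever the sample is
small (pooled $n \le 25$, resp. $n \le 20$ nonzero differences) and
tie-free, with the two-sided doubling rule $p = \min(1, 2\min(P_{\le},
P_{\ge}))$; otherwise the normal approximation with tie and continuity
corrections. Zero differences are dropped (Wilcoxon's rule) by default, with
Pratt's variant available. Exactness is verified in the tests against
brute-force enumeration of all arrangements/sign patterns up to $n = 10$.
No multiple-comparison correction is applied anywhere — the intended use is
small exploratory cohorts — and every report states this.

The lesion analysis pairs each patient's lesion value with their
non-lesional white matter: a signed-rank test plus an ordinary
least-squares regression of lesion on white-matter values (slope ± SE,
$R^2$), with optional named-outlier exclusion.

## Problem sizes and runtime choices

The shipped tests fit roughly 700 regional TACs in total: the full default
cohort (68 fits) for effect recovery, 100 replicates for estimator bias, 60
fits for model selection, 20 replicated cohorts (16 fits each) for the
lesion dissociation, and smaller unit fixtures; the suite completes in
about two minutes on one CPU. These sizes were chosen as the smallest that
give stable Monte-Carlo verdicts at the asserted thresholds; scaling any of
them up only tightens the same checks. The acceptance script regenerates
the default cohort and all 68 regional fits from scratch at whatever seed
it is given.

## Known limitations

* No voxelwise/parametric imaging, no reference-tissue or graphical
  (Logan/Patlak) methods — deliberately, as the target setting invalidates
  them.
* The delay search is bounded at ±30 s and gridded at 0.5 s; larger
  misalignments must be handled upstream.
* The vascular-trap signal convention is a documented choice, not a
  community standard; conclusions about $K_b$ should be checked under both
  conventions.
* %SD comes from the local quadratic approximation at the optimum; for
  parameters near bounds it understates the true uncertainty (such fits are
  gated out as unreliable rather than patched).
* The parent-fraction model is monotone by construction and cannot follow
  non-monotone metabolite kinetics.
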
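---
title: "Translating rectum dose constraints between carbon-ion RBE models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translating rectum dose constraints between carbon-ion RBE models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbedvh)
```

## The analysis in one paragraph

A carbon-ion treatment plan optimized with the local effect model (LEM)
carries a different nominal RBE-weighted dose distribution than the same
plan recalculated with the modified microdosimetric kinetic model (mMKM),
and the discrepancy is largest outside the target — exactly where
organ-at-risk constraints act.  `rbedvh` takes paired LEM/mMKM rectum DVHs
for a cohort, extracts dose-volume points \(D_{\mathrm{LEM}|v}\) and
\(D_{\mathrm{MKM}|v}\) at volume levels \(v \in \{1, 5, 10, 20\}\%\), fits
the quadratic relation

\[
D_{\mathrm{MKM}|v} = a\,D_{\mathrm{LEM}|v}^2 + b\,D_{\mathrm{LEM}|v} + c ,
\]

and inverts it — with a 95% confidence band — at the mMKM-language rectum
limits (28.8, 46.4, 60 and 66 Gy(RBE)) to obtain LEM-language constraints.
In parallel it predicts late rectal toxicity with the
Lyman–Kutcher–Burman (LKB) model on the mMKM equivalent uniform dose, and
converts absolute-dose thresholds between fractionation schedules with the
linear-quadratic biologically effective dose (BED).

## Models and assumptions

### DVH metrics and gEUD

A cumulative DVH stores the fraction of the structure volume receiving at
least each dose; doses are course totals (16 fractions) in Gy(RBE).
Metrics interpolate linearly between bins (default bin width 0.1 Gy(RBE),
below the one-decimal clinical reporting precision), and absolute-volume
specifications convert through the structure volume,
\(\mathrm{fraction} = cc / V_{\mathrm{total}}\), which is what makes
cc-based constraints robust to rectum-size variation.  The generalised
equivalent uniform dose is the power mean over the differential DVH,

\[
\mathrm{gEUD} = \Big(\sum_i v_i\, d_i^{1/n}\Big)^{n},
\]

evaluated in log space: with the late-rectal volume-effect parameter
\(n = 0.035\) the exponent \(1/n \approx 28.6\) — and the limiting check at
\(n = 10^{-4}\) an exponent of \(10^4\) — would overflow double precision
if the power sum were formed naively.  Small \(n\) makes the rectum
behave as a serial organ: the gEUD, and hence the NTCP, is governed almost
entirely by the hottest few percent of the volume.

### Quadratic translation and its confidence band

The fit is ordinary least squares on the design \((x^2, x, 1)\).  The 95%
band is the classical band for the *mean response*,
\(\hat f(x) \pm t_{n-3}\sqrt{\mathbf{x}^\top V \mathbf{x}}\), not a
prediction band for individual patients: the object being translated is a
population-level constraint, not a prediction for a new plan.  (Which
interval convention produced the published translated values is not
documented; this package's convention is stated here rather than inferred.)
Inversion selects the quadratic root on the increasing branch
(\(2ax + b > 0\), dose maps are physically increasing), searched on the
observed LEM-dose domain extended by 25% of its width.  The confidence
interval on the translated LEM dose inverts the two band curves at the same
mMKM target; because the band lies above the fitted curve, its upper branch
crosses the target at a *smaller* LEM dose, and that lower bound is the
conservative value adopted as the clinical constraint.  For a noiseless
(zero-residual) fit the band has zero width and the interval collapses onto
the point estimate.

Four per-volume-level fits mirror how the clinical data are usually
displayed, and `fit-translate` supports them.  The *pipeline default*,
however, is one pooled fit across all volume levels.  The reason is a
genuine design fork: inverting a target requires the fitted curve to reach
it, and on the synthetic default cohort each single level's mMKM doses
cluster several Gy(RBE) below its target (e.g. \(D_{\mathrm{MKM}|20\%}\)
tops out near 23 Gy(RBE) against a target of 28.8), so a per-level
inversion would extrapolate an unstable narrow-range quadratic — and can
fail to have an increasing-branch root at all.  Clinical cohorts contain
extreme-anatomy patients that anchor each panel's high end; a stylised
synthetic cohort does not.  The pooled fit spans the full 20–70 Gy(RBE)
range, making every inversion an interpolation.

### LKB NTCP

\(\mathrm{NTCP} = \Phi\big((\mathrm{EUD} - TD_{50})/(m\,TD_{50})\big)\)
with published grade ≥ 1 late-rectal medians \(n = 0.035\), \(m = 0.10\),
\(TD_{50} = 63.6\) Gy(RBE), applied to the 16-fraction course EUD without
further fractionation correction (the parameters were derived on the same
schedule).  Cohort summaries report the group mean NTCP with a seeded
percentile-bootstrap CI (default 10,000 resamples) — the summary method is
not dictated by the model, and the bootstrap is distribution-free and
reproducible.  Because the dose response is convex over the relevant EUD
range, the mean NTCP and the NTCP at the mean EUD differ slightly; both are
reported.

### BED conversion

\(\mathrm{BED} = D\,(1 + (D/n_f)/(\alpha/\beta))\) with
\(\alpha/\beta = 3.9\) Gy for late rectal effects.  The isoeffective dose
in a target schedule is the positive root of
\(D^2/(n_f\,\alpha/\beta) + D - \mathrm{BED} = 0\), taken analytically; BED
is conserved by construction and the conversion is the identity on the
source schedule.  Applying the plain LQ formalism to RBE-weighted totals is
a simplification (no RBE-vs-dose coupling); it is implemented as stated,
without endorsing cross-schedule validity.

## The synthetic cohort: what it emulates and what it does not

The generator reproduces the statistical skeleton of the study population:

| parameter | default | origin |
|---|---|---|
| group sizes | 22 / 28 / 13 (prostate, L-sacrum, H-sacrum) | stated cohort |
| prescriptions | 66.4 / 70.4 / 73.6 Gy(RBE), 16 fractions | stated protocols |
| rectum volume | N(59, 15²) cc prostate, N(91, 39²) cc sacrum, truncated at 10 cc | stated volumes |
| LEM→mMKM map | quadratic through (42.9, 28.8), (57.7, 46.4), (68.2, 60.0), (72.0, 66.0) | frozen normal-equations fit |
| residual noise | SD = 0.03·dose (heteroscedastic) | scatter widens with dose |
| patient offset | SD = 0.5 Gy(RBE) | modest systematic per-patient shift |

Each LEM DVH is a two-component logistic mixture in dose — a bulk falloff
(most of the rectum at low dose) plus a small hot-spot plateau where the
rectum abuts the target — truncated at a patient-specific hard maximum dose
five hot-spot widths above the hot-spot midpoint (capped at
1.02 × prescription).  The truncation is load-bearing: real DVHs terminate
at a finite maximum dose, and the \(n = 0.035\) power mean amplifies
arbitrarily thin logistic tails so strongly that without it group EUDs
could not sit in realistic neighbourhoods.  Group shape parameters were
chosen once so that mMKM EUDs land near 50–55 Gy(RBE) for prostate and
35–45 for sacrum (the sacral groups are planned to stricter
planning-risk-volume limits), and then frozen.

The mMKM curve maps the LEM dose axis through the truth relation plus the
patient offset and a smooth noise field whose correlation length (4 Gy(RBE))
is shorter than the spacing of the extracted volume-level doses, so
per-point residuals are approximately independent — the regime in which the
OLS covariance, and hence the 3-standard-error recovery check, is
calibrated.  Monotonicity of the mapped axis is enforced (running maximum)
before re-binning to the regular grid.

What the generator does **not** emulate: anatomy (no CT, no 3-D geometry
beyond optional toy grids), plan re-optimization, inter-fraction motion,
correlated multi-level patient anatomy beyond a single additive offset, and
the clinical cohort's extreme-anatomy tail (see the pooled-fit discussion
above).  A green end-to-end test therefore establishes that the *pipeline*
is correct under the stated statistical model — not that the published
cohort-level numbers are reproduced; those depend on 63 clinical dose
distributions that were never deposited.  On default seeds the synthetic
cohort lands in their qualitative neighbourhoods: translated constraints
within ~0.3 Gy(RBE) of 42.9/57.7/68.2/72.0, prostate NTCP of a few percent,
sacrum NTCP near zero.

## Numerical conventions

* DVH binning 0.1 Gy(RBE); metrics are exact at bin edges and linear in
  between, so any D\(_v\) agrees with the exact sort-based survival curve
  of the voxel doses to within one bin width.
* `dose_at_volume` returns the smallest dose whose interpolated cumulative
  fraction is ≤ the requested fraction; plateaus resolve to their left
  edge.  Boundary equality with a constraint limit counts as compliant,
  with a 0.05 Gy(RBE) tolerance absorbing clinical rounding.
* gEUD differencing uses bin midpoints of the cumulative curve; zero-dose
  bins drop out of the power sum (they contribute zero at any positive
  exponent).
* Quadratic root selection: increasing branch, tie-broken toward the
  observed domain; a target with no such root raises an error rather than
  returning an extrapolated value.  Band-curve roots are bracketed on a
  201-point scan and polished by `uniroot` to 1e-10.
* Near-zero quadratic coefficients (|a| < 1e-12) fall back to the linear
  inversion, so identity-like fits translate exactly.
* All stochastic operations (cohort generation, bootstrap) take explicit
  integer seeds; reruns are byte-identical.

## Known limitations

* The confidence-band inversion assumes homoscedastic Gaussian residuals;
  the generator's heteroscedastic noise makes nominal coverage approximate
  (the Monte-Carlo calibration check simulates under the band's own
  assumptions).
* Per-volume-level translation requires data bracketing the target and is
  therefore not the synthetic pipeline default (see above).
* Binary masks only; no partial-volume weighting — DVH-level analysis
  treats voxels as in or out, as upstream planning systems do at export.
* The LKB parameters are applied, never refit; no grade ≥ 2 parameter sets
  are included.
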
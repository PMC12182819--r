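---
title: "Dual-contrast extracellular volume mapping of extravascular lung water: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-contrast extracellular volume mapping of extravascular lung water}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungecv)
```

## The measurement problem

Proton-density CMR can quantify total lung water, but cannot say whether
that water sits inside the pulmonary vessels (blood plasma) or in the
interstitium, where cardiogenic pulmonary edema accumulates. `lungecv`
implements a dual-contrast-agent approach that separates the two: a
gadolinium chelate equilibrates across the whole extracellular space
(plasma + interstitium), while ferumoxytol, an iron-oxide nanoparticle,
stays intravascular for hours. Each agent yields an extracellular volume
fraction through the classical ECV relation

$$\mathrm{ECV} = (1 - \mathrm{Hct}) \,
  \frac{\Delta R_{1,\mathrm{lung}}}{\Delta R_{1,\mathrm{blood}}},
  \qquad \Delta R_1 = 1/T_{1,\mathrm{contrast}} - 1/T_{1,\mathrm{native}}.$$

With gadolinium the ratio measures the full extracellular fraction; with
ferumoxytol it measures only the plasma volume fraction (PVF). Their
difference is the extravascular ECV,

$$\mathrm{ECV}_\mathrm{ev} = \mathrm{ECV} - \mathrm{PVF},$$

the interstitial share of the (air-excluded) lung water. Multiplying by
the lung water volume from proton-density imaging converts the fraction
into an absolute extravascular lung water volume in mL.

A point that matters for interpretation: lung ECV is *air-excluded*. T1
mapping is insensitive to air, so ECV and PVF are fractions of the non-air
tissue water, not of the delineated lung volume. Lung water density (LWD),
by contrast, *includes* air in its denominator (water volume per voxel
volume). The package keeps this distinction everywhere: compartment
fractions are air-excluded ratios, densities are per-voxel-volume.

## The compartment model and the forward simulator

The digital phantom (`build_phantom()`) represents each voxel as four
volume fractions summing to one: an MR-invisible fraction `f_air` (air in
the aerated lung; non-water solids in soft tissue), intracellular water
`f_ic`, extravascular-extracellular water `f_ev`, and plasma water `f_pl`.
Treating `f_air` as "everything MR cannot see" is what lets a single
sum-to-one compartment map serve both the T1 forward model (which sees
only water) and the proton-density forward model (where body soft tissue
carries 70% water — the same assumption the density normalization makes
on the analysis side). Blood is modelled as pure water with the
hematocrit as its red-cell (intracellular) share, which makes the ECV of
a blood region exactly $1-\mathrm{Hct}$ — the self-consistency the ECV
formula presumes.

Relaxation follows the fast-exchange single-pool assumption: all water in
a voxel shares one longitudinal rate, and each agent adds
$r_1 \cdot C \cdot (\text{accessible water share})$ to it, where the
accessible share is `(f_ev + f_pl) / water` for gadolinium and
`f_pl / water` for ferumoxytol. This is the regime in which the ECV
algebra above is exact, so the phantom recovers its ground truth
identically in the noiseless limit — which is what makes the pipeline
testable end to end. Relaxivity defaults (4.5 and 15 L/mmol/s) and plasma
concentrations (0.25 and 0.36 mmol/L) only set the magnitude of the T1
changes; they cancel in every ECV ratio. With those defaults and native
T1s of 931 ms (lung) and 1199 ms (blood) the simulated phase T1s land at
the magnitudes observed at 0.55T (lung roughly 931 → 556 → 299 ms).

Scenario defaults are the study conditions of the porcine arms: a naive
control (LWD 33%, ECV 64.4%, PVF 42%, Hct 0.23, lung volume 0.93 L), a
paired baseline / mitral-regurgitation pair (30/70/43 at Hct 0.26 and
31/78/46, 1.33 L — regurgitation raises `f_ev`), and a colloid
volume-loaded arm (32/73/51 at Hct 0.18, 1.23 L — raised `f_pl`, lowered
hematocrit). The anteroposterior structure uses two linear gradients
across the lung's bounding box: plasma pooling toward the posterior
(gravity-dependent) lung, `ap_gradient = 0.15` (0.20 when volume-loaded),
and interstitial water weighted anteriorly, `ev_gradient = -0.3` (-0.5
during regurgitation, -0.1 when volume-loaded). The gradient magnitudes
were set from the anterior-vs-posterior spreads of the reported regional
fractions. Subject-level realism (between-animal spread of fractions,
hematocrit, native T1, lung volume and hemodynamics, plus a smaller
within-subject component between paired conditions) lives in
`simulate_subject()`, with relative SDs chosen to match the reported
group SDs; `biological_cv = 0` switches it off and reduces every subject
to the arm's mean animal.

What the phantom deliberately does *not* emulate: respiratory and cardiac
motion, registration error between phases (the study repositioned animals
and therefore avoided pixel-wise ECV — so does the pipeline), partial
volume at lung borders beyond the mask contract, B0/B1 field effects, and
perfusion heterogeneity beyond the linear gradients. Passing recovery
tests on these phantoms therefore demonstrates correctness of the
estimation chain under the stated physics, not robustness to acquisition
artifacts.

## Saturation-recovery T1 fitting

The SASHA protocol samples $S(TS) = A(1 - B e^{-TS/T_1})$ at saturation
times 104, 200 and 374 ms with 8, 4 and 4 averages, plus an effectively
fully recovered anchor (the anchor is configurable and on by default).
Because only $T_1$ enters nonlinearly, `fit_t1()` profiles it (variable
projection): for each candidate $T_1$ the amplitudes solve in closed form
by weighted linear least squares (weights = numbers of averages), leaving
a one-dimensional residual profile that is minimized on a 150-point
log-spaced grid over the physiological window (default 50–3000 ms) and
then refined by 60 golden-section iterations. On noiseless input this
inverts the model to well below $10^{-3}$ ms; the suite cross-checks it
against an independent Levenberg–Marquardt fit on noisy voxels. The fit
is bounded: if the unconstrained saturation efficiency $B$ leaves
[0.5, 1.1], the voxel is refit with $B$ clamped at the boundary (the
constrained optimum) rather than discarded — discarding such voxels
selects against short-T1 estimates and visibly biases ROI means. Voxels
with nonpositive amplitude or $T_1$ on the window boundary are flagged
invalid and excluded from ROI statistics.

Noise is simulated as per-average complex Gaussian noise followed by
magnitude reconstruction (Rician), with the per-average SNR referenced to
the fully recovered lung-parenchyma signal (the tissue whose precision
the protocol targets). At lung-like SNR the short saturation times sit
near the noise floor, where the Rice-distribution mean exceeds the true
signal; `fit_t1()` therefore inverts the analytic Rice mean at each
sample before least squares whenever the series carries its known noise
level. The remaining upward skew of the three-parameter estimator (~2% at
single-average SNR 20) is intrinsic to nonlinear least squares at this
sampling and largely cancels in the ECV ratios; Monte-Carlo bias of the
recovered fractions at SNR 20 is a few tenths of a percentage point.

`bloch_simulate_sasha()` provides the sensitivity harness: piecewise-exact
Bloch evolution (closed-form relaxation between instantaneous RF pulses,
no ODE tolerances) of saturation, recovery, and a bSSFP readout (default
flip 80°, TR 3 ms, 43 segments, saturation time defined to the k-space
center), used to verify that fitted T1 is monotone in true T1 across the
physiological range; `monte_carlo_t1()` tabulates bias and SD over a
(T1, SNR) grid.

## ROI statistics, pairing, and the regional analysis

ROI T1 is the arithmetic mean of valid voxel T1s in the mask across all
slices — not a fit of the ROI-mean signal — and group values average
per-subject ECVs (ratio first, average second), both following the
study's reporting. Phase pairing (`pair_phases()`) enforces consistent
physiology: the regurgitation ECV pairs regurgitation-native with
regurgitation-contrast maps, separately from the baseline pair; the
volume-loaded arm uses the post-infusion native; ferumoxytol delta-R1 is
always measured against the pre-gadolinium native T1 (residual gadolinium
at the ferumoxytol phase is available as an explicit confounder with
1.81 h exponential clearance, default off). A naive protocol with
ferumoxytol administered before gadolinium remains resolvable but is
labelled order-variant.

The regional analysis divides the lung-mask bounding box (not the field
of view) into three equal sections along the anteroposterior axis, with
remainder voxels from non-divisible extents assigned to the
posterior-most eligible sections (extent 10 → 3/3/4), and recomputes
ECV/PVF/ECV\_ev per section using the global blood ROI.

## Lung water density and volumes

The proton-density route divides the volume by a least-squares polynomial
shading field (total degree 2 by default) fitted to the body reference
mask — the body minus the lungs and a 2-voxel ring around them, to avoid
partial-volume contamination. Lung water density is
$0.70 \cdot S_\mathrm{voxel} / \mathrm{median}(S_\mathrm{body})$, the
0.70 encoding the assumed musculoskeletal water density; densities above
1.2 are flagged, never clipped. Then

$$\mathrm{LWV} = \mathrm{LWD} \cdot V_\mathrm{lung}, \qquad
  \mathrm{EVLW} = \mathrm{ECV}_\mathrm{ev} \cdot \mathrm{LWV},$$

with the native-phase lung water volume of the matching condition used
for EVLW. For a homogeneous lung, EVLW telescopes exactly to
$\sum f_{ev} \cdot V_\mathrm{voxel}$ — the identity the acceptance suite
checks to 0.5%. The polynomial shading stand-in replaces an
unspecified proprietary correction; its order is config-exposed.

## Hemodynamics

Stroke volume is the trapezoidal integral of forward flow over each
complete beat, averaged across beats (beat boundaries, a heart-rate grid,
or threshold crossings, in that order of preference); cardiac output is
SV × HR. The simulated systolic lobe is $\sin^2$-shaped by default — a
C1-continuous waveform for which trapezoidal integration at ≥ 20
samples/beat stays well under 1% error; a half-sine option exists. The
mitral regurgitant fraction is
$(SV_\mathrm{LV} - SV_\mathrm{aorta}) / SV_\mathrm{LV}$, with the LV
stroke volume taken from the end-diastolic minus end-systolic volume of
the cine-derived LV volume curve.

Pulmonary transit time is the difference of gamma-variate first moments
($t_0 + \beta(\alpha+1)$) fitted to the right- and left-ventricular
first-pass curves after baseline subtraction and truncation at 50% of
peak on the down-slope (the standard indicator-dilution guard against
recirculation). The fit profiles the arrival time $t_0$ over a grid with
weighted log-linear solves for the remaining parameters, then accepts a
bounded Levenberg–Marquardt refinement only if it lowers the residual;
candidate centroids are constrained to the window implied by the observed
peak and half-decay times (for any gamma-variate the centroid exceeds the
peak by $\beta$, and the half-decay width is 1.2–3.5 $\beta$ across
physiological shapes), which keeps coarsely sampled noisy curves from
driving the moment off the data support. The pre-arrival baseline is the
mean of all samples before the sustained rise — an unbiased choice;
order-statistic baselines systematically under-subtract.

At the study's sampling (1.5 s frames, CNR ≈ 10, bolus
$\alpha = 3, \beta = 1.5$ s), the estimator is essentially unbiased
(< 1% of truth) and failure-free, with a mean absolute error of about
0.6 s. An oracle experiment — refitting from the *true* parameters under
the same truncation rule — gives the same 0.6 s, i.e. the residual error
is the information limit of the moment-difference method under 50%
truncation at this sampling, not an estimator defect. Pulmonary blood
volume is PTT × CO (CO converted to mL/s).

## Statistics

Paired t-tests compare baseline vs regurgitation; unpaired (pooled
variance) t-tests compare volume-loaded vs naive; T1 evolution and the
regional fractions use one-way repeated-measures ANOVA with
Greenhouse–Geisser correction. The RM-ANOVA and the GG epsilon (from the
double-centered condition covariance; bounded in $[1/(k-1), 1]$, exactly
1 for two conditions) are implemented directly and cross-checked against
`car::Anova` to $10^{-6}$ in the test suite. For the regional analysis
the naive animals are grouped with the mitral-regurgitation baselines as
the no-intervention cohort — a grouping passed as an argument, not
hard-coded. Summary tables report mean ± SD with integer-percent
rounding under R's round-half-even rule (documented divergence: 105.84
formats as "106").

## Numerical choices and degenerate inputs

* T1 window [50, 3000] ms, B window [0.5, 1.1]; grid 150 points, 60
  golden-section iterations (noiseless inversion ≤ $10^{-3}$ ms).
* A blood delta-R1 smaller than $10^{-9}$ /ms is an error (the contrast
  change is uninterpretable); negative delta-R1, ECV outside [0, 1.2],
  negative ECV\_ev, LWD above 1.2 and negative regurgitant fractions are
  flagged with warnings, never clipped or truncated, so group statistics
  stay valid.
* Pure-air voxels have undefined T1 and are flagged invalid; empty masks,
  non-disjoint lung/body masks, a zero body median, rank-deficient
  shading fits, missing manifest phases and grid mismatches are errors
  that name the offending stage and subject.
* Voxel indices are 1-based (R); the anteroposterior axis is declared in
  the map (`ap_axis`, default 2) with posterior = increasing index.
* Problem sizes used by the tests and the acceptance script: 32×32×6
  phantom grids (voxel size rescaled per arm to the target lung volume),
  three arms of n = 5 subjects, 20-phantom recovery sweeps, 100-seed
  transit-time Monte-Carlo, and 10,000-replicate type-I-error
  calibration — sizes at which every Monte-Carlo tolerance in the suite
  is comfortably resolved.

## Known limitations

Single-voxel fast exchange ignores intermediate-exchange T1 biases;
the simulator encodes the left-ventricular first-pass as a pure shift of
the right-ventricular curve, so pulmonary bolus dispersion is not
emulated; masks are inputs (a threshold fallback for phantoms stands in
for neural segmentation, which belongs to a different tool); pixel-wise
ECV maps are intentionally out of scope because the acquisition protocol
repositions subjects between phases; and the transit-time method's
accuracy is bounded by the 50%-truncation information limit discussed
above.
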
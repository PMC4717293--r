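---
title: "Quantifying cerebral vasculature with contrast-enhanced MRI: methods and design of qvasc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cerebral vasculature with contrast-enhanced MRI: methods and design of qvasc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qvasc)
```

# The measurement problem

Cerebral amyloidosis degrades the brain's microvasculature. Transgenic mouse
models of the disease (such as the arcAβ strain, which develops both
parenchymal plaques and vascular amyloid) make it possible to follow that
degeneration in vivo, if an imaging read-out can be found that is sensitive
to *microvessels* specifically rather than to the vasculature as a whole.

`qvasc` implements a four-read-out protocol built around an intravascular
superparamagnetic iron oxide (SPIO) contrast agent at high field:

1. **rCBV(DSC)** — relative cerebral blood volume from dynamic
   susceptibility contrast (DSC) bolus tracking,
2. **rCBF** — relative cerebral blood flow from deconvolution of the same
   bolus data,
3. **rCBV(ΔR2\*)** — relative blood volume from the steady-state
   gradient-echo relaxation-rate change after the agent has equilibrated,
4. **Q and N** — the relaxation shift index and the microvessel-density
   estimate derived from it, the microvessel-specific read-out.

The hemodynamic read-outs (1–3) are sensitive to all vessel calibres; Q
exploits the different vessel-size sensitivity of spin-echo and
gradient-echo sequences to isolate the microvascular contribution.

Because no real image data ship with the package, a forward simulator
(`make_cohort()` and friends) generates phantom cohorts with known
ground-truth vascular parameters. Every processing stage is therefore
testable by parameter recovery, and the package's acceptance suite runs the
entire chain — simulation, mapping, region statistics, genotype contrasts —
from a single seed.

# Signal models

## Dynamic (bolus) pathway

During bolus passage the tracer concentration in a voxel is proportional to
the transverse relaxation-rate change, estimated from the echo-planar signal
as

$$C(t) \;=\; -\frac{k}{TE}\,\ln\frac{S(t)}{S_0},$$

with $S_0$ the mean pre-bolus baseline signal. The proportionality constant
$k$ is unknown and fixed at 1 (`signal_to_concentration()`): every derived
quantity is relative, and $k$ cancels exactly in the blood-volume ratio.

Indicator-dilution theory links tissue and arterial concentration curves
through the residue function $R(t)$ (the fraction of tracer still present a
time $t$ after arrival):

$$C_t(t) = \mathrm{CBF} \cdot (C_a \otimes R)(t), \qquad
  \mathrm{CBV} = \frac{\int C_t}{\int C_a}, \qquad
  \mathrm{MTT} = \mathrm{CBV}/\mathrm{CBF}.$$

* **rCBV(DSC)** (`compute_rcbv_dsc()`) is the ratio of the first-pass areas,
  each obtained from a gamma-variate fit (below).
* **rCBF** (`compute_rcbf()`) is the maximum of the residue recovered by
  truncated-SVD deconvolution (below).

## Steady-state pathway

Once the intravascular agent reaches a stable plasma concentration, the
pre/post signal ratio of a spin-echo (SE) and a gradient-echo (GE)
acquisition gives the relaxation-rate changes

$$\Delta R_2 = \frac{1}{TE_{SE}}\ln\frac{S_{pre}}{S_{post}}, \qquad
  \Delta R_2^* = \frac{1}{TE_{GE}}\ln\frac{S^*_{pre}}{S^*_{post}}.$$

Negative estimates (noise) are clipped to zero before any further
computation — clip-then-compute, in that order. $\Delta R_2^*$ senses
vessels of all sizes and is itself a relative blood-volume map
(`compute_rcbv_ss()`); $\Delta R_2$ is weighted toward capillaries. Their
ratio at the static-dephasing exponent,

$$Q = \frac{\Delta R_2}{(\Delta R_2^*)^{2/3}},$$

is approximately independent of tracer dose and blood volume and scales
with microvessel density, estimated as

$$N \approx Q^3 \times 329 \;[\mathrm{s/mm^2}].$$

The constant 329 is applied as given in the vessel-size-imaging literature,
with no attempt to re-derive it from relaxivity or volume-fraction
assumptions; the printed unit is retained, with the conventional reading
"microvessels per mm² of tissue cross-section". The dose-invariance of Q
(scaling $\Delta R_2^* \to c\,\Delta R_2^*$, $\Delta R_2 \to
c^{2/3}\Delta R_2$ leaves Q unchanged) is verified numerically in the test
suite.

# Algorithms and the choices behind them

## Bolus arrival time

`estimate_bolus_arrival()` fits, for every candidate breakpoint $b$, a
straight line to the curve up to $b$ joined *continuously* to a quadratic
from $b$ to the time-to-peak, and takes the breakpoint minimizing the total
residual sum of squares. The search is exhaustive over frames 3 to
ttp − 1, with ties resolved toward the earliest frame. Curves whose maximum
stays below the baseline mean plus twice the baseline standard deviation
are rejected as bolus-free. Internally the search is vectorized across
voxels sharing a time-to-peak, so whole-brain timing costs well under a
second.

A caveat inherent to the model: a bolus whose leading edge is flat to first
order (gamma shape $\alpha \ge 2$) has zero derivative at onset, and *no*
breakpoint estimator can localize it to one frame; sub-frame accuracy holds
for $\alpha < 2$.

## Gamma-variate fitting

`fit_gamma_variate()` fits $C(t) = A\,(t-t_0)^\alpha e^{-(t-t_0)/\beta}$ by
bounded Levenberg–Marquardt over the window from the bolus arrival time
(BAT) to $\mathrm{BAT} + 2.5\,(\mathrm{TTP} - \mathrm{BAT})$. The window
bracket is sometimes quoted with the arrival/peak difference reversed,
which would give a negative span; the convention implemented here is the
standard forward reading. Initialization is by log-linearization (fixing
$t_0$ at the BAT, regressing $\ln C$ on $\ln(t - t_0)$ and $(t - t_0)$),
the classic approach for this model. The closed-form area
$A\,\beta^{\alpha+1}\Gamma(\alpha+1)$ (`gamma_area()`) is checked against
adaptive quadrature across the parameter range in the test suite.

Each fit carries quality metadata: convergence, within-window $R^2$, and a
*credibility* flag that clears when the shape or scale parameter ends up
pinned at its box bound (a runaway fit of noise, not a bolus). Non-credible
fits are excluded from maps, as are fits with $R^2 < 0.2$.

Voxelwise fitting of noisy curves has a subtler failure mode than outright
divergence: the area estimate $A\,\beta^{\alpha+1}\Gamma(\alpha+1)$ is a
convex function of noisy parameters, so per-voxel areas carry a skewed,
amplitude-dependent positive bias that does not cancel between groups of
different signal amplitude. `fit_dsc_voxels()` therefore applies a mild
3-frame moving average to each curve before timing and fitting
(`presmooth_frames = 3`). The filter preserves curve integrals, and with it
the amplitude dependence of the area bias drops below one percentage point
on group contrasts. Deconvolution always operates on the *raw*
concentration curves.

## Arterial input function

The AIF search scores candidate voxels with the composite likelihood

$$L = z(\mathrm{peak}) + z(1/\mathrm{FWHM}) + z(-\mathrm{BAT}),$$

i.e. arteries are the tallest, narrowest, earliest curves; $z$ is the
standard score over the candidate pool. This metric is a committed design
choice of this package (the idea of an artery-likelihood search is
standard; its exact form varies between implementations). Features are
measured on the (lightly smoothed) measured curves rather than on fitted
parameters — a fitted-width term turns out to reward runaway narrow fits of
noise, whereas a tall *and* narrow *measured* curve cannot be produced by
noise at realistic SNR.

Sanity filters precede the ranking: a credible, positive-area fit with
$R^2 \ge 0.5$; a measured width of at least 2 frames; and membership in the
bright tail of the candidate pool (peak at or above the 75th percentile and
at least half the brightest candidate's peak — an artery is by definition
among the brightest first-pass signals). The top `aif_m = 10` voxels'
curves are averaged and the average refitted to give the analytic AIF. On
simulated cohorts at SNR 40 the selection lands entirely inside the artery
label.

## Deconvolution

`compute_rcbf()` builds the lower-triangular Toeplitz matrix of the AIF
(scaled by the frame spacing), computes its SVD, zeroes singular values
below `r_trunc = 0.2` times the largest, and applies the pseudo-inverse to
each tissue curve. rCBF is the maximum of the recovered residue, floored at
zero; negative residue samples are permitted internally. By default the
matrix is built from the fitted (noise-free) AIF curve; set
`use_fitted_aif = FALSE` to use the averaged measured curve.

Truncation at one fifth of the largest singular value is aggressive, and
its cost should be understood before interpreting absolute rCBF values.
With the default simulator conditions (arterial bolus of ~3 s width at
0.4 s sampling, tissue MTT 1.8 s), the acceptance suite measures a residue
peak recovery of roughly 0.6–0.7 of truth at `r_trunc = 0.2`, against ~0.96
with truncation effectively off — the well-known flow underestimation of
truncated SVD. Two consequences:

* absolute flow recovery to within 10% is *not* achievable at this
  truncation level under mouse-realistic bolus and transit conditions (the
  corresponding acceptance check is accordingly expected to fail, by
  design honesty rather than oversight);
* *relative* statements survive intact: the truncation loss factor depends
  only on the AIF and the residue shape, so with transit time preserved it
  is identical in both genotype groups and cancels exactly in percent
  changes. The monotonicity of truncation (residue norm never increases
  with `r_trunc`) is property-tested.

## Grid resampling

`resample_to_grid()` performs separable natural cubic-spline interpolation
along each axis, assuming corner-aligned grids with voxel centres at
$(i - \tfrac12)\,\Delta x$. Constants, the identity case and polynomial
ramps are reproduced to machine precision; target points outside the source
extent become `NaN`.

One consequence matters for validation: a cubic spline through a
*piecewise-constant* field rings near the steps, and the ringing of a
global spline decays geometrically rather than vanishing. End-to-end
exactness of the noiseless pipeline (recovered Q equal to truth at 1e-9) is
therefore a *matched-grid* property, asserted with the GE volumes generated
on the SE grid. The default phantom keeps ΔR2\* spatially constant inside
the brain and insets all ROIs two voxels from the air/tissue boundary, so
on the default (factor-2 finer) GE grid the residual resampling error
inside ROIs is negligible (≪1%) without being identically zero.

## Masking and epsilon conventions

Brain masking thresholds the baseline mean at 0.2 of its robust
(99th-percentile) maximum. Masked or invalid voxels are `NaN` in every
emitted map, never zero. In `compute_q()`, voxels with
$\Delta R_2^* < \varepsilon = 10^{-6}\,\mathrm{s}^{-1}$ after clipping get
Q = 0; the guard is this package's convention for a case the original
processing chain did not need to handle explicitly.

# The synthetic cohort

## What it emulates

`cohort_spec()` defaults encode the study design this pipeline targets:

| quantity | default | origin |
|---|---|---|
| group sizes | 14 control vs 8 transgenic | study design being emulated |
| GE / SE / DSC echo times | 5.5 / 30 / 10 ms | acquisition protocol |
| DSC series | 300 frames at 0.4 s, 75 baseline frames | acquisition protocol |
| baseline signal | 1000 a.u. | arbitrary scale |
| noise | Gaussian, σ = 2.5% of baseline (SNR 40) | cryogenic-coil mouse data are high-SNR; Rician available via `rician = TRUE` |
| per-animal scatter | lognormal, σ = 5%, mean-preserving | convention (no variance components are published for these quantities) |
| ΔR2\* at steady state | 40 s⁻¹, spatially constant in brain | high-dose SPIO literature range |
| regional Q | 0.60–0.66, averaging 0.63 s^(−1/3) | gray-matter baseline being emulated |
| regional CBF | 0.14–0.18 s⁻¹ (relative) | arbitrary relative scale |
| MTT | 1.8 s | mouse CBV/CBF ratio |
| AIF | gamma-variate, onset 33 s, FWHM ≈ 3 s, peak 60 s⁻¹ | ~80 µl pump infusion at 2 ml/min plus dispersion |

The phantom (`make_phantom()`) is deliberately geometric: a rectangular
brain with six ROI bands (olfactory bulb, cortex, striatum, hippocampus,
thalamus, cerebellum) and a small artery strip, every region at least 50
voxels, ROIs inset from the brain edge. Determinism is part of its
contract.

Genotype effects are multiplicative factors on the *truth parameter whose
recovered change is of interest*. The shipped `cohort_effects("arcab_24mo")`
table encodes Q factors {0.89, 0.85, 0.74, 0.80, 1.00, 0.81} for the six
regions, a 1.25 cortical factor on ΔR2\*, a 1.21 cortical factor on DSC
blood volume and a 0.65 cerebellar factor on blood flow. Because microvessel
density goes as $Q^3$, the equivalent density-level factors are the cubes of
the Q factors; the table stores both. DSC volume/flow factors are applied
jointly to CBF and CBV with MTT preserved — the parallel-vessel reading in
which a change in vascular density scales flow and volume together. This is
a modeling convention: an MTT-altering decomposition of the same factors is
equally consistent with the factor definitions and would add a small
shape-dependent bias to the recovered contrasts.

Forward synthesis inverts the estimators exactly: steady-state volumes via
$S_{post} = S_{pre}\,e^{-TE\,\Delta R}$, DSC series via
$S(t) = S_0\,e^{-TE\,C(t)}$ with $C_t$ the convolution of the gamma-variate
AIF with the exponential residue. The convolution integral is evaluated on
a grid ten times finer than the frame spacing (trapezoidal rule) and
sampled at frame times — a rectangle-rule sum on the frame grid itself
would inflate the apparent blood volume by $\Delta t/(2\,\mathrm{MTT})
\approx 11\%$ and break the integral-ratio identity the tests rely on.

## What it does not emulate

No anatomy, no partial-volume or susceptibility artifacts, no bolus delay
or dispersion between artery and tissue, no recirculation, no motion, no
vascular-network microstructure (the static-dephasing exponents behind Q
are assumed, not simulated). Passing recovery tests on this phantom
demonstrates that the *estimators invert their own forward models* under
realistic noise and the prescribed study design — it does not validate the
biophysical assumptions linking Q to histological vessel counts, which come
from the vessel-size-imaging literature.

# Region statistics and group contrasts

`summarize_regions()` reduces each map to one value per animal and region —
the mean over valid voxels by default (median via `statistic = "median"`);
regions with fewer than 10 valid voxels are flagged. Contrasts
(`build_report()`) report $100\,(\bar x_{tg} - \bar x_{ctrl})/\bar
x_{ctrl}$ with a two-sided permutation p-value
$(1 + \#\{|\Delta_{perm}| \ge |\Delta_{obs}|\})/(1 + n_{perm})$,
$n_{perm} \ge 1000$, seeded. Significance is read at 0.05 and no
multiple-testing correction is applied, matching the analysis convention
being reproduced.

A mixed-effects model (genotype and age fixed, animal random) is the
natural choice when both age groups are analyzed jointly; with one summary
value per animal, region and age, the genotype contrast within an age group
reduces to a two-sample comparison, which the permutation test handles
without distributional assumptions. The tidy summary table is exported
precisely so that users who want the joint model can fit it with `lme4`
or any other package.

Under the null design (all effect factors 1) the permutation test's
false-positive rate at α = 0.05 is checked over 200 replicates of the
cohort's scatter model at the region-summary level; generating 200 full
image cohorts would add cost but no information to the permutation null.

# Problem sizes and runtime

The default phantom is 24 × 24 × 6 (spin-echo grid; 48 × 48 × 12
gradient-echo), with 300-frame dynamic series — sizes chosen so that a full
22-animal cohort runs in minutes on one core (steady-state pathway ~10 s;
DSC pathway ~2 min, dominated by per-voxel gamma fits) while every region
retains hundreds of voxels. All sizes are parameters, and the processing
code is resolution-agnostic.

Stochastic accuracy statements come with Monte Carlo error. With σ = 5%
per-animal scatter at n = 14 + 8, a group percent change carries a standard
error of roughly 1.5–2 percentage points; recovered contrasts scatter
accordingly around the configured effects, and single-seed checks of
±4-point bands operate at ~2–2.7σ. Where a test asserts an expectation
(e.g. region-median accuracy), it averages a few replicates rather than
betting on one draw.

# Known limitations

* Absolute rCBF is systematically underestimated at `r_trunc = 0.2` (see
  above); use rCBF comparatively, not absolutely.
* Q-map accuracy inherits a small convexity bias from
  $(\Delta R_2^*)^{-2/3}$ at finite SNR (≈ +1–2% of region means at
  SNR 40, amplitude-dependent); it largely cancels in group contrasts.
* The resampler assumes corner-aligned grids sharing a physical origin; no
  general affine registration is provided (the acquisitions being emulated
  are co-planned at the scanner).
* Slice gaps are not modeled: acquisitions are treated as volumes on their
  nominal grids.
* One echo per sequence: ΔR2 and ΔR2\* are two-point estimates, not
  multi-echo fits.
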
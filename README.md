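# qvasc

Quantitative vascular MRI of the rodent brain: DSC perfusion mapping and
relaxation-shift-index Q mapping, with a synthetic-cohort simulator for
end-to-end validation.

## What it does, and for whom

Cerebral amyloidosis (as in Alzheimer's disease and its mouse models)
degrades the brain's microvasculature. Hemodynamic MRI read-outs — relative
cerebral blood volume (rCBV) and flow (rCBF) — sense vessels of all sizes
and can miss microvascular loss; the relaxation shift index **Q** isolates
the microvascular signal by combining spin-echo and gradient-echo
relaxation-rate changes measured before and after an intravascular iron
oxide contrast agent reaches steady state.

`qvasc` is for imaging scientists who want a tested, scriptable pipeline
for this four-read-out protocol:

* **Dynamic pathway** (bolus tracking): signal → concentration conversion
  `C(t) = -(k/TE) ln(S(t)/S0)`, bolus-arrival-time detection by piecewise
  linear–quadratic regression, gamma-variate fitting
  `C(t) = A (t-t0)^α e^-(t-t0)/β` over the window
  `[BAT, BAT + 2.5 (TTP - BAT)]`, automatic arterial-input-function (AIF)
  selection by an artery-likelihood search, **rCBV(DSC) = ∫C_t / ∫C_a**
  (closed-form gamma areas), and **rCBF** from truncated-SVD deconvolution
  (`r_trunc = 0.2`).
* **Steady-state pathway**: `ΔR2 = (1/TE) ln(S_pre/S_post)` (spin echo),
  `ΔR2*` likewise (gradient echo), negatives clipped to zero, cubic-spline
  resampling of ΔR2\* onto the ΔR2 grid, then
  **Q = ΔR2 / (ΔR2\*)^(2/3)**, microvessel density **N ≈ Q³ × 329 s/mm²**,
  and **rCBV(ΔR2\*) ≡ ΔR2\***.
* **Region statistics**: ROI summaries per animal, genotype percent
  changes, seeded permutation tests.
* **Synthetic cohorts**: a forward simulator generating pre/post GE/SE
  volumes and 4D DSC series for a two-genotype mouse cohort with
  configurable region-specific effect sizes, so the whole chain is
  validated by parameter recovery.

Volumes and series are NIfTI-1 (via `RNifti`); configs are YAML/JSON;
reports are CSV.

## Worked example

Simulate the default 24-month cohort (14 control vs 8 transgenic animals,
5% biological scatter, SNR 40), run the steady-state Q-mapping pathway and
contrast the genotypes:

```r
library(qvasc)

coh  <- make_cohort(cohort_spec(seed = 1, modalities = "steady_state"))
summ <- analyze_cohort(coh)                     # per-animal region summaries
rep  <- build_report(summ, n_perm = 1000, seed = 2)
subset(rep, map == "q")[, c("region", "mean_ctrl", "mean_tg",
                            "percent_change", "p_perm")]
```

```
         region mean_ctrl mean_tg percent_change   p_perm
 olfactory_bulb     0.673   0.575         -14.57 0.000999
         cortex     0.637   0.539         -15.36 0.000999
       striatum     0.588   0.462         -21.47 0.000999
    hippocampus     0.633   0.502         -20.70 0.000999
       thalamus     0.616   0.610          -1.09 0.621379
     cerebellum     0.674   0.534         -20.79 0.000999
```

Reading the output: control-group regional Q sits around 0.63 s^(-1/3)
(the configured gray-matter baseline); the transgenic group shows
significant Q reductions everywhere except the thalamus — the simulated
effect table configures reductions of 11–26% with no thalamic effect, and
the pipeline recovers that pattern from the images to within sampling
scatter (each contrast carries a standard error of roughly 1.5–2
percentage points at these group sizes). `percent_change` is
`100 (mean_tg - mean_ctrl)/mean_ctrl`; `p_perm` is a two-sided permutation
p-value over genotype relabelings.

The DSC pathway runs the same way with `modalities = "dsc"` (about two
minutes for the full cohort; per-voxel gamma fits dominate), yielding
`rcbv_dsc` and `rcbf` rows. A single command chains everything from a
config file:

```r
run_pipeline(system.file("extdata", "study_arcab_24mo.yaml", package = "qvasc"))
```

which writes `summaries.csv`, `report.csv` and a seed/checksum manifest. A
thin CLI wrapper with `run`/`simulate`/`dsc`/`qmap`/`regions` subcommands
lives at `inst/cli/qvasc.R`.

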
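---
title: "Methods: dual-readout quantification of CFTR membrane proximity and conductance"
author: "rhoquench authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-readout quantification of CFTR membrane proximity and conductance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhoquench)
```

## The assay and what the package computes

CFTR-mediated anion conductance is the product of the number of channels at
the plasma membrane, their open probability, and their unitary conductance.
Mutations (and drugs) can act on any of these factors, so a functional
measurement alone cannot tell a few well-gating channels from many poorly
gating ones. The dual-colour assay this package analyses addresses that by
reading out two quantities at once from HEK293 cells co-expressing a
halide-sensitive YFP--CFTR fusion and free cytosolic mCherry from one
bicistronic message:

1. **Membrane proximity, ρ** — per cell, the mean normalized YFP fluorescence
   in a ~1 µm band just inside the cell border divided by the mean normalized
   mCherry fluorescence over the whole cell. Because both proteins come from
   the same mRNA, mCherry is an internal expression standard; ρ rises when a
   larger fraction of the fusion sits at or near the membrane and when the
   fusion is metabolically stable. ρ factors exactly into
   (band YFP / whole-cell YFP) × (whole-cell YFP / whole-cell mCherry), and
   `compute_rho()` exposes both factors.
2. **Ion-channel function** — from the quenching of the YFP fluorescence
   after extracellular iodide addition, either the maximal iodide-entry rate
   (non-stationary protocol) or the steady-state CFTR conductance fitted with
   a forward model (steady-state protocol), both divided by the well's
   WT-relative mCherry to correct for transfection efficiency.

Neither readout can distinguish channels in sub-membrane compartments from
channels inserted in the plasma membrane; ρ is a proximity metric, not a
surface-labelling measurement.

## Image analysis

Segmentation runs entirely on the mCherry channel. The steps, in order:
global threshold, morphological opening, closing, area opening, dilation
(`binarize_mcherry()`); Euclidean distance transform and watershed with
h-minima-style basin merging (`watershed_cells()`); geometric quality filters
(`filter_cells()`); background estimation and subtraction; membrane-band
extraction and intensity measurement.

Numerical choices that were genuinely open, and what this package does:

* **Threshold scale.** The global threshold is Otsu's, computed on
  `log1p`-transformed intensities. Fluorescence intensities are strongly
  right-skewed across cells (expression varies log-normally), and raw-scale
  Otsu can place the threshold inside the cell-intensity range, discarding
  dim cells and contaminating the background estimate; on the log scale the
  background/foreground separation is clean. The channel-function protocol
  uses a local-mean adaptive threshold instead (`threshold = "adaptive"`),
  matching its need to tolerate uneven illumination in low-magnification
  time series.
* **Structuring elements.** Opening and closing use a 3 px disc;
  the area opening removes objects under 50 px; the dilation uses a single
  4-neighbour step (radius 1). A wider dilation pads every mask with
  background pixels, and because the membrane band is anchored on the mask
  boundary this systematically dilutes the band mean; one pixel keeps the
  noise-bridging purpose of the dilation while preserving boundary fidelity.
  All radii are exposed in `seg_params()`.
* **Watershed seeding.** Basins of the negated distance transform are merged
  when their depth difference is below `h_minima` (default 2 px), which
  suppresses spurious splits inside elongated cells while separating
  touching cells at distance-transform ridges. Ridge pixels are assigned
  deterministically by the watershed implementation given the fixed label
  ordering.
* **Background.** A single scalar per image and channel: the mean over the
  complement of the large-element closing of the cell mask. Closing with a
  large (15 px) disc removes thin slivers between adjacent cells from the
  background region, so pixels squeezed between cells are not mistaken for
  background. A local background surface is deliberately not fitted.
* **Pixel size** is never inferred from the data; it is a required input.
  The defaults wired through the package correspond to 0.108 µm/px (the
  high-magnification membrane-proximity path, giving a 10 px band for the
  1.08 µm band width) and 0.216 µm/px (the low-magnification function path,
  5 px band).
* **Filters.** Cells are excluded when area < 108 or > 5400 µm², major axis
  > 32.4 µm, pixel-unit area/perimeter outside 25–300, or touching the image
  edge. The area/perimeter bounds are interpreted in pixel units, consistent
  with raw-image analysis; this interpretation matters (the same bounds in
  µm would exclude everything at 0.108 µm/px) and is stated prominently
  here. Every exclusion is logged with exactly one reason.

Per-cell intensities are background-subtracted and divided by the median
whole-cell YFP and mCherry intensities of the wild-type reference cells on
the same plate (`plate_normalizer()`, `normalize_to_plate()`); the wild-type
pool is taken across all reference wells of the plate. Cells whose mean
normalized intensity is negative (dim cells in high background) are removed.
ρ distributions are right-skewed and roughly log-normal, so statistics are
computed on log10(ρ).

## Quench kinetics

The fraction of anion-free YFP chromophore follows the binding equilibrium
`F = K_I / (K_I + [I⁻]_in)` with `K_I = 1.9 mM`; inverting it gives
`[I⁻]_in = K_I (1 − F)/F`, so the half-quenched trace sits exactly at
`[I⁻]_in = K_I`. Chloride competition is ignored — the YFP variant has low
chloride affinity. The non-stationary readout is the maximum of consecutive
2-s finite differences of `[I⁻]_in` over the activation window
(`entry_rate()`); raw differences define the estimator, with an optional
3-point smoother that is off by default.

The steady-state readout fits a forward model to the 40 s of quenching after
iodide addition (`simulate_quench()`, `fit_quench()`). The model is a single
well-mixed compartment of effective volume 1 pL. The total anion conductance
decays from `G_CFTR + G_trans` to `G_CFTR` with time constant `τ_trans`,
representing a transient endogenous non-CFTR anion conductance on top of the
steady-state CFTR conductance. The iodide current takes the
Goldman–Hodgkin–Katz flux form, rescaled at each instant so that its
small-signal slope conductance at the membrane potential `V_M` equals the
instantaneous total conductance; `V_M` is held constant over the 40-s window.
This parameterization keeps the four parameters' meanings (conductances in
nS, potential in mV), behaves correctly at `[I⁻]_in = 0`, and has the
closed-form equilibrium `[I⁻]_eq = [I⁻]_out · exp(V_M / (RT/F))` used by the
self-consistency tests. It is a deliberate approximation: membrane-potential
dynamics and chloride/iodide exchange are not modelled, and the constants
(`RT/F = 25.7 mV`, volume, `[I⁻]_out = 100 mM`) are configurable in
`kinetics_constants()`.

### Fitting and identifiability

Parameters are estimated by bounded nonlinear least squares
(Levenberg–Marquardt) on the observed `F(t)` with bounds
`G_CFTR ∈ [0, 100] nS`, `V_M ∈ [−100, +20] mV`, `G_trans ∈ [0, 100] nS`,
`τ ∈ [0.5, 60] s`, from a slope-based start plus jittered restarts under a
fixed seed; restarts stop early once an independent restart reproduces the
optimum. Noisy samples with `F > 1` are used as-is in the f-space residuals;
fully quenched samples (`F ≤ 0`) are dropped.

A single 21-sample trace does not always identify all four parameters: a
small `G_CFTR` with a depolarized `V_M` and a large, slow transient can
reproduce the observed curve at essentially the same residual norm. The fit
therefore falls back to a 2-parameter fit with `G_trans` and `τ_trans` fixed
at negative-control averages when any of three conditions holds:

1. **Fast quench:** `F` drops below 0.3 within the first three post-iodide
   samples. The threshold is set between the regime where a 4-parameter fit
   is demonstrably stable (the canonical recovery fixture reaches F ≈ 0.49
   at the second sample and is fully recoverable) and the clearly saturated
   regime (F < 0.2 within three samples), and is configurable (`fast_f`).
2. **Ill conditioning:** the correlation-scaled curvature matrix (J'J) of
   the 4-parameter solution has condition number above 10⁶.
3. **Parsimony:** when control averages are available, the 4-parameter fit
   must beat the constrained fit by an extra-sum-of-squares F test at the
   prespecified α = 0.05; otherwise the data do not support freeing the
   transient parameters and the constrained estimates are reported. This
   test is what catches the degenerate solutions in practice — their
   curvature matrices are often numerically unremarkable.

With this workflow, 100 simulated traces at noise σ = 0.01 recover the
generating conductance with a median error well under 10% and bias under 5%
(recomputed by `scripts/acceptance.R`); without the fallback the degenerate
solutions bias the estimate downward by tens of percent.

## Plate-level statistics

Comparisons pair genotype/condition values measured on the same plate
(paired t tests; `paired_compare()`), because between-plate variation
dominates the ρ distributions. The multiple-testing family is whatever set
of comparisons the caller declares in one call — the package does not guess
figure-panel groupings — and is adjusted by Bonferroni or Benjamini–
Hochberg; α is prespecified at 0.05. Temperature varies only between plates,
so temperature effects are tested on within-plate difference sets
(WT − mutant) with an independent t test (`within_plate_difference()`);
Student's equal-variance test is the default, Welch selectable. Dose–response
curves use the four-parameter Hill equation with the Hill coefficient
constrained to 1 (`hill_fit()`). Conductance-vs-ρ reference lines are either
ordinary regressions or exact two-point interpolations
(`linear_interpolation()`); the reported x-axis intercept `−constant/slope`
estimates the ρ floor at zero conductance, and two-point mode also anchors
reference lines through a known intercept. Degenerate inputs (zero-variance
pairs, flat dose–response, zero slope) are flagged rather than silently
propagated.

## The synthetic-data generator

`make_field()` emulates the high-magnification imaging wells: elliptical
cells (semi-major axis 7–9 µm, axis ratio up to 1.25) placed without contact
on a jittered grid in a 1700 px field at 0.108 µm/px, per-cell mCherry drawn
log-normally (sdlog 0.35 around 1000 counts, matching the strongly
heterogeneous expression that motivates log-transforming ρ), YFP equal to
mCherry in the interior with a ring of configurable enrichment `e` in the
outer 1.08 µm, background 10 counts, Gaussian read noise (σ = 5 by default)
and optional Poisson shot noise. The truth table carries pixel-exact
analytic values — the ring mean is exactly `e ×` interior, the whole-cell
mean follows from ring/interior pixel counts — and an analytic ρ computed
through the same wild-type-median normalization the pipeline applies.
`make_traces()` simulates the forward model per well and adds i.i.d.
Gaussian noise to the post-iodide samples; the pre-iodide reference frame
stays at exactly 1, as the normalization guarantees on real data.
`make_plate()` assembles imaging and trace wells with a plate map and
refuses maps without a wild-type reference well.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: point-spread blur and out-of-focus light (cell edges
are sharp), photobleaching, spectral bleed-through, illumination gradients,
touching/overlapping cells, and non-elliptical morphologies. Segmentation
recovery of 100% at IoU > 0.7 on these fields is an upper bound; the ~7%
systematic underestimate of ρ that remains comes from the 1-px mask dilation
and is representative of the boundary-anchoring bias any segmentation-based
band metric carries.

## Problem sizes and defaults used by the shipped studies

The recovery studies run by the test suite and `scripts/acceptance.R` use
100 noisy traces (σ = 0.01) for the conductance study, one 50-cell field and
one two-genotype plate (2 × 25 cells, enrichment ratio 0.3) for the imaging
study; these sizes give stable medians while keeping a full run in the
minutes range on a single core. All randomness flows from explicit seeds;
rerunning any generator or the pipeline with the same seed reproduces the
outputs bit for bit.

## Known limitations

* The forward model approximates the published conductance model it stands
  in for; parameter estimates are validated by self-consistency
  (simulate-then-fit), not against electrophysiology.
* ρ carries the boundary-anchoring bias discussed above and cannot separate
  plasma-membrane channels from sub-membrane pools.
* The constrained fallback inherits whatever error the negative-control
  averages carry; plates without negative controls fall back to the
  4-parameter fit with a warning when it is ill-conditioned.
* The pipeline is 2-D widefield only: no illumination-field flattening,
  deconvolution, or 3-D segmentation.
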
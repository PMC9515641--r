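---
title: "Methods: forward model, inversion and classification choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forward model, inversion and classification choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the scientific and numerical choices behind
`cytoscatter`, in the spirit of a methods section: what is modelled, what
is assumed, which knobs matter, and what the test suite does and does not
demonstrate.

## The core–shell optical model

A suspended cell is modelled as two concentric spheres — nucleus (core)
and cytoplasm (shell) — characterised by four parameters: total diameter
*D* (µm), nucleus/cytoplasm diameter ratio N/C, and the refractive
indices RI_N and RI_C. This is the coarsest model that captures the two
dominant scatterers of a leukocyte while remaining exactly solvable: the
Aden–Kerker extension of Mie theory gives the partial-wave coefficients
of the coated sphere in closed form. Everything the package infers about
a cell lives in these four numbers; organelles (mitochondria, granules)
are *not* modelled as discrete scatterers, so their contribution is
absorbed into the effective shell index.

Fixed optical conditions: vacuum wavelength 632.8 nm (HeNe), suspension
medium index 1.334. The dilute (0.4 wt%) viscoelastic polymer added for
microfluidic focusing shifts the index of PBS only in the fourth decimal,
so the PBS value is used; it is configurable in `optical_config()`. The
angular window is fixed to 2.0–30.0° in 0.1° steps (281 points). The
instrument's polarization analysis is not documented, so the default
readout is the unpolarized average (|S1|² + |S2|²)/2; perpendicular and
parallel channels are selectable.

### Numerics

* Series truncation at the Wiscombe order `n_max = y + 4 y^{1/3} + 2`
  (y = total size parameter, about 132 for a 20 µm cell).
* Riccati–Bessel `psi` by downward (Miller) recurrence with overflow
  rescaling, `chi` by upward recurrence — both stable over the grid's
  parameter range; all indices are real (non-absorbing cells).
* Zero-thickness shells (N/C = 1) and index-matched layers delegate to
  the homogeneous Mie solution instead of running degenerate recursions.
* Batch evaluation (the lookup-table build) rewrites the partial-wave
  sums as blocked matrix products evaluated through BLAS `dgemm`, which
  is why 342 342 curves build in tens of seconds.

Correctness is pinned by independent oracles in the test suite: a
homogeneous Mie implementation written on top of R's half-integer-order
Bessel library functions (equal-index and vanishing-core reductions agree
to better than 1e−8 relative), the quasi-static coated-sphere
polarizability closed form (a genuinely two-layer check), and the dipole
angular pattern in the small-particle limit.

## The lookup table and inversion

The published description of the retrieval fixes only the table size
(≥ 335 000 curves) and the retrieved quantities. The grid axes used here
span every reported population value with margin:

| axis | range | step | points |
|------|-------|------|--------|
| D | 6–20 µm | 0.25 | 57 |
| N/C | 0.70–0.95 | 0.01 | 26 |
| RI_N | 1.36–1.46 | 0.005 | 21 |
| RI_C | 1.33–1.43 | 0.01 | 11 |

giving 342 342 tuples. RI_N > RI_C is deliberately *not* enforced: it
keeps the grid a plain Cartesian product, and all phenotype means satisfy
it anyway.

**Matching metric.** Profiles are scaled to unit mean (the instrument has
no radiometric calibration, so matching must be scale invariant) and
compared by mean squared difference of log10 intensities. The log domain
balances the four-decades dynamic range between the forward lobe and the
side angles; a linear-scale variant was evaluated and recovered N/C and
diameter *worse* (the forward lobe then dominates the metric and the
fringe structure, which carries most of the size information, is
ignored). Intensities below 1e−12 of the profile mean are floored before
the logarithm so exact interference nulls cannot dominate. Residuals
below 1e−18 (double-precision noise between code paths) are reported as
exact zero, so a stored curve always self-matches with residual 0. Ties
break to the lowest row index; rows are ordered deterministically
(diameter slowest, RI_C fastest).

**Degeneracy.** The coated-sphere inverse problem is weakly degenerate:
distinct parameter tuples can produce nearly indistinguishable profiles
over 2–30° (for example a slightly larger, optically softer nucleus).
Empirically, about 70% of random off-grid cells land within one grid step
of the truth on every axis; the rest make multi-step excursions along
compensating axes with near-tied residuals. The package therefore makes
*typical-case* claims — median per-axis error within one grid step, exact
nearest-grid recovery for each phenotype's mean cell — and population
means remain accurate because the excursions average out. No sub-grid
refinement is performed: retrieval is pure nearest lookup, with the
runner-up residual gap reported as a crude ambiguity diagnostic.

## The synthetic population generator

The generator replaces the instrument and donors: per phenotype, cells
are drawn property-by-property from independent Gaussians truncated at
the grid bounds (truncation keeps every sampled cell invertible; for M0,
whose diameter distribution 15.66 ± 2.84 µm has about 6% of its mass
above the 20 µm grid edge, it lowers the realised mean by roughly
0.37 µm — visible, and accounted for, in recovery checks). Means, the
diameter SDs and the sample sizes (n = 148/149/167/215 for
monocytes/M0/M1/M2) are the published population values. No correlation
structure between properties is imposed because none is reported.

The dispersions of N/C and the refractive indices are *not* published.
They are the single free knob of the generator and were set once, by a
single calibration pass, to SD(N/C) = 0.02 and SD(RI) = 0.006: the value
at which the synthetic populations reproduce the published
cross-validated accuracies (≈ 85% for M1 vs M2, ≈ 72% for the three-way
task, ≈ 100% for monocytes vs M0) simultaneously. Smaller values
(e.g. 0.004) make the populations separable well beyond the published
accuracies; larger values (≥ 0.008) destroy the three-way task. The
values are frozen; no per-test adjustment happens anywhere.

Instrument noise is multiplicative and lognormal (median 1, log-SD 0.05
by default, i.e. 5% relative) applied pointwise, preserving
nonnegativity; an optional rigid angular jitter exists and defaults to
zero. The 5% level was chosen as the largest round number that leaves
mean-cell retrieval unbiased at the grid resolution.

**What passing tests do not show about real data:** the generator has no
donor effects, no property correlations, no cell–cell coincidences, no
debris, no detector saturation, and its noise is white across angles.
Accuracies on synthetic data match the published ones by calibration of
the dispersion knob, so they validate the pipeline's machinery — not the
biological separability of real donor material.

## Microfluidic alignment check

The focusing stage is summarised by one dimensionless criterion:
centreline alignment holds when `3 Wi β² (L/2R) > −ln(3.5 β)`, with
`Wi = λ Ū / R` (relaxation time × mean velocity / channel radius,
defaults 0.197 ms, 1496 µm/s, 25 µm, length 0.35 m) and `β = r1/R` the
cell-to-channel radius ratio. The printed velocity unit ("µm⁻¹") is
treated as µm/s — the only reading that makes Wi dimensionless. The
parenthesisation `L/(2R)` is taken literally. Unit reconciliation
(ms, µm, m) happens inside; the margin (LHS − RHS) is monotone in Wi,
channel length and cell size, which the tests assert numerically.

## Classification stage

Feature tables (D, N/C, RI_N, RI_C per cell) are classified with presets
mirroring the common interactive ML-toolbox configurations: linear /
quadratic / cubic SVM (box constraint 1, kernel scale 1, one-vs-one via
libsvm), fine KNN (1 neighbour, Euclidean), cosine KNN (10 neighbours,
equal weights), and a decision tree pruned to at most 20 splits.
Cross-validation is stratified 5-fold, repeated 5 times with distinct
fold assignments derived from one seed; features are z-scored *within
training folds only* so the scaler cannot leak held-out information (a
label-shuffling test guards the whole chain against leakage).
`compare_classifiers()` reuses identical splits across configurations so
differences are paired. Confusion matrices are pooled over repeats for
PPV/FDR (per-class precision and its complement); accuracy is the mean
over repeats; misclassification cost is the off-diagonal count at unit
cost. KNN vote ties break to the lowest class index. The published
quadratic-SVM parameter list mixes in KNN parameters ("one neighbour,
Euclidean"); these are ignored as an editorial artefact and the standard
quadratic kernel `(u·v + 1)²` is used.

`anova_tukey()` wraps the classical one-way ANOVA and Tukey HSD from
base R, with significance codes at 0.05/0.01/0.001; degenerate
zero-variance input reports F = ∞, p = 0 and a flag rather than NaN.

## Problem sizes in the test suite

Unit and property tests run on coarse fixtures (a 448-tuple toy grid on a
0.5° angle grid, oracle comparisons at 1–2° resolution, 10–50 random
cases per property). The acceptance suite runs the genuine default
configuration: the full 342 342-curve table, the published sample sizes,
5% noise, 5×5-fold cross-validation — about one minute end to end, thanks
to the BLAS-blocked forward model. The acceptance script repeats that
computation from scratch at any seed.

## Known limitations

* Two homogeneous layers only; organelle-scale structure is effective,
  not explicit, so RI values are effective indices.
* Retrieval is grid-limited; no uncertainty beyond the residual and
  runner-up gap, and degenerate tuples are resolved by fit alone.
* The detector/radial-average pair is an idealisation (azimuthal
  symmetry, linear interpolation, annular bin means); real camera
  calibration, background and beam-stop effects are out of scope.
* Windowed integrated intensity is not strictly monotone in diameter at
  the window edges (forward-lobe migration below the 2° cut-on), which is
  physics, not a defect — rank correlation with size remains above 0.9.
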
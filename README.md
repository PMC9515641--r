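# cytoscatter

Label-free single-cell phenotyping from small-angle light-scattering
profiles (LSPs), for researchers who want to tell monocyte and macrophage
phenotypes (M0 unpolarized, M1 pro-inflammatory, M2 anti-inflammatory)
apart without staining. The package provides the complete desk-scale
analysis chain of a scattering-cytometry experiment: a forward optical
model of the cell, lookup-table inversion of measured profiles into
biophysical properties, a synthetic population generator that stands in
for the microfluidic instrument, a viscoelastic-focusing design check, and
supervised classification with the statistics used to report such
experiments.

## The model

A cell in suspension is idealised as two concentric spheres: the nucleus
(core, refractive index RI_N) inside the cytoplasm (shell, RI_C), with
total diameter *D* and nucleus/cytoplasm diameter ratio N/C. Its far-field
scattering is the exact Aden–Kerker (coated-sphere) extension of Mie
theory: partial-wave coefficients *a_n*, *b_n* feed the amplitude sums

    S1(θ) = Σ_n (2n+1)/(n(n+1)) [a_n π_n(cosθ) + b_n τ_n(cosθ)]
    S2(θ) = Σ_n (2n+1)/(n(n+1)) [a_n τ_n(cosθ) + b_n π_n(cosθ)]

and the recorded LSP is the unpolarized intensity (|S1|² + |S2|²)/2 on a
2–30° grid at 0.1° steps (281 angles, λ = 632.8 nm, medium index 1.334).
The series is truncated at the Wiscombe order and evaluated in compiled
code; building the full default lookup table of 342 342 theoretical
profiles (D 6–20 µm × N/C 0.70–0.95 × RI_N 1.36–1.46 × RI_C 1.33–1.43)
takes well under a minute on one CPU.

Inversion is nearest-match search: observed profiles are scaled to unit
mean, compared in log10 against the table by mean squared difference, and
summarised by the four retrieved properties (`lsp_fit()` with the usual
`coef`/`residuals`/`predict`/`summary` methods). Downstream, feature
tables are classified with repeated stratified cross-validation (SVM,
k-nearest-neighbour, decision tree presets), reported as confusion
matrices with per-class PPV/FDR, and compared across groups with one-way
ANOVA plus Tukey HSD.

## Worked example

```r
library(cytoscatter)

cell <- core_shell_cell(15.66, 0.85, 1.42, 1.39)   # an average M0 cell
prof <- lsp_intensity(cell, optical_config())
prof
#> LSP: 281 angles on [2.00, 30.00] deg, peak intensity 2.398e+06

tab <- build_lookup(grid_spec(diameter = c(14, 17, 0.25),
                              nc_ratio = c(0.80, 0.90, 0.01),
                              ri_nucleus = c(1.40, 1.45, 0.005),
                              ri_cytoplasm = c(1.37, 1.41, 0.01)))
match_lsp(add_noise(prof, noise_model(0.05), seed = 1), tab)
#> Lookup match
#>   Core-shell cell: D = 15.75 um, N/C = 0.850, RI_N = 1.4200, RI_C = 1.3900
#>   residual = 0.0196 (runner-up gap 0.004037)

alignment_satisfied(alignment_params(cell_radius_um = 7.8))
#> Viscoelastic alignment check
#>   Wi = 0.01179, beta = 0.312
#>   criterion: 24.1 > -0.08801  ->  aligned (margin 24.19)
```

The noisy profile of the 15.66 µm cell inverts to the nearest grid point
(15.75 µm) with the other three properties recovered exactly; the
alignment check confirms that a 15.6 µm cell focuses onto the channel
centreline at the default operating point (Wi ≈ 0.0118).

A full simulated experiment — sample labelled populations, forward-model,
add noise, invert, classify, write every artifact — is one call:

```r
run_pipeline(run_config(seed = 42), out_dir = "run1")
```

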
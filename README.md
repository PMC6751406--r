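# brainrheo

Viscoelastic characterization of brain tissue from magnetic resonance
elastography (MRE) and flat-punch nanoindentation.

MRE images externally induced shear waves and reports, per voxel and
actuation frequency, the complex dynamic shear modulus
G(ω) = G′(ω) + i G″(ω): the storage modulus G′ (elastic) and loss modulus
G″ (viscous). Both depend strongly on frequency, so regional comparisons —
across scanners, conditions, or between the living and the post-mortem
brain — need frequency-independent material parameters. `brainrheo` is
built around that identification and the analysis chain surrounding it:

* **Four rheological models** with closed-form moduli: Maxwell
  (G = iωημ/(μ+iωη)), Voigt (G = μ+iωη), springpot (G = κ(iω)^α), and the
  standard linear solid (G = (μ₁μ₂+iωη(μ₁+μ₂))/(μ₂+iωη)), plus their
  quasi-static and infinite-frequency limits and the effective stiffness
  G_eff = (G′² + G″²)^½.
* **`rheofit()`** — multi-start Nelder–Mead identification minimizing the
  normalized mean-square relative misfit
  Φ = (1/2n_ω) Σᵢ [((G′ᵢ−G′ᵢᵐ)/G′ᵢ)² + ((G″ᵢ−G″ᵢᵐ)/G″ᵢ)²],
  reported as the percent error 100·√Φ, with a classed result supporting
  `print`, `summary`, `coef`, `predict`, `plot`, `residuals`, `fitted` and
  `simulate`.
* **A synthetic elastography chain**: five-region nested-ellipsoid brain
  phantoms, plane shear-wave synthesis with complex wavenumber
  k = ω√(ρ/G*), eight-phase-offset demodulation, algebraic Helmholtz
  inversion G* = −ρω²u/∇²u, and the boxplot-style regional statistics
  (median, quartiles, 3×IQR far-outlier fences).
* **Flat-punch indentation conversions**: G = k_s/(4d), G′ = k_d/(3d),
  G″ = ωC_d/(3d) at incompressibility, with the general-ν forms, loading
  curve slope extraction, and the 4δ/(πd) average strain.
* **Myelin-fraction scoring** of stained sections by HSV color
  thresholding, and the stiffness–myelin regression.
* **A post-mortem stiffening report** from the packaged regional moduli
  table (five regions × in vivo / 3 min / 45 min / 16 h timepoints at
  80 Hz).

## Worked example

Fit the standard linear solid to a noisy synthetic in vivo cerebrum sweep:

```r
library(brainrheo)

sw <- make_sweep(region_sls_defaults()$cerebrum, noise_sd = 0.02, seed = 42)
sw
#> Frequency sweep: 5 frequencies, 40 - 100 Hz
#>  frequency_hz storage_kpa  loss_kpa
#>            40   0.9760482 0.2394906
#>            60   1.0341865 0.2967064
#>            80   1.1382067 0.2994320
#>            90   1.1799203 0.3099581
#>           100   1.2055226 0.2923158

fit <- rheofit(sw, "sls", multistart_config(n_starts = 27))
fit
#> Viscoelastic fit: sls model, 5 frequencies
#>   parameters: mu1 = 0.839420, mu2 = 0.608098, eta = 0.001195
#>   phi = 0.0002329  (error 1.53%)
```

The fitted equilibrium stiffness μ₁ ≈ 0.84 kPa, non-equilibrium branch
μ₂ ≈ 0.61 kPa and viscosity η ≈ 0.0012 kPa·s recover the generating
parameters (0.83, 0.60, 0.0012) to within the 2% measurement noise, and
the 1.53% normalized RMS error is on the scale of that noise — an order of
magnitude below the ~10% misfits a structurally wrong model produces.

The stiffening report turns the packaged regional moduli into percent
changes relative to the in vivo baseline:

```r
rep <- build_stiffening_report()
subset(as.data.frame(rep), region == "corpus_callosum" & modulus == "storage")
#>             region modulus   timepoint before_kpa after_kpa percent_raw percent
#> 15 corpus_callosum storage     pm_3min       1.22      1.93    58.19672      58
#> 16 corpus_callosum storage    pm_45min       1.22      2.95   141.80328     142
#> 17 corpus_callosum storage in_situ_16h       1.22      4.57   274.59016     275
```

i.e. the corpus callosum storage modulus rises 58% within three minutes of
death and 142% within 45 minutes — the strongest post-mortem stiffening of
the five regions, versus 8% and 7% in the brainstem.

The full synthetic chain — phantom, wave simulation, demodulation,
inversion, regional statistics, per-region fits and the report — runs with
one seed:

```r
res <- run_pipeline(pipeline_config(n_starts = 8, seed = 2))
res$region_storage        # recovered regional storage medians
coef(res$fits$cerebrum)   # fitted SLS parameters per region
```

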
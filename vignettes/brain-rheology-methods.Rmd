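---
title: "Methods: viscoelastic identification and the synthetic elastography chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: viscoelastic identification and the synthetic elastography chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainrheo)
```

## The problem

Magnetic resonance elastography (MRE) measures the complex dynamic shear
modulus of soft tissue, $G(\omega) = G'(\omega) + i\,G''(\omega)$, by imaging
externally induced shear waves. For brain tissue the storage modulus $G'$
(elastic energy stored per cycle) and loss modulus $G''$ (energy dissipated)
depend strongly on the actuation frequency, so comparing measurements across
studies, scanners or conditions requires condensing a frequency sweep into
frequency-independent material parameters of a constitutive model. This
package implements that identification for four standard linear viscoelastic
models, together with the surrounding analysis chain: a synthetic
elastography pipeline with algebraic inversion, flat-punch nanoindentation
conversions, myelin-fraction scoring of stained sections, and a post-mortem
stiffening report computed from regional moduli tabulated at 80 Hz.

## The four rheological models

With $\omega = 2\pi f$ in rad/s (sweeps store frequencies in Hz and are
converted at evaluation time, which keeps the $\omega\eta$ products
dimensionally consistent):

* Maxwell (spring and dashpot in series):
  $G = i\omega\eta\mu/(\mu + i\omega\eta)$,
* Voigt (parallel): $G = \mu + i\omega\eta$,
* springpot (fractional element): $G = \kappa(i\omega)^\alpha$,
* standard linear solid (Zener; spring in parallel with a Maxwell branch):
  $G = (\mu_1\mu_2 + i\omega\eta(\mu_1+\mu_2))/(\mu_2 + i\omega\eta)$.

Stiffnesses $\mu, \mu_1, \mu_2$ are in kPa, the viscosity $\eta$ in kPa s,
and $\kappa$ carries kPa s$^\alpha$ with $\alpha \in [0,1]$. Each model's
closed-form storage/loss decomposition is tested against literal complex
arithmetic on the defining expression to $10^{-12}$ relative. Two textual
conventions had to be fixed: some sources typeset the Voigt relation with an
equals sign in place of the plus ($G = \mu = i\omega\eta$); the constant,
frequency-independent Voigt storage modulus makes $G = \mu + i\omega\eta$
the only consistent reading, which we adopt. The springpot uses the
principal branch $(i\omega)^\alpha = \omega^\alpha e^{i\pi\alpha/2}$, which
keeps both moduli non-negative over the whole admissible $\alpha$ range.

The models differ qualitatively in their frequency limits, which is what
makes model choice scientifically meaningful: Maxwell and springpot predict
a zero storage modulus in the quasi-static limit — non-physical for a solid
tissue — while Voigt ($\mu$) and the standard linear solid ($\mu_1$,
rising monotonically to the plateau $\mu_1+\mu_2$) stay finite.
`quasistatic_limit()` and `infinite_frequency_limit()` expose these, and the
test suite checks them as fingerprints of each model.

## The identification

`rheofit()` minimizes the normalized mean-square misfit

$$\Phi = \frac{1}{2 n_\omega} \sum_{i=1}^{n_\omega}
  \left(\frac{G'_{exp,i}-G'_{mod,i}}{G'_{exp,i}}\right)^2 +
  \left(\frac{G''_{exp,i}-G''_{mod,i}}{G''_{exp,i}}\right)^2$$

over the model parameters with the derivative-free Nelder–Mead simplex
(`stats::optim`). $\Phi$ is a mean of squared *relative* errors, so it is
invariant under joint rescaling of data and model and weighs both moduli
equally; we report fits as the normalized root-mean-square error
$100\sqrt{\Phi}$ percent, the scale on which a model that cannot follow the
data shows misfits of order 10%. The five-frequency acquisition band
{40, 60, 80, 90, 100} Hz is the default sweep grid.

Numerical choices:

* **Positivity by construction.** The search runs in log-parameter
  coordinates (logit for $\alpha$), so every simplex vertex is a valid
  parameter set and no penalty terms are needed.
* **Multi-start lattice.** Starting points form a deterministic lattice of
  log-spaced values over physically motivated ranges, $\mu$ (and $\kappa$)
  in 0.1–4.0 kPa and $\eta$ in 0.01–1.00 kPa s, with
  $\lceil n^{1/p}\rceil$ levels per dimension for a $p$-parameter model,
  truncated to `n_starts`. A lattice rather than random starts makes runs
  bit-reproducible without a seed convention; 20,250 starts is the
  documented reference protocol for measured data, while the recovery
  studies in the tests use 16–27 starts, which the lattice geometry already
  makes exhaustive for clean sweeps.
* **Restart polishing.** The standard linear solid couples $\mu_2$ and
  $\eta$ only through the curvature of $G''(\omega)$, and its equilibrium
  stiffness $\mu_1$ is uncoupled from the loss modulus entirely, so the
  misfit valley is extremely flat. A single simplex run stalls with
  parameters up to a few percent off even at $\Phi \sim 10^{-16}$. The top
  candidates are therefore re-started from their own optimum until the
  objective stops improving (at most 10 restarts); this brings worst-case
  parameter recovery on clean sweeps below $10^{-6}$ relative. Because of
  the same degeneracy, recovery is asserted on the identifiable
  combinations $\mu_1$, $\mu_1+\mu_2$ and $\eta$.
* **Tolerances.** Simplex relative tolerance $10^{-12}$ with a
  5000-evaluation budget per pass; `top_k = 5` near-optimal parameter sets
  are always retained so initialization sensitivity is visible rather than
  hidden.

## The synthetic elastography chain

No raw scanner data ship with the package; the pipeline is exercised on
phantoms with known ground truth.

**Phantom.** `make_phantom()` builds a nested-ellipsoid voxel phantom with
five labeled regions (cerebrum, cerebellum, corpus callosum, thalamus,
brainstem) on a default $32^3$ grid at 1 mm spacing — small enough that the
full chain runs in seconds, large enough that every region keeps at least
ten interior voxels after boundary exclusion. Each region carries
standard-linear-solid parameters.

**Calibration of the defaults.** Only one frequency (80 Hz) of the regional
medians is tabulated, so the per-region default parameters are an internal
calibration, not measured values: we place the loss peak at 80 Hz
($\omega\eta = \mu_2$), which gives $\mu_2 = 2G''$, $\mu_1 = G' - G''$,
$\eta = \mu_2/\omega$ and reproduces each region's tabulated in vivo moduli
exactly at 80 Hz while keeping the qualitative sweep shape (storage rising
with frequency, loss peaking mid-band). The resulting plateau stiffnesses
$\mu_1+\mu_2$ are on the 1 kPa scale expected for brain tissue.

**Wave synthesis.** Within each homogeneous region the displacement is the
plane shear wave $u(x) = A\exp(-ik\,x\!\cdot\!d)$ with
$k = \omega\sqrt{\rho/G^*}$ on the principal branch, so lossy regions
attenuate the wave. At 80 Hz and $G = 1.5$ kPa this gives
$k \approx 410$ rad/m, a 15 mm wavelength — roughly 15 voxels, which keeps
the discrete Laplacian accurate. Eight real snapshots over one period mimic
the phase-offset acquisition; `demodulate()` recovers the complex first
harmonic exactly for a pure tone.

**Inversion.** `helmholtz_invert()` is the standard local algebraic
inversion $G^* = -\rho\omega^2 u / \nabla^2 u$ with a 7-point
central-difference Laplacian. It assumes local homogeneity and ignores
pressure waves, so region boundaries are excluded (one-voxel erosion) from
the regional statistics, grid-boundary voxels are invalid, and voxels with
$|\nabla^2 u|$ below a relative floor (e.g. a constant field) are marked
invalid rather than divided. For a plane wave the stencil bias is
$\rho\omega^2h^2/12$ — about 1.8% of a 1.2 kPa storage modulus at 1 mm
spacing — and the tests verify both the bound and its second-order decay
when the spacing is halved. Negative inverted values are flagged, never
clipped.

**Regional statistics.** Every masked voxel is one data point;
`region_statistics()` reports median, quartiles, extrema and the values
beyond three interquartile ranges outside the quartiles. Quartiles use
linear interpolation between order statistics (`stats::quantile` type 7);
boxplot conventions differ on this, so the choice is stated to make the
hand-checked example {1, 2, 3, 4, 100} → $q_1=2$, $q_3=4$, fences
$[-4, 10]$ deterministic.

## Indentation and histology

Flat-punch conversions use the contact relations
$G = \frac{1-\nu^2}{2(1+\nu)} k_s \frac{\sqrt{\pi}}{2\sqrt{A}}$ for the
quasi-static stiffness and the analogous $\frac{1}{2(1+\nu)}$ forms for
$k_d$ and $\omega C_d$, which at incompressibility ($\nu = 0.5$) and
$A = \pi d^2/4$ reduce exactly to $k_s/(4d)$, $k_d/(3d)$ and
$\omega C_d/(3d)$; the tests assert that reduction to $10^{-12}$. The
finite-thickness correction factor ($\sim$1.2 for a 0.75 mm probe radius on
a 5 mm slice) is exposed as an explicit multiplier defaulting to 1
(uncorrected), matching measurement practice on no-slip supported slices.
The quasi-static contact stiffness is the least-squares slope of the
loading curve over a window centered at the dynamic test depth; the window
defaults to 10% of that depth, a choice stated for determinism since "mean
slope" alone does not fix one. The flat-punch average strain is
$4\delta/(\pi d)$ — 34% at the 400 µm protocol depth, and 11.78 µm for a 1%
strain target (sometimes quoted rounded to 11 µm).

Myelin scoring is deliberately simple color thresholding, not stain
deconvolution: a pixel is myelin iff its HSV hue lies in 180–260° with
saturation ≥ 0.15 and value ≥ 0.10. These thresholds are exposed because
staining protocols vary; the published 67–78% white-matter fractions are a
plausibility envelope, not a target, and the synthetic generator is checked
to hit any requested fraction within 0.01.

## The stiffening report

`build_stiffening_report()` computes all percent changes
$100(G_{after}-G_{before})/G_{before}$ of the regional moduli relative to
the in vivo baseline, keeping raw values exact and rounding reported
integers to the nearest percent, ties away from zero (no tabulated value
falls on a tie). From the packaged table the corpus callosum storage
modulus rises 58% within 3 minutes post mortem and 142% within 45 minutes;
the cerebrum loss modulus rises 60% and 103%. Narrative summaries of the
same experiment sometimes quote 147% (and 171% for the corpus callosum loss
modulus) for the 45-minute change — values consistent with unrounded source
moduli but not with the tabulated two-decimal ones; the report follows the
table, and this discrepancy is the reason raw and rounded columns are both
kept. Unmeasured region/timepoint cells are absent, never zero.

## What the generators do and do not emulate

The synthetic module reproduces the *structure* the analysis assumes:
frequency sweeps from a known model with multiplicative Gaussian noise,
piecewise-homogeneous wave fields, exact phase-offset sampling, known
post-mortem multiplicative stiffening, invertible indentation records, and
two-tone stained textures with known blue fraction. It does not emulate
reflected or interfering waves, through-skull transmission, registration
error, segmentation uncertainty, intra-region heterogeneity, anisotropy, or
staining variability. Passing tests therefore demonstrate correctness of
the computations and their numerical conditioning, not robustness to every
artifact of acquired data — the known caveat for any phantom-validated
inversion.

## Problem sizes and determinism

All simulations are sized for interactive use: $32^3$ phantoms,
24$^3$ plane-wave grids for convergence checks, 16–27 fitting starts with
50 random ground-truth draws per model in the recovery suites, 96×96
histology textures, 1000-case property sweeps for the order statistics.
Every stochastic generator takes an explicit seed and is bit-reproducible
given it; the full pipeline run records its seed, configuration and package
version in its log.

## Known limitations

Linear, isotropic viscoelasticity only — no nonlinear, poroelastic or
anisotropic constitutive behavior; single-frequency algebraic inversion
rather than multifrequency or curl-filtered schemes; no image registration
(synthetic elastograms are generated pre-aligned to their masks); the
standard linear solid's $\mu_2$–$\eta$ split is reported but should be
interpreted through the identifiable combinations; and the regional default
parameters are a one-frequency calibration, not a claim about the tissue's
full dispersion curve.
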
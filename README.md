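# qmrcart

**Quantitative MRI–informed computational modelling of articular cartilage.**

Articular cartilage degenerates mechanically before it degenerates visibly.
Quantitative MRI (qMRI) maps the tissue's relaxation time constants — T1,
T1&rho;, T2, T2\* — pixel by pixel, and those constants co-vary with the
tissue's composition: interstitial fluid, collagen fibrils and
proteoglycans. `qmrcart` closes the loop from image to mechanics: it fits
relaxation maps, converts them into depth-resolved volume fractions
&Phi;<sub>f</sub>, &Phi;<sub>co</sub>, &Phi;<sub>pg</sub>, feeds those into a
fiber-reinforced hyperelastic constitutive model with osmotic swelling, and
predicts (or inversely fits) the tissue's relaxed response to confined
compression. It is written for researchers in cartilage biomechanics and
quantitative musculoskeletal imaging.

## The model in brief

* **Relaxometry.** Per-pixel least-squares fits of
  `S(TI) = |A(1 − 2e^(−TI/T1) + e^(−TR/T1))|`,
  `S(TSL) = A e^(−TSL/T1ρ)`, `S(TE) = A e^(−TE/T2) + B`,
  `S(TE) = A e^(−TE/T2*)`, with an echo-time cutoff TE ≤ 60 ms for the
  multi-echo decays, adjusted-R² quality control and boundary-pixel
  exclusion.
* **Composition.** Exponential calibrations `Tx(φ) = a e^(bφ) + c` with
  clamped monotone inverses; rational depth profiles
  `(αz³+βz²+γz+δ)/(εz+1)`; weighted combination
  `Φ_ξ(z) = Σ_x w_Tx^ξ φ̃_ξ^Tx(z)` with `Σ_x w_Tx^ξ = 1`; proteoglycan as the
  saturation remainder `Φ_pg = 1 − Φ_f − Φ_co ≥ 10⁻⁶`.
* **Constitutive model.** Isochoric energy
  `Ψ̄ = Φ_co Σᵢ k₁[exp(k̃₂(Ī₄ᵢ−1))/k̃₂ + (K̄ᵢ^k̃₃ − 1)/k̃₃] + Φ_pg a₀(Ī₁−3)`
  over eight arcade-oriented fiber families with dispersion-weighted
  structural tensors, plus the osmotic multiplier
  `π = a₀((1−Φ_s)/(J−Φ_s))^(2Φ_f a₁) − a₀`, which diverges at the compaction
  point `J → Φ_s`. Cauchy stress is the derivative of this energy (analytic,
  verified against central differences). Default global constants:
  k₁ = 0.6 MPa, k₂ = 50, k₃ = 25, a₀ = 0.35 MPa, a₁ = 5, w = 0.3, with
  modality weights (0.41, 0.42, 0.16, 0.01) for fluid and
  (0.31, 0.12, 0.11, 0.46) for collagen.
* **Mechanics.** A layered series column replaces the 3-D FE mesh for the
  confined-compression geometry; equilibrium (equal layer stress, prescribed
  mean strain) is solved by nested Newton iterations to 10⁻¹² residual, over
  a 20-step, 1%-per-step loading protocol; goodness-of-fit is reported as
  R² (squared Pearson) and Ω = 100·‖y−f‖/‖y‖. Global constants are
  identified by bound-constrained multi-start optimization over all samples
  simultaneously.

Everything is testable offline: `phantom_qmri_stack()` and
`phantom_sample()` generate seeded synthetic image stacks and stress curves
with known ground truth.

## Worked example

```r
library(qmrcart)

# 1. synthetic qMRI stack -> fitted T2 map
spec <- phantom_spec()                       # 64x64, noise-free defaults
ph   <- phantom_qmri_stack(spec)
map  <- build_parameter_map(ph$stacks$T2, ph$protocols$T2, ph$mask)
map
#> <parameter_map> T2 64x64, 3364 fitted pixels, median 57.5 ms, median adj. R2 1

# 2. depth-resolved composition (idealized reference profiles)
wilson_reference_profile(seq(0, 1, 0.25))
#>      z phi_f phi_co phi_pg
#> 1 0.00 0.850  0.100  0.050
#> 2 0.25 0.803  0.119  0.078
#> 3 0.50 0.762  0.150  0.088
#> 4 0.75 0.728  0.194  0.078
#> 5 1.00 0.700  0.250  0.050

# 3. forward confined-compression simulation
z    <- seq(0, 1, 0.01)
ref  <- wilson_reference_profile(z)
comp <- composition_field(z, ref$phi_f, ref$phi_co)
mesh <- build_column(comp, material_parameters(), thickness = 4.2, n_layers = 20)
sol  <- simulate_protocol(mesh)              # 20 relaxed states, 1%..20%
sol
#> <equilibrium_solution> 20 levels to 20%, stress -0.07047..-4.661 MPa
stiffness_at(sol, 0.15)                      # tangent modulus at 15% strain
#> [1] 32.6       # MPa; secant definition gives 15.96 MPa
```

The fitted map reproduces the phantom's depth-graded truth to ~10⁻⁶
relative; the simulated curve is monotone and convex in |stress| (stiffening
toward the compaction point), and the tangent/secant gap at 15% reflects
that convexity.

The package also ships the reference characterization of eight human
osteochondral samples (`cartilage_cohort()`): mean T1 713.5 ms, T2 63.8 ms,
T2\* 35.6 ms, measured stiffness at 15% strain 1.53 ± 0.68 MPa (per-sample
range 1.02–3.05), and model-vs-measurement goodness of fit R² 0.966 ± 0.03
(0.904–0.993) with Ω ranging 20–47%. `cohort_summary()` recomputes these
from the per-sample table.

A command-line front end (`exec/qmrcart`) exposes the same pipeline as
`phantom`, `fit-maps`, `compose`, `simulate`, `fit-global` and `run`
subcommands for shell use.

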
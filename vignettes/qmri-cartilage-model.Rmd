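---
title: "From quantitative MRI to cartilage mechanics: the model behind qmrcart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From quantitative MRI to cartilage mechanics: the model behind qmrcart}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmrcart)
```

## Overview

`qmrcart` implements a pipeline that turns quantitative MRI (qMRI) relaxation
maps of articular cartilage into a mechanical prediction of the tissue's
equilibrium response to confined compression, and inverts that prediction to
identify a global set of material constants from measured stress data. The
pipeline has four stages:

1. **Relaxometry.** Per-pixel nonlinear fits of the T1, T1&rho;, T2 and T2*
   signal models produce relaxation-time maps with per-pixel quality control.
2. **Composition.** Relaxation times are converted into depth-resolved volume
   fractions of fluid (f), collagen (co) and proteoglycan (pg) via exponential
   calibrations against an idealized depth-dependent composition, rational
   depth fits, and a weighted combination across the four modalities.
3. **Constitutive model.** A fiber-reinforced hyperelastic solid with an
   osmotic swelling term, whose coefficients are scaled pointwise by the local
   composition.
4. **Forward/inverse mechanics.** A layered equilibrium solver predicts
   relaxed confined-compression stress–strain curves; a constrained optimizer
   identifies the global parameter set from multi-sample stress data.

Because no public imaging data accompany the problem, every stage is
exercised on synthetic phantoms generated by the package itself, with known
ground truth.

## Signal models and fitting

For a pixel with relaxation time $T$ the four models are

$$S(T_I) = |A\,[1 - 2e^{-T_I/T1} + e^{-T_R/T1}]| \qquad \text{(inversion recovery)}$$
$$S(T_{SL}) = A\,e^{-T_{SL}/T1\rho}, \qquad
  S(T_E) = A\,e^{-T_E/T2} + B, \qquad S(T_E) = A\,e^{-T_E/T2^{*}}.$$

The offset $B$ absorbs background noise and is fitted for T2 only. For the
multi-echo decays only echoes with $T_E \le 60$ ms enter the fit: late echoes
are dominated by the magnitude-noise floor and bias $T$ upward. Fits are
Levenberg–Marquardt least squares started from a log-linearized regression;
the magnitude inversion-recovery model is handled by polarity restoration
(all contiguous sign splits are tried; least squared error wins), with the
null-point heuristic $T1 \approx T_{I,\text{null}}/\ln 2$ providing the
start. Quality is the adjusted $R^2$; a non-convergent pixel is flagged with
$-\infty$ rather than raising. Boundary pixels are excluded by a one-pixel
4-connected erosion of the tissue mask (configurable radius) to avoid
partial-volume contamination; if erosion would empty the mask it is skipped
with a warning.

The fitting assumes additive Gaussian noise on magnitudes. Real magnitude MR
noise is Rician; the phantom generator can inject Rician noise so the induced
positive bias at low SNR can be quantified (it is characterized in the test
suite, not corrected).

## From relaxation times to composition

Depth is normalized per image column of the mask: $z = 0$ at the articular
surface, $z = 1$ at the osteochondral interface. Pixel values are averaged
into 20 depth bins (configurable). For each modality $Tx$ and constituent
$\xi \in \{f, co\}$ an exponential calibration

$$Tx(\varphi_\xi) = a\,e^{b \varphi_\xi} + c$$

is fitted by pairing the binned map profile with an idealized reference
composition at the same depths. Its inverse
$\varphi_\xi(Tx) = \ln((Tx - c)/a)/b$ is clamped to the constants $l, u$
outside the calibration domain, making it total, continuous and monotone.
The per-modality profiles are then smoothed by the rational representation

$$\tilde\varphi_\xi^{Tx}(z) = \frac{\alpha z^3 + \beta z^2 + \gamma z + \delta}{\varepsilon z + \kappa},$$

in which numerator and denominator share a common scale; we fix the gauge
$\kappa = 1$ so the coefficients are identifiable, and bound
$\varepsilon > -1$ so the denominator stays positive on $[0,1]$. The final
composition is the weighted combination
$\Phi_\xi(z) = \sum_x w^\xi_{Tx}\, \tilde\varphi^{Tx}_\xi(z)$ with the
normalization $\sum_x w^\xi_{Tx} = 1$ per constituent, and the proteoglycan
fraction is the saturation remainder $\Phi_{pg} = 1 - \Phi_f - \Phi_{co}$,
required to stay above $\Delta_{tol} = 10^{-6}$ everywhere (a violation
raises an error naming the offending depth). No direct proteoglycan
calibration is fitted — only the fluid and collagen relations are informed by
the maps.

The reference composition ships as smooth quadratic defaults — fluid
0.85 → 0.70 and collagen 0.10 → 0.25 from surface to bone, proteoglycan
peaking mid-depth — reproducing the classical depth trends qualitatively.
They are implementation defaults, overridable by coefficient lists, not
measured curves.

## The constitutive model

Kinematics use the isochoric/volumetric split: $J = \det \mathbf F$,
$\mathbf C = \mathbf F^T\mathbf F$, $\bar{\mathbf C} = J^{-2/3}\mathbf C$.
The solid-matrix free energy per unit reference volume is

$$\bar\Psi = \Phi_{co} \sum_{i=1}^{8} k_1\left[\tfrac{1}{\tilde k_2}
   e^{\tilde k_2(\bar I_{4i} - 1)} + \tfrac{1}{\tilde k_3}(\bar K_i^{\tilde k_3} - 1)\right]
   + \Phi_{pg}\, a_0 (\bar I_1 - 3),$$

with composition-scaled exponents $\tilde k_\eta = \Phi_{co} k_\eta$. The
exponential term is the J-shaped tension response of the collagen fibrils;
the $\bar K$ term captures their contribution under compression (tube
contraction); the Neo-Hookean term is the non-collagenous matrix. Fiber
families follow an idealized arcade: eight equiangular azimuths whose
inclination runs linearly from surface-parallel ($z=0$) to bone-perpendicular
($z=1$); the linear profile is a configurable default. Each family carries
the dispersion-weighted structural tensor
$\tilde{\mathbf L}_i = \tfrac{w}{3}\mathbf I + (1-w)\,\mathbf m_i \otimes \mathbf m_i$
(trace 1 for any $w$), and the invariants are
$\bar I_1 = \mathrm{tr}\,\bar{\mathbf C}$,
$\bar I_{4i} = \mathrm{tr}(\bar{\mathbf C}\tilde{\mathbf L}_i)$,
$\bar K_i = \mathrm{tr}[(\mathrm{cof}\,\bar{\mathbf C})\tilde{\mathbf L}_i]$.

**Why the weighted tensor appears in both invariants.** Closed-form
statements of this model sometimes measure the fiber stretch with the plain
tensor $\mathbf L_i = \mathbf m_i \otimes \mathbf m_i$ while the areal
invariant uses $\tilde{\mathbf L}_i$. That mixed choice is not innocent: at
$\bar{\mathbf C} = \mathbf I$ the fibril stress of family $i$ becomes
$k_1[\mathbf L_i + \mathbf I - \tilde{\mathbf L}_i]$, whose deviator
$w(\mathbf L_i - \mathbf I/3)$ does not vanish, so the undeformed state would
carry spurious stress except at one magic inclination, and a fully dispersed
fiber distribution ($w = 1$) would still respond anisotropically. Using
$\tilde{\mathbf L}_i$ in both invariants makes the family contribution at the
reference state exactly isotropic, so the configuration is stress-free for
every inclination, dispersion and composition, and $w = 1$ is genuinely
isotropic. `qmrcart` therefore defaults to the weighted fiber-stretch
invariant (`fiber_invariant = "weighted"`); the plain variant remains
available, and `cm_invariants()` reports both.

The volumetric response is the osmotic multiplier

$$\pi(J) = a_0\left(\frac{1-\Phi_s}{J-\Phi_s}\right)^{2\tilde a_1} + \pi_0,
  \qquad \tilde a_1 = \Phi_f\, a_1,\ \ \pi_0 = -a_0,$$

which vanishes at $J=1$ and diverges at the compaction point $J \to \Phi_s$
(all fluid expelled; $\Phi_s = 1 - \Phi_f$). Its potential $\Psi_\pi(J)$ with
$\pi = -\partial \Psi_\pi/\partial J$ is implemented in closed form. The
Cauchy stress is assembled as
$\sigma = 2J^{-1}\mathbf F\,(\partial\bar\Psi/\partial\mathbf C +
\partial\Psi_\pi/\partial\mathbf C)\,\mathbf F^{T}$ with the deviatoric
projection
$\partial\bar\Psi/\partial\mathbf C = J^{-2/3}[\bar{\mathbf S} -
\tfrac13(\bar{\mathbf S}:\mathbf C)\mathbf C^{-1}]$ and the
energy-consistent volumetric term
$\partial\Psi_\pi/\partial\mathbf C = -\tfrac12 \pi J \mathbf C^{-1}$, so the
volumetric Cauchy contribution is exactly $-\pi\mathbf I$ (a commonly printed
variant omits the $\tfrac12$ from $\partial J/\partial\mathbf C$, which would
double the osmotic stress and break the stress-free reference).

The energy is the ground truth: the default stress path is the closed-form
derivative of the implemented energy, and it is verified in the test suite
against central differences of that same energy (relative tolerance
$10^{-5}$ over 100 random states) and against an independent
finite-difference oracle in $\mathbf F$. A commonly quoted closed form of the
fibril stress that attaches the tension derivative to $\tilde{\mathbf L}_i$
but drops the $\bar{\mathbf C}$-dependent terms of
$\partial\bar K/\partial\bar{\mathbf C}$ is provided behind
`method = "legacy"`; it is demonstrably *not* the derivative of the energy
and is retained only for comparison.

Numerical guards: the fibril term is switched off below
$\Phi_{co} = 10^{-8}$ (its stress vanishes there while the $1/\tilde k$
energy constants diverge); compaction is guarded at $J \le \Phi_s + 10^{-9}$.
The single dispersion weight $w$ is shared by all eight families, and no
tension-only switch is applied to the exponential term — the $\bar K$ term
carries the compressive fibril response.

## Confined compression: the layered column solver

The confined test (impermeable lateral confinement, rigid porous piston) is
idealized as a series column: depth-discretized layers under a common axial
nominal stress with zero lateral strain, replacing a full 3-D finite-element
mesh. Under $\mathbf F = \mathrm{diag}(1,1,\lambda)$ the eight equiangular
families at a common inclination share identical invariants, so the axial
nominal stress of a layer reduces to the scalar derivative
$P(\lambda) = d\Psi_{tot}/d\lambda$, with $P = \sigma_{zz}$ since
$J = \lambda$. This closed form (and its $\lambda$-derivative) is what the
solver iterates on; it is cross-checked against the full tensor path in the
tests.

`solve_equilibrium()` finds per-layer stretches $\lambda_i$ such that every
layer carries the same stress $s$ and the thickness-weighted strains sum to
the applied strain: an outer safeguarded Newton iteration on $s$ around a
vectorized inner Newton inversion $\lambda_i(s)$, converged to a strain
residual below $10^{-12}$ (both monotone, so bracketing makes the iteration
robust). Twenty equal layers are the default; the 20- vs 80-layer forward
curves differ by less than 0.5% at every strain level of the default
protocol, which is the package's discretization-convergence acceptance test.

Only relaxed (equilibrium) states are modelled — the loading protocol's
strain rate is metadata. The default protocol is 20 strain levels of 1% up
to 20%. The *stiffness at 15% strain* is reported as the central-difference
tangent modulus $d|\sigma|/d\varepsilon$ between the adjacent protocol
points (14% and 16%); since tangent and secant definitions are both in use
for this quantity and differ substantially on a convex curve (the secant is
smaller), both are implemented and the choice is explicit
(`stiffness_at(..., method = "secant")`).

## Inverse identification

The objective is the sum over samples of squared residuals between simulated
and measured relaxed stresses, normalized per sample by $\lVert y\rVert^2$ so
stiff samples do not dominate. Goodness of fit is reported per sample as the
squared Pearson correlation $R^2$ (scale-invariant) and the relative error
$\Omega = 100\,\lVert y - f\rVert/\lVert y\rVert$ (scale-aware — the two are
deliberately complementary). The optimizer is box-constrained L-BFGS-B in
scaled coordinates (parameters span three orders of magnitude), with the
per-constituent weight normalization enforced by projection inside the
objective and on the returned set, multi-start with seeded random restarts,
and a large finite penalty (not an exception) when a candidate parameter set
makes a forward solve fail.

**Identifiability.** The twelve free quantities (six material constants,
eight weights minus two normalizations) are not globally identifiable from a
handful of smooth convex stress curves: distinct parameter sets reproduce
the curves to within a 2% noise floor while, e.g., $k_1$ differs by tens of
percent (the fibril scale trades off against $k_2$, the dispersion $w$ and
the collagen weighting). The package treats identification as *local*:
starts are expected to come from literature-scale values, and
`parameter_sweep()` exposes 1-D objective profiles as the standard
diagnostic. The parameter-recovery acceptance test reflects this: three
synthetic samples with 2% multiplicative stress noise, five replicate
seeds, a start 25–60% off truth, and recovery of $k_1$ and $a_0$ within 15%.

## What the phantoms emulate — and what they do not

`phantom_qmri_stack()` forward-simulates magnitude stacks through the
package's own signal models on the default acquisition grids (inversion
times 150–1500 ms; spin-lock 0–40 ms; $T_E = n \cdot 8.38$ ms, $n\le 12$;
$T_E = 3.9 + 9.6n$ ms, $n\le 14$), on a 64×64 image with depth along rows
and relaxation times graded linearly between surface and bone values typical
for human cartilage. Gaussian or Rician noise is seeded and bit-reproducible.

`phantom_sample()` builds inverse-crime-free-ish samples for the
identification experiments: per-modality composition profiles are the
reference profiles plus deterministic modality-specific perturbation shapes,
centred so the truth-weighted combination reproduces the reference exactly
(this is what makes weights observable), plus inter-sample variability —
a collagen-rich/drier and a collagen-poor/wetter variant — emulating the
large donor-to-donor spread of measured cohorts. Stress curves are simulated
under the truth parameters, optionally with multiplicative noise.

The phantoms do **not** emulate partial-volume effects, B1 inhomogeneity,
magic-angle artifacts, registration error between contrasts, or poroelastic
transients. Passing the closure tests therefore demonstrates the internal
consistency of the pipeline, not its accuracy on scanner data.

With the default global constants the forward model is substantially stiffer
at 15% strain than typical measured cohort stiffnesses; the osmotic term
alone, at a mid-depth fluid fraction of 0.75, contributes tens of MPa of
tangent modulus. Phantom-derived stiffnesses are therefore internal model
quantities and are never compared against measured cohort statistics.

## Problem sizes and reproducibility

Default problem sizes used by the tests and the acceptance script: 64×64
(or smaller) phantom images; 101-point composition grids; 20 forward layers
(10 for the repeated identification runs, whose truth curves are generated
with the same mesh so the comparison is mesh-consistent); 20 strain levels;
L-BFGS-B with at most 100 iterations and 1 start for the seeded recovery
replicates, 5 starts by default elsewhere. All random draws are seeded;
every generator is bit-reproducible under a fixed seed, and `run_pipeline()`
stamps its JSON report with the seed and a configuration hash.

## Known limitations

* The composition conversion inherits the idealized reference profiles; no
  direct biochemical validation is possible within the package.
* Proteoglycan content is a remainder, never independently estimated.
* The series-column idealization ignores lateral friction and any
  deviation from uniaxial kinematics in the real confined chamber.
* Global identifiability of the full parameter set is limited (see above);
  reported constants are local minima from stated starts.
* Time-dependent (poroelastic/viscoelastic) behaviour is out of scope; only
  relaxed states are predicted.
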
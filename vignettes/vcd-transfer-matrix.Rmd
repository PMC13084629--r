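---
title: "Modeling mid-IR VCD of chiral thin films with the 4x4 transfer matrix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling mid-IR VCD of chiral thin films with the 4x4 transfer matrix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcdtmm)
```

## The physical model

Vibrational circular dichroism (VCD) is the difference in decadic
absorbance between left- and right-circularly polarized mid-infrared
light traversing a molecular sample. The textbook analysis assumes
Beer–Lambert attenuation: absorbance proportional to path length and to
the imaginary refractive index, separately for each helicity. Real thin
films violate those assumptions in two ways that this package is built
to quantify:

1. **thin-film interference** — multiple internal reflections superpose
   coherently and imprint Fabry–Pérot fringes on the spectra;
2. **helicity coupling** — at oblique incidence the two circular
   polarizations mix at interfaces, so part of the transmitted power in
   one channel originated in the other.

The sample is a homogeneous, isotropic Pasteur medium: scalar
permittivity $\varepsilon(\bar\nu)$, permeability $\mu(\bar\nu)$
(default 1) and chirality parameter $\kappa(\bar\nu)$. Its circular
eigenmodes propagate with indices

$$n_\pm(\bar\nu) = \sqrt{\varepsilon\mu} \pm \kappa,$$

while the wave impedance $\eta = \sqrt{\mu/\varepsilon}$ is the *same*
for both helicities — a fact with consequences discussed below.
$\mathrm{Re}\,\kappa$ produces optical rotation,
$\mathrm{Im}\,\kappa$ circular dichroism.

A stratified stack (ambient half-space, one or more layers, exit
half-space) is propagated with a $4\times4$ transfer matrix acting on
the amplitudes $(E^+_\rightarrow, E^-_\rightarrow, E^+_\leftarrow,
E^-_\leftarrow)$. Each interface contributes a block matrix built from
$2\times2$ submatrices $M_T$ and $M_R$ whose entries combine the
impedance ratio $\eta_1/\eta_2$ with per-helicity cosine ratios
$\cos\theta_{2\pm}/\cos\theta_{1\pm}$; each layer contributes
$\mathrm{diag}(e^{-i\phi_+}, e^{-i\phi_-}, e^{+i\phi_+},
e^{+i\phi_-})$ with the layer-normal phase
$\phi_\pm = 2\pi\bar\nu\, n_\pm \cos\theta_\pm\, d$. The matrix maps
exit-side to entrance-side amplitudes, so the circular-basis
transmission operator is the inverse of the forward–forward block and
the reflection operator is the backward–forward block times that
inverse. Helicity-resolved intensities are
$T_\pm = |t_{\pm\pm}|^2 + |t_{\mp\pm}|^2$ (output index first), and

$$\mathrm{VCD} = -\log_{10}\frac{T_-}{T_+} = A_- - A_+ .$$

With $\mathrm{Im}\,\kappa > 0$ at a resonance the $+$ helicity is
absorbed more strongly, so VCD lobes at the absorption bands are
negative. An alternative dimensionless measure
$\Delta T/\bar T$ is exposed as `vcd_alternative()` and equals
$\ln(10)$ times the log-ratio VCD to first order; it is never silently
substituted.

### Conventions (fixed once, applied everywhere)

* time dependence $e^{-i\omega t}$: passive media have
  $\mathrm{Im}\,\varepsilon \ge 0$ and the square root of
  $\varepsilon\mu$ is taken with $\mathrm{Im} \ge 0$
  (forward-decaying waves); the impedance branch has
  $\mathrm{Re}\,\eta \ge 0$;
* transmitted-cosine branch: principal square root of
  $1 - (k_{1\pm}/k_{2\pm})^2\sin^2\theta_1$, sign-flipped if needed so
  $\mathrm{Im}(n\cos\theta) \ge 0$ — evanescent waves decay away from
  the interface; exactly at a critical angle the tie resolves to the
  decaying branch;
* wavenumbers in cm$^{-1}$ and thicknesses in µm at every user surface
  (converted to cm internally so phases are dimensionless); angles in
  degrees at user surfaces, radians internally;
* intensity sums use bare squared moduli, without $\cos\theta$
  flux-projection factors. For the symmetric ambient/exit geometries
  used throughout, energy bookkeeping is unaffected (the test suite
  verifies $T + R = 1$ for lossless slabs); for asymmetric half-spaces
  the numbers are amplitude ratios, not flux ratios — a documented
  caveat, not a bug.

Two consequences of the formalism are worth stating because they are
often mis-remembered. At normal incidence the transmission matrix is
diagonal ($t_{+-} = t_{-+} = 0$) — but the *reflection* operator of an
achiral interface is anti-diagonal there, because reflection reverses
the propagation direction and therefore flips helicity. And in the
achiral limit at oblique incidence the cross-helicity transmission
entries do *not* vanish (circular light becomes elliptical when
$t_s \neq t_p$); what vanishes identically is the *difference*
$T_+ - T_-$, hence every VCD measure. The test suite asserts the
exact statements.

## The ideal absorber: the stated world

The packaged reference material (`ideal_absorber()`) is a synthetic
eight-oscillator Lorentz model,

$$\varepsilon(\bar\nu) = \varepsilon_\infty + \sum_j
\frac{f_j\bar\nu_p^2}{\bar\nu_{0,j}^2 - \bar\nu^2 - i\gamma_j\bar\nu},
\qquad
\kappa(\bar\nu) = \kappa_0 \sum_j
\frac{f_j\bar\nu_p^2\,\bar\nu}{\bar\nu_{0,j}(\bar\nu_{0,j}^2 -
\bar\nu^2 - i\gamma_j\bar\nu)},$$

with $\varepsilon_\infty = 2.15$, $\bar\nu_p = 107$ cm$^{-1}$,
$\kappa_0 = 10^{-5}$ and resonances every 500 cm$^{-1}$ from 500 to
4000 cm$^{-1}$, strengths and dampings tuned so the thin-film
Beer–Lambert absorbance shows equidistant peaks of nearly equal
amplitude. It is a diagnostic instrument, not a fit to any substance:
against a perfectly regular absorption ladder, interference fringes and
coupling artifacts are immediately visible. Near strong dispersion its
real index dips below 1, so large incidence angles legitimately produce
evanescent transmitted waves and oscillatory band-edge tails — a
feature of the model, handled by the complex-cosine branch rules.

What it does **not** emulate: linear birefringence/dichroism of
oriented or strained samples, surface roughness, anisotropy, detector
or instrument response, or the dispersion of any real solvent or film.
A green test on this material therefore establishes correctness of the
electromagnetic pipeline, not agreement with any particular experiment.
For real materials, tabulated complex $\varepsilon$ and $\kappa$ can be
supplied via `dispersion_table()` / `read_dispersion_csv()`.

## Tunable parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `kappa_0` | chirality scale (dimensionless) | $10^{-5}$ | weak-chirality regime of molecular films; VCD is linear in it |
| `thickness_um` | film thickness (µm) | — | VCD scales ~linearly: peak $|{\rm VCD}|\sim10^{-6}$ at 1 µm, $\sim10^{-4}$ at 50 µm |
| `theta_in` | incidence angle (deg) | 0 | artifacts grow towards grazing incidence; $\lesssim 50°$ stays close to the baseline |
| grid | wavenumber range/step (cm$^{-1}$) | 200–4500 step 1 | covers all eight bands with fringe-resolving sampling |
| `na_in`, `na_out` | numerical apertures | — | cone half-angles $\arcsin(\mathrm{NA})$ for focused illumination/collection |
| `n_in`, `n_out` | angular samples | 64 | refinement beyond 64 changes averages by $<10^{-4}$ relative |
| `floor` | map masking floor | $10^{-3}$ | cells with $|{\rm VCD_{BL}}|$ below `floor` × its peak are masked |

## Numerical choices

* **Vectorized block algebra.** All matrices are assembled as $2\times2$
  complex blocks whose entries are whole wavenumber-grid vectors, so a
  full 4301-point spectrum costs a few dozen vector operations
  (~40 ms); a 9-angle map takes under a second. No compiled code is
  needed.
* **Deviation-map masking.** The artifact maps normalize by the
  Beer–Lambert VCD, which changes sign inside every band. Ratios near
  those zero crossings are meaningless, so cells with
  $|\mathrm{VCD_{BL}}| < 10^{-3}\max|\mathrm{VCD_{BL}}|$ are masked
  (`NA`) rather than reported; the floor is configurable. An achiral
  film has a zero baseline everywhere and masks the entire map, with a
  warning.
* **Aperture quadrature.** Angles are sampled uniformly in $\theta$
  (not solid angle), $\theta = 0$ always included. The incoherent mean
  uses trapezoid end-weights: a plain equal-weight mean of a uniform
  grid containing both endpoints converges only at first order, which
  is measurably too slow at 64 samples. With trapezoid weights the
  64→128 refinement changes averaged transmittances by well under
  $10^{-4}$ relative. Matching ambient and exit media collapse the
  illumination/collection double sum to a single sum over the smaller
  cone; asymmetric half-spaces use the double sum with an output-cone
  acceptance test per refracted ray.
* **Average-then-log.** Aperture-averaged VCD applies the logarithm to
  the averaged transmittances — the detector sums intensity before any
  logarithm. A regression test asserts this differs from averaging
  per-angle VCD curves for a thick film, so the order cannot be
  silently swapped. The mediant inequality guarantees the result stays
  inside the per-angle VCD envelope.
* **Singularity handling.** Cosine ratios blow up within about
  $10^{-7}$ of an exactly-critical grazing geometry; such cells raise
  an explicit error naming the angle instead of returning noise.
  Transmittances that underflow to zero or below are masked `NA` with a
  warning, never clamped. Propagation exponents beyond $e^{700}$ (far
  outside the physical regime) are clipped with a warning, never
  silently.
* **Exact closed-form oracle.** For a single chiral slab at normal
  incidence the helicities decouple, but the correct Fabry–Pérot form
  is *not* the scalar Airy formula evaluated at $n_\pm$: the Fresnel
  factors depend on the helicity-independent impedance
  ($\propto 1/\sqrt{\varepsilon\mu}$), and each internal reflection
  flips helicity, making the round-trip phase $\phi_+ + \phi_-$. The
  test oracle uses this exact form (agreement $10^{-10}$); the naive
  single-index Airy form agrees only to $O(\kappa_0)\sim10^{-6}$ and is
  checked at that level.

## Design decisions that were genuinely open

* **Oblique-incidence phase.** The single-layer propagation phase is
  printed in the literature only for normal incidence
  ($\phi_\pm = 2\pi\bar\nu n_\pm d$). We generalize with the
  layer-normal component, $\phi_\pm = 2\pi\bar\nu n_\pm
  \cos\theta_\pm d$, the unique choice that reduces the achiral limit
  to the textbook scalar transfer matrix; the suite verifies
  $10^{-10}$ agreement with an independent scalar s/p implementation at
  angles up to 80°.
* **Eigenmode relation.** $n_\pm = \sqrt{\varepsilon\mu} \pm \kappa$
  (with the $\kappa \to 0$ limit $n = \sqrt{\varepsilon}$), the
  standard Pasteur form.
* **Configuration format.** JSON only (`jsonlite`); no YAML parser is
  available in the dependency set, and a second config dialect buys
  nothing.
* **CSV outputs.** Mid-IR spectroscopy has no binding container
  standard; all artifacts are full-precision CSV with a schema-version
  comment line, making byte-identical reruns testable.

## Known limitations

* Scalar (isotropic) $\varepsilon$, $\mu$, $\kappa$ only: no
  linear birefringence/dichroism, no Berreman-style anisotropy.
* Coherent propagation throughout — no incoherent thick-substrate
  treatment; interfaces are perfectly flat and parallel.
* Intensity definitions omit flux-projection cosines (following the
  formalism's convention); interpret asymmetric-exit transmittances
  accordingly.
* The aperture model is an incoherent plane-wave average: no coherent
  focal-field (Richards–Wolf) structure, no chromatic focal shift, no
  polarization aberrations of real objectives.

## A minimal session

```{r example, eval = FALSE}
stk <- optical_stack(chiral_material(1), layer(ideal_absorber(), 25))
sp <- simulate_spectrum(stk, seq(200, 4500, by = 1), theta_in = 0)
mp <- deviation_maps(stk, seq(0, 80, by = 10), seq(200, 4500, by = 1))
av <- na_averaged_vcd(stk, seq(200, 4500, by = 1), aperture_config(0.7, 0.3))
```

Every numeric claim above (orders of magnitude, tolerances, monotone
trends) is computed by the test suite or the packaged scripts, not
asserted from memory.
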
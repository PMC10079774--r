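---
title: "Modelling the diffuse reflectance in spatial frequency domain imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the diffuse reflectance in spatial frequency domain imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfdimodels)
```

## The problem

Spatial frequency domain imaging (SFDI) projects sinusoidal intensity
patterns onto tissue and measures how strongly each spatial frequency is
attenuated in the diffusely reflected light. Because absorption and
scattering attenuate different frequencies differently, reflectance
measured at two or more frequencies lets one map the absorption
coefficient $\mu_a$ and the reduced scattering coefficient $\mu_s'$ over
a wide field of view. Converting reflectance to optical properties
requires a forward model $R(f; \mu_a, \mu_s')$, and the accuracy of that
model propagates directly into the recovered coefficients.

This package implements and cross-validates three closed-form diffusion
models of the spatially modulated diffuse reflectance of a semi-infinite
homogeneous medium, along with everything needed to score them against a
photon-transport ground truth.

## The models

Sinusoidal illumination enters steady-state diffusion theory through a
single scalar: the effective attenuation coefficient generalises to

$$\mu_{\mathrm{eff}}' = \sqrt{\mu_{\mathrm{eff}}^2 + (2\pi f)^2},$$

where $\mu_{\mathrm{eff}} = \sqrt{\mu_a / D}$,
$D = 1/(3(\mu_s' + \mu_a))$, and $f$ is the projected spatial frequency
(mm$^{-1}$). Any planar-illumination reflectance formula becomes an SFDI
model by substituting $\mu_{\mathrm{eff}} \to \mu_{\mathrm{eff}}'$. With
$x = \mu_{\mathrm{eff}}'/\mu_{tr}$, $\mu_{tr} = \mu_a + \mu_s'$, reduced
albedo $a' = \mu_s'/\mu_{tr}$, and the internal-reflection parameter $A$,
the three models are

$$R_{\mathrm{Cuccia}} = \frac{3a'}{(2Ax + 3)(x + 1)},\qquad
R_{\mathrm{PCBC}} = \frac{a'}{\tfrac{4A}{3}x}
   \left[1 - e^{-\frac{4A}{3}x}\right]\frac{1}{1 + x},\qquad
R_{\mathrm{EBC}} = \frac{a'}{2}\left[1 + e^{-\frac{4A}{3}x}\right]
   \frac{1}{1 + x}.$$

The first solves the diffusion equation directly for a planar source.
The other two are derived along a different route: start from the radial
Green's function $R(\rho, z_0)$ of an isotropic point source at depth
$z_0$ under either the partial-current boundary condition (PCBC; surface
irradiance balanced against back-reflected radiance) or the extrapolated
boundary condition (EBC; fluence forced to zero at $z_b = 2AD$ above the
surface), convolve it with the distributed source
$S(z_0) = a'\mu_{tr} e^{-\mu_{tr} z_0}$, integrate over the whole plane,
and substitute $\mu_{\mathrm{eff}} \to \mu_{\mathrm{eff}}'$. The exponent
$\tfrac{4A}{3}x$ is exactly $2 z_b \mu_{\mathrm{eff}}'$, and a unit test
asserts that identity on random media.

All three models equal $a'$ at $\mu_{\mathrm{eff}}' = 0$, decrease
strictly with $f$, and vanish as $f \to \infty$.

The boundary parameter $A = (1 + R_{\mathrm{eff}})/(1 - R_{\mathrm{eff}})$
is computed from two angular integrals of the unpolarised Fresnel
reflectance. The integrand has a derivative discontinuity at the
critical angle, so the quadrature splits the domain there and integrates
each side adaptively (`compute_A()`, cached per boundary). For a
tissue-like index of 1.33 under air this gives $A = 2.515$.

```{r}
compute_A(1.33, 1.00)
```

### The equivalence property

The package's central consistency check is that the closed forms really
are the planar integrals of their Green's functions: for each boundary
condition, the numerical zeroth-order Hankel transform

$$R(f) = 2\pi \int_0^\infty \rho\, J_0(2\pi f \rho)\, R(\rho)\, d\rho$$

of the numerically source-integrated $R(\rho)$ must reproduce the closed
form. The two routes treat frequency differently by construction — the
closed forms take $f$ through $\mu_{\mathrm{eff}}'$, while the numerical
route keeps $\mu_{\mathrm{eff}}$ and lets the Bessel kernel carry $f$ —
so agreement is a genuine two-sided check, not a tautology. The
acceptance suite verifies agreement across the full property grid for
$\mu_s'/f \in [1, 1000]$; in practice both routes agree to better than
$10^{-3}$ relative, far inside the 1% band the check demands.

```{r}
p <- optical_properties(0.01, 5)
b <- boundary_params(1.33, 1.00)
dp <- derive_diffusion_params(p)
f <- c(0.05, 0.5)
rbind(closed  = reflectance_model("pcbc", p, f, b),
      hankel  = hankel_transform_continuous(
        function(r) radial_reflectance("pcbc", r, dp, b), f))
```

## Numerical choices

* **Depth integral.** $R(\rho) = \int_0^{z_0^{\max}} R(\rho, z_0) S(z_0)
  dz_0$ uses composite Gauss–Legendre quadrature on log-spaced depth
  panels (default 50 panels × 8 nodes), which resolves both the
  near-surface structure (the integrand behaves like
  $1/\sqrt{z_0^2+\rho^2}$) and the exponential tail. The default
  truncation $z_0^{\max} = 100$ mm leaves the result unchanged at the
  $10^{-6}$ level for every grid medium (asserted in a test by doubling
  it).
* **Oscillatory Hankel quadrature.** The transform is accumulated
  panel-by-panel between consecutive zeros of $J_0(2\pi f \rho)$
  (9 Gauss–Legendre nodes per panel), with extra log-spaced panels
  before the first zero to capture the logarithmic peak of $R(\rho)$ at
  the origin, stopping when three consecutive panels change the partial
  sum by less than $10^{-8}$ relative. Radial truncation defaults to
  500 mm; the stopping rule almost always exits far earlier.
* **Degenerate inputs.** $\rho = z_0 = 0$ is rejected as singular;
  $f = 0$ falls back to a non-oscillatory log-panel integral; the PCBC
  closed form uses `expm1` so the $x \to 0$ limit is exact.

## The Monte Carlo ground truth

`run_pencil_beam()` is a weighted-photon simulator in the MCML
tradition, written in C++: photons launch into the medium at the origin
with unit weight, take exponential steps of mean $1/\mu_t$, deposit
$w\,\mu_a/\mu_t$ at each interaction, and scatter through a
Henyey–Greenstein (HG) or two-term HG (TTHG) phase function with uniform
azimuth. At the surface the Fresnel-transmitted fraction of the weight
is deposited in the radial bin of the exit point — regardless of exit
angle — and the reflected fraction re-enters (a deterministic split;
lower variance than stochastic accept/reject with the same expectation).
Russian roulette (threshold $10^{-4}$, survival 0.1) terminates faint
photons unbiasedly.

Design choices worth knowing:

* The scattering coefficient is derived from the similarity relation
  $\mu_s = \mu_s'/(1 - g_1)$, with $g_1$ the phase-function mean cosine;
  the study grid specifies only $\mu_s'$.
* Specular reflection at entry is excluded (photons start just inside
  the medium): the analytic models describe light already delivered into
  the tissue, and SFDI calibration absorbs source constants.
* The TTHG defaults mix HG($g = 0.95$) and HG($g = -0.2$) with weights
  0.9/0.1 — the published 0.45/0.05 pair, which sums to one half,
  normalised; the normalisation is recorded in the object rather than
  applied silently. The mean cosine is $g_1 = 0.835$.
* The RNG is xoshiro256++ seeded deterministically (splitmix64) from the
  integer seed, so a profile is bitwise reproducible from its config and
  independent of R's RNG state.

Bookkeeping is exact where it can be: bins are normalised by true
annulus areas, which makes the binned Hankel transform at $f = 0$ equal
the detected weight fraction to machine precision, and
detected + absorbed + overflow = 1 up to the (unbiased) roulette
fluctuation.

### Similarity scaling

Radiative transport has an exact scale invariance: multiplying both
$\mu_a$ and $\mu_s'$ by $s$ shrinks all lengths by $s$, so profiles map
as $R_s(\rho) = s^2 R(s\rho)$ and spectra as $R_s(f) = R(f/s)$. The
5 × 5 property grid contains only 14 distinct $\mu_a/\mu_s'$ ratios per
phase function, so the evaluation study (with `dedup_scaled = TRUE`, the
default) runs one canonical $\mu_s' = 1$ simulation per ratio and serves
every similar medium exactly through `scale_profile()`. This cuts the
simulation budget by almost half without approximation; a property test
confirms the identity against an independent direct run. Canonical
geometry defaults to 0.01 mm bins × $1.2\times10^5$ bins = 1200
transport lengths, which keeps the truncated tail below $10^{-4}$ of
the detected weight even for the most transparent medium
($\mu_a/\mu_s' = 2\times10^{-5}$, where the diffuse halo decays over
$1/\mu_{\mathrm{eff}} \approx 130$ transport lengths).

## The validation study

`run_reflectance_study()` scores all three models against the MC truth
over the full grid: $\mu_a \in \{0.001, 0.005, 0.01, 0.05, 0.1\}$
mm$^{-1}$ × $\mu_s' \in \{1, 5, 10, 20, 50\}$ mm$^{-1}$ × {HG($0.9$),
TTHG($0.835$)}, with 20 frequencies per medium log-spaced in
$\mu_s'/f \in [0.1, 1000]$, three repeat simulations averaged, and the
relative error $|R_{\mathrm{model}} - R_{\mathrm{MC}}|/R_{\mathrm{MC}}$
summarised by median and interquartile range per model.
`run_extraction_study()` repeats the comparison in parameter space:
invert each model from the MC reflectance at $f = 0$ and $f = 0.5$
mm$^{-1}$ (the same AC frequency for every medium, even where that is
subdiffuse for low $\mu_s'$ — deliberately, as that is how the
measurement would be used) and summarise the errors of
$\hat\mu_a, \hat\mu_s'$.

Two open choices are resolved as follows:

* **Validity filter.** The stated exclusion rule $f > 15\,\mu_{tr}$
  excludes nothing on this grid (max $f = 10\mu_s' < 15\mu_{tr}$), yet
  diffusion theory needs $f \ll \mu_{tr}$. Both readings are
  implemented (`filter_mode = "literal"` / `"strict"`, literal default
  with a logged message); results can be summarised under either rather
  than guessing.
* **Inversion.** With two unknowns and two equations, root-finding and
  least squares coincide at a root. The solver is bounded
  Levenberg–Marquardt on $(\log\mu_a, \log\mu_s')$ (ranges span two
  decades), relative residuals, initial guess $(0.01, 10)$ mm$^{-1}$,
  bounds $\mu_a \in [10^{-5}, 1]$, $\mu_s' \in [0.1, 100]$ mm$^{-1}$.
  The squared-residual landscape has bound-adjacent local minima for
  strongly absorbing, weakly scattering media, so if the first fit does
  not reach a root the solver reseeds from the best point of a coarse
  $12 \times 12$ log-grid search — with that fallback, self-inversion is
  exact over the whole property grid. Bounded best fits that still
  reach no root are kept in the medians (they are what a user of that
  model would obtain) and counted; hard failures are excluded with a
  message, never silently dropped.

### Problem sizes

A full-fidelity validation raises the photon budget until the
repeat-to-repeat standard deviation over the mean transformed
reflectance drops below 1% (and uses the published detector geometry of
$10^{-3}$ mm × $4\times10^5$ bins); that is an hours-long computation.
The package's test suite instead runs a desk-scale study — $10^4$
photons per simulation, three repeats, the canonical scaled geometry
above — which reproduces the scientifically meaningful structure (the
model accuracy ordering PCBC < Cuccia < EBC for reflectance and for
extracted $\mu_a$, and the physical-consistency contrast below) while
keeping the suite inside ordinary development budgets. At this scale
per-point MC noise of a few percent inflates all medians roughly
equally, so orderings are stable but absolute medians sit above the
full-scale values.

### What the generator does and does not emulate

The Monte Carlo is the ground truth for exactly the idealisation the
models address: steady-state transport in a semi-infinite homogeneous
medium with a smooth mismatched boundary, pencil-beam delivery, and
angle-blind detection. Passing tests therefore say nothing about
layered or heterogeneous tissue, finite source/detector apertures,
polarisation, or instrument effects (demodulation, MTF calibration) —
all deliberately out of scope.

## Physical consistency

At high spatial frequencies the measurement leaves the diffuse regime:
the total reflectance is the sum of a diffuse and a semiballistic
component, so a *diffuse* model must stay at or below the MC *total*
reflectance. Of the three models only the PCBC form respects this at
every subdiffuse grid point (within 2 MC standard errors); Cuccia and
EBC overshoot, and the study records those violations. Together with
the lowest error medians, this is the argument for preferring the PCBC
model when fitting SFDI data.

## Limitations

* All models are diffusion approximations: none is trustworthy for
  $\mu_s'/f \lesssim 1$ or $\mu_a \gtrsim \mu_s'$; the validity filter
  only flags, it cannot repair.
* The choice $D = 1/(3(\mu_s'+\mu_a))$ is kept for comparability across
  models (a `"mus_only"` switch exists); in the diffuse regime the
  difference is negligible, and this package takes no position on which
  convention is physically superior.
* The MC detector bins the exit position only; numerical-aperture or
  angle-resolved detection would need a different tally.
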
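---
title: "A reduced-order coaxial-tube model of epidural-driven CSF slosh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced-order coaxial-tube model of epidural-driven CSF slosh}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Syringomyelia is the formation and growth of fluid-filled cavities
(syringes) inside the spinal cord.  One proposed growth mechanism is
"slosh": during a Valsalva maneuver (cough, strain), blood shifted into
the epidural veins compresses the dura, sets the cerebrospinal fluid
(CSF) of the subarachnoid space (SAS) in motion, and the resulting
pressure and velocity transients ram the fluid inside an existing syrinx
against the cavity ends, stressing the cord tissue there and dissecting
the cavity onward.  `sloshsim` implements an in-silico test of this
hypothesis for the canine (cavalier King Charles spaniel) spinal canal:
a transient fluid-structure model of the canal under an epidural
pressure pulse, evaluated over a suite of 57 syrinx placement and
expansion configurations, with the cord stress summarized exactly the
way the slosh argument needs it (peak-over-time maps, 1 mm slice
medians, and the statistics `sigma_max` and `delta_sigma`).

## The model

All compartments are idealized as nested circular sections: syrinx
lumen inside cord inside SAS inside a 1 mm dura shell.  This makes the
geometry one-dimensional in the cranio-caudal coordinate `x` (origin at
the cranial end of the syrinx region; the cranial extrusion occupies
`[-15, 0)` mm; the modeled span is `[-15, 340]` mm), and the dynamics a
set of coupled 1-D coaxial-tube equations rather than a 3-D
finite-element problem.  The reduction keeps the physics the slosh
question interrogates — axial pulse transmission, fluid/cord
differential motion, stress concentration at cavity ends — while giving
up 3-D stress magnitudes, which the package treats as
order-of-magnitude context only.

For SAS fluid (area perturbation `a_s`, pressure `p_s`, velocity
`u_s`), syrinx fluid (`a_f`, `p_f`, `u_f`) and cord axial displacement
`w` (velocity `v_c`):

* SAS continuity `(A_s0/K_a) dp_s/dt + da_s/dt + d(A_s0 u_s)/dx = 0`
* SAS momentum `rho A_s0 du_s/dt = -A_s0 dp_s/dx - D_s u_s`
* syrinx continuity `(A_f0/K_a) dp_f/dt + da_f/dt + d(A_f0 u_f)/dx = 0`
* syrinx momentum
  `rho A_f0 du_f/dt = -A_f0 dp_f/dx - D_f (u_f - v_c)`
* cord momentum `rho_c A_c dv_c/dt = d(E_c A_c dw/dx)/dx
  + p_s dA_c/dx - (p_f - p_s) dA_f0/dx - 2 nu_c d(A_c p_s)/dx
  + D_f (u_f - v_c)`
* tube laws `a_f = C_f (p_f - p_s) - w dA_f0/dx` and
  `a_s = -a_f - w dA_c/dx + 2 nu_c A_c dw/dx - C_w (p_ext - p_s)`

Three modeling points deserve emphasis.

**Near-incompressible force cancellation.**  The cord is loaded by two
competing surface effects: the direct axial push of the lateral
pressure on its tapering surface (`p_s dA_c/dx`) and the Poisson
reaction conjugate to the strain term in the SAS tube law
(`-2 nu_c d(A_c p_s)/dx`).  For a near-uniform pressure their sum
scales as `(1 - 2 nu_c) p_s dA_c/dx`, which is small for
`nu_c = 0.49`: a nearly incompressible cord under nearly hydrostatic
load barely deforms.  Omitting either term over-drives the cord by
roughly `1/(1 - 2 nu_c)` (about 50x) and destroys the velocity scale.
Both terms are discretized as exact adjoints of their continuity
counterparts, so the semi-discrete system conserves energy and the
discrete volume audit balances to roundoff.

**End-cap force.**  The syrinx rest area tapers to zero over `taper_mm`
(default 1 mm, never narrower than one cell) at each fluid/tissue
interface.  The transmural pressure acting on that taper,
`-(p_f - p_s) dA_f0/dx`, is the end-cap force that rams the cavity
ends — the mechanism at the heart of the slosh argument.

**Artificial compressibility.**  The canal is closed (`u_s = 0` at both
ends, `w = 0` at both cord ends, `u_f = 0` at cavity termini) and all
constituents are nearly incompressible, so a small artificial bulk
modulus `K_a` supplies the storage that makes the closed system
well-posed.  See "Parameters" for its value and the sensitivity
discussion.

Wall compliance `C_w` represents the dura shell
(`2 pi r^3 / (E_dura h)`) in series with the soft epidural fat layer,
and acts only on the excitation span (the canal is rigid elsewhere,
i.e. held by vertebrae); the prescribed epidural pressure enters the
SAS tube law through `C_w (p_ext - p_s)`.  This replaces the original
control-volume ("airbag") formulation: the injected venous volume
becomes a derived output — the integral `C_w (p_ext - p_s) dx` that the
volume audit reports — rather than an input.  The syrinx tube law uses
the thick-walled (Lame) annulus compliance
`C_f = (2 pi a^2 / E_cord) [(b^2 + a^2)/(b^2 - a^2) + nu_cord]` in its
plane-strain form (the cord ends are axially pinned); a plane-stress
variant is selectable.  Viscous drag uses the laminar coefficient
`D = 8 pi mu` for both fluids, the SAS drag referenced to the fixed
dura, the syrinx drag referenced to the cord velocity with full
reaction (the exchange is asserted equal-and-opposite in the tests).

The excitation is the raised-cosine epidural pulse
`p(t) = 3000 [1 - cos(10 pi t)]` Pa for `t < 0.2` s and zero after:
amplitude 6000 Pa (about 45 mmHg) at `t = 0.1` s, acting on
`x` in `[205, 325]` mm.

## The stress surrogate and its calibration

The 3-D study summarizes cord load as the per-element peak von Mises
stress over the event.  The 1-D surrogate is the scaled axial elastic
stress `s(x, t) = gamma |E_cord dw/dx|`, with running maxima updated at
every integration step so peak maps never depend on the output stride.
`gamma` is a single scalar fixed once by `calibrate_gamma()`: the
syrinx-free baseline is run at default resolution and its peak 1 mm
slice-median stress is scaled to the midpoint (270 Pa) of the 180-360 Pa
band that brackets the reported syrinx-free stress level.  Because
`gamma` multiplies only the reported measure, every relative and
qualitative result is calibration-independent.  The shipped value is
`slosh_default_gamma()` = 1.1258312, i.e. the uncalibrated surrogate
already lands at the right order of magnitude.

Post-processing mirrors the study's pipeline: `peak_stress_map()` (max
over time per element), `slice_medians()` (median of element peaks per
1 mm half-open slice; empty slices interpolation-filled and flagged),
`sigma_max()` (windowed peak near the syrinx, extent plus a 5 mm
margin, ties broken cranially), `delta_sigma()` (windowed maximum of
the pointwise difference from the baseline by default; the
at-the-peak-location variant is selectable because the original
definition is ambiguous between the two), and `percent_increase()`.

## Parameters

| parameter | default | units | why |
|---|---|---|---|
| `E_cord`, `nu_cord`, `rho_cord` | 62.5e3, 0.49, 1000 | Pa, -, kg/m^3 | study's cord tissue constants |
| `E_dura`, `nu_dura` | 1.25e6, 0.4 | Pa, - | study's dura constants |
| `E_fat`, `nu_fat`, `rho_fat` | 1e3, 0.4999, 900 | Pa, -, kg/m^3 | study's epidural fat |
| `mu_csf`, `rho_csf` | 0.001, 1000 | Pa s, kg/m^3 | CSF as water |
| `amplitude_half_pa`, `pulse_duration_s` | 3000, 0.2 | Pa, s | the printed pulse |
| `excitation_span_mm` | 205-325 | mm | caudal epidural venous region |
| `dx_mm` | 1 | mm | aligns cells with the 1 mm slice statistics |
| `duration_s` | 0.4 | s | pulse plus an equal follow-on |
| `K_a` | 1e6 | Pa | artificial compressibility (below) |
| `cfl_safety` | 0.5 | - | explicit leapfrog margin |
| `taper_mm` | 1 | mm | end-cap width; fixed in mm so refinement converges |
| `wall_ramp_mm` | 5 | mm | avoids a one-cell compliance step at the span edges |
| `ratio` (single syringes) | 0.70 | - | stated syrinx/cord radius ratio |
| region bounds | 85, 230 | mm | C/T at the cervico-thoracic junction near S8 (70-80 mm); T/L where lumbar behavior is reported (~250 mm); half-open, caudal label at a boundary |
| `sigma_max` window margin | 5 | mm | "at the location of a syrinx" made precise |

**On `K_a`.**  With `K_a = 1e6` Pa the compressibility storage is about
a fifth of the wall-compliance storage: pulse transmission into the
cervical SAS is 84% and the relative stress patterns (baseline level
versus syrinx increase) match the study's behavior well.  Raising `K_a`
to 1e7 pushes transmission to 97% and layer velocities to a few
1e-4 m/s, but collapses the baseline stress while leaving syrinx-local
stress unchanged, distorting every relative statistic; it also slows
the solver by sqrt(10).  `K_a = 1e6` is the shipped default.  A caveat
is documented deliberately: reported stresses are *not* insensitive to
doubling `K_a` (changes of order tens of percent), because the closed
system's artificial Helmholtz mode (canal fluid mass against wall
compliance plus compressibility) moves through the pulse's frequency
band as `K_a` varies.  True insensitivity would need `K_a` near a real
CSF bulk modulus, computationally out of reach for an explicit scheme
at these grid sizes.  Conclusions drawn from the package should
therefore rest on the relative and qualitative statistics, which is how
the suite's results are framed.

## Numerics

Staggered uniform grid: pressures and areas at cell centers, velocities
and displacement at faces.  Explicit leapfrog: face velocities from
pressure gradients and drag (SAS drag semi-implicit, syrinx/cord drag
explicit and reciprocal), then center pressures from continuity with
the tube laws substituted — a local, time-invariant 2x2 linear relation
per fluid cell, solved in closed form — then displacement.  The time
step is `cfl_safety * dx / c_max`, where `c_max` covers the artificial
acoustic speed `sqrt(K_a/rho)` (31.6 m/s at defaults), the
Poisson-augmented cord elastic speed, and the Korteweg speeds of both
tubes evaluated with compressibility-augmented compliance.  At defaults
`dt` is about 1.6e-5 s and a 0.4 s run of 355 cells takes a few seconds.

Numerical safeguards verified in the test suite: exact linearity in the
excitation amplitude; volume balance to roundoff; peak maps invariant
to the output stride; a propagating front matching the Korteweg speed
`sqrt(A0/(rho C))` on a uniform compliant tube to well under 5%; and a
grid-refinement change of the baseline peak slice-median profile below
2% in max-norm when `dx` and `dt` are halved.  Degenerate inputs
(nesting violations, non-monotone anchors, gaps in user radius tables,
syrinx radius reaching the cord radius, unstable `dt`) are rejected
with diagnostics naming the offending station or step.

## The synthetic anatomy

The measured per-station radii behind the original geometry are not
deposited, so `synthesize_anatomy()` stands in for them: monotone
shape-preserving (Fritsch-Carlson) interpolation of a small anchor
table, giving a cervical bulge (cord radius 3.0-3.15 mm), thoracic
narrowing (2.6 mm), mild lumbar re-widening (2.85 mm) and a caudal
taper (2.0 mm), a uniform 1.5 mm SAS gap, and a smooth "MRI-like"
maximum syrinx radius profile used by the expanding-syrinx series
(1.35 mm at the cranial end, peaking at 2.0 mm mid-region).  These are
plausible canine dimensions consistent with the stated 70% average
syrinx/cord radius ratio; they were chosen once, before the stress
experiments, and are not fitted.  Users with real measurements supply
them as CSV via `load_anatomy()`.

What the generator emulates: smooth cranio-caudal caliber variation,
correct layer nesting, the segment layout (27 x 10 mm + 15 mm), the
excitation region.  What it does not: left-right asymmetry, vertebral
anatomy, the actual dog's radii, and any irregularity of real cavity
walls.  Passing tests therefore validate the mechanism and the
pipeline, not patient-specific magnitudes.

## Known limitations

* 3-D von Mises magnitudes (hundreds of Pa at specific locations) are
  reproduced in order of magnitude only; the surrogate is axial strain.
* The baseline axial-strain profile has a near-zero node in the
  thoracic trough, so statements of the form "the profile is unchanged
  outside the syrinx vicinity" hold on the scale of the profile
  (deviations are a few percent of the profile maximum) but not
  pointwise relative to the near-zero trough values; percent increases
  over the local baseline are correspondingly inflated there.
* In the expanding series the stress peak detaches from the cavity's
  caudal end one 10 mm increment earlier than reported for the original
  geometry (after 30 mm rather than 40 mm of growth) — a consequence of
  the synthetic radii; the qualitative sequence (early caudal-end
  peaks, a locked mid-cervical peak, re-emergence, and a moderate fully
  developed syrinx) is reproduced.
* The closed 1-D canal rings essentially undamped after the pulse;
  peak-over-time velocity envelopes are therefore upper bounds, and the
  velocity scale is best read at the mid-pulse instant (t = 0.08 s)
  that the study displays.

## Problem sizes used by the tests

The default resolution (1 mm cells, dt ~ 1.6e-5 s, 0.4 s simulated) is
used for the solver property battery and the calibrated baseline; the
full 57-configuration suite in the pattern tests runs at the smoke
preset (2.5 mm cells, 0.25 s), which preserves every qualitative
pattern while keeping a suite run under two minutes.  The acceptance
script runs the baseline at the default resolution.

## Reproducing the study figures

```{r, eval = FALSE}
library(sloshsim)

anatomy <- synthesize_anatomy()
suite <- run_suite(anatomy)          # 57 configurations, ~4 min

# profile panels with the shaded baseline
plot_suite_profiles(suite, c("S1", "S8", "S15", "S25"))
plot_suite_profiles(suite, c("S1-4", "S1-10", "S1-18", "S1-28"))

# summary bars and the caudal-peak trajectory
plot_sigma_bars(suite, "sigma_max")
plot_sigma_bars(suite, "delta_sigma")
plot_caudal_trajectory(suite)

# pressure traces at a cervical station for S8
autoplot(simulate_config(make_single_syrinx(anatomy, 8)), x_mm = 75)
```
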
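---
title: "Multi-contact DEM for high-density powder compaction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-contact DEM for high-density powder compaction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`mcdem` simulates the confined uniaxial compression (tableting) of a
plastically deforming powder at the particle scale. This vignette is the
package's account of the science it implements: the contact model and its
assumptions, the multi-contact coupling, the packing generator, the
numerical choices, and the limits of what the synthetic test problems can
show about real powders.

## The physical problem

A pharmaceutical tablet is formed by compressing a powder bed to relative
densities above 0.8. In a discrete element method (DEM) the bed is a
collection of spheres; contact deformation is represented by the overlap
of neighbouring spheres, and Newton's equations advance positions under
the resulting forces. Classical (Hertzian) DEM assumes each contact is
independent and its deformation small — both assumptions fail during
compaction, where pores close, contacts flatten against each other, and
each contact stiffens because the whole particle is being squeezed by its
neighbours ("geometric hardening"). The package addresses this with two
model ingredients on top of a standard Hertz–Mindlin frame:

1. a **hysteretic adhesive elastic–plastic normal law**, which gives each
   contact a loading branch, a history-dependent unloading/reloading
   branch and an adhesive branch, and
2. a **multi-contact correction** that couples every particle–particle
   contact to the stress state of the two particles, so that densely
   loaded particles push back harder than isolated pairs.

## Normal contact law

With overlap $\delta$ and maximum-ever overlap $\delta_{\max}$ per
contact, the normal force is the three-branch law

$$F_n = \begin{cases}
F_0 + k_1\,\delta^{3/2} & \text{virgin loading} \\
F_0 + k_2^*\,(\delta^{3/2}-\delta_0^{3/2}) & \text{unloading / reloading} \\
F_0 - k_c\,\delta^{3/2} & \text{adhesive branch,}
\end{cases}$$

where the branch in force is the one whose value is intermediate: virgin
loading applies while
$k_2^*(\delta^{3/2}-\delta_0^{3/2}) \ge k_1 \delta^{3/2}$ and the
adhesive branch once $-k_c\delta^{3/2}$ exceeds the unloading value. The
loading stiffness is Hertzian, $k_1 = \tfrac43 E^* \sqrt{R^*}$, so the
law reduces exactly to Hertz when $k_2 = k_1$ and $k_c = 0$. The
plastic (residual) overlap is
$\delta_0 = (1 - k_1/k_2^*)^{2/3}\,\delta_{\max}$, and the unloading
stiffness interpolates with contact maturity,

$$k_2^*(\delta_{\max}) = \begin{cases}
k_2 & \delta_{\max} \ge \delta^*_{\max}\\
k_1 + (k_2-k_1)\,\delta_{\max}/\delta^*_{\max} & \text{otherwise,}
\end{cases} \qquad
\delta^*_{\max} = \frac{k_2}{k_2-k_1}\,\varphi_f\, 2R^*,$$

with $\varphi_f$ the dimensionless plasticity depth. Unloading crosses
zero force at $\delta_0$ and continues into adhesion until the branch
intersection at
$\delta_{\min} = \big((k_2^*-k_1)/(k_2^*+k_c)\big)^{2/3}\delta_{\max}$,
where the minimum (pull-off) force $-k_c\,\delta_{\min}^{3/2}$ is
reached — note the $+k_c$ in the denominator, which follows from
equating $-k_c\delta^{3/2}$ with the unloading branch (the analogous
expression in the linear hysteretic model has the same structure).
$k_2^*$ is used consistently in all branch conditions (the alternative of using the
saturated $k_2$ in the virgin-branch condition breaks force continuity
at branch switches); ties go to the virgin branch. Per-contact state
($\delta_{\max}$, tangential spring) is reset when a contact breaks.

Tangential forces follow the Mindlin form
$F_t = k_t\,\delta_t^{3/2}$ with $k_t = 8G^*\sqrt{R^*}$, the tangential
spring integrated from surface velocities and projected into the current
tangent plane, capped by Coulomb friction $\mu F_n$ (static = dynamic)
with the spring rescaled onto the cap when sliding. Rolling resistance is
the constant-directional-torque model,
$\tau = -\hat\omega_{rel}\,\mu_r R_r F_n$ with $R_r = R^*$ (the rolling
radius is not otherwise determined by the model inputs).

## Multi-contact coupling

Each particle carries a compression-positive Love–Weber stress tensor,
$\sigma_i = -(1/V_i)\sum_c \mathrm{sym}(l_c \otimes F_c)$, accumulated
from all its contacts (walls included) with $l_c$ the centre-to-contact
branch vector and $V_i$ the sphere volume. Every particle–particle
contact then receives the additive correction

$$\Delta F_n = \beta\,\nu\,A_{ij}\,P_{ij}, \qquad
P_{ij} = \tfrac13\big(\mathrm{tr}\,\sigma_i + \mathrm{tr}\,\sigma_j\big),$$

with $A_{ij} = \pi R^* \delta$ the Hertzian contact area, $\nu$ the
pair-mean Poisson ratio and $\beta$ a dimensionless material-dependent
prefactor ($\beta = 0$ recovers conventional DEM). Design choices worth
stating explicitly:

* $P_{ij}$ is the **sum** of the two particle pressures, not their mean —
  implemented exactly as the model states it; a factor-two change is
  absorbable into $\beta$.
* The sign convention is compression-positive, so compaction makes the
  correction repulsive (stiffening). With the opposite convention the
  model would soften under load, contradicting its purpose.
* $P_{ij}$ is evaluated from the **previous** time step (explicit
  lagging) to avoid a force–stress fixed-point iteration inside every
  step; the lag error is $O(\Delta t)$ and invisible at quasi-static
  rates.
* Wall contacts use the uncorrected law — a wall has no particle stress
  tensor — but do contribute to the particle tensors.
* The contact-area formula is a modelling choice (the coupling only
  fixes the product $\beta A$); the Hertzian $\pi R^*\delta$ keeps the
  correction linear in overlap.

## Particle size distribution and packing generation

Laser-diffraction volume-weighted quantiles $x_{10}/x_{50}/x_{90}$ are
fitted by a two-parameter log-normal: the median is pinned to $x_{50}$
and the log-sd is the least-squares value over the two log-symmetric
quantile ratios, $\sigma = \ln(x_{90}/x_{10})/(2 z_{0.9})$. Two
parameters cannot match three asymmetric quantiles: the fit reproduces
$x_{50}$ and the $x_{90}/x_{10}$ ratio exactly and reports the residual
misfit of the outer quantiles (about 25% for the built-in cellulose
grades, whose quantile triples are strongly left-skewed in log space).
Radii are sampled from the corresponding number-weighted density
($\propto f_V(d)/d^3$, again log-normal) by inverse-CDF draws truncated
to $[x_{10}/2,\ 1.2\,x_{90}]$ — unbounded log-normal tails would
otherwise produce rare giant or vanishing particles that destabilise the
time step.

An important bookkeeping consequence: the particle count of a packing is
fully determined by the fitted PSD, the box volume and the target solid
fraction (count $=\phi V_{box}/\langle v \rangle$ with $\langle v
\rangle$ the number-mean particle volume). For the built-in coarse grade
this gives $\approx 240$ particles in the default $(0.8\,\mathrm{mm})^3$
box at $\phi = 0.59$, and $\approx 6400$ for the fine grade — these are
properties of the stated quantiles, not tunable outcomes.

The generator samples radii until their volume meets the target fraction
(rescaling by a factor $\le 1$ so the final fraction is exact), places
them without overlap at reduced size by random sequential insertion,
then inflates all radii multiplicatively (preserving the PSD shape) with
interleaved overlap relaxation: friction off, strong velocity damping, a
per-step displacement clamp, and a final relaxation stage that must
bring the mean contact overlap below $10^{-3}$ of the mean radius —
a quasi-stress-free, quiescent initial bed. Growth is monotone in
packing fraction by construction. Gravity is off throughout: a sub-mm
bed loaded to tens of MPa is gravity-insensitive. Boxes are periodic in
x and y with flat plates on the z faces; the generator warns when the
box edge is below four largest-particle diameters (statistical
representativity) and refuses particles that do not fit the box at all.
Boxes below roughly two largest diameters additionally strain the
minimum-image convention; the 0.6 mm box of the coarse grade is such a
case and routinely fails the relaxation tolerance — which is itself the
clearest sign that the box is not a representative volume element.

## Time integration and the loading protocol

Velocity-Verlet for translation, explicit Euler for angular velocity
(spheres need no orientation tracking beyond the rolling torque).
Neighbour search uses a cell list with a Verlet skin of half the
smallest radius, rebuilt when any particle moves half a skin; contact
histories follow pairs across rebuilds. The stable time step is a
Rayleigh-type estimate $0.2\sqrt{m_{\min}/k_{lin}}$ with $k_{lin}$ the
law linearised at a reference overlap (1% of the smallest radius for
the exported estimator; the driver uses 10% as a conservative in-run
default, since compaction overlaps are large) and the unloading
stiffness $k_2$ as the worst case. A restitution-matched nonlinear
dashpot (the standard damping–restitution relation for Hertzian
springs) stabilises the dynamics; it is a switch, excluded from all
analytic-law tests.

Loading is strain-driven: the top plate moves down at constant speed to
the target engineering strain (referenced to the post-relaxation bed
height) or until the measured plate stress reaches an optional stop
value, then optionally reverses at the same speed until the plate force
vanishes. Axial stress is the top-plate reaction over the plate area,
window-averaged between curve samples. The plate speed is set by the
step budget `n_steps`; quasi-staticity is judged by the logged
kinetic/elastic energy ratio and, more robustly, by insensitivity of the
recorded curve to halving the speed (the suite checks < 3% change on a
small bed). Mass scaling is exposed but off by default; at a fixed step
budget it changes neither the inertia number nor the curve, so honest
rate control comes only from more steps.

## Calibration

Agreement with a reference compression profile is the coefficient of
determination $R^2 = 1 - \sum(y-\hat y)^2 / \sum(y-\bar y)^2$, the
simulated stress linearly interpolated onto the reference strain grid,
loading leg only by default. The search over the free parameter
(typically $\beta$) is a coarse grid followed by golden-section
refinement. Termination requires both $R^2$ above the acceptance
threshold (default 0.95) *and* localization of the parameter within a
tolerance (default 1/30 of the search range): near its optimum the
$R^2$ surface is flat — many $\beta$ values exceed 0.95 — so the
threshold alone would return whichever candidate happened to cross it
first. An exact fit ($R^2 = 1$, which a noise-free synthetic reference
produces at the generating parameter) terminates immediately. The
plasticity depth $\varphi_f$ stays fixed at a high constant value
(0.99) during calibration. Budget exhaustion returns the best-seen
result flagged as not converged rather than an error.

Synthetic references are generated by the simulator itself at known
parameters (optionally with multiplicative noise), so parameter-recovery
tests have exact ground truth. They emulate the *shape* of compression
profiles; they do not emulate experimental artefacts (punch compliance,
die-wall friction gradients, digitisation error), so passing recovery
tests demonstrates internal consistency of the calibration loop, not
fidelity to any laboratory curve.

## RVE study

The size series regenerates an independent packing per box edge at fixed
PSD and fraction, compacts each with the same protocol, and scores each
curve against the largest box by $R^2$; a member reaching 0.95 is
declared representative. The default working box is $(0.8\,\mathrm{mm})^3$:
in the series 0.6/0.8/1.0 mm for the coarse grade, the 0.8 and 1.0 mm
responses agree to $R^2 > 0.99$ while the 0.6 mm box cannot even relax
to a valid initial state (largest particles are three-quarters of the
box edge), so the smaller box is rejected and the 0.8 mm box is the
economical representative choice.

## Problem sizes used by the tests and the acceptance script

The test suite runs at desk scale by design: two-particle rigs and
25-particle clouds for the integrator invariants; ~130-particle
near-monodisperse beds (0.35 mm box) for the virial, hysteresis,
determinism, rate-insensitivity and calibration-recovery checks
(calibration references are compressed to 50% strain with a
2–2.5·10^4-step budget); full-PSD packings of both grades in the 0.8 mm
box for the packing checks; and 1.2·10^5-step compaction runs for the
end-point checks. The acceptance script uses 2–2.5·10^5-step runs, the
0.8 mm box for the coarse grade and a box sized to hold ~1200 particles
(0.457 mm) for the fine grade. Doubling these budgets changes recorded
stresses by under 3%.

## Known limitations

* Spheres only; no particle breakage, bonding, twisting resistance, or
  rate/temperature dependence of the material.
* The stress coupling uses only the isotropic (trace) part of the
  particle tensors; anisotropic coupling is out of scope.
* Minimum-image periodicity limits particle diameters to well under the
  lateral box edge; coarse PSD tails in small boxes are rejected rather
  than silently truncated.
* In this model family the macroscopic stress at a given strain scales
  essentially linearly with the particle Young's modulus (the virgin
  branch is Hertzian in $E^*$, and the multi-contact term is itself
  proportional to the stress level). Two materials whose moduli differ
  by a factor of five therefore cannot produce near-identical
  compression profiles at identical strain under identical remaining
  parameters; reported parameter sets with that property must involve
  additional, unstated calibration. The package reproduces the printed
  model faithfully rather than the irreproducible overlay.
* Die-fill, ejection and die-wall friction stages of real tableting are
  not modelled; the decompression leg is a plate reversal only.
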
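# mcdem — multi-contact DEM simulation of powder compaction

`mcdem` simulates the confined uniaxial compression (tableting) of
plastically deforming powders at the particle scale, for formulation
scientists and granular-mechanics researchers who need compression
profiles — axial stress versus engineering strain — predicted from
single-particle properties at relative densities where classical DEM
breaks down.

## The model

Particles are soft spheres in a laterally periodic box between rigid
plates. The normal contact law is a non-linear hysteretic adhesive
elastic–plastic model:

```
       F0 + k1 δ^{3/2}                virgin loading
Fn  =  F0 + k2*(δ^{3/2} − δ0^{3/2})   unloading / reloading
       F0 − kc δ^{3/2}                adhesive branch
```

with Hertzian loading stiffness `k1 = (4/3) E* sqrt(R*)`, plastic
overlap `δ0 = (1 − k1/k2*)^{2/3} δmax`, and an unloading stiffness
`k2*` that interpolates between `k1` and `k2` with the maximum overlap
`δmax` reached at that contact, saturating at
`δ*max = k2/(k2−k1) φf 2R*`. Setting `k2 = k1, kc = 0` recovers plain
Hertz–Mindlin. On top of this, every particle–particle contact receives
the **multi-contact correction**

```
ΔFn = (β ν A_ij) P_ij ,   P_ij = (tr σi + tr σj) / 3
```

where `σi` is the particle's compression-positive Love–Weber stress
tensor, `A_ij = π R* δ` the contact area, `ν` the Poisson ratio and `β`
a material-dependent prefactor (`β = 0` is conventional DEM). This
couples each contact to the load carried by its neighbours — the
"geometric hardening" that dominates compaction beyond ~20% strain.
Tangential forces are Mindlin springs with a Coulomb cap; rolling
resistance is the constant-directional-torque model. Around the contact
model the package provides log-normal PSD fitting from Q3 quantiles,
packing generation by particle growth, strain-driven
compaction/decompression, RVE size series, and `R²`-based calibration
of `β` against reference curves.

Two microcrystalline cellulose parameter sets ship with the package:
`mcc_a()` (coarse grade, Avicel PH 200 type) and `mcc_p()` (fine grade,
Pharmacel 102 type), including wall properties, friction/restitution
coefficients and PSD quantiles.

## Worked example

```r
library(mcdem)
grade  <- mcc_a()                       # material + PSD of the coarse grade
fit    <- fit_psd(grade$psd)
pk     <- generate_packing(0.5e-3, fit, 0.59, grade$material, seed = 1)
params <- contact_model_params(k2_over_k1 = 120, kc_over_k1 = 0.5,
                               phi_f = 0.99, beta = 1.3)
sim    <- run_uniaxial(pk, params, loading_protocol(max_strain = 0.5),
                       sim_control(n_steps = 1e5))
print(pk)
print(sim)
sim$curve[c(160, 320, 400), c("strain", "stress", "relative_density")]
```

```
<mcdem_packing> 76 particles, box 0.5 x 0.5 x 0.5 mm, fraction 0.590
<mcdem_compaction> 401 samples, peak stress 44 MPa at strain 0.501 (100250 steps, dt = 3.92e-09 s)
    strain   stress relative_density
160    0.2  6885563           0.7375
320    0.4 25759232           0.9833
400    0.5 43779720           1.1800
```

The packing generator grew 76 spheres sampled from the fitted
volume-weighted log-normal (median 224.6 µm) to exactly 59% solid
fraction in a (0.5 mm)³ periodic box. Compressing the bed to 50%
engineering strain drives the relative density from 0.59 past 1 —
nominal sphere volume exceeds the bed volume, i.e. deep plastic overlap
— and the axial stress climbs to 44 MPa, with the multi-contact term
supplying the growing extra stiffness at high density. A `beta = 0` run
on the same packing stays noticeably softer beyond ~20% strain.

A thin command-line interface wraps the same functions
(`exec/mcdem compress|probe|calibrate|rve --config run.yaml ...`); the
YAML config schema is documented at the top of that script.

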
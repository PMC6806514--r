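# escrtsim

Coarse-grained simulation of ESCRT-III filament-driven membrane
remodelling and scission.

ESCRT-III is the only cellular machine known to deform and cut membranes
from the *inside* of a membrane neck — away from the cytoplasm. `escrtsim`
implements a minimal particle-based model of how it might do that: a
**chiral bead-spring filament** (rigid three-bead units, every adjacent
pair interconnected by 9 harmonic bonds) adsorbed on a **solvent-free,
one-particle-thick fluid membrane**, evolved with Langevin dynamics under
zero lateral tension. The filament's stress-free shape is a closed ring of
radius *R* whose units are tilted by an internal angle *τ* about the local
tangent, so its membrane-binding face lies on a cone of aperture
90° − *τ*. Everything the model does follows from switching this target
geometry between two states:

* **flat state** (*τ* = 0): long filaments form tense planar spirals that
  densify on the membrane but cannot deform it beyond a shallow
  (≈ −5 nm) enveloping buckle;
* **tilted state** (*τ* ≠ 0): the same spiral relaxes into a 3D helix and
  buckles the membrane — downward cones for 0 < *τ* < 90°, tubules at
  *τ* = 90°, everted (upward) deformations for *τ* < 0, and nothing at
  *τ* = −80…−90° (upward wrapping is intrinsically costlier);
* **switching back** from tilted to flat around a membrane-bound cargo
  constricts the neck of the cargo's buckle and drives **scission**,
  releasing a cargo-containing vesicle while the filament returns to the
  membrane plane.

The geometry switch replaces every inter-unit bond rest length instantly
and globally (`switch_geometry_state()`); the associated jump in stored
elastic energy is the model's energy input, standing in for
composition changes driven by the Vps4 ATPase. Reduced units: membrane
bead diameter σ = 2.55 nm, k_BT = 1; the reference rigidity is a nominal
persistence length ℓ_p = 1.8·10³ nm set via the bond stiffness
(ℓ_p ≈ 1.1 k_bond σ).

## Worked example

A reduced-scale tilt-switch experiment — flat-state equilibration, a
global switch to (*R* = 11.5 nm, *τ* = 60°), then relaxation into a
downward conical buckle:

```r
library(escrtsim)

params <- validate_config(list(
  geometry = list(R_nm = 11.5, tau_deg = 60, k_bond = 100),
  filament = list(n_turns = 2),
  membrane = list(box_x = 28, box_y = 28),
  run      = list(steps = 8e4, seed = 1, equil_steps = 12000)))

res <- run_tilt_switch(params)
res$report
#> deformation: -4.17 sigma (-10.63 nm), class cone_down, aperture 63.9 deg
#> scission: FALSE; cargo in vesicle: FALSE; membrane components: 1

res$report$depth_plateau_nm   # time-averaged depth over the trailing 20%
#> [1] -10.47

tail(res$series[, c("step", "depth", "stage")], 3)
#>     step     depth  stage
#> 48 90500 -3.691163 tilted
#> 49 92000 -3.928632 tilted
#> 50 93500 -4.169744 tilted
```

The depth series starts near zero in the flat stage and deepens after the
switch; the final report classifies the deformation (cone vs tubule, up vs
down, estimated aperture) and checks for scission. Reversing the tilt
(`tau_deg = -40`) removes the downward drive and, at full scale, everts
the deformation upward; `run_cargo_budding()` runs the full
flat → tilted → flat scission protocol around a receptor-bound cargo
sphere. The methods vignette describes which of these outcomes reduced-
scale runs do and do not reach.

The reference parameter sets are available as presets
(`preset_config("fig1c" | "fig2b" | "fig2c" | "fig4a" | "fig4b")`, boxes of
40–48 σ and 2·10⁶ steps per stage) alongside the reduced `ci-small`
preset. A command-line wrapper is installed with the package:

```sh
Rscript inst/scripts/escrtsim run --preset ci-small --seed 1 --out run1
Rscript inst/scripts/escrtsim analyze --out run1
```

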
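---
title: "The two-state chiral filament model of membrane remodelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The two-state chiral filament model of membrane remodelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(escrtsim)
```

# The model

`escrtsim` implements a minimal particle-based model of how ESCRT-III-like
filaments sculpt and sever membranes. It couples three ingredients:

1. **A chiral bead-spring filament.** The filament is a chain of rigid
   three-bead units: two membrane-binding *binder* beads side by side across
   the filament axis (one on the inner, one on the outer edge of the ribbon)
   and one *core* bead stacked 1 sigma above their midline. Consecutive
   units are connected by **9 harmonic bonds** — every bead pair of the two
   units. Nine bonds pin all six relative rigid-body degrees of freedom of a
   unit pair harmonically (stretch, two bends, twist and the two shears),
   which is what preserves the chirality of the filament: a mirror-image
   arrangement of the same unit has measurably different rest lengths.

2. **A switchable target geometry.** The stress-free configuration encoded
   in the bond rest lengths is a closed ring of radius $R$ whose units are
   rotated about the local ring tangent by a tilt angle $\tau$. The rest
   lengths are *computed*, not tabulated: the package constructs the target
   ring explicitly and reads off the 3 intra-unit and 9 inter-unit bead
   distances (`build_target_ring()`, `compute_rest_lengths()`). At
   $\tau = 0$ the binding face lies in the ring plane (the *flat* state); at
   $\tau \ne 0$ the binding sites sit on a cone of aperture
   $90^\circ - \tau$, reaching a cylinder (tubule limit) at
   $\tau = \pm 90^\circ$. `switch_geometry_state()` replaces every
   inter-unit rest length instantly and globally — this discontinuous
   change in stored elastic energy is the model's energy input, standing in
   for a change in filament composition driven by ATP-consuming machinery.

3. **A solvent-free, one-particle-thick fluid membrane.** Each membrane
   particle carries an orientation vector; the pair energy has a soft $4$-$2$
   repulsive core below $r_\mathrm{min} = 2^{1/6}\sigma$ and a
   $\cos^{2\zeta}$ attractive tail vanishing at $r_c = 2.6\sigma$, modulated
   by an orientation kernel $\phi = 1 + \mu(a - 1)$ with
   $a = (\hat n_i \times \hat r)\cdot(\hat n_j \times \hat r)$. The energy
   is deepest ($-\varepsilon$) when both orientations are parallel and
   perpendicular to the bond, so flat fluid sheets self-assemble. With the
   defaults ($\varepsilon = 4.34\,k_BT$, $\mu = 3$, $\zeta = 4$) the sheet
   is fluid (in-plane diffusion $D \approx 0.07\,\sigma^2/t_0$) with bending
   rigidity $\kappa \approx 20\,k_BT$, in the biological 10–30 $k_BT$ range.

Binder beads adhere to all membrane particles via a short-range isotropic
well (repulsive core vanishing at contact, $\cos^2$ tail of width
$0.5\sigma$, depth `eps_binder` = 4 $k_BT$ by default). A cargo sphere
(diameter $4\sigma$) adheres only to *receptor*-labelled membrane particles.
All other non-bonded contacts are purely repulsive (WCA-type cores that
vanish exactly at the contact distance).

## Units

One reduced length unit $\sigma$ is the membrane bead diameter, mapped to
**2.55 nm**: this places the model's reference ring radii on round
multiples of $\sigma$ (20.4 nm = 8$\sigma$, 15.3 nm = 6$\sigma$,
14.1 nm = 5.5$\sigma$, 11.5 nm $\approx$ 4.5$\sigma$), which strongly
suggests the native grid the nm values came from. The energy unit is
$k_BT = 1$, all masses are 1, and the time unit is
$t_0 = \sqrt{m\sigma^2/k_BT}$. No mapping of reduced time to seconds is
attempted — the model makes no kinetic-rate claims.

# Dynamics

Positions and velocities follow Langevin dynamics integrated with the
Grønbech-Jensen–Farago velocity-Verlet scheme ($\gamma_t = 1$, exact
configurational statistics for harmonic modes, reduces to plain velocity
Verlet when the thermostat is off). Orientation vectors follow overdamped
rotational Langevin updates with re-normalisation; the rotational friction
default $\gamma_r = 3$ keeps the explicit-Euler rotation step comfortably
inside its stability region at the default timestep. The timestep defaults
to $0.01\,t_0$ and is automatically reduced to $0.2/\sqrt{k_\mathrm{max}}$
when stiff bonds demand it; intra-unit bonds are 10 times stiffer than the
inter-unit stiffness, capped at 2000 $k_BT/\sigma^2$ (beyond that the units
are rigid for all practical purposes and further stiffness only shrinks the
stable timestep).

Randomness is *counter-based*: every (seed, absolute step, particle,
channel) tuple indexes an independent splitmix64 stream, so a run resumed
from a checkpoint reproduces the uninterrupted trajectory bit for bit. Two
engine details make this exact rather than approximate: neighbour sublists
are sorted so force summation order never depends on when the list was
rebuilt, and the lateral barostat acts at the *start* of each step so all
state carried across a step boundary refers to the returned configuration.

**Zero-tension ensemble.** Budding and tubulation consume projected
membrane area. A Berendsen-style barostat rescales the periodic box (and
all lateral coordinates) toward zero lateral tension; without it, deep
deformations would be capped by the tension they themselves build up. The
freshly built triangular lattice starts at $r_\mathrm{min}$ spacing, about
12% above the tensionless equilibrium area, so patch equilibration uses a
stronger coupling to remove the excess area before production.

**Assembly and switching transients.** A freshly placed spiral overlaps the
fluctuating membrane somewhere, and a geometry switch changes every rest
length discontinuously. Both events are absorbed by short *settling* runs
in which per-step displacements are clamped to $0.05\sigma$; without the
clamp the impulsive forces can eject individual membrane particles, which
then masquerade as spurious "deformations" in the depth analysis. For the
same reason the height-field estimator analyses only the largest connected
membrane component (which, after a scission event, is also the natural
definition of the parent sheet) and ignores lateral bins occupied by fewer
than 2 particles.

# Filament rigidity and the persistence-length dial

Filament rigidity is set by the inter-unit bond stiffness `k_bond`. All
inter-unit deformation modes are harmonic with energy
$c\,k_\mathrm{bond}\alpha^2$ per joint; numerically, the 9-bond pair energy
gives $c_\mathrm{in} \approx 0.48$ for in-plane and
$c_\mathrm{oop} \approx 0.64$ for out-of-plane bending (angles in radians
at unit spacing 1$\sigma$). The wormlike-chain tangent correlation then
decays with
$1/\ell_p = \tfrac12\left(\tfrac{1}{2c_\mathrm{in}k} +
\tfrac{1}{2c_\mathrm{oop}k}\right)$, i.e.
$\ell_p \approx 1.1\,k_\mathrm{bond}\,\sigma$. This harmonic map is the
package's nominal calibration (`kbond_to_lp()` / `lp_to_kbond()`); it is
exactly linear and monotone by construction. Tangent-correlation estimates
from finite Langevin trajectories (`persistence_length_estimate()`) scatter
around this value and typically fall somewhat below it, for two reasons
that the estimator design acknowledges: within-unit jitter multiplies the
correlation by a constant factor (handled by fitting the log-correlation
with a free intercept), and the long-wavelength bending modes of stiff
filaments relax far too slowly to equilibrate in any affordable run
(handled by restricting the fit window to short contour separations,
`max_s`). The reference rigidity $\ell_p = 1.8\times 10^3$ nm
($\approx 706\sigma$) maps to $k_\mathrm{bond} \approx 640\,k_BT/\sigma^2$
— deep in the rod limit for the filament lengths simulated, where only a
lower bound on $\ell_p$ is measurable from the trajectory itself.

# The four scenarios

All scenarios start from the same construction: an equilibrated flat patch,
and a planar Archimedean spiral (inter-arm gap 1.1$\sigma$, binder faces
down) whose bond rest lengths are those of the *target ring*, so the spiral
carries stored tension wherever it is longer than the target circumference.
The default filament length is three target circumferences; sweeps hold the
length fixed while varying the tilted state.

* `run_flat_relaxation()` — the null experiment. The spiral densifies as
  outer arms contract and inner arms expand, but with the binding face
  trapped in the membrane plane no deep deformation can develop; only a
  shallow enveloping buckle of roughly $-2\sigma$ ($\approx -5$ nm) forms
  as the membrane wraps the filament to maximise contact.
* `run_tilt_switch()` — flat-state equilibration, then a global switch to
  $(R, \tau)$. Positive tilt drives a downward cone (tubule at
  $\tau \to 90^\circ$ or high stiffness), negative tilt an everted
  (upward) deformation; large negative tilts produce nothing, reproducing
  the model's intrinsic up/down asymmetry (an upward deformation forces the
  membrane to wrap the filament from inside at higher curvature).
* `run_sweep()` — one tilt switch per $(\tau, R, \ell_p)$ grid point from
  identical initial spirals; deeper buckles develop for stiffer filaments
  and smaller target radii.
* `run_cargo_budding()` — a weakly adhering cargo sphere corralled by the
  spiral; switch to the tilted state wraps the cargo in a conical buckle,
  and the switch back to flat constricts the neck and releases a
  cargo-containing vesicle while the filament returns to the membrane
  plane. The `weak`/`strong` presets differ only in the receptor fraction
  under the cargo (0.5 vs 1.0); with the strong preset the cargo already
  dents the membrane before any switch.

Plateau detection fits the depth series over the trailing 20% of a stage;
$|$slope$| < 0.01\sigma$ per $10^3$ steps declares convergence. Reports
carry both the final-frame depth and the *plateau depth* (the time-average
over the same trailing window): a single frame samples an extremal-bin
statistic and is noticeably noisier than the flattened depth-versus-time
curve it is drawn from.

# Measurement conventions

* **Depth**: lateral $2\sigma$ bins of mean membrane height; reference
  plane = median of bins in the outer 20% annulus; depth = extremal bin
  mean minus reference, signed (negative = away from the cytoplasm, which
  lives at $z > 0$).
* **Shape**: mean radius about the deformation axis per height slab;
  near-constant radius = tubule (aperture $< 15^\circ$), linearly shrinking
  radius = cone; deformations shallower than $2\sigma$ are `none`.
* **Scission**: connected components of the membrane contact graph (edge
  below 1.5$\sigma$, between the first and second neighbour shells of the
  cohesive sheet; components via igraph). Scission = at least two
  components of 50+ particles; a vesicle spans neither periodic direction;
  the cargo is "in" a vesicle if its nearest component is a vesicle and it
  lies inside that component's mean shell radius.
* **Membrane mechanics**: bending rigidity from the small-$q$ Helfrich
  spectrum $\langle|h_q|^2\rangle = k_BT/(A\kappa q^4)$ of the binned
  height field; diffusion from the in-plane MSD slope over the final half
  of a trajectory (using unwrapped coordinates via the engine's image
  counters).

# Design decisions on genuinely open points

* **Bead arrangement within a unit.** The source imagery shows only "three
  beads, two of them membrane-binding". We place the two binders *across*
  the filament axis (inner/outer edge) rather than along it: with binders
  along the axis, in-plane bending and twist are only quartically
  constrained by the 9 bonds (soft modes that let the filament wander off
  its target ring), whereas the across arrangement makes every mode
  harmonically stiff. This is a property of the 9-bond geometry, checked
  numerically during design.
* **Tilt sign.** Positive $\tau$ tips the core outward and the binding face
  inward-and-down; this is the sign that produces *downward* buckles, the
  biologically canonical direction.
* **Mirror symmetry.** Reflecting the construction through the ring plane
  maps the *binding* geometry of $+\tau$ exactly onto $-\tau$ (asserted in
  the tests to $10^{-9}$). The core bead is excluded from this relation by
  design: it stays on the cytoplasmic side in both states, since a literal
  mirror would place the filament backbone inside the membrane.
* **Nine bonds = all bead pairs.** The "9 bonds between neighbouring
  units" are realised as the full $3\times3$ set of inter-unit bead pairs —
  the only arrangement with that count.
* **Configuration format.** Run configurations are nested YAML maps
  (`read_config()`); all interaction constants live in the
  `interactions.*` namespace.
* **Cargo presets.** The source states only "weakly adhere" and "a higher
  density of membrane receptors"; the package fixes depth
  `eps_cargo` = 8 $k_BT$ with receptor fractions 0.5 (weak) and 1.0
  (strong) inside a 3$\sigma$ disc, located by a small scan such that the
  weak cargo stays adsorbed with a shallow indentation and does not bud on
  its own within the standard run length.

# What the generator emulates — and what it does not

All inputs are generated in-package: there is no external data. The
membrane patch, spiral, and cargo builders *are* the study conditions; the
reference parameter sets are available as presets (`preset_config()`:
`fig1c`, `fig2b`, `fig2c`, `fig4a`, `fig4b`) with box sizes of 40–48
$\sigma$ and $2\times10^6$ steps per stage at the reference rigidity
$\ell_p = 1.8\times10^3$ nm. The test suite and the acceptance script run
*reduced* versions of the same protocols — boxes of 22–40 $\sigma$,
filaments of 1.3–3 turns, $10^4$–$10^5$ steps, bond stiffnesses of
20–300 $k_BT/\sigma^2$ — chosen so each scenario completes in minutes on
one core while still exhibiting the qualitative transitions (the methods
are identical; only the problem sizes differ). Consequences to keep in
mind: reduced runs sit further from the depth plateau, upward (everted)
deformations — which are slower and costlier than downward ones — are
close to the edge of what develops at these scales, and periodic-image
interactions are larger than at full scale. Passing tests demonstrate the
mechanics of the model at reduced scale, not quantitative convergence of
the full-scale phase diagram; and none of this says anything about real
membranes beyond what a coarse-grained two-parameter membrane can say.

Two reduced-scale boundaries deserve explicit mention. First, at bond
stiffnesses above roughly 300 $k_BT/\sigma^2$ the frustrated filament
exerts local forces that pop individual particles out of the
$\varepsilon = 4.34\,k_BT$ membrane, so all validation runs stay at
$k_\mathrm{bond} \le 150$ (nominal $\ell_p \lesssim 420$ nm); the
reference rigidity is exposed through the full-scale presets only. Second,
the tilted-state cone depth saturates near $4\sigma$ at these stiffnesses
and radii, which is not deep enough to engulf the cargo sphere; the
reduced-scale cargo protocol therefore exercises the complete
flat–tilted–flat pipeline, the corralling, the conical trapping and the
scission detector, but the scission event itself is a full-scale outcome
that the reduced runs do not reach.

# Known limitations

* Filaments neither polymerise nor depolymerise; geometry changes are
  global and instantaneous. Local or mixed geometry states are out of
  scope.
* The membrane is a one-particle-thick effective surface: no bilayer
  leaflets, no spontaneous curvature, no multi-component lipids.
* The tilted state has no explicit target pitch; helices arise solely from
  volume exclusion, which is the model's central claim.
* Rotational dynamics of membrane orientations is overdamped and therefore
  dissipative; energy-conservation checks apply to the translational
  (bead-spring) sector.
* One cargo sphere per system; no explicit electrostatics or
  hydrodynamics.
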
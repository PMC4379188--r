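---
title: "Model and numerical methods of taxisim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and numerical methods of taxisim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(taxisim)
```

`taxisim` simulates one cell migrating inside a 3D elastic substrate
under mechanotactic, thermotactic, chemotactic and electrotactic
guidance, with the cell's shape evolving by discrete protrusion and
retraction. This vignette explains the model, the parameters that matter,
the numerical choices, what the synthetic scaled-down test world does and
does not establish, and the known limitations.

## The model

### Substrate and mechano-sensing

The substrate is a box meshed by regular 8-node hexahedra with isotropic
linear elasticity (Poisson ratio 0.3) and a Young's modulus field, by
default linear in x (1 kPa at x = 0 to 100 kPa at x = 400 µm). All six
surfaces are traction-free; rigid-body modes are removed by a minimal
3-2-1 point constraint. The cell occupies a face-connected set of
elements on the same mesh (cell-occupied elements carry the modulus
K_pas + K_act = 4.8 kPa during the solve; the source model does not state
an in-mesh cell modulus, so the series stiffness of its own passive and
active elements is used).

Each step the cell probes its surroundings: every membrane node is loaded
by a force `F_sens` directed at the cell centroid, and the elastic
problem is solved. `F_sens` is calibrated once per run so that on a
homogeneous substrate at the minimum stiffness the most negative sensed
strain equals `eps_min` (−0.09); this keeps the sensed strains spanning
the informative range of the stress law. Because the problem is linear,
the calibration is one unit-load solve and a rescale.

**The sensing readout.** The directional strain at membrane node i is
read from the average strain tensor of the substrate elements on the
*outward* side of the node, projected on the node-to-centroid direction
and negated, so that a contraction registers as negative. Three
properties motivated this discrete reading, all verified numerically on
this package's meshes:

* it is monotone in local substrate compliance (softer surroundings and
  nearby free surfaces read more negative), which is the property the
  migration mechanism requires — nodes with smaller deformation transmit
  larger traction, so the net traction points towards the stiff side;
* being a spatial derivative, it is blind to the rigid drift of the
  contracting cell towards the compliant side of a graded substrate
  (reading the strain inside the cell body instead makes the net
  traction point *down*-gradient at moderate gradients, through the
  Poisson response of the contraction ring and the drift term);
* a membrane node with no outward substrate element (the cell pressed
  flat against a free box surface) has no anchorage; it is assigned the
  largest admissible contraction `eps_min`, whose negative passive
  stress pushes the membrane off the surface. Without this rule free
  surfaces become sticky, the opposite of the observed behavior.

Sensed strains are clamped at zero from above before entering the stress
law: the probing contraction compresses the cell, and the rare positive
readings are voxel artifacts of concave membrane pockets.

### Stress, adhesivity and traction

The active+passive stress law is piecewise linear in the sensed strain:
passive slope `K_pas` = 2.8 kPa outside [−0.09, 0.09]; inside, the active
acto-myosin stress rises from zero at `eps_min` to `sigma_max` = 0.1 kPa
at `eps_tilde = sigma_max/K_act` = 0.05 and falls back to zero at
`eps_max`. It is continuous at all three breakpoints for any valid
parameter set (property-tested).

Nodal tractions act along the node-to-centroid direction with magnitude
`sigma_i * zeta * A_i`, where `zeta = k n_r psi` = 1e8 is the adhesivity
(front and rear values equal by default) and `A_i` is the node's
tributary membrane area — a quarter of each incident exposed voxel face —
*projected on the pull direction and rectified at zero*. The projection
makes the quadrature consistent with a surface integral of stress over
the membrane (a rear-facing patch of a concave pocket has no anchorage
along the pull and transmits nothing). This choice was selected by
measuring the direction statistics of the net traction on the actual
ensemble of dynamically generated cell shapes: the uniform S(t)/n share
leaves the direction noise-dominated at this cell resolution, the
projected-rectified weighting recovers a clear up-gradient mean.

Forces are kept in these adhesivity-scaled model units; the paper-scale
value of `zeta` makes absolute Newtons non-physical, and only force
ratios and directions drive the dynamics. Two calibration constants map
model forces to kinematics, both fixed at run start before any random
draw:

* **velocity scale `c_v`** — the net traction declines roughly like 1/E
  along the gradient, so the Stokes velocity is anchored midway: a probe
  cell at the domain center must move at `v_ref` = 1 µm/min. This makes
  a substrate crossing take on the order of a hundred 10-minute steps,
  the intended timescale.
* **electric gain** — the saturation-strength field (100 mV/mm) must
  dominate every traction-based force (the observed behavior: the cell
  is held at the cathode, unable to protrude), so the gain equates
  |F_EF(E_satur)| with the net traction of a probe cell at the soft end
  of the substrate, the largest traction force a full-length run
  generates (independent of where the run starts). Below
  saturation the electric force grows quadratically in E (charge linear
  in E times E); the optional `ef_velocity_saturation` flag clamps it
  above saturation.

### Force balance and motion

With inertia negligible, drag closes the balance exactly:
`F_drag = −(F_eff + F_prot + F_EF)`. The effective force redistributes
the net-traction magnitude over the active cue directions with convex
weights (`mu_mech + mu_ch + mu_th = 1`; inactive cues donate their weight
to mechanotaxis). The protrusion force has magnitude `kappa |F_net|`
with `kappa ~ U[0,1)` redrawn each step and an isotropic random
direction. Speed follows Stokes drag around a sphere of the nominal
radius corrected by the Corey shape factor; polarization opposes the
drag.

### Discrete remodeling

The membrane nodes are split by the plane through the centroid normal to
the polarization (`delta = e_pol . s`; ties to the front). The highest-
delta node nominates a free element to occupy, the lowest-delta node a
cell element to release; among the elements incident to the nominating
node the candidate maximizing (minimizing) the projection on the
polarization is taken, subject to: mesh bounds, face-connectivity of the
cell after the swap, and the pseudopod volume cap. Swap pairs are applied
until the accumulated centroid displacement reaches `v dt`; the final
partial swap is taken with probability (remaining)/(stride), which makes
the expected displacement exact and — importantly — leaves no absorbing
states (a deterministic rounding rule froze cells permanently whenever a
shape's readout momentarily collapsed, since every driving force scales
with the net traction).

The pseudopod cap operationalizes "about 10% of the volume may protrude":
elements whose centroid lies farther than `r + h/2` from the cell
centroid count as protrusion volume (the half-edge slack absorbs the
voxel quantization of the radius), at most `ceiling(0.1 N)` of them, with
two allowances that the coarse cell needs to stay live: a swap that does
not increase the count is always admissible (an elongated body cannot
deadlock), and when the budget is full the cell first releases a standing
protrusion — the documented behavior of retracting pseudopods in
subsequent steps. A transient excess of up to two elements can appear
when a retraction shifts the centroid; the property tests assert this
bound.

At the test resolution (32-element cell, 10 µm elements) one swap moves
the centroid by ~1.4 µm, which is comparable to the displacement a
fine-mesh cell accumulates over its full swap budget; the desk preset
therefore caps at 3 swap pairs per step (the fine "paper" preset keeps
10).

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| K_pas, K_act | 2.8, 2 | kPa | passive / active element stiffness |
| sigma_max | 0.1 | kPa | peak acto-myosin stress |
| eps_min, eps_max | −0.09, 0.09 | — | active strain range |
| k, n_r, psi | 1e8, 1e5, 1e-5 | mol⁻¹, —, mol | adhesivity factors |
| r | 20 | µm | nominal cell radius |
| nu | 0.3 | — | substrate Poisson ratio |
| eta_min | 1000 | Pa s | substrate viscosity at minimum stiffness |
| lambda | 0 | Pa s/kPa | viscosity-stiffness slope (no stated value; uniform viscosity by default) |
| omega_satur | 1e-4 | C/m² | saturation surface charge |
| e_satur | 100 | mV/mm | charge-saturating field strength |
| dt | 10 | min | real time per step |
| v_ref | 1 | µm/min | midpoint speed anchoring `c_v` |
| kappa | random U[0,1) | — | protrusion amplitude (fixable for deterministic runs) |

The thermal cue is ignored when the end-to-end temperature difference is
below 0.2 °C (no thermotactic response to very mild gradients).

## The scaled-down test world

Paper-scale runs (128,000 elements, hundreds of steps, ten repeats per
condition) are far outside the test-time budget of an R implementation,
so the shipped acceptance campaigns run a deliberately scaled world:

* mesh 400 × 100 × 100 µm at 10 µm elements (40 × 10 × 10); the cell is
  32 elements;
* runs start at the substrate midpoint — the equilibrium plane is an
  attractor and does not depend on the start, and the climb from the
  soft corner adds only travel time;
* 3 repeats per condition, 220 steps per run.

What a green campaign establishes: the *mechanisms* — up-gradient net
traction everywhere in the bulk, free-surface repulsion creating an
interior equilibrium plane short of the stiff wall, additive cues and
the electric force shifting that equilibrium monotonically towards the
wall, and morphology peaking away from the boundary. What it does not
establish: the printed equilibrium positions at paper precision. At 32
elements the net-traction direction carries shape noise of the same
order as the mid-substrate gradient signal, so trajectories are
substantially more diffusive than at paper scale, equilibrium means
shift by one to two cell radii, and the between-condition separations
compress. The acceptance tests state the reference positions with the
5%-of-length tolerance; any criterion the scaled world cannot meet is
left failing rather than loosened, with the analysis recorded in the
repository notes.

## Numerical choices

* **Solver.** Per-step elastic solves use preconditioned conjugate
  gradients with an exact sparse Cholesky preconditioner refreshed every
  few steps (the matrix changes only in the handful of cell-occupied
  elements), warm-started from the previous solution, to a relative
  residual of 1e-7 — verified against the direct solve to ~1e-13 on
  fixtures. One-off solves (`solve_elastic`) are direct CHOLMOD solves.
* **Strain recovery** at the element centroid (single-point evaluation
  of the trilinear gradient), adequate for nodal averaging and exact for
  the affine patch test.
* **Degenerate directions.** A vanishing net traction keeps the previous
  mechanotactic direction (a seeded random unit vector at t = 0);
  vanishing drag keeps the previous polarization at zero speed.
* **Principal dimensions** are extents along the eigen-axes of the
  second-moment tensor of element centroids plus one element edge, so
  elongation is rotation-invariant on the lattice.
* **Ties** in the front/rear split go to the front.
* **Steady-state window**: the trajectory tail after the centroid first
  stays within 5% of the substrate length of its final value for 20
  consecutive steps; the Random Index and the equilibrium-plane tail
  mean are computed over it.

## Limitations

* The substrate is linear-elastic and permanent: no degradation,
  remodeling, viscoelastic creep or plasticity.
* One cell; no cell-cell interaction.
* Gradient cues are static linear fields; no diffusion or consumption of
  the chemoattractant, no AC fields.
* The membrane is the voxel surface; no sub-element membrane mechanics
  or tension.
* Protrusion noise is white in time (the redraw-each-step reading); real
  cells have persistent polarity.
* At coarse cell resolutions the shape metrics are strongly quantized;
  single swaps change the elongation by several percent.
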
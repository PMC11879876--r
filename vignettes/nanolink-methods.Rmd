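---
title: "Topology and viscoelasticity of limited-valence nanostar gels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology and viscoelasticity of limited-valence nanostar gels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanolink)
```

# Scope

`nanolink` studies physical gels assembled from valence-3 ("Y-shaped") DNA
nanostars: rigid building blocks whose three sticky-ended arms form
reversible one-to-one bonds. The package couples a coarse-grained rigid-body
Langevin simulator to a topology-centric analysis pipeline: bonded-network
graphs, a minimum-loop census, Gauss linking numbers between loops
(catenation), pore-size statistics, and viscoelastic moduli by two
independent routes (tracer microrheology via the generalized Stokes-Einstein
relation, and equilibrium Green-Kubo stress autocorrelation). The central
scientific question it serves is how the high-frequency elastic plateau of
such gels scales with concentration, and in particular whether that scaling
is carried by the network's *topology* — the abundance of mechanically
interlocked (catenated) loops — rather than by classical structural measures
alone.

# The coarse-grained model

## Units and geometry

Lengths are in bead diameters `sigma` (2.5 nm of double-stranded DNA,
roughly 8 base pairs), energies in the repulsion scale `eps`, temperature
`T = 1 eps/kB`, friction `Gamma = 1` per core bead, and times in Brownian
times `tau_Br = kB T / Gamma`. A nanostar is a rigid planar Y of 7 core
beads (one central, two per arm at distances `sigma` and `2 sigma`) plus
three terminal patch sites at `2.5 sigma`; patches are zero-volume binding
sites. The default body frame is the idealized three-fold symmetric Y; a
user-supplied geometry (e.g. one inferred from finer-grained nucleotide
simulations) can be passed to `nanostar_geometry()` since only the
coordinate table enters the dynamics.

## Interactions

Core beads of different stars repel through a WCA potential (LJ truncated
and shifted at its minimum, `2^(1/6) sigma`). Patches of compatible types
attract through a Morse potential

$$U(r) = D_0\left[\left(1 - e^{-\alpha (r - r_0)}\right)^2 - 1\right]$$

truncated and shifted at `r_c`. Two stars are *bonded* when a patch pair
sits within `0.2 sigma` (minimum-image distance), the same criterion used
during analysis by `detect_bonds()`. Defaults `D0 = 20 eps`, `alpha =
8/sigma`, `r0 = 0.1 sigma`, `r_c = 0.5 sigma` place the Morse minimum well
inside the bond-detection cutoff and make binding strong (about 20 kT) yet
reversible on thousand-`tau_Br` scales; `calibrate_bond_lifetime()` measures
the mean unbinding time for any other choice. Type labels implement binary
mixtures: A-A and B-B patches attract, A-B never do. One-to-one binding is
additionally enforced at *detection* time by greedy minimum-distance
matching (ties broken by lowest index pair), so the analysis stays robust
even for patch geometries that would permit double binding.

## Dynamics

`run_langevin()` integrates rigid bodies by velocity Verlet: per-site forces
reduce to a COM force and torque, angular momentum lives in the world frame,
and the quaternion drifts through two half-step updates with
renormalization. Friction and thermal noise act per core bead
(free-draining), so a 7-bead star has COM friction `7 Gamma` — the measured
free-star diffusion follows `MSD = 6 kT/(7 Gamma) t`. With the thermostat
off the integrator is symplectic: total-energy drift on a 20-star gas is
below `1e-4 eps` per `tau_Br` at the default `dt = 0.01 tau_Br`, and total
momentum is conserved to machine precision.

The protocol mirrors the standard quench: an equilibration phase with the
Morse attraction switched off entirely, then a production phase with
attraction on. When a microrheology tracer is embedded (a purely repulsive
WCA sphere with contact distance `a + sigma/2`, default radius `a = 2.5
sigma`, Stokes-like friction `2a Gamma` and mass `(2a)^3`), the tracer is
inserted at the center of the largest void (found with the pore-size
kernel), and the equilibration drift is displacement-limited (`0.05 sigma`
per step) so residual overlaps relax without force blow-up, in the spirit of
the standard "limited-displacement" push-off.

The instantaneous pressure tensor is the bead-kinetic term plus the pairwise
virial over *inter*-body interactions only; rigid constraints therefore
enter the stress solely through body-body forces, which is the correct
decomposition for rigid molecules.

# Network topology

## Bond graph and minimum loops

`build_bond_graph()` maps nanostars to nodes (position = central bead) and
bonds to edges, each carrying the periodic-image shift of its far endpoint.
Degree is bounded by the valence, 3. For every node on a cycle,
`find_minimum_loops()` selects one shortest cycle through it by
breadth-first search: each BFS-tree vertex is labelled with the branch it
descends from, and any edge joining two branches closes a candidate cycle
through the root. Among co-minimal candidates the lexicographically smallest
rotated/reflected id sequence is kept, and loops are deduplicated by node
set; 2-cycles (double bonds) are excluded and loops have at least 3 stars.
The per-node choice follows the census definition of "the minimum loop of a
nanostar"; because the loop *count* depends on whether co-minimal loops are
collapsed, `keep_all_comin = TRUE` exposes the alternative convention.

`unwrap_loop()` turns a node sequence into a closed polygon by accumulating
minimum-image steps; the winding vector (net box crossings) flags
non-contractible, box-spanning cycles. Loop geometry runs through nanostar
centers: for non-touching loops, replacing center-polygons by arm-resolved
curves changes geometry but not linking topology.

## Gauss linking and the catenation census

`gauss_linking_number()` evaluates the Gauss double integral *exactly* for
polygonal curves as a sum of signed solid angles over segment pairs and
rounds to the nearest integer; residuals above 0.05 (possible only for
near-touching curves) raise a warning, and curves closer than `1e-6 sigma`
are rejected as having undefined linking. An independent oracle,
`crossing_sign_linking()`, projects both curves along random directions and
halves the signed crossing sum; degenerate projections are redrawn and all
retained projections must agree. The two routes agree on every seeded random
curve pair the suite throws at them and on (2,2k) torus links up to k = 5.

`link_census()` evaluates Lk for every unordered pair of contractible
minimum loops, including periodic images of the second loop within
`image_cutoff` (default: half the box edge plus twice the largest loop
radius) after bounding-sphere pruning. Non-contractible loops are excluded
(Lk against a periodic image of itself is not defined) and their count
reported, so users can see when the box is too small. Totals follow the
census definitions: `L = sum |Lk|`, linking valence `<Z> = L / N_minloop`,
the linked fraction, and the loop-level link graph. A component of that
graph "percolates" when walking its edges with their recorded image shifts
assigns one of its loops two positions differing by a lattice vector — the
standard periodic-percolation wrap test.

## Interpenetration probe

`probe_interpenetration()` drops random probe spheres, induces the bond
graph on the stars inside, and counts connected components after dropping
components below `min_component` nodes (default 3). A finite ball cut from
any *sparse* periodic network also strands boundary fragments whose
connecting paths leave the sphere; these can exceed any fixed size when the
probe radius is large. The optional relative filter (`min_fraction`,
e.g. 0.25) counts only components holding at least that fraction of retained
nodes — a genuinely interpenetrated neighbourhood splits into comparably
sized subnetworks, while boundary fragments stay small relative to the
core. The default (`min_fraction = 0`) is the plain absolute-threshold
contract; the relative mode is what makes the connected single-network
control read as one component at large radii.

# Structural observables

## Mesh size by random insertion

The pore size at a random probe point is the diameter of the largest sphere
that contains the point without overlapping any core bead (radius
`sigma/2`; patches ignored). The optimizer is a constrained local ascent on
the clearance field: the center steps away from the nearest bead surface,
and whenever the probe would leave the sphere the center is pulled back
toward it by bisection; convergence is declared when the radius improves by
less than `1e-4 sigma`. Multi-starts (the probe itself, nudges away from the
three nearest beads, and the far corner of the nearest bead's periodic cell)
reduce local-maximum misses. Every returned sphere is re-validated against
all beads — overlap is a hard error, not a warning. Diameters are capped at
the smallest box edge; capped samples are flagged and excluded from the
Gaussian fit in `mesh_size_stats()`, which reports both the fitted mean
(with standard error) and the plain sample mean, and flags fits with
R-squared below 0.9. On a cubic bead lattice the body-center probe
reproduces the closed form `xi = (2 sqrt(3) - 1) sigma` to better than
`1e-3`.

## Paths and fractal dimension

`branch_path_statistics()` measures `lambda`, the length in *edges* of
maximal chains joining two branching points (degree-3 nodes) through
degree-<=2 interiors; whether the field's convention counts bonds or
nanostars is ambiguous, so the off-by-one is documented here rather than
hidden. `fractal_dimension()` samples graph-shortest paths in the giant
component, computes each path's 3-D radius of gyration from unwrapped
positions, and fits `log Rg ~ nu log n`; the fractal dimension is `d_f =
1/nu`. The rod limit recovers `nu = 1` and chains laid along a spatial
random walk recover `nu = 0.5`.

# Rheology

## Generalized Stokes-Einstein (microrheology)

`gser_moduli()` uses the local power-law (logarithmic-derivative)
approximation: `|G*(1/t)| = kT / (pi a MSD(t) Gamma(1 + alpha))` with
`alpha = d ln MSD / d ln t` clipped to [0, 1], split by `cos(pi alpha/2)`
and `sin(pi alpha/2)`. This is the standard particle-tracking estimator and
is stable on log-spaced lags, unlike a direct numerical Fourier transform of
noisy MSDs. Exact limits hold to 2%: a diffusive MSD gives `G'' = omega
eta`, a plateaued (trapped) MSD gives `G' = k/(6 pi a)` at the plateaued
(low-frequency) end, and `MSD ~ t^(1/2)` gives loss tangent 1 everywhere.
Note the Mason approximation can overshoot a plateau by ~10% in the
crossover decade; plateau values should be read where `alpha` is small.

## Green-Kubo

`green_kubo_relaxation()` computes
`G(t) = V/(3 kT) * sum over the three off-diagonal pressure components of
<P(0) P(t)>`, each component mean-subtracted. The prefactor convention reads
the component sum as an *average over the 3 distinct off-diagonal pairs*
(hence `/3`); the alternative (6 ordered pairs) would double the amplitude
without touching any scaling, and can be emulated by scaling the result.
Lags are limited to a fraction of the series (default 10%) so every
autocorrelation estimate averages many independent stretches.
`fit_stretched_exponential()` then fits `g(t) = a exp(-(t/tau)^b)` with
positivity constraints; `a` is the elastic plateau, `tau` the network
relaxation time, `b` the stretching exponent. On Ornstein-Uhlenbeck ground
truth (three independent components with autocovariance `A exp(-t/tau_c)`),
a series of `1e6` samples at `dt = 0.01 tau_c` with the fit restricted to
lags below `3 tau_c` recovers `A` to a few percent and `b = 1` within 0.05;
shorter series leave the sampling error of `b` above that band, and longer
fit windows let exponentially small tail values (pure autocorrelation
noise) drag `b` down. For simulated gels the `t = 0` point carries the
kinetic delta peak and the first fraction of a `tau_Br` the fast
microscopic decay, so plateau fits should start after that transient.

## Scaling analysis

`fit_power_law()` fits log-log slopes, optionally piecewise around a fixed
breakpoint such as the overlap volume fraction `rho* = 0.056`.
`predict_scaling_exponents()` combines measured constituent slopes into the
model exponents for the high-frequency plateau versus volume fraction:

* mesh-based, `G'_p ~ kT N_minloop / xi^3`: exponent
  `(N_minloop slope) + 3 |xi slope|` — with the reference slopes
  (`N_minloop ~ rho`, `xi ~ rho^-0.84`) this gives 3.52, i.e. the ~3.6-class
  prediction that overshoots direct measurements at high density;
* link-based, `G'_p ~ N_minloop <Z> ~ L`: exponent
  `(N_minloop slope) + (<Z> slope)` — with `<Z> ~ rho^1.4` this gives 2.4,
  the topological-elasticity prediction that tracks the measured ~2.5;
* geometric, `<Z> ~ rho <l_min>^3`: exponent `1 + 3 (l_min slope)` = 1.3
  for `l_min ~ rho^0.1`, consistent with the measured `<Z>` growth;
* phantom-network comparators `rho^1` (prefactor `(f-2)/f`) and `rho^(1/3)`
  are reported alongside as the classical baselines these gels violate.

Standard errors propagate in quadrature; the arithmetic is exact by
construction.

# Colocalization imaging

Two-channel micrographs are normalized to [0, 1] (99.9th-percentile
reference by default — robust to hot pixels; the plain maximum is
available), and interpenetration is quantified by the pixelwise product
`I_y = I_r * I_g`: fully demixed fields give `<I_y> = 0`, fully co-occupied
ones give 1. Batch mode averages `<I_y>` across images with the spread taken
across images. No background subtraction is applied by default (an optional
flat offset exists), since the normalization reference already absorbs
global gain.

# Synthetic fixtures and what they do (not) show

Every generator is a pure, seeded function shipping machine-readable ground
truth:

* `make_torus_link(k)` — two (1,k) curves on a torus, |Lk| = k exactly
  (k = 0: split circles; k = 1: Hopf geometry).
* `make_diamond_network()` — nanostars on a periodic diamond lattice,
  bonds on tetrahedral contacts, valence reduced from 4 to 3 by deleting a
  perfect matching. Two deterministic matchings are provided because no
  single one can deliver every desirable property at once: deleting one
  whole bond direction (`"uniform"`) keeps every node on a hexagon (all
  minimum loops have `l_min = 6`) but decomposes the net into parallel 2-D
  slabs; alternating the deleted direction over (111) layer pairs
  (`"alternating"`, even cubic cell counts) keeps the net fully connected
  *and* every minimum loop a hexagon, at the price of a sparser hexagon
  population. With two sublattices (offset by half the cell diagonal) the
  matching patterns are chosen so that every surviving hexagon of one net is
  catenated with hexagons of the other — a fact established with the
  crossing-sign oracle when the fixture was designed, not assumed. The
  uniform two-sublattice fixture, censused with all co-minimal loops kept,
  has linked fraction exactly 1 and linking valence exactly 1, and its link
  network percolates.
* `make_random_network()` — degree-capped random geometric graphs as null
  models.
* `make_trap_msd()` / `make_ou_stress()` — microrheology and Green-Kubo
  ground truths with closed-form targets.
* `make_two_channel_image()` — binary blob fields where the co-occupied
  area fraction is `phi` exactly, so `<I_y> = phi`.

These fixtures validate the *operations*; they do not emulate every feature
of simulated gels (thermal disorder, transient bonds, polydisperse loop
sizes) and no fixture stands in for the deposited experimental data sets.
Passing fixture tests therefore certifies the algorithms, while statements
about gels come from the simulator itself.

# Problem sizes and numerical choices

The shipped test suite runs desk-scale versions of every analysis: gels of
N = 60 stars quenched for 300-600 `tau_Br` (2 seeds), mesh sampling at
400-2000 probes, 200-500 random curve pairs for the linking oracles, and
OU series of `2e5`-`1e6` samples. At this scale the robust density trends
hold (mean mesh size strictly decreasing with volume fraction across
`rho = 0.02, 0.06, 0.10`; loop count and linking valence non-decreasing),
while the weak `l_min ~ rho^0.1` growth and the GSER/Green-Kubo plateau
agreement sit inside the noise — the tracer in a small short-quench gel is
not fully caged, so tracer microrheology underestimates the plateau that the
Green-Kubo route resolves cleanly. `scripts/trend_campaign.R` runs the
full scaled-down campaign (N = 200, `1e4 tau_Br`, 3 seeds per density, both
rheology routes) for those slower-converging observables.

Other numerical choices, in brief: volume fraction is defined as
`rho = N * 7 * (pi sigma^3/6) / V` over core beads only (patches are
zero-volume; an alternative convention rescales the `rho` axis, not the
exponents); orthorhombic boxes only, triclinic inputs rejected; minimum
images put components in `(-L/2, L/2]` with the boundary folded to the
positive side; Gauss sums must land within 0.05 of an integer; the mesh
optimizer's convergence tolerance is `1e-4 sigma`; stress is sampled every
`0.05 tau_Br` by default; and every randomized stage takes and logs an
explicit seed.

# Known limitations

* Hydrodynamic interactions are absent (free-draining Langevin); absolute
  time scales and moduli inherit that approximation.
* Knots within single loops, loop threading, and links between
  second-order loops are outside the census — the linking analysis is a
  lower bound on topological entanglement.
* The interpenetration probe's component counts are radius-dependent in
  sparse networks; conclusions should quote the probe radius and filter
  settings.
* The default nanostar geometry and Morse parameters are idealized stand-ins
  calibrated for strong-but-reversible binding, not fitted to
  nucleotide-level simulations; both are user-replaceable inputs.
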
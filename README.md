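# nanolink

Topology and viscoelasticity of limited-valence DNA-nanostar gels.

DNA nanostars with three sticky-ended arms (valence f = 3) assemble into
reversible physical networks whose high-frequency elasticity grows far
faster with concentration than classical network theories predict
(phantom-network theory expects `G'_p ∝ ρ (f−2)/f`). `nanolink` implements
the computational machinery needed to test a topological explanation: these
networks interpenetrate, their minimum loops become mutually *catenated*
(mechanically interlocked) above the overlap volume fraction `ρ* ≈ 0.056`,
and the elastic plateau then tracks the total Gauss linking,

    G'_p  ∝  N_minloop ⟨Z⟩  ∝  𝓛 = Σ_{i>j} |Lk(i, j)| ,

with `Lk` the Gauss linking number between minimum loops, `⟨Z⟩ = 𝓛 /
N_minloop` the linking valence, giving `G'_p ∝ ρ^2.4` from the measured
`N_minloop ∝ ρ` and `⟨Z⟩ ∝ ρ^1.4` — against `∝ ρ^3.6` for a mesh-based
estimate `G'_p ∝ k_B T N_minloop / ξ^3`.

The package is aimed at soft-matter simulators and DNA-nanotechnology
researchers and provides:

* a rigid-body Langevin simulator of patchy Y-shaped nanostars (WCA cores,
  Morse sticky patches, A/B type-selective binding, embedded microrheology
  tracer, stress-tensor sampling);
* readers/writers for LAMMPS dump, LAMMPS data and XYZ trajectories;
* bonded-network graphs, branch statistics and a spherical-neighbourhood
  interpenetration probe;
* a minimum-loop census and exact polygonal Gauss linking numbers with an
  independent crossing-sign oracle, periodic-image-aware catenation census,
  and link-network percolation;
* mesh-size (pore) statistics by random insertion, branch-path and fractal
  analysis;
* GSER microrheology and Green–Kubo stress-relaxation moduli, stretched
  exponential plateau extraction and scaling-exponent predictions;
* two-channel image colocalization (the pixelwise "yellow" product map);
* seeded synthetic fixtures (torus links, interpenetrated diamond networks,
  viscoelastic ground truths, colocalization images) with exact expected
  values for every stage.

## Worked example

Catenation census of an interpenetrated diamond fixture, then a small gel
quench:

```r
library(nanolink)

d2 <- make_diamond_network(cells = c(3, 3, 3), sublattices = 2,
                           matching = "uniform", seed = 1)
loops <- find_minimum_loops(d2$graph, keep_all_comin = TRUE)
loops
#> loop_set: 216 minimum loops, l_min in [6, 6], mean 6.00
link_census(loops, d2$config$box, config = d2$config)
#> link_network: 216 loops, total linking L = 216, <Z> = 1.000,
#>   linked fraction 1.000, percolating: TRUE

cfg  <- init_configuration(60, rho = 0.10, seed = 1)
traj <- run_langevin(cfg, force_field(), langevin_params(seed = 1),
                     simulation_protocol(equilibration = 5, production = 300,
                                         frame_every = 300, stress_every = 300))
detect_bonds(traj$final)
#> bond_list: 71 bonds (78.9% of 180 arms bonded, cutoff 0.20 sigma)
g <- build_bond_graph(traj$final, detect_bonds(traj$final))
find_minimum_loops(g)
#> loop_set: 13 minimum loops, l_min in [4, 10], mean 7.46
mesh <- sample_mesh_size(traj$final, n_samples = 1000, seed = 1)
mean(mesh$xi[!mesh$capped])
#> [1] 2.88
```

Every hexagon of one diamond sublattice is Hopf-linked with hexagons of the
other (linked fraction 1, linking valence 1, and the link network itself
percolates); the quenched gel bonds ~79% of its arms within 300 Brownian
times and its pores are ~2.9 bead diameters wide at volume fraction 0.10.
Combining the reference constituent slopes into plateau exponents:

```r
predict_scaling_exponents(nminloop_slope = 1.0, z_slope = 1.4,
                          lmin_slope = 0.1, xi_slope = -0.84)
#> mesh-based plateau exponent:    3.520 +/- 0.000
#> link-based plateau exponent:    2.400 +/- 0.000
#> geometric <Z> exponent:         1.300 +/- 0.000
#> phantom comparators: rho^1 (prefactor 0.333), rho^(1/3)
```

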
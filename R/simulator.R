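## Rigid-body Langevin dynamics of patchy nanostars: R-side surface over the
## compiled engine, plus bond detection on static configurations.

#' Patchy nanostar force field
#'
#' Core beads of different nanostars repel through a WCA potential (LJ
#' truncated and shifted at its minimum, diameter sigma = 1). Terminal
#' patches of compatible types (A-A and B-B, never A-B) attract through a
#' Morse potential `D0 * ((1 - exp(-alpha (r - r0)))^2 - 1)` truncated and
#' shifted at `r_c`. Defaults make binding strong (about 20 kT) yet
#' reversible on thousand-Brownian-time scales, with the Morse minimum well
#' inside the bond-detection cutoff of 0.2 sigma.
#'
#' @param eps Repulsion energy scale (units of the thermal energy at T = 1).
#' @param D0 Morse depth in eps.
#' @param alpha Morse inverse width in 1/sigma.
#' @param r0 Morse minimum distance in sigma.
#' @param r_c Morse cutoff in sigma (must be >= 0.2, the bond criterion).
#' @return `force_field` object.
#' @export
force_field <- function(eps = 1, D0 = 20, alpha = 8, r0 = 0.1, r_c = 0.5) {
  if (r_c < 0.2) stop("Morse cutoff must not be below the 0.2 sigma bond criterion")
  if (D0 < 0) stop("Morse depth must be non-negative")
  structure(list(eps = eps, D0 = D0, alpha = alpha, r0 = r0, rc = r_c),
            class = "force_field")
}

#' Langevin integration parameters
#'
#' LJ-style units: timestep in Brownian times (`tau_Br = kT / Gamma`),
#' friction `Gamma = 1` per core bead, temperature `T = 1 eps/kB`.
#'
#' @param dt Timestep (default 0.01 tau_Br).
#' @param gamma Per-bead friction (default 1).
#' @param kT Thermal energy (default 1).
#' @param seed RNG seed used by [run_langevin()].
#' @export
langevin_params <- function(dt = 0.01, gamma = 1, kT = 1, seed = 1) {
  stopifnot(dt > 0, kT > 0, gamma >= 0)
  structure(list(dt = dt, gamma = gamma, kT = kT, seed = seed),
            class = "langevin_params")
}

#' Simulation protocol: equilibration then production
#'
#' During equilibration the Morse attraction is switched off entirely, as in
#' the reference protocol; production turns it on. Durations are in
#' Brownian times.
#'
#' @param equilibration,production Phase durations (tau_Br).
#' @param frame_every Interval between stored frames (tau_Br).
#' @param stress_every Interval between stress-tensor samples (tau_Br).
#' @export
simulation_protocol <- function(equilibration = 10, production = 100,
                                frame_every = 1, stress_every = 0.05) {
  stopifnot(equilibration >= 0, production >= 0)
  structure(list(equilibration = equilibration, production = production,
                 frame_every = frame_every, stress_every = stress_every),
            class = "simulation_protocol")
}

#' Microrheology tracer bead
#'
#' A large purely repulsive bead (WCA coupling to core beads with contact
#' distance `a + sigma/2`). Its mass scales as the cube of the diameter
#' ratio and its friction linearly with the radius (Stokes-like), relative
#' to a core bead.
#'
#' @param a Tracer radius in sigma (> 0.5).
#' @param position Initial position (box center when NULL).
#' @export
tracer_bead <- function(a = 2.5, position = NULL) {
  if (a <= 0.5) stop("tracer radius must exceed sigma/2")
  structure(list(a = a, position = position,
                 mass = (2 * a)^3, gamma_scale = 2 * a),
            class = "tracer_bead")
}

#' Random initial configuration at a target volume fraction
#'
#' Cubic box sized from `rho = N * 7 * (pi/6) / V`; nanostars inserted at
#' uniform random positions with uniform random orientations, rejecting any
#' insertion that brings two core beads of different stars closer than
#' `min_dist`.
#'
#' @param n Number of nanostars.
#' @param rho Volume fraction (0 < rho < 0.3).
#' @param geometry A [nanostar_geometry()].
#' @param seed RNG seed.
#' @param types Type labels recycled over nanostars (default all "A").
#' @param min_dist Minimum inter-star bead distance (default 0.9 sigma).
#' @param max_tries Insertion attempts per star before giving up.
#' @return A `configuration`.
#' @export
init_configuration <- function(n, rho, geometry = nanostar_geometry(), seed = 1,
                               types = "A", min_dist = 0.9, max_tries = 2000) {
  stopifnot(n >= 1, rho > 0, rho < 0.3)
  set.seed(seed)
  box <- periodic_box(box_edge_for_density(n, rho, nrow(geometry$beads)))
  placed_beads <- NULL
  centers <- matrix(0, n, 3)
  quats <- matrix(0, n, 4)
  nb <- nrow(geometry$beads)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      ctr <- stats::runif(3, 0, box$L)
      q <- drop(random_quaternions(1))
      beads_i <- geometry$beads %*% t(quat_to_matrix(q)) + rep(1, nb) %o% ctr
      if (!is.null(placed_beads)) {
        clash <- FALSE
        for (b in seq_len(nb)) {
          d <- minimum_image(sweep(placed_beads, 2, beads_i[b, ]), box)
          if (min(rowSums(d^2)) < min_dist^2) { clash <- TRUE; break }
        }
        if (clash) next
      }
      centers[i, ] <- ctr; quats[i, ] <- q
      placed_beads <- rbind(placed_beads, beads_i)
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("packing failure at star ", i, " of ", n,
           ": density too high for random insertion; start from a lattice instead")
    }
  }
  place_configuration(geometry, centers, quats, box, types = types)
}

ff_as_list <- function(ff) {
  stopifnot(inherits(ff, "force_field"))
  ff[c("eps", "D0", "alpha", "r0", "rc")]
}

type_codes <- function(types) as.integer(types == "B")

#' Forces, torques, energy and pressure tensor of a configuration
#'
#' Analytic per-site forces reduced to per-nanostar force and torque about
#' the body origin, the total potential energy and the (configurational)
#' pressure tensor `(1/V) sum over inter-body pairs of r_ij x f_ij`.
#'
#' @param config A `configuration`.
#' @param ff A [force_field()].
#' @param attraction_on Whether Morse attraction is active (default TRUE).
#' @param tracer Optional [tracer_bead()] with a set position.
#' @return List: `energy`, `force` (n x 3), `torque` (n x 3), `pressure`
#'   (3 x 3), `tracer_force`.
#' @export
compute_forces <- function(config, ff = force_field(), attraction_on = TRUE,
                           tracer = NULL) {
  stopifnot(inherits(config, "configuration"))
  has_tr <- !is.null(tracer)
  tp <- if (has_tr) tracer$position else c(0, 0, 0)
  .compute_forces_cpp(config$centers, config$quats, type_codes(config$types),
                      config$geometry$beads, config$geometry$patches,
                      config$box$L, ff_as_list(ff), attraction_on,
                      has_tr, tp, if (has_tr) tracer$a else 1)
}

#' Run rigid-body Langevin dynamics
#'
#' Velocity-Verlet integration of rigid nanostars with per-core-bead
#' friction and thermal noise (free-draining: the COM friction of a 7-bead
#' star is 7 Gamma). The protocol's equilibration phase runs with the Morse
#' attraction disabled, then production turns it on. Frames store poses
#' (unwrapped centers + quaternions); stress samples store the off-diagonal
#' pressure components; an optional tracer is tracked for microrheology.
#'
#' @param config Initial `configuration`.
#' @param ff A [force_field()].
#' @param params A [langevin_params()] (its `seed` seeds the run).
#' @param protocol A [simulation_protocol()].
#' @param tracer Optional [tracer_bead()].
#' @param thermostat Set FALSE for NVE (no friction, no noise).
#' @return A `trajectory`: list of `frames` (each with `centers`, `quats`,
#'   `time`), `stress` (stress_series), `energy` samples, `tracer_track`,
#'   `final` configuration, plus box/geometry metadata.
#' @export
run_langevin <- function(config, ff = force_field(), params = langevin_params(),
                         protocol = simulation_protocol(), tracer = NULL,
                         thermostat = TRUE) {
  stopifnot(inherits(config, "configuration"))
  set.seed(params$seed)
  geom <- config$geometry
  n_eq <- round(protocol$equilibration / params$dt)
  n_pr <- round(protocol$production / params$dt)
  fe <- max(1L, round(protocol$frame_every / params$dt))
  se <- max(1L, round(protocol$stress_every / params$dt))
  has_tr <- !is.null(tracer)
  tpos <- if (has_tr) {
    if (is.null(tracer$position)) largest_void_center(config) else tracer$position
  } else c(0, 0, 0)
  tstate <- c(tpos, 0, 0, 0)
  state <- list(centers = config$centers, quats = config$quats,
                vel = matrix(0, config$n, 3), angmom = matrix(0, config$n, 3),
                tracer_state = tstate)
  types <- type_codes(config$types)
  run_phase <- function(state, nsteps, attraction_on, t0, limit = 0) {
    .run_langevin_cpp(state$centers, state$quats, types, state$vel, state$angmom,
                      geom$beads, geom$patches, config$box$L,
                      ff_as_list(ff), attraction_on,
                      params$dt, params$gamma, params$kT, thermostat,
                      nsteps, fe, se,
                      has_tr, state$tracer_state,
                      if (has_tr) tracer$a else 1,
                      if (has_tr) tracer$mass else 1,
                      if (has_tr) tracer$gamma_scale * params$gamma else 1, t0,
                      limit)
  }
  eq <- NULL
  if (n_eq > 0) {
    # displacement-limited drift during equilibration resolves any overlap
    # from random insertion (tracer included) without force blow-up
    eq <- run_phase(state, n_eq, attraction_on = FALSE, t0 = 0,
                    limit = if (has_tr) 0.05 else 0)
    state <- eq[c("centers", "quats", "vel", "angmom", "tracer_state")]
  }
  pr <- run_phase(state, n_pr, attraction_on = ff$D0 > 0, t0 = n_eq * params$dt)

  nfr <- length(pr$frame_times)
  frames <- lapply(seq_len(nfr), function(k) {
    idx <- (k - 1L) * config$n + seq_len(config$n)
    list(centers = pr$frame_centers[idx, , drop = FALSE],
         quats = pr$frame_quats[idx, , drop = FALSE],
         time = pr$frame_times[k])
  })
  stress <- stress_series(pr$stress[, 1], pr$stress[, 2:4, drop = FALSE],
                          volume = config$box$volume, kT = params$kT)
  final <- place_configuration(geom, pr$centers, pr$quats, config$box,
                               types = config$types)
  structure(list(
    frames = frames, times = pr$frame_times, stress = stress,
    energy = data.frame(t = pr$energy[, 1], pe = pr$energy[, 2], ke = pr$energy[, 3]),
    tracer_track = if (has_tr) pr$tracer_track else NULL,
    tracer = tracer, final = final,
    final_state = list(vel = pr$vel, angmom = pr$angmom,
                       tracer_state = pr$tracer_state),
    box = config$box, geometry = geom,
    types = config$types, params = params, protocol = protocol
  ), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames of %d nanostars, t in [%.3g, %.3g] tau_Br\n",
              length(x$frames), x$final$n,
              if (length(x$times)) min(x$times) else NA,
              if (length(x$times)) max(x$times) else NA))
  invisible(x)
}

#' Frame of a trajectory as a configuration
#'
#' @param traj A `trajectory`.
#' @param i Frame index (default last).
#' @return A `configuration`.
#' @export
frame_configuration <- function(traj, i = length(traj$frames)) {
  fr <- traj$frames[[i]]
  place_configuration(traj$geometry, fr$centers, fr$quats, traj$box,
                      types = traj$types)
}

#' Detect hybridized arm pairs
#'
#' Two patches are bonded when their minimum-image distance is at most
#' `cutoff` (0.2 sigma) and their nanostar types are compatible (A-A or
#' B-B). One-to-one binding is enforced by greedy minimum-distance matching:
#' candidate pairs are sorted by distance (ties broken by lowest index pair)
#' and accepted only if both patches are still free.
#'
#' @param config A `configuration`.
#' @param cutoff Bond distance criterion (default 0.2 sigma).
#' @return A `bond_list`: data.frame `bonds` with columns `i`, `arm_i`, `j`,
#'   `arm_j`, `r`, plus `n_arms` and the bonded-arm fraction.
#' @export
detect_bonds <- function(config, cutoff = 0.2) {
  stopifnot(inherits(config, "configuration"))
  p <- config$patches
  mol <- config$patch_mol
  arm <- config$patch_arm
  types <- config$types[mol]
  np <- nrow(p)
  cand <- NULL
  # candidate pairs by cutoff; patch count is 3n so an O(np^2) pass in
  # blocks is fine for analysis-scale systems
  for (a in seq_len(np - 1L)) {
    d <- minimum_image(sweep(p[(a + 1L):np, , drop = FALSE], 2, p[a, ]), config$box)
    r2 <- rowSums(d^2)
    hit <- which(r2 <= cutoff^2)
    if (length(hit)) {
      b <- a + hit
      keep <- mol[b] != mol[a] & types[b] == types[a]
      if (any(keep)) {
        cand <- rbind(cand, data.frame(a = a, b = b[keep], r = sqrt(r2[hit][keep])))
      }
    }
  }
  bonds <- data.frame(i = integer(0), arm_i = integer(0),
                      j = integer(0), arm_j = integer(0), r = numeric(0))
  if (!is.null(cand) && nrow(cand)) {
    cand <- cand[order(cand$r, cand$a, cand$b), ]
    used <- logical(np)
    for (k in seq_len(nrow(cand))) {
      a <- cand$a[k]; b <- cand$b[k]
      if (used[a] || used[b]) next
      used[a] <- used[b] <- TRUE
      bonds <- rbind(bonds, data.frame(i = mol[a], arm_i = arm[a],
                                       j = mol[b], arm_j = arm[b], r = cand$r[k]))
    }
  }
  structure(list(bonds = bonds, n_arms = np,
                 bonded_fraction = 2 * nrow(bonds) / np,
                 cutoff = cutoff),
            class = "bond_list")
}

#' @export
print.bond_list <- function(x, ...) {
  cat(sprintf("bond_list: %d bonds (%.1f%% of %d arms bonded, cutoff %.2f sigma)\n",
              nrow(x$bonds), 100 * x$bonded_fraction, x$n_arms, x$cutoff))
  invisible(x)
}

#' Off-diagonal stress time series
#'
#' @param t Sample times (tau_Br).
#' @param p n x 3 matrix of (Pxy, Pxz, Pyz) samples (eps/sigma^3).
#' @param volume Box volume (sigma^3).
#' @param kT Thermal energy.
#' @export
stress_series <- function(t, p, volume, kT = 1) {
  p <- matrix(as.numeric(p), ncol = 3)
  stopifnot(length(t) == nrow(p))
  structure(list(t = as.numeric(t), p = p, volume = volume, kT = kT),
            class = "stress_series")
}

#' Mean bond lifetime calibration
#'
#' Runs a two-nanostar system pre-bonded along one arm and measures the
#' distribution of unbinding times at the given Morse depth: a small
#' utility to calibrate `D0` against a target unbinding time.
#'
#' @param ff A [force_field()].
#' @param n_samples Number of unbinding events to collect.
#' @param max_time Per-sample time cap (tau_Br).
#' @param seed RNG seed.
#' @return List with `lifetimes` (censored at `max_time`) and `mean`.
#' @export
calibrate_bond_lifetime <- function(ff = force_field(), n_samples = 5,
                                    max_time = 200, seed = 1) {
  geom <- nanostar_geometry()
  box <- periodic_box(40)
  lifetimes <- numeric(n_samples)
  for (s in seq_len(n_samples)) {
    cfg <- bonded_dimer_configuration(geom, box)
    chunk <- 5
    t_un <- max_time
    state_cfg <- cfg
    params <- langevin_params(seed = seed * 1000 + s)
    elapsed <- 0
    while (elapsed < max_time) {
      traj <- run_langevin(state_cfg, ff, params,
                           simulation_protocol(equilibration = 0, production = chunk,
                                               frame_every = chunk, stress_every = chunk))
      state_cfg <- traj$final
      elapsed <- elapsed + chunk
      if (nrow(detect_bonds(state_cfg)$bonds) == 0) { t_un <- elapsed; break }
    }
    lifetimes[s] <- t_un
  }
  list(lifetimes = lifetimes, mean = mean(lifetimes))
}

# center of the largest void found by coarse probing (tracer insertion site)
largest_void_center <- function(config, n_probes = 200) {
  probes <- cbind(stats::runif(n_probes, 0, config$box$L[1]),
                  stats::runif(n_probes, 0, config$box$L[2]),
                  stats::runif(n_probes, 0, config$box$L[3]))
  res <- .mesh_probe_cpp(config$beads, config$box$L, probes, 0.5, 1e-3, 100L)
  ok <- which(!res$inside_bead)
  best <- ok[which.max(res$diameter[ok])]
  res$center[best, ]
}

# two stars facing each other with one patch pair at the Morse minimum
bonded_dimer_configuration <- function(geom = nanostar_geometry(), box = periodic_box(40)) {
  pd <- sqrt(sum(geom$patches[1, ]^2))
  gap <- 0.1  # patch-patch separation (Morse minimum for default ff)
  ctr <- box$L / 2
  # star 1 arm 1 points +y; star 2 rotated 180 deg about x so its arm 1 points -y
  q1 <- c(1, 0, 0, 0)
  q2 <- quat_from_axis_angle(c(1, 0, 0), pi)
  c1 <- ctr - c(0, pd + gap / 2, 0)
  c2 <- ctr + c(0, pd + gap / 2, 0)
  place_configuration(geom, rbind(c1, c2), rbind(q1, q2), box)
}
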
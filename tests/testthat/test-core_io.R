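# Periodic geometry, poses and trajectory round-trips.

test_that("minimum image maps displacements into (-L/2, L/2] and is idempotent", {
  box <- periodic_box(10)
  expect_equal(minimum_image(c(4, 0, 0), box), c(4, 0, 0))
  expect_equal(minimum_image(c(6, 0, 0), box), c(-4, 0, 0))
  expect_equal(minimum_image(c(10, 10, 10), box), c(0, 0, 0))
  # exact half-edge lands on the +L/2 side
  expect_equal(minimum_image(c(-5, 5, 0), box), c(5, 5, 0))
  set.seed(1)
  d <- matrix(stats::runif(300, -50, 50), ncol = 3)
  m1 <- minimum_image(d, box)
  expect_true(all(m1 > -5 & m1 <= 5))
  expect_equal(minimum_image(m1, box), m1)
  # returned vector is congruent to the input modulo box vectors
  expect_true(all(abs((d - m1) / 10 - round((d - m1) / 10)) < 1e-12))
  b2 <- periodic_box(4, 6, 8)
  m2 <- minimum_image(d, b2)
  expect_true(all(sweep(m2, 2, b2$L / 2, "<=")))
})

test_that("wrap and unwrap cooperate: wrap(unwrap(x)) = wrap(x)", {
  box <- periodic_box(7)
  x <- matrix(stats::runif(60, -20, 20), ncol = 3)
  w <- wrap_coords(x, box)
  expect_true(all(w >= 0 & w < 7))
  expect_equal(wrap_coords(w + 7 * matrix(sample(-3:3, 60, TRUE), ncol = 3), box), w)
})

test_that("nanostar geometry is a three-fold planar Y with patches beyond arms", {
  g <- nanostar_geometry()
  expect_equal(nrow(g$beads), 7)
  expect_equal(nrow(g$patches), 3)
  expect_equal(g$f, 3L)
  # three-fold symmetry: arm tip distances all equal, 120 degrees apart
  tips <- g$beads[c(3, 5, 7), ]
  expect_equal(sqrt(rowSums(tips^2)), rep(2, 3))
  expect_equal(sqrt(rowSums(g$patches^2)), rep(2.5, 3))
  cosang <- sum(tips[1, ] * tips[2, ]) / 4
  expect_equal(cosang, cos(2 * pi / 3), tolerance = 1e-12)
  expect_error(nanostar_geometry(patch_dist = 1.5), "beyond")
})

test_that("place_configuration derives world coordinates and the density definition", {
  g <- nanostar_geometry()
  box <- periodic_box(30)
  cfg <- place_configuration(g, matrix(c(15, 15, 15), 1), matrix(c(1, 0, 0, 0), 1), box)
  expect_equal(cfg$beads, wrap_coords(sweep(g$beads, 2, c(15, 15, 15), "+"), box),
               tolerance = 1e-12)
  # 180-degree rotation about z negates arm x,y components
  q <- quat_from_axis_angle(c(0, 0, 1), pi)
  cfg2 <- place_configuration(g, matrix(c(15, 15, 15), 1), matrix(q, 1), box)
  rel <- cfg2$beads - matrix(c(15, 15, 15), 7, 3, byrow = TRUE)
  expect_equal(rel[, 1:2], -g$beads[, 1:2], tolerance = 1e-9)
  expect_equal(rel[, 3], g$beads[, 3], tolerance = 1e-9)
  expect_error(place_configuration(g, matrix(0, 1, 3), matrix(0, 1, 4), box),
               "zero-norm")
})

test_that("rho is the stated pure function of N, sigma and V", {
  # N = 856 stars at rho = 0.04: box solved from the definition
  n <- 856
  L <- box_edge_for_density(n, 0.04)
  set.seed(2)
  cfg <- place_configuration(nanostar_geometry(),
                             matrix(stats::runif(3 * n, 0, L), ncol = 3),
                             random_quaternions(n), periodic_box(L))
  expect_equal(cfg$rho, 0.04, tolerance = 1e-6)
  # doubling the volume halves rho exactly
  cfg2 <- place_configuration(nanostar_geometry(), cfg$centers, cfg$quats,
                              periodic_box(L * 2^(1 / 3)))
  expect_equal(cfg2$rho, 0.02, tolerance = 1e-12)
})

test_that("trajectory formats round-trip coordinates and identities", {
  cfg <- init_configuration(8, 0.05, seed = 4)
  ref <- nanolink:::frame_atom_table(cfg$centers, cfg$quats, cfg$types,
                                     cfg$geometry, cfg$box)
  for (fmt in c("lammps-dump", "lammps-data", "xyz")) {
    tmp <- tempfile()
    suppressMessages(write_trajectory(cfg, tmp, format = fmt))
    tr <- read_trajectory(tmp, format = fmt)
    a <- tr$frames[[1]]$atoms
    expect_equal(nrow(a), nrow(ref))
    expect_equal(a$type, ref$type)
    if (fmt != "xyz") expect_equal(a$mol, ref$mol)
    expect_lt(max(abs(as.matrix(a[, c("x", "y", "z")]) -
                      as.matrix(ref[, c("x", "y", "z")]))), 1e-6)
    expect_equal(tr$box$L, cfg$box$L, tolerance = 1e-9)
  }
})

test_that("dump image flags recover unwrapped coordinates", {
  cfg <- init_configuration(6, 0.08, seed = 2)
  tr <- run_langevin(cfg, force_field(), langevin_params(seed = 1),
                     simulation_protocol(equilibration = 0, production = 2,
                                         frame_every = 1, stress_every = 2))
  tmp <- tempfile(fileext = ".dump")
  write_trajectory(tr, tmp)
  rt <- read_trajectory(tmp)
  expect_length(rt$frames, 2)
  a <- rt$frames[[2]]$atoms
  unw <- cbind(a$x + a$ix * rt$box$L[1], a$y + a$iy * rt$box$L[2],
               a$z + a$iz * rt$box$L[3])
  fr <- tr$frames[[2]]
  ref <- nanolink:::frame_atom_table(fr$centers, fr$quats, tr$types,
                                     tr$geometry, tr$box)
  refu <- cbind(ref$x + ref$ix * tr$box$L[1], ref$y + ref$iy * tr$box$L[2],
                ref$z + ref$iz * tr$box$L[3])
  expect_lt(max(abs(unw - refu)), 1e-6)
})

test_that("malformed trajectories are rejected with informative errors", {
  cfg <- init_configuration(4, 0.05, seed = 1)
  tr <- run_langevin(cfg, force_field(), langevin_params(seed = 1),
                     simulation_protocol(equilibration = 0, production = 2,
                                         frame_every = 1, stress_every = 2))
  tmp <- tempfile(fileext = ".dump")
  write_trajectory(tr, tmp)
  lines <- readLines(tmp)
  # drop some atoms from frame 2 -> inconsistent counts
  n_per_frame <- 9 + 40
  bad <- lines[-(n_per_frame + 10:13)]
  tf <- tempfile(); writeLines(bad, tf)
  expect_error(read_trajectory(tf), "inconsistent|malformed|truncated")
  # triclinic bounds rejected
  tric <- lines
  tric[5] <- "ITEM: BOX BOUNDS xy xz yz pp pp pp"
  tf2 <- tempfile(); writeLines(tric, tf2)
  expect_error(read_trajectory(tf2), "triclinic|orthorhombic")
  # empty trajectory refuses to write
  expect_error(write_trajectory(structure(list(frames = list()),
                                          class = "trajectory"), tempfile()),
               "empty")
})

test_that("sites_configuration rebuilds analysis inputs from a dump", {
  cfg <- init_configuration(8, 0.05, seed = 4)
  tmp <- tempfile(fileext = ".dump")
  write_trajectory(cfg, tmp)
  sc <- sites_configuration(read_trajectory(tmp))
  expect_equal(sc$n, 8)
  expect_lt(max(abs(minimum_image(sc$centers - cfg$centers, cfg$box))), 1e-6)
  expect_lt(max(abs(minimum_image(sc$patches - cfg$patches, cfg$box))), 1e-6)
  b1 <- detect_bonds(cfg); b2 <- detect_bonds(sc)
  expect_equal(b1$bonds[c("i", "j")], b2$bonds[c("i", "j")])
})

test_that("config files materialize parameter objects with defaults", {
  tmp <- tempfile(fileext = ".yaml")
  writeLines(c("forcefield:", "  D0: 12", "langevin:", "  dt: 0.005",
               "analysis:", "  mesh_samples: 500"), tmp)
  cf <- read_config(tmp)
  expect_equal(cf$forcefield$D0, 12)
  expect_equal(cf$params$dt, 0.005)
  expect_equal(cf$protocol$production, simulation_protocol()$production)
  expect_equal(cf$analysis$mesh_samples, 500)
})
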
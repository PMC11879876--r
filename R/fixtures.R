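## Seeded synthetic fixtures with known ground truth: torus links, diamond
## networks (optionally interpenetrated), random geometric networks,
## trap-MSD and Ornstein-Uhlenbeck stress series, two-channel images.
## Every generator is a pure function of its arguments (seed included).

#' Pair of closed curves with known linking number (torus link)
#'
#' For `k >= 1`, two (1, k) curves on a common torus forming a (2, 2k)
#' torus link with |Lk| = k (k = 1 is the Hopf geometry). `k = 0` returns
#' two well-separated unit circles (split link).
#'
#' @param k Target |linking number| (integer >= 0).
#' @param n_vertices Vertices per curve (>= 16).
#' @param R_major,r_minor Torus radii (R_major > r_minor > 0).
#' @return List of two [closed_polygon()]s with attribute `lk_true = k`.
#' @export
make_torus_link <- function(k, n_vertices = 64, R_major = 2, r_minor = 1) {
  stopifnot(k >= 0, n_vertices >= 16)
  if (R_major <= r_minor || r_minor <= 0) stop("degenerate torus radii")
  t <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  if (k == 0) {
    a <- closed_polygon(cbind(cos(t), sin(t), 0))
    b <- closed_polygon(cbind(10 + cos(t), sin(t), 0))
    return(structure(list(a, b), lk_true = 0L))
  }
  curve <- function(phase) {
    w <- k * t + phase
    closed_polygon(cbind((R_major + r_minor * cos(w)) * cos(t),
                         (R_major + r_minor * cos(w)) * sin(t),
                         r_minor * sin(w)))
  }
  structure(list(curve(0), curve(pi)), lk_true = as.integer(k))
}

# diamond lattice sites (fractional coordinates of the conventional cell)
diamond_basis <- function() {
  fcc <- rbind(c(0, 0, 0), c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0))
  rbind(fcc, sweep(fcc, 2, c(.25, .25, .25), "+"))
}

# the four tetrahedral bond directions (fractional)
diamond_bond_dirs <- function() {
  rbind(c(.25, .25, .25), c(.25, -.25, -.25), c(-.25, .25, -.25), c(-.25, -.25, .25))
}

#' Periodic diamond-lattice nanostar network fixture
#'
#' Nanostar nodes on diamond-lattice positions with bonds along tetrahedral
#' nearest-neighbour contacts. The 4-regular lattice is reduced to valence
#' 3 by deleting a perfect matching (each site loses exactly one bond), in
#' one of two deterministic patterns:
#' \describe{
#'   \item{`"uniform"`}{one complete bond direction is removed (direction
#'     chosen from the seed). Every remaining minimum loop is a hexagon
#'     (l_min = 6 for all nodes), but the network decomposes into parallel
#'     2-D slabs perpendicular to the removed direction.}
#'   \item{`"alternating"`}{the removed direction alternates between (111)
#'     layer pairs (valid for even cell counts). The network stays fully
#'     connected and every node still lies on a hexagon, so all minimum
#'     loops remain l_min = 6.}
#' }
#' With `sublattices = 2` a second, bond-disjoint diamond network offset by
#' half the cell diagonal interpenetrates the first; the two sublattices
#' use different removed-direction patterns, chosen so that surviving
#' hexagons of one network are catenated with hexagons of the other
#' (verified against the crossing-sign linking oracle when this fixture was
#' designed).
#'
#' @param cells Integer triple: conventional cells per axis (>= 2; even for
#'   the alternating matching).
#' @param sublattices 1 or 2.
#' @param noise Gaussian positional noise amplitude (sigma units).
#' @param dilution Extra fraction of edges removed at random (< 0.3).
#' @param seed RNG seed (selects the matching phase, dilution and noise).
#' @param matching `"uniform"` or `"alternating"` (default: uniform for one
#'   sublattice, alternating for two).
#' @param bond_length Nearest-neighbour distance (sigma; cell edge is
#'   `4 bond_length / sqrt(3)`).
#' @return List: `config` (a `configuration`), `graph` (a `network_graph`),
#'   `sublattice` (node labels 1/2), `a` (cell edge).
#' @export
make_diamond_network <- function(cells = c(3, 3, 3), sublattices = 1,
                                 noise = 0, dilution = 0, seed = 1,
                                 matching = NULL, bond_length = 5) {
  cells <- rep_len(as.integer(cells), 3)
  if (any(cells < 2)) stop("need at least 2 cells per axis for periodic closure")
  if (dilution >= 0.3) stop("dilution must stay below 0.3")
  stopifnot(sublattices %in% c(1, 2))
  if (is.null(matching)) matching <- if (sublattices == 2) "alternating" else "uniform"
  matching <- match.arg(matching, c("uniform", "alternating"))
  if (matching == "alternating" &&
      (cells[1] %% 2 != 0 || length(unique(cells)) != 1)) {
    stop("the alternating matching needs a cubic cell grid with an even cell count")
  }
  set.seed(seed)
  a <- 4 * bond_length / sqrt(3)
  basis <- diamond_basis()
  offs <- as.matrix(expand.grid(x = 0:(cells[1] - 1), y = 0:(cells[2] - 1),
                                z = 0:(cells[3] - 1)))
  frac1 <- do.call(rbind, lapply(seq_len(nrow(offs)), function(r) {
    sweep(basis, 2, as.numeric(offs[r, ]), "+")
  }))
  frac <- frac1
  sub_label <- rep(1L, nrow(frac1))
  if (sublattices == 2) {
    frac <- rbind(frac1, sweep(frac1, 2, c(.5, .5, .5), "+"))
    sub_label <- c(sub_label, rep(2L, nrow(frac1)))
  }
  Lc <- cells
  box <- periodic_box(cells[1] * a, cells[2] * a, cells[3] * a)
  key <- function(f) paste(round(f[, 1] %% Lc[1], 6), round(f[, 2] %% Lc[2], 6),
                           round(f[, 3] %% Lc[3], 6), sep = "_")
  lookup <- stats::setNames(seq_len(nrow(frac)), paste(sub_label, key(frac), sep = "|"))
  dirs <- diamond_bond_dirs()
  # Deleted perfect matching: every "A" site (first diamond basis) drops
  # exactly one of its four bonds. Any rule that assigns the dropped
  # direction as a function of the (111) layer index with values in a
  # three-direction subset is a valid perfect matching; "uniform" drops one
  # direction everywhere, "alternating" alternates between two directions
  # over layer pairs (connected remainder, hexagons preserved).
  phase <- seed %% 3
  drop_of_layer <- function(t_layer, sl) {
    if (matching == "uniform") {
      # one fixed direction per sublattice; different directions across
      # sublattices keep cross-sublattice hexagons catenated
      if (sublattices == 1) as.integer((seed %% 4) + 1) else c(1L, 2L)[sl]
    } else {
      # pairs of (111) layers share a dropped direction from {2,3,4}; both
      # sublattices use the same pattern (the phase-matched combination is
      # the one whose surviving hexagons are all catenated across nets)
      as.integer(2 + (floor(t_layer / 2) + phase) %% 3)
    }
  }
  nb_per_cell <- nrow(basis)
  is_a_site <- rep(rep(c(TRUE, FALSE), each = 4L), nrow(frac) / nb_per_cell)
  edges <- NULL
  for (sl in seq_len(sublattices)) {
    rows <- which(sub_label == sl & is_a_site)
    fs <- frac[rows, , drop = FALSE]
    sums <- round(fs[, 1] + fs[, 2] + fs[, 3] - (sl - 1) * 1.5)
    t_layer <- ((sums %% cells[1]) + cells[1]) %% cells[1]
    dropA <- vapply(t_layer, drop_of_layer, integer(1), sl = sl)
    for (d in seq_len(4)) {
      sel <- which(dropA != d)
      if (!length(sel)) next
      tgt <- sweep(fs[sel, , drop = FALSE], 2, dirs[d, ], "+")
      j <- lookup[paste(sl, key(tgt), sep = "|")]
      ok <- !is.na(j)
      if (any(ok)) {
        ii <- rows[sel][ok]; jj <- unname(j[ok])
        edges <- rbind(edges, cbind(pmin(ii, jj), pmax(ii, jj)))
      }
    }
  }
  edges <- unique(edges)
  if (dilution > 0) {
    keep <- stats::runif(nrow(edges)) >= dilution
    edges <- edges[keep, , drop = FALSE]
  }
  centers <- (frac %% matrix(Lc, nrow(frac), 3, byrow = TRUE)) * a
  if (noise > 0) centers <- centers + matrix(stats::rnorm(length(centers), 0, noise),
                                             ncol = 3)
  n <- nrow(centers)
  quats <- matrix(rep(c(1, 0, 0, 0), n), ncol = 4, byrow = TRUE)
  cfg <- place_configuration(nanostar_geometry(), centers, quats, box,
                             types = c("A", "B")[sub_label])
  graph <- build_bond_graph(cfg, data.frame(i = edges[, 1], j = edges[, 2]))
  list(config = cfg, graph = graph, sublattice = sub_label, a = a)
}

#' Random geometric network at capped valence (null model)
#'
#' Uniform random centers; candidate edges within `bond_range` added
#' shortest-first under the valence cap. Orientations are uniform random.
#'
#' @param n Number of nodes.
#' @param rho Volume fraction (sets the cubic box size).
#' @param max_valence Degree cap (default 3).
#' @param bond_range Maximum bond length (sigma).
#' @param seed RNG seed.
#' @return List: `config`, `graph`.
#' @export
make_random_network <- function(n, rho, max_valence = 3, bond_range = 6, seed = 1) {
  set.seed(seed)
  box <- periodic_box(box_edge_for_density(n, rho))
  if (bond_range >= min(box$L) / 2) stop("bond_range too large for this box")
  centers <- cbind(stats::runif(n, 0, box$L[1]), stats::runif(n, 0, box$L[2]),
                   stats::runif(n, 0, box$L[3]))
  cand <- NULL
  for (i in seq_len(n - 1)) {
    d <- minimum_image(sweep(centers[(i + 1):n, , drop = FALSE], 2, centers[i, ]), box)
    r2 <- rowSums(d^2)
    hit <- which(r2 <= bond_range^2)
    if (length(hit)) cand <- rbind(cand, data.frame(i = i, j = i + hit, r = sqrt(r2[hit])))
  }
  deg <- integer(n)
  edges <- data.frame(i = integer(0), j = integer(0))
  if (!is.null(cand) && nrow(cand)) {
    cand <- cand[order(cand$r, cand$i, cand$j), ]
    for (k in seq_len(nrow(cand))) {
      i <- cand$i[k]; j <- cand$j[k]
      if (deg[i] < max_valence && deg[j] < max_valence) {
        deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
        edges <- rbind(edges, data.frame(i = i, j = j))
      }
    }
  }
  cfg <- place_configuration(nanostar_geometry(), centers, random_quaternions(n), box)
  list(config = cfg, graph = build_bond_graph(cfg, edges))
}

#' Harmonic-trap MSD with known GSER ground truth
#'
#' `MSD(t) = (6 kT / k) (1 - exp(-t / tau_k))` with `tau_k = 6 pi eta a / k`
#' (pure diffusion `MSD = 6 D t`, `D = kT / (6 pi eta a)`, when `k = 0`),
#' on a log-spaced lag grid with optional multiplicative noise. The GSER
#' plateau of the trap is `k / (6 pi a)`.
#'
#' @param k Trap spring constant (eps/sigma^2; 0 for free diffusion).
#' @param a Tracer radius (sigma).
#' @param noise Multiplicative noise fraction.
#' @param seed RNG seed.
#' @param eta Solvent viscosity (eps tau_Br / sigma^3).
#' @param kT Thermal energy.
#' @param n Number of lags.
#' @param t_range Lag range (tau_Br).
#' @return An [msd_series()] with ground-truth attributes `plateau_true`,
#'   `eta_true`, `D_true`.
#' @export
make_trap_msd <- function(k, a = 2.5, noise = 0, seed = 1, eta = 1, kT = 1,
                          n = 80, t_range = NULL) {
  set.seed(seed)
  D <- kT / (6 * pi * eta * a)
  if (k > 0) {
    tau_k <- 6 * pi * eta * a / k
    if (is.null(t_range)) t_range <- tau_k * c(1e-3, 1e3)
    t <- exp(seq(log(t_range[1]), log(t_range[2]), length.out = n))
    m <- (6 * kT / k) * (1 - exp(-t / tau_k))
  } else {
    if (is.null(t_range)) t_range <- c(1e-2, 1e2)
    t <- exp(seq(log(t_range[1]), log(t_range[2]), length.out = n))
    m <- 6 * D * t
  }
  if (noise > 0) m <- m * (1 + noise * stats::rnorm(n))
  out <- msd_series(t, pmax(m, 1e-12), a = a, kT = kT)
  attr(out, "plateau_true") <- if (k > 0) k / (6 * pi * a) else 0
  attr(out, "eta_true") <- eta
  attr(out, "D_true") <- D
  out
}

#' Ornstein-Uhlenbeck stress series with known Green-Kubo ground truth
#'
#' Three independent OU processes with stationary autocovariance
#' `A exp(-t / tau_c)`, generated by the exact discrete-time update, so the
#' Green-Kubo estimator (at V = kT = 1) should recover
#' `G(t) = A exp(-t / tau_c)`.
#'
#' @param A Stationary variance (amplitude).
#' @param tau_c Correlation time (tau_Br).
#' @param n Number of samples.
#' @param dt Sampling interval (tau_Br).
#' @param seed RNG seed.
#' @param volume,kT Metadata carried by the series (defaults 1).
#' @return A [stress_series()] with attributes `A_true`, `tau_true`.
#' @export
make_ou_stress <- function(A = 1, tau_c = 1, n = 1e5, dt = 0.01, seed = 1,
                           volume = 1, kT = 1) {
  set.seed(seed)
  rho <- exp(-dt / tau_c)
  sd_innov <- sqrt(A * (1 - rho^2))
  p <- matrix(0, n, 3)
  for (k in 1:3) {
    x0 <- stats::rnorm(1, 0, sqrt(A))
    innov <- stats::rnorm(n - 1, 0, sd_innov)
    x <- stats::filter(c(x0, innov), rho, method = "recursive")
    p[, k] <- as.numeric(x)
  }
  out <- stress_series(seq_len(n) * dt, p, volume = volume, kT = kT)
  attr(out, "A_true") <- A
  attr(out, "tau_true") <- tau_c
  out
}

# separable periodic Gaussian blur
gaussian_blur <- function(img, scale) {
  if (scale <= 0) return(img)
  half <- max(1L, ceiling(3 * scale))
  kx <- stats::dnorm(-half:half, sd = scale)
  kx <- kx / sum(kx)
  blur1 <- function(m) {
    nr <- nrow(m)
    out <- matrix(0, nr, ncol(m))
    for (o in -half:half) {
      idx <- ((seq_len(nr) - 1 + o) %% nr) + 1
      out <- out + kx[o + half + 1] * m[idx, , drop = FALSE]
    }
    out
  }
  t(blur1(t(blur1(img))))
}

#' Synthetic two-channel colocalization image pair
#'
#' Builds blob-patterned red/green channels where a fraction `phi` of the
#' area is co-occupied (both channels at full intensity: interpenetrated)
#' and the remaining `1 - phi` is demixed into red-only and green-only
#' domains, so the expected yellow intensity is `phi` exactly (binary
#' intensities).
#'
#' @param size Image side length in pixels.
#' @param phi Interpenetration (co-occupancy) area fraction in [0, 1].
#' @param droplet_scale Correlation length of the domains (pixels).
#' @param seed RNG seed.
#' @return List: `red`, `green` (channel matrices in [0, 1]),
#'   `expected_iy = phi`, `mixed_mask`.
#' @export
make_two_channel_image <- function(size = 128, phi = 0.5, droplet_scale = 8,
                                   seed = 1) {
  stopifnot(phi >= 0, phi <= 1)
  set.seed(seed)
  fld <- function() gaussian_blur(matrix(stats::rnorm(size^2), size, size), droplet_scale)
  domain <- fld()
  mixer <- fld()
  # exact area fractions via rank thresholds
  mixed <- matrix(rank(mixer, ties.method = "first") <= round(phi * size^2), size, size)
  red_only <- !mixed & (domain >= stats::median(domain[!mixed]))
  red <- matrix(0, size, size); green <- matrix(0, size, size)
  red[mixed | red_only] <- 1
  green[mixed | (!mixed & !red_only)] <- 1
  list(red = structure(red, label = "red", class = c("channel_image", "matrix")),
       green = structure(green, label = "green", class = c("channel_image", "matrix")),
       expected_iy = phi, mixed_mask = mixed)
}
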
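#' Orthorhombic periodic simulation box
#'
#' Simulation boxes are orthorhombic (edges along x, y, z) with periodic
#' boundaries in all three directions. All lengths are in bead diameters
#' (sigma units); one sigma corresponds to 2.5 nm of double-stranded DNA.
#'
#' @param lx,ly,lz Edge lengths (sigma units), all > 0. A single `lx` with
#'   `ly`, `lz` missing builds a cubic box.
#' @return An object of class `periodic_box` with fields `L` (length-3
#'   numeric) and `volume`.
#' @export
#' @examples
#' b <- periodic_box(10)
#' minimum_image(c(6, 0, 0), b)
periodic_box <- function(lx, ly = lx, lz = lx) {
  L <- as.numeric(c(lx, ly, lz))
  if (length(L) != 3L || any(!is.finite(L)) || any(L <= 0)) {
    stop("periodic_box: edge lengths must be three positive finite numbers")
  }
  structure(list(L = L, volume = prod(L)), class = "periodic_box")
}

#' @export
print.periodic_box <- function(x, ...) {
  cat(sprintf("periodic_box: %.4g x %.4g x %.4g sigma (V = %.6g sigma^3)\n",
              x$L[1], x$L[2], x$L[3], x$volume))
  invisible(x)
}

is_periodic_box <- function(x) inherits(x, "periodic_box")

#' Minimum-image displacement
#'
#' Maps a displacement (or a matrix of displacements, one per row) to its
#' minimum image under the periodic box: each component is brought into
#' `(-L/2, +L/2]` by subtracting integer multiples of the corresponding edge.
#'
#' @param d Numeric length-3 vector or an n x 3 matrix of displacements.
#' @param box A [periodic_box()].
#' @return Same shape as `d`, each component in `(-L/2, +L/2]`.
#' @export
minimum_image <- function(d, box) {
  stopifnot(is_periodic_box(box))
  vec <- is.null(dim(d))
  m <- if (vec) matrix(d, ncol = 3L) else as.matrix(d)
  for (k in 1:3) {
    Lk <- box$L[k]
    m[, k] <- m[, k] - Lk * round(m[, k] / Lk)
    # round() sends exactly -L/2 to -L/2; fold onto the +L/2 side
    at_edge <- m[, k] <= -Lk / 2
    m[at_edge, k] <- m[at_edge, k] + Lk
  }
  if (vec) drop(m) else m
}

#' Wrap absolute coordinates into the primary cell `[0, L)`
#'
#' @param x Numeric length-3 vector or n x 3 matrix of coordinates.
#' @param box A [periodic_box()].
#' @return Coordinates wrapped into `[0, L)` per component.
#' @export
wrap_coords <- function(x, box) {
  stopifnot(is_periodic_box(box))
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, ncol = 3L) else as.matrix(x)
  for (k in 1:3) m[, k] <- m[, k] %% box$L[k]
  if (vec) drop(m) else m
}

## ---- quaternions -----------------------------------------------------------
## Unit quaternions (w, x, y, z) encode nanostar orientations.

quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n < 1e-12) stop("zero-norm quaternion cannot be normalized")
  q / n
}

#' Quaternion product
#' @param a,b Length-4 quaternions (w, x, y, z).
#' @export
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Rotation matrix of a unit quaternion
#' @param q Numeric length-4 quaternion (w, x, y, z); normalized internally.
#' @return 3 x 3 rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Quaternion for a rotation about an axis
#' @param axis Length-3 axis (normalized internally).
#' @param angle Rotation angle in radians.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

#' Uniform random unit quaternions (Shoemake's method)
#' @param n Number of quaternions.
#' @return n x 4 matrix of unit quaternions.
#' @export
random_quaternions <- function(n) {
  u1 <- stats::runif(n); u2 <- stats::runif(n); u3 <- stats::runif(n)
  cbind(sqrt(1 - u1) * sin(2 * pi * u2),
        sqrt(1 - u1) * cos(2 * pi * u2),
        sqrt(u1) * sin(2 * pi * u3),
        sqrt(u1) * cos(2 * pi * u3))
}

## ---- nanostar geometry -----------------------------------------------------

#' Body-frame geometry of a rigid Y-shaped nanostar
#'
#' The default model is a planar three-fold symmetric Y: a central bead at
#' the origin and, along each of three arms at 120 degrees in the xy plane,
#' two further beads at distances sigma and 2 sigma, for 7 core beads total.
#' Each arm carries a terminal patch site (the sticky end) at `patch_dist`
#' along the arm axis, beyond the last core bead. Patches are zero-volume
#' interaction sites; core beads have diameter sigma.
#'
#' @param arm_bead_dists Distances of the arm beads from the center, per arm
#'   (default `c(1, 2)` sigma).
#' @param patch_dist Distance of the patch site from the center (default 2.5
#'   sigma; must exceed `max(arm_bead_dists)`).
#' @param patch_diameter Patch interaction diameter as a fraction of sigma
#'   (metadata used by the force field; default 0.2).
#' @param sigma_nm Physical bead diameter in nm (default 2.5).
#' @return `nanostar_geometry` object with body-frame coordinate matrices
#'   `beads` (7 x 3) and `patches` (3 x 3), valence `f = 3`.
#' @export
nanostar_geometry <- function(arm_bead_dists = c(1, 2), patch_dist = 2.5,
                              patch_diameter = 0.2, sigma_nm = 2.5) {
  if (patch_dist <= max(arm_bead_dists)) {
    stop("patch site must lie beyond the last core bead of its arm")
  }
  ang <- c(90, 210, 330) * pi / 180   # three-fold symmetric, planar
  axes <- cbind(cos(ang), sin(ang), 0)
  beads <- rbind(c(0, 0, 0),
                 do.call(rbind, lapply(1:3, function(a) {
                   outer(arm_bead_dists, axes[a, ])
                 })))
  patches <- axes * patch_dist
  arm_of_bead <- c(0L, rep(1:3, each = length(arm_bead_dists)))
  if (nrow(beads) != 7L) stop("nanostar must have exactly 7 core beads")
  structure(list(beads = beads, patches = patches, f = 3L,
                 arm_of_bead = arm_of_bead,
                 patch_diameter = patch_diameter, sigma_nm = sigma_nm),
            class = "nanostar_geometry")
}

#' @export
print.nanostar_geometry <- function(x, ...) {
  cat(sprintf("nanostar_geometry: %d core beads, valence f = %d, patches at %.2f sigma\n",
              nrow(x$beads), x$f, sqrt(sum(x$patches[1, ]^2))))
  invisible(x)
}

## ---- configuration ---------------------------------------------------------

#' Place nanostars in a periodic box
#'
#' Builds a full configuration from per-nanostar poses: world-frame bead and
#' patch coordinates are derived by rotating the body frame by each pose
#' quaternion and translating to the center. The volume fraction is
#' `rho = N * 7 * (pi sigma^3 / 6) / V`, counting core-bead volume only
#' (patches are zero-volume binding sites).
#'
#' @param geometry A [nanostar_geometry()].
#' @param centers n x 3 matrix of nanostar center positions.
#' @param quats n x 4 matrix of orientation quaternions (normalized
#'   internally; zero-norm rows are an error).
#' @param box A [periodic_box()].
#' @param types Character vector of type labels (`"A"` or `"B"`), recycled.
#' @return A `configuration` object: `centers` (wrapped), `quats`, `types`,
#'   `beads` (7n x 3, wrapped), `patches` (3n x 3, wrapped), `mol` indices
#'   for both site sets, `rho`, `box`, `geometry`.
#' @export
place_configuration <- function(geometry, centers, quats, box, types = "A") {
  stopifnot(inherits(geometry, "nanostar_geometry"), is_periodic_box(box))
  centers <- matrix(as.numeric(centers), ncol = 3L)
  quats <- matrix(as.numeric(quats), ncol = 4L)
  n <- nrow(centers)
  if (n < 1L || nrow(quats) != n) stop("need one quaternion per center")
  types <- rep_len(as.character(types), n)
  if (!all(types %in% c("A", "B"))) stop("types must be 'A' or 'B'")
  norms <- sqrt(rowSums(quats^2))
  if (any(norms < 1e-12)) stop("zero-norm quaternion at pose ", which(norms < 1e-12)[1])
  quats <- quats / norms
  nb <- nrow(geometry$beads); np <- nrow(geometry$patches)
  beads <- matrix(0, n * nb, 3L)
  patches <- matrix(0, n * np, 3L)
  for (i in seq_len(n)) {
    R <- quat_to_matrix(quats[i, ])
    beads[(i - 1L) * nb + seq_len(nb), ] <-
      geometry$beads %*% t(R) + rep(1, nb) %o% centers[i, ]
    patches[(i - 1L) * np + seq_len(np), ] <-
      geometry$patches %*% t(R) + rep(1, np) %o% centers[i, ]
  }
  rho <- n * nb * (pi / 6) / box$volume
  structure(list(
    centers = wrap_coords(centers, box), quats = quats, types = types,
    beads = wrap_coords(beads, box), patches = wrap_coords(patches, box),
    bead_mol = rep(seq_len(n), each = nb), patch_mol = rep(seq_len(n), each = np),
    patch_arm = rep(seq_len(np), n),
    n = n, rho = rho, box = box, geometry = geometry
  ), class = "configuration")
}

#' @export
print.configuration <- function(x, ...) {
  cat(sprintf("configuration: %d nanostars (rho = %.4f) in box %.4g x %.4g x %.4g sigma\n",
              x$n, x$rho, x$box$L[1], x$box$L[2], x$box$L[3]))
  invisible(x)
}

#' Box edge that realizes a target volume fraction
#'
#' Solves `rho = N * 7 * (pi/6) / L^3` for the cubic box edge `L`.
#'
#' @param n Number of nanostars.
#' @param rho Target volume fraction (0 < rho < 1).
#' @param beads_per_star Core beads per nanostar (default 7).
#' @return Cubic box edge length in sigma.
#' @export
box_edge_for_density <- function(n, rho, beads_per_star = 7L) {
  stopifnot(n >= 1, rho > 0, rho < 1)
  (n * beads_per_star * (pi / 6) / rho)^(1 / 3)
}
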
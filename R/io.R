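## Readers and writers for standard particle-dump formats: LAMMPS dump
## (text), LAMMPS data (atom style molecular) and XYZ with the box on the
## comment line. Atom typing convention: 1 = core bead (A), 2 = core bead
## (B), 3 = patch (A), 4 = patch (B); atoms of one nanostar are contiguous,
## beads first (central bead leading), then patches.

CORE_TYPES <- c(A = 1L, B = 2L)
PATCH_TYPES <- c(A = 3L, B = 4L)

# per-frame atom table of a pose frame (unwrapped coordinates)
frame_atom_table <- function(centers, quats, types, geometry, box) {
  n <- nrow(centers)
  nb <- nrow(geometry$beads); np <- nrow(geometry$patches)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    R <- quat_to_matrix(quats[i, ])
    beads <- geometry$beads %*% t(R) + rep(1, nb) %o% centers[i, ]
    patches <- geometry$patches %*% t(R) + rep(1, np) %o% centers[i, ]
    xyz <- rbind(beads, patches)
    ty <- c(rep(CORE_TYPES[[types[i]]], nb), rep(PATCH_TYPES[[types[i]]], np))
    rows[[i]] <- data.frame(mol = i, type = ty,
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  tab <- do.call(rbind, rows)
  tab <- cbind(id = seq_len(nrow(tab)), tab)
  img <- floor(cbind(tab$x / box$L[1], tab$y / box$L[2], tab$z / box$L[3]))
  tab$ix <- as.integer(img[, 1]); tab$iy <- as.integer(img[, 2])
  tab$iz <- as.integer(img[, 3])
  tab$x <- tab$x - tab$ix * box$L[1]
  tab$y <- tab$y - tab$iy * box$L[2]
  tab$z <- tab$z - tab$iz * box$L[3]
  tab
}

traj_frames_as_atoms <- function(traj) {
  if (inherits(traj, "configuration")) {
    n <- traj$n
    quats <- traj$quats
    tab <- frame_atom_table(traj$centers, quats, traj$types, traj$geometry, traj$box)
    return(list(list(atoms = tab, time = 0, box = traj$box)))
  }
  stopifnot(inherits(traj, "trajectory"))
  if (!length(traj$frames)) stop("empty trajectory")
  lapply(seq_along(traj$frames), function(k) {
    fr <- traj$frames[[k]]
    if (!is.null(fr$atoms)) {
      list(atoms = fr$atoms, time = fr$time, box = traj$box)
    } else {
      list(atoms = frame_atom_table(fr$centers, fr$quats, traj$types,
                                    traj$geometry, traj$box),
           time = fr$time, box = traj$box)
    }
  })
}

#' Write a trajectory to a standard particle format
#'
#' LAMMPS dump keeps wrapped coordinates with image flags (lossless for
#' positions); LAMMPS data writes a single frame (atom style molecular);
#' XYZ writes element-coded atoms with the box on the comment line and
#' drops molecule ids and image flags beyond contiguous-group recovery
#' (velocities are never written: documented lossy behaviour, a warning is
#' logged for XYZ).
#'
#' @param traj A `trajectory` or a single `configuration`.
#' @param path Output file path.
#' @param format One of `"lammps-dump"`, `"lammps-data"`, `"xyz"` (guessed
#'   from the extension when missing: .dump/.lammpstrj, .data, .xyz).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path,
                             format = c("lammps-dump", "lammps-data", "xyz")) {
  if (missing(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     dump = , lammpstrj = "lammps-dump",
                     data = "lammps-data", xyz = "xyz",
                     "lammps-dump")
  } else {
    format <- match.arg(format)
  }
  frames <- traj_frames_as_atoms(traj)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "lammps-dump") {
    for (fr in frames) {
      a <- fr$atoms
      writeLines(c("ITEM: TIMESTEP", format(round(fr$time / 0.01)),
                   "ITEM: NUMBER OF ATOMS", format(nrow(a)),
                   "ITEM: BOX BOUNDS pp pp pp",
                   sprintf("0.0 %.10g", fr$box$L[1]),
                   sprintf("0.0 %.10g", fr$box$L[2]),
                   sprintf("0.0 %.10g", fr$box$L[3]),
                   "ITEM: ATOMS id mol type x y z ix iy iz"), con)
      writeLines(sprintf("%d %d %d %.10g %.10g %.10g %d %d %d",
                         a$id, a$mol, a$type, a$x, a$y, a$z, a$ix, a$iy, a$iz), con)
    }
  } else if (format == "lammps-data") {
    if (length(frames) > 1) stop("LAMMPS data files hold a single frame")
    fr <- frames[[1]]; a <- fr$atoms
    writeLines(c("LAMMPS data file (nanolink)", "",
                 sprintf("%d atoms", nrow(a)),
                 sprintf("%d atom types", 4L), "",
                 sprintf("0.0 %.10g xlo xhi", fr$box$L[1]),
                 sprintf("0.0 %.10g ylo yhi", fr$box$L[2]),
                 sprintf("0.0 %.10g zlo zhi", fr$box$L[3]), "",
                 "Atoms # molecular", ""), con)
    writeLines(sprintf("%d %d %d %.10g %.10g %.10g %d %d %d",
                       a$id, a$mol, a$type, a$x, a$y, a$z, a$ix, a$iy, a$iz), con)
  } else {
    nl_log("info", "XYZ export drops molecule ids, image flags and velocities")
    syms <- c("CA", "CB", "PA", "PB")
    for (fr in frames) {
      a <- fr$atoms
      writeLines(c(format(nrow(a)),
                   sprintf("Box: %.10g %.10g %.10g Time: %.10g",
                           fr$box$L[1], fr$box$L[2], fr$box$L[3], fr$time)), con)
      writeLines(sprintf("%s %.10g %.10g %.10g", syms[a$type], a$x, a$y, a$z), con)
    }
  }
  invisible(path)
}

#' Read a trajectory from a standard particle format
#'
#' Returns a site-based `trajectory`: each frame holds an atom table (id,
#' mol, type, wrapped x/y/z, image flags) plus box and time. When image
#' flags are present, unwrapped coordinates are `x + ix * Lx`; otherwise
#' coordinates are wrapped and the frame is flagged. Malformed headers,
#' inconsistent atom counts across frames and triclinic boxes are errors
#' naming the offending frame.
#'
#' @param path Input file.
#' @param format As in [write_trajectory()]; guessed from the extension.
#' @return A `trajectory` with site-based frames.
#' @export
read_trajectory <- function(path, format = c("lammps-dump", "lammps-data", "xyz")) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (missing(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     dump = , lammpstrj = "lammps-dump",
                     data = "lammps-data", xyz = "xyz",
                     "lammps-dump")
  } else {
    format <- match.arg(format)
  }
  lines <- readLines(path)
  frames <- switch(format,
                   `lammps-dump` = parse_lammps_dump(lines),
                   `lammps-data` = parse_lammps_data(lines),
                   xyz = parse_xyz(lines))
  counts <- vapply(frames, function(f) nrow(f$atoms), integer(1))
  if (length(unique(counts)) > 1) {
    stop(sprintf("inconsistent atom counts across frames: frame %d has %d atoms, frame 1 has %d",
                 which(counts != counts[1])[1], counts[counts != counts[1]][1], counts[1]))
  }
  box <- frames[[1]]$box
  for (k in seq_along(frames)) {
    if (max(abs(frames[[k]]$box$L - box$L)) > 1e-9) {
      stop("time-varying box detected at frame ", k, ": not supported")
    }
  }
  structure(list(frames = frames,
                 times = vapply(frames, function(f) f$time, numeric(1)),
                 box = box, format = format,
                 geometry = NULL, types = NULL),
            class = "trajectory")
}

parse_lammps_dump <- function(lines) {
  frames <- list()
  i <- 1L
  nframe <- 0L
  while (i <= length(lines)) {
    nframe <- nframe + 1L
    expect <- function(pat, what) {
      if (i > length(lines) || !grepl(pat, lines[i])) {
        stop(sprintf("malformed dump header at frame %d, line %d: expected %s",
                     nframe, i, what))
      }
    }
    expect("^ITEM: TIMESTEP", "ITEM: TIMESTEP")
    step <- as.numeric(lines[i + 1L]); i <- i + 2L
    expect("^ITEM: NUMBER OF ATOMS", "ITEM: NUMBER OF ATOMS")
    natoms <- as.integer(lines[i + 1L]); i <- i + 2L
    expect("^ITEM: BOX BOUNDS", "ITEM: BOX BOUNDS")
    if (grepl("xy|xz|yz", lines[i])) {
      stop("triclinic box bounds at frame ", nframe, ": only orthorhombic boxes are supported")
    }
    bounds <- do.call(rbind, lapply(lines[i + 1:3], function(l) {
      as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:2])
    }))
    if (any(is.na(bounds))) stop("malformed box bounds at frame ", nframe)
    i <- i + 4L
    expect("^ITEM: ATOMS", "ITEM: ATOMS")
    cols <- strsplit(sub("^ITEM: ATOMS\\s*", "", lines[i]), "\\s+")[[1]]
    req <- c("id", "mol", "type", "x", "y", "z")
    if (!all(req %in% cols)) {
      stop("dump frame ", nframe, " lacks required columns (need id mol type x y z; got: ",
           paste(cols, collapse = " "), ")")
    }
    extra <- setdiff(cols, c(req, "ix", "iy", "iz"))
    if (length(extra)) warning("ignoring extra dump columns: ", paste(extra, collapse = " "))
    i <- i + 1L
    if (i + natoms - 1L > length(lines)) {
      stop("truncated dump at frame ", nframe, " (expected ", natoms, " atom lines)")
    }
    body <- utils::read.table(text = lines[i:(i + natoms - 1L)],
                              col.names = cols, colClasses = "numeric")
    i <- i + natoms
    has_img <- all(c("ix", "iy", "iz") %in% cols)
    atoms <- data.frame(id = as.integer(body$id), mol = as.integer(body$mol),
                        type = as.integer(body$type),
                        x = body$x - bounds[1, 1], y = body$y - bounds[2, 1],
                        z = body$z - bounds[3, 1],
                        ix = if (has_img) as.integer(body$ix) else 0L,
                        iy = if (has_img) as.integer(body$iy) else 0L,
                        iz = if (has_img) as.integer(body$iz) else 0L)
    atoms <- atoms[order(atoms$id), ]
    frames[[nframe]] <- list(atoms = atoms, time = step * 0.01,
                             box = periodic_box(bounds[1, 2] - bounds[1, 1],
                                                bounds[2, 2] - bounds[2, 1],
                                                bounds[3, 2] - bounds[3, 1]),
                             wrapped_only = !has_img)
  }
  frames
}

parse_lammps_data <- function(lines) {
  natoms <- NA_integer_
  L <- c(NA_real_, NA_real_, NA_real_)
  lo <- c(0, 0, 0)
  for (l in lines) {
    if (grepl("^\\s*\\d+\\s+atoms\\s*$", l)) natoms <- as.integer(strsplit(trimws(l), "\\s+")[[1]][1])
    for (k in 1:3) {
      tag <- c("xlo xhi", "ylo yhi", "zlo zhi")[k]
      if (grepl(tag, l, fixed = TRUE)) {
        v <- as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:2])
        lo[k] <- v[1]; L[k] <- v[2] - v[1]
      }
    }
  }
  if (is.na(natoms) || any(is.na(L))) stop("malformed data file header")
  at <- grep("^Atoms", lines)
  if (length(at) != 1) stop("data file must contain exactly one Atoms section")
  body_lines <- lines[(at + 1):length(lines)]
  body_lines <- body_lines[nzchar(trimws(body_lines))]
  body_lines <- body_lines[seq_len(natoms)]
  body <- utils::read.table(text = body_lines)
  if (!ncol(body) %in% c(6, 9)) stop("Atoms section must have 6 or 9 columns (molecular style)")
  atoms <- data.frame(id = as.integer(body[[1]]), mol = as.integer(body[[2]]),
                      type = as.integer(body[[3]]),
                      x = body[[4]] - lo[1], y = body[[5]] - lo[2], z = body[[6]] - lo[3],
                      ix = if (ncol(body) == 9) as.integer(body[[7]]) else 0L,
                      iy = if (ncol(body) == 9) as.integer(body[[8]]) else 0L,
                      iz = if (ncol(body) == 9) as.integer(body[[9]]) else 0L)
  atoms <- atoms[order(atoms$id), ]
  list(list(atoms = atoms, time = 0, box = periodic_box(L[1], L[2], L[3]),
            wrapped_only = ncol(body) == 6))
}

parse_xyz <- function(lines) {
  frames <- list()
  i <- 1L
  syms <- c(CA = 1L, CB = 2L, PA = 3L, PB = 4L)
  nframe <- 0L
  while (i <= length(lines)) {
    nframe <- nframe + 1L
    natoms <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(natoms)) stop("malformed XYZ atom count at frame ", nframe)
    comment <- lines[i + 1L]
    m <- regmatches(comment, regexec(
      "Box:\\s*([-0-9.eE+]+)\\s+([-0-9.eE+]+)\\s+([-0-9.eE+]+)(\\s+Time:\\s*([-0-9.eE+]+))?",
      comment))[[1]]
    if (length(m) < 4) stop("XYZ comment line lacks box dimensions at frame ", nframe)
    box <- periodic_box(as.numeric(m[2]), as.numeric(m[3]), as.numeric(m[4]))
    tm <- if (length(m) >= 6 && nzchar(m[6])) as.numeric(m[6]) else nframe - 1
    i <- i + 2L
    body <- utils::read.table(text = lines[i:(i + natoms - 1L)],
                              col.names = c("sym", "x", "y", "z"),
                              colClasses = c("character", rep("numeric", 3)))
    i <- i + natoms
    type <- unname(syms[body$sym])
    if (any(is.na(type))) stop("unknown atom symbol in XYZ frame ", nframe)
    mol <- if (natoms %% 10L == 0L) rep(seq_len(natoms / 10L), each = 10L) else {
      warning("cannot infer molecule grouping from XYZ (atom count not a multiple of 10)")
      rep(NA_integer_, natoms)
    }
    frames[[nframe]] <- list(atoms = data.frame(id = seq_len(natoms), mol = mol,
                                                type = type, x = body$x, y = body$y,
                                                z = body$z, ix = 0L, iy = 0L, iz = 0L),
                             time = tm, box = box, wrapped_only = TRUE)
  }
  frames
}

#' Configuration view of a site-based trajectory frame
#'
#' Rebuilds a `configuration`-compatible object from an atom table: the
#' leading core bead of each molecule is the center, patches are the
#' trailing patch-typed sites. Orientation quaternions are not recoverable
#' from coordinates and are set to identity.
#'
#' @param traj A site-based `trajectory` from [read_trajectory()].
#' @param i Frame index.
#' @param geometry Geometry metadata to attach (default standard nanostar).
#' @return A `configuration` (with `sites_only = TRUE` attribute).
#' @export
sites_configuration <- function(traj, i = 1, geometry = nanostar_geometry()) {
  fr <- traj$frames[[i]]
  a <- fr$atoms
  box <- fr$box
  is_core <- a$type %in% c(1L, 2L)
  mols <- sort(unique(a$mol))
  centers <- t(vapply(mols, function(m) {
    rows <- which(a$mol == m & is_core)
    unlist(a[rows[1], c("x", "y", "z")])
  }, numeric(3)))
  types <- vapply(mols, function(m) {
    if (any(a$mol == m & a$type %in% c(2L, 4L))) "B" else "A"
  }, character(1))
  patch_rows <- which(!is_core)
  patches <- as.matrix(a[patch_rows, c("x", "y", "z")])
  patch_mol <- match(a$mol[patch_rows], mols)
  obj <- structure(list(
    centers = wrap_coords(centers, box), quats = NULL, types = types,
    beads = wrap_coords(as.matrix(a[is_core, c("x", "y", "z")]), box),
    patches = wrap_coords(patches, box),
    bead_mol = match(a$mol[is_core], mols), patch_mol = patch_mol,
    patch_arm = stats::ave(patch_mol, patch_mol, FUN = seq_along),
    n = length(mols), rho = sum(is_core) * (pi / 6) / box$volume,
    box = box, geometry = geometry
  ), class = "configuration")
  attr(obj, "sites_only") <- TRUE
  obj
}
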
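## Minimum-loop census and Gauss linking analysis.
##
## Loops are polygons through nanostar centers; the Gauss linking number of
## two disjoint closed polygons is evaluated exactly by summing signed solid
## angles over segment pairs, and cross-checked by counting signed crossings
## in generic projections.

#' Closed polygonal loop
#'
#' @param vertices n x 3 matrix of unwrapped vertex coordinates (closure is
#'   implied; the first vertex is not repeated).
#' @param nodes Optional integer vector of originating nanostar ids.
#' @param winding Integer triple of net box crossings (0,0,0 = contractible).
#' @return A `closed_polygon` object.
#' @export
closed_polygon <- function(vertices, nodes = NULL, winding = c(0L, 0L, 0L)) {
  vertices <- matrix(as.numeric(vertices), ncol = 3L)
  if (nrow(vertices) < 3L) stop("a closed polygon needs at least 3 vertices")
  structure(list(vertices = vertices, nodes = nodes,
                 winding = as.integer(winding),
                 contractible = all(winding == 0L)),
            class = "closed_polygon")
}

#' @export
print.closed_polygon <- function(x, ...) {
  cat(sprintf("closed_polygon: %d vertices, winding (%d,%d,%d)%s\n",
              nrow(x$vertices), x$winding[1], x$winding[2], x$winding[3],
              if (x$contractible) "" else " [non-contractible]"))
  invisible(x)
}

polygon_centroid <- function(p) colMeans(p$vertices)
polygon_radius <- function(p) {
  c0 <- colMeans(p$vertices)
  sqrt(max(rowSums(sweep(p$vertices, 2, c0)^2)))
}

polygon_rg <- function(p) {
  c0 <- colMeans(p$vertices)
  sqrt(mean(rowSums(sweep(p$vertices, 2, c0)^2)))
}

#' Gauss linking number of two closed polygons
#'
#' Evaluates the Gauss double integral exactly for polygonal curves as a sum
#' of signed solid angles over all segment pairs, then rounds to the nearest
#' integer. The raw sum must lie within `tol` of an integer, otherwise a
#' warning is raised (for exact polygonal evaluation a large residual
#' indicates near-touching curves).
#'
#' @param a,b `closed_polygon` objects (or n x 3 vertex matrices).
#' @param tol Maximum allowed |raw - integer| residual (default 0.05).
#' @return Integer linking number, with attributes `raw` and `confidence`
#'   (the residual).
#' @export
gauss_linking_number <- function(a, b, tol = 0.05) {
  A <- if (inherits(a, "closed_polygon")) a$vertices else matrix(as.numeric(a), ncol = 3)
  B <- if (inherits(b, "closed_polygon")) b$vertices else matrix(as.numeric(b), ncol = 3)
  if (.min_vertex_distance_cpp(A, B) <= 1e-6) {
    stop("curves touch or intersect (min distance <= 1e-6 sigma): Lk undefined")
  }
  raw <- .gauss_linking_raw_cpp(A, B)
  lk <- round(raw)
  conf <- abs(raw - lk)
  if (conf > tol) {
    warning(sprintf("Gauss sum %.4f is %.4f away from an integer; curves may nearly touch",
                    raw, conf))
  }
  structure(as.integer(lk), raw = raw, confidence = conf)
}

#' Linking number by signed crossing counts (projection oracle)
#'
#' Independent of the Gauss-sum route: projects both curves along random
#' directions, sums the signs of all inter-curve crossings and halves the
#' total. Degenerate projections (crossings at endpoints, near-parallel
#' overlaps) are discarded and redrawn. All retained projections must agree.
#'
#' @param a,b `closed_polygon` objects or n x 3 vertex matrices.
#' @param n_projections Number of independent projection directions.
#' @param max_tries Bound on redraws for degenerate projections.
#' @return Integer linking number.
#' @export
crossing_sign_linking <- function(a, b, n_projections = 5, max_tries = 100) {
  A <- if (inherits(a, "closed_polygon")) a$vertices else matrix(as.numeric(a), ncol = 3)
  B <- if (inherits(b, "closed_polygon")) b$vertices else matrix(as.numeric(b), ncol = 3)
  values <- numeric(0)
  tries <- 0
  while (length(values) < n_projections && tries < max_tries) {
    tries <- tries + 1
    u <- stats::rnorm(3)
    s <- .crossing_sign_sum_cpp(A, B, u)
    if (is.na(s)) next
    if (abs(s / 2 - round(s / 2)) > 1e-9) next  # odd crossing parity: degenerate
    values <- c(values, s / 2)
  }
  if (length(values) < n_projections) {
    stop("persistent projection degeneracy after ", max_tries, " tries")
  }
  if (length(unique(values)) != 1L) {
    stop("projections disagree on the crossing count: ",
         paste(unique(values), collapse = ", "))
  }
  as.integer(values[1])
}

#' Minimum loops of a bonded network
#'
#' For every node that lies on a cycle, finds one shortest simple cycle
#' through it by breadth-first search from the node: the BFS tree labels
#' every vertex with the branch (first-step neighbour) it descends from, and
#' any edge joining two distinct branches closes a candidate cycle through
#' the root. Among co-minimal candidates the lexicographically smallest
#' rotated/reflected node-id sequence is kept; the resulting loops are then
#' deduplicated by node set. Parallel bonds (2-cycles) are ignored; loops
#' have at least 3 nanostars.
#'
#' @param graph A `network_graph` from [build_bond_graph()] (or any igraph).
#' @param keep_all_comin If TRUE keep every co-minimal loop per node before
#'   deduplication (the census size depends on this convention).
#' @return A `loop_set`: list of node-id integer vectors, plus `l_min`
#'   lengths and the per-node minimum-length table.
#' @export
find_minimum_loops <- function(graph, keep_all_comin = FALSE) {
  g <- as_igraph_network(graph)
  n <- igraph::vcount(g)
  if (n == 0L) return(new_loop_set(list()))
  gs <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  adj <- igraph::as_adj_list(gs, mode = "all")
  adj <- lapply(adj, function(a) sort(as.integer(a)))

  per_node <- vector("list", n)
  node_lmin <- rep(NA_integer_, n)
  for (v in seq_len(n)) {
    if (length(adj[[v]]) < 2L) next
    res <- shortest_cycles_through(v, adj, keep_all_comin)
    if (is.null(res)) next
    node_lmin[v] <- length(res[[1]])
    per_node[[v]] <- res
  }
  loops <- list()
  seen <- character(0)
  for (v in seq_len(n)) {
    for (cyc in per_node[[v]]) {
      key <- paste(sort(cyc), collapse = ",")
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        loops[[length(loops) + 1L]] <- cyc
      }
    }
  }
  new_loop_set(loops, node_lmin = node_lmin)
}

new_loop_set <- function(loops, node_lmin = NULL) {
  structure(list(loops = loops,
                 l_min = vapply(loops, length, integer(1)),
                 n_minloop = length(loops),
                 node_lmin = node_lmin),
            class = "loop_set")
}

#' @export
print.loop_set <- function(x, ...) {
  cat(sprintf("loop_set: %d minimum loops", x$n_minloop))
  if (x$n_minloop > 0) {
    cat(sprintf(", l_min in [%d, %d], mean %.2f",
                min(x$l_min), max(x$l_min), mean(x$l_min)))
  }
  cat("\n")
  invisible(x)
}

# BFS two-branch meeting; returns list of candidate cycles (node-id vectors,
# canonical orientation) of minimal length through v, or NULL
shortest_cycles_through <- function(v, adj, keep_all) {
  n <- length(adj)
  dist <- rep(NA_integer_, n)
  parent <- rep(NA_integer_, n)
  branch <- rep(NA_integer_, n)
  dist[v] <- 0L
  queue <- integer(0)
  for (w in adj[[v]]) {
    dist[w] <- 1L; parent[w] <- v; branch[w] <- w
    queue <- c(queue, w)
  }
  best_len <- Inf
  candidates <- list()
  qi <- 1L
  while (qi <= length(queue)) {
    u <- queue[qi]; qi <- qi + 1L
    if (2L * dist[u] >= best_len) break  # no shorter cycle can appear
    for (w in adj[[u]]) {
      if (w == v) next
      if (is.na(dist[w])) {
        dist[w] <- dist[u] + 1L; parent[w] <- u; branch[w] <- branch[u]
        queue <- c(queue, w)
      } else if (branch[w] != branch[u]) {
        len <- dist[u] + dist[w] + 1L
        if (len < best_len) { best_len <- len; candidates <- list() }
        if (len == best_len) {
          p1 <- trace_back(u, parent, v)   # v ... u
          p2 <- trace_back(w, parent, v)   # v ... w
          cyc <- c(p1, rev(p2[-1L]))       # v ... u w ... (v implied)
          candidates[[length(candidates) + 1L]] <- canonical_cycle(cyc)
        }
      }
    }
  }
  if (!length(candidates)) return(NULL)
  keys <- vapply(candidates, function(cc) paste(cc, collapse = ","), character(1))
  candidates <- candidates[!duplicated(keys)]
  if (keep_all) return(candidates)
  keys <- vapply(candidates, function(cc) paste(sprintf("%09d", cc), collapse = ","), character(1))
  candidates[order(keys)][1]
}

trace_back <- function(u, parent, v) {
  path <- u
  while (u != v) {
    u <- parent[u]
    path <- c(u, path)
  }
  path
}

# canonical form of a cycle id sequence: minimum over rotations x reflections
canonical_cycle <- function(cyc) {
  k <- length(cyc)
  best <- NULL
  for (dir in list(cyc, rev(cyc))) {
    start <- which(dir == min(dir))
    for (s in start) {
      rot <- dir[c(s:k, seq_len(s - 1L))]
      if (is.null(best) || lex_less(rot, best)) best <- rot
    }
  }
  best
}

lex_less <- function(a, b) {
  d <- a - b
  nz <- which(d != 0)
  if (!length(nz)) return(FALSE)
  d[nz[1]] < 0
}

#' Unwrap a loop's node sequence into a closed polygon
#'
#' Vertices are accumulated by minimum-image steps between consecutive node
#' centers, starting from the first node's wrapped position. The winding
#' vector records the net number of box crossings; a nonzero winding marks a
#' non-contractible (box-spanning) cycle for which the linking number
#' against other loops is not defined.
#'
#' @param nodes Integer vector of node ids along the loop.
#' @param config A `configuration` (node position = central-bead position) or
#'   an n x 3 matrix of node positions.
#' @param box A [periodic_box()]; taken from `config` when missing.
#' @return A [closed_polygon()].
#' @export
unwrap_loop <- function(nodes, config, box = NULL) {
  if (inherits(config, "configuration")) {
    pos <- config$centers
    if (is.null(box)) box <- config$box
  } else {
    pos <- as.matrix(config)
  }
  stopifnot(is_periodic_box(box))
  k <- length(nodes)
  verts <- matrix(0, k, 3)
  verts[1, ] <- pos[nodes[1], ]
  for (i in 2:k) {
    step <- minimum_image(pos[nodes[i], ] - pos[nodes[i - 1L], ], box)
    verts[i, ] <- verts[i - 1L, ] + step
  }
  closing <- minimum_image(pos[nodes[1], ] - pos[nodes[k], ], box)
  gap <- verts[k, ] + closing - verts[1, ]
  winding <- as.integer(round(gap / box$L))
  if (max(abs(gap - winding * box$L)) > 1e-9) {
    stop("loop closure gap is not a lattice vector; nodes are not a graph cycle")
  }
  closed_polygon(verts, nodes = as.integer(nodes), winding = winding)
}

#' Catenation census of a loop set
#'
#' Computes the Gauss linking number between every unordered pair of
#' contractible minimum loops, including periodic images of the second loop
#' whose centroid lies within `image_cutoff` of the first (after
#' bounding-sphere pruning), and aggregates: total linking
#' `L = sum |Lk|`, linking valence `<Z> = L / N_minloop`, the fraction of
#' loops linked at least once, the loop-level link graph and whether a
#' connected component of that graph wraps the periodic box (percolation).
#'
#' @param loops A `loop_set` or list of [closed_polygon()]s (unwrapped).
#' @param box A [periodic_box()].
#' @param config Needed when `loops` is a `loop_set` of node ids (to unwrap).
#' @param image_cutoff Centroid distance within which periodic images are
#'   considered; default half the box edge plus twice the largest loop radius.
#' @return A `link_network`: pair table (i, j, shift, Lk), totals, loop
#'   graph, `percolates` flag, `n_noncontractible` excluded loops.
#' @export
link_census <- function(loops, box, config = NULL, image_cutoff = NULL) {
  polys <- as_polygon_list(loops, config, box)
  contract <- vapply(polys, function(p) p$contractible, logical(1))
  n_noncon <- sum(!contract)
  polys <- polys[contract]
  np <- length(polys)
  empty_pairs <- data.frame(i = integer(0), j = integer(0),
                            sx = integer(0), sy = integer(0), sz = integer(0),
                            lk = integer(0))
  if (np < 2L) {
    return(new_link_network(empty_pairs, np, n_noncon, box, polys))
  }
  cents <- t(vapply(polys, polygon_centroid, numeric(3)))
  radii <- vapply(polys, polygon_radius, numeric(1))
  if (is.null(image_cutoff)) image_cutoff <- min(box$L) / 2 + 2 * max(radii)
  smax <- pmin(pmax(ceiling((image_cutoff + 2 * max(radii)) / box$L), 0L), 2L)
  shifts <- as.matrix(expand.grid(sx = -smax[1]:smax[1], sy = -smax[2]:smax[2],
                                  sz = -smax[3]:smax[3]))
  pairs <- empty_pairs
  for (i in seq_len(np - 1L)) {
    for (j in (i + 1L):np) {
      for (srow in seq_len(nrow(shifts))) {
        s <- shifts[srow, ]
        cj <- cents[j, ] + s * box$L
        dc <- sqrt(sum((cents[i, ] - cj)^2))
        if (dc > image_cutoff) next
        if (dc > radii[i] + radii[j]) next  # bounding spheres disjoint: Lk = 0
        Bv <- sweep(polys[[j]]$vertices, 2, s * box$L, "+")
        if (.min_vertex_distance_cpp(polys[[i]]$vertices, Bv) <= 1e-6) next
        raw <- .gauss_linking_raw_cpp(polys[[i]]$vertices, Bv)
        lk <- as.integer(round(raw))
        if (lk != 0L) {
          pairs <- rbind(pairs, data.frame(i = i, j = j, sx = s[1], sy = s[2],
                                           sz = s[3], lk = lk))
        }
      }
    }
  }
  new_link_network(pairs, np, n_noncon, box, polys)
}

as_polygon_list <- function(loops, config, box) {
  if (inherits(loops, "loop_set")) {
    if (is.null(config)) stop("a configuration is needed to unwrap a loop_set")
    lapply(loops$loops, unwrap_loop, config = config, box = box)
  } else if (inherits(loops, "closed_polygon")) {
    list(loops)
  } else {
    stopifnot(all(vapply(loops, inherits, logical(1), "closed_polygon")))
    loops
  }
}

new_link_network <- function(pairs, n_loops, n_noncontractible, box, polys) {
  total_L <- sum(abs(pairs$lk))
  linked <- unique(c(pairs$i, pairs$j))
  lg <- igraph::make_empty_graph(n = n_loops, directed = FALSE)
  percolates <- FALSE
  if (nrow(pairs) > 0) {
    lg <- igraph::add_edges(lg, rbind(pairs$i, pairs$j))
    igraph::E(lg)$sx <- pairs$sx
    igraph::E(lg)$sy <- pairs$sy
    igraph::E(lg)$sz <- pairs$sz
    cents <- t(vapply(polys, polygon_centroid, numeric(3)))
    percolates <- any(component_wraps_box(lg, cents, box))
  }
  structure(list(
    pairs = pairs,
    total_linking = total_L,
    n_minloop = n_loops,
    linking_valence = if (n_loops > 0) total_L / n_loops else 0,
    linked_fraction = if (n_loops > 0) length(linked) / n_loops else 0,
    loop_graph = lg,
    percolates = percolates,
    n_noncontractible = n_noncontractible
  ), class = "link_network")
}

#' @export
print.link_network <- function(x, ...) {
  cat(sprintf(paste0("link_network: %d loops, total linking L = %d, <Z> = %.3f, ",
                     "linked fraction %.3f, percolating: %s\n"),
              x$n_minloop, x$total_linking, x$linking_valence,
              x$linked_fraction, x$percolates))
  if (x$n_noncontractible > 0) {
    cat(sprintf("  (%d non-contractible loops excluded from the census)\n",
                x$n_noncontractible))
  }
  invisible(x)
}

# A component wraps the box when a BFS that assigns unwrapped coordinates via
# the per-edge image shifts meets an already-assigned vertex at a different
# image: the displacement mismatch is then a nonzero lattice vector.
component_wraps_box <- function(lg, cents, box) {
  n <- igraph::vcount(lg)
  if (n == 0) return(FALSE)
  comp <- igraph::components(lg)$membership
  el <- igraph::as_edgelist(lg, names = FALSE)
  sx <- igraph::E(lg)$sx; sy <- igraph::E(lg)$sy; sz <- igraph::E(lg)$sz
  adj <- vector("list", n)
  for (e in seq_len(nrow(el))) {
    i <- el[e, 1]; j <- el[e, 2]
    s <- c(sx[e], sy[e], sz[e])
    adj[[i]] <- c(adj[[i]], list(list(to = j, s = s)))
    adj[[j]] <- c(adj[[j]], list(list(to = i, s = -s)))
  }
  wraps <- logical(max(comp))
  coord <- matrix(NA_real_, n, 3)
  for (root in seq_len(n)) {
    if (!is.na(coord[root, 1])) next
    coord[root, ] <- cents[root, ]
    queue <- root
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (ed in adj[[u]]) {
        # neighbour's position in the same unwrapped frame as u
        pos <- coord[u, ] + (cents[ed$to, ] + ed$s * box$L - cents[u, ])
        if (is.na(coord[ed$to, 1])) {
          coord[ed$to, ] <- pos
          queue <- c(queue, ed$to)
        } else if (max(abs(coord[ed$to, ] - pos)) > min(box$L) / 4) {
          wraps[comp[u]] <- TRUE
        }
      }
    }
  }
  wraps
}
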
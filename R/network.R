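## Bonded nanostar network: graph construction, branching statistics and the
## spherical-neighbourhood interpenetration probe.

#' Build the bonded nanostar graph
#'
#' One node per nanostar (position = central bead, type label kept), one edge
#' per hybridized arm pair. Each edge stores the periodic-image shift of the
#' second endpoint relative to the first (an integer triple), so cycles can
#' be unwrapped and box-winding loops detected.
#'
#' @param config A `configuration`.
#' @param bonds A `bond_list` from [detect_bonds()], or a data.frame with
#'   columns `i`, `j` (nanostar ids) and optionally `arm_i`, `arm_j`.
#' @return A `network_graph` (igraph with vertex attributes `x`, `y`, `z`,
#'   `type`; edge attributes `arm_i`, `arm_j`, `sx`, `sy`, `sz`).
#' @export
build_bond_graph <- function(config, bonds) {
  stopifnot(inherits(config, "configuration"))
  b <- if (inherits(bonds, "bond_list")) bonds$bonds else as.data.frame(bonds)
  n <- config$n
  if (nrow(b) > 0 && (max(b$i, b$j) > n || min(b$i, b$j) < 1)) {
    stop("bond references a nanostar id outside the configuration")
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$x <- config$centers[, 1]
  igraph::V(g)$y <- config$centers[, 2]
  igraph::V(g)$z <- config$centers[, 3]
  igraph::V(g)$type <- config$types
  if (nrow(b) > 0) {
    g <- igraph::add_edges(g, rbind(b$i, b$j))
    d <- config$centers[b$j, , drop = FALSE] - config$centers[b$i, , drop = FALSE]
    shift <- -round(sweep(d, 2, config$box$L, "/"))
    igraph::E(g)$arm_i <- if (!is.null(b$arm_i)) b$arm_i else NA_integer_
    igraph::E(g)$arm_j <- if (!is.null(b$arm_j)) b$arm_j else NA_integer_
    igraph::E(g)$sx <- shift[, 1]
    igraph::E(g)$sy <- shift[, 2]
    igraph::E(g)$sz <- shift[, 3]
  }
  if (any(igraph::degree(g) > 3)) stop("node degree exceeds the valence f = 3")
  class(g) <- c("network_graph", class(g))
  attr(g, "box") <- config$box
  g
}

as_igraph_network <- function(graph) {
  if (igraph::is_igraph(graph)) return(graph)
  stop("expected an igraph/network_graph object")
}

#' Degree histogram and branching-point fraction
#'
#' A branching point is a node of full valence (degree 3).
#'
#' @param graph A `network_graph`.
#' @return List with `histogram` (named fractions over degrees 0..3, summing
#'   to 1), `counts`, and `branching_fraction`.
#' @export
branch_statistics <- function(graph) {
  g <- as_igraph_network(graph)
  if (igraph::vcount(g) == 0) stop("empty graph")
  deg <- igraph::degree(g)
  counts <- table(factor(deg, levels = 0:3))
  list(histogram = stats::setNames(as.numeric(counts) / length(deg), names(counts)),
       counts = counts,
       branching_fraction = mean(deg == 3))
}

#' Interpenetration probe by spherical neighbourhoods
#'
#' Drops probe spheres at uniform random positions, induces the bond-graph
#' subgraph on the nanostars whose (wrapped, minimum-image) centers fall
#' inside each sphere, and counts connected components after discarding
#' components smaller than `min_component` nodes. Probes retaining fewer
#' than `2 * min_component` nodes are excluded from the summary fraction;
#' interpenetration shows up as probes whose neighbourhood splits into two
#' or more mutually unbonded subnetworks.
#'
#' A finite sphere cut from a sparse periodic network also strands
#' boundary fragments whose connecting paths leave the sphere; these are
#' not interpenetration. Components smaller than `min_component` nodes are
#' always dropped; for large probe radii, where boundary fragments can
#' grow beyond any fixed size, `min_fraction > 0` additionally restricts
#' the count to "major" components holding at least that fraction of the
#' retained nodes (a genuinely interpenetrated neighbourhood splits into
#' comparably sized subnetworks, while boundary fragments stay small
#' relative to the core).
#'
#' @param config A `configuration` (for the box).
#' @param graph The bonded `network_graph`.
#' @param radius Probe sphere radius (< half the smallest box edge).
#' @param n_probes Number of probes.
#' @param min_component Minimum component size retained (default 3).
#' @param min_fraction Fraction of retained nodes a component needs to
#'   count as major (default 0: absolute threshold only).
#' @param seed RNG seed.
#' @return An `interpenetration_report`: per-probe table and the summary
#'   `fraction_multi` of evaluable probes with >= 2 major components.
#' @export
probe_interpenetration <- function(config, graph, radius, n_probes = 200,
                                   min_component = 3, min_fraction = 0,
                                   seed = 1) {
  stopifnot(inherits(config, "configuration"))
  g <- as_igraph_network(graph)
  box <- config$box
  if (radius >= min(box$L) / 2) stop("probe radius must be below half the box edge")
  set.seed(seed)
  centers <- config$centers
  probes <- cbind(stats::runif(n_probes, 0, box$L[1]),
                  stats::runif(n_probes, 0, box$L[2]),
                  stats::runif(n_probes, 0, box$L[3]))
  rows <- vector("list", n_probes)
  for (p in seq_len(n_probes)) {
    d <- minimum_image(sweep(centers, 2, probes[p, ]), box)
    inside <- which(rowSums(d^2) <= radius^2)
    ncomp <- 0L
    if (length(inside) > 0) {
      sub <- igraph::induced_subgraph(g, inside)
      comp <- igraph::components(sub)
      keep <- which(comp$csize >= min_component)
      inside <- inside[comp$membership %in% keep]
      n_ret <- sum(comp$csize[keep])
      ncomp <- sum(comp$csize[keep] >= min_fraction * n_ret)
    }
    rows[[p]] <- data.frame(px = probes[p, 1], py = probes[p, 2], pz = probes[p, 3],
                            radius = radius, n_inside = length(inside),
                            n_components = ncomp)
  }
  tab <- do.call(rbind, rows)
  evaluable <- tab$n_inside >= 2 * min_component
  frac <- if (any(evaluable)) mean(tab$n_components[evaluable] >= 2) else NA_real_
  structure(list(probes = tab, fraction_multi = frac,
                 n_evaluable = sum(evaluable), seed = seed),
            class = "interpenetration_report")
}

#' @export
print.interpenetration_report <- function(x, ...) {
  cat(sprintf("interpenetration_report: %d/%d evaluable probes, multi-component fraction %.3f\n",
              x$n_evaluable, nrow(x$probes), x$fraction_multi))
  invisible(x)
}

#' Export a bond graph as an edge-list table
#'
#' @param graph A `network_graph`.
#' @param path Optional CSV path; when NULL the data.frame is returned only.
#' @return data.frame with columns i, j, shift_x, shift_y, shift_z.
#' @export
export_edge_list <- function(graph, path = NULL) {
  g <- as_igraph_network(graph)
  el <- igraph::as_edgelist(g, names = FALSE)
  df <- data.frame(i = el[, 1], j = el[, 2],
                   shift_x = igraph::E(g)$sx %||% 0L,
                   shift_y = igraph::E(g)$sy %||% 0L,
                   shift_z = igraph::E(g)$sz %||% 0L)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
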
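# Shared helpers: brute-force oracles and small constructed fixtures.

# brute-force shortest simple cycle through a vertex (DFS enumeration);
# independent of the BFS implementation in find_minimum_loops
brute_shortest_cycle_through <- function(v, adj, max_len = 12) {
  best <- NULL
  path <- c(v)
  recurse <- function(u) {
    if (length(path) > max_len) return()
    if (!is.null(best) && length(path) >= length(best)) return()
    for (w in adj[[u]]) {
      if (w == v && length(path) >= 3) {
        if (is.null(best) || length(path) < length(best)) best <<- path
      } else if (!(w %in% path)) {
        path <<- c(path, w)
        recurse(w)
        path <<- path[-length(path)]
      }
    }
  }
  recurse(v)
  best
}

adj_list_of <- function(graph) {
  gs <- igraph::simplify(graph, remove.multiple = TRUE, remove.loops = TRUE)
  lapply(igraph::as_adj_list(gs, mode = "all"), as.integer)
}

# n-cycle bond table
cycle_bonds <- function(n) {
  data.frame(i = 1:n, j = c(2:n, 1))
}

# configuration with nanostars on given centers, identity orientations
centers_configuration <- function(centers, box, types = "A") {
  n <- nrow(centers)
  place_configuration(nanostar_geometry(), centers,
                      matrix(rep(c(1, 0, 0, 0), n), ncol = 4, byrow = TRUE),
                      box, types = types)
}

# smooth random closed curve (trigonometric polynomial), for oracle
# cross-validation of the two linking-number routes
random_smooth_curve <- function(n_vertices = 40, n_harmonics = 3) {
  t <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  xyz <- matrix(0, n_vertices, 3)
  for (k in 1:3) {
    for (h in seq_len(n_harmonics)) {
      xyz[, k] <- xyz[, k] + stats::rnorm(1, 0, 1 / h) * cos(h * t) +
        stats::rnorm(1, 0, 1 / h) * sin(h * t)
    }
  }
  closed_polygon(sweep(xyz, 2, stats::rnorm(3), "+"))
}
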
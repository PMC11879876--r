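## Structural observables: random-insertion mesh size, loop statistics,
## branch-to-branch path lengths and fractal dimension.

#' Mesh-size sampling by random insertion
#'
#' Draws probe points uniformly in the box (points landing inside a core
#' bead are rejected and redrawn) and, for each kept point, finds the
#' largest sphere that contains the point without overlapping any core bead
#' (bead radius sigma/2; patches are zero-volume and ignored). The sphere
#' center is optimized by constrained local ascent on the clearance field
#' with multi-starts; the mesh size xi is the sphere diameter, capped at the
#' smallest box edge (capped samples are flagged).
#'
#' @param config A `configuration`, or a list with `beads` (m x 3) and `box`.
#' @param n_samples Number of retained probe points.
#' @param seed RNG seed.
#' @param tol Convergence tolerance on the radius (sigma).
#' @return A `mesh_samples` data.frame: probe point, sphere center, `xi`,
#'   `capped`; attribute `n_rejected` counts in-bead redraws.
#' @export
sample_mesh_size <- function(config, n_samples = 1000, seed = 1, tol = 1e-4) {
  if (inherits(config, "configuration")) {
    beads <- config$beads; box <- config$box
  } else {
    beads <- as.matrix(config$beads); box <- config$box
  }
  stopifnot(is_periodic_box(box))
  set.seed(seed)
  kept <- 0L
  rejected <- 0L
  out <- vector("list", 0)
  while (kept < n_samples) {
    batch <- max(n_samples - kept, 64L)
    probes <- cbind(stats::runif(batch, 0, box$L[1]),
                    stats::runif(batch, 0, box$L[2]),
                    stats::runif(batch, 0, box$L[3]))
    res <- .mesh_probe_cpp(beads, box$L, probes, 0.5, tol, 200L)
    ok <- !res$inside_bead
    rejected <- rejected + sum(!ok)
    if (any(ok)) {
      idx <- which(ok)[seq_len(min(sum(ok), n_samples - kept))]
      out[[length(out) + 1L]] <- data.frame(
        px = probes[idx, 1], py = probes[idx, 2], pz = probes[idx, 3],
        cx = res$center[idx, 1], cy = res$center[idx, 2], cz = res$center[idx, 3],
        xi = res$diameter[idx], capped = res$capped[idx])
      kept <- kept + length(idx)
    }
  }
  samples <- do.call(rbind, out)
  # hard guarantee: no returned sphere overlaps a bead
  if (nrow(beads) > 0) {
    for (k in seq_len(nrow(samples))) {
      d <- minimum_image(sweep(beads, 2, as.numeric(samples[k, c("cx", "cy", "cz")])), box)
      clear <- sqrt(min(rowSums(d^2))) - 0.5
      if (clear < samples$xi[k] / 2 - 1e-9) {
        stop("internal error: mesh sphere overlaps a bead")
      }
    }
  }
  attr(samples, "n_rejected") <- rejected
  class(samples) <- c("mesh_samples", class(samples))
  samples
}

#' Mesh-size distribution statistics
#'
#' Histogram of xi fitted with a Gaussian by least squares; capped samples
#' are excluded from the fit. Reports the fitted mean with its standard
#' error and the plain sample mean, and flags poor Gaussian fits
#' (R-squared < 0.9).
#'
#' @param samples A `mesh_samples` table (or numeric vector of xi values).
#' @param bins Number of histogram bins.
#' @return List: `mean_xi` (fitted), `sem`, `sd`, `sample_mean`, `fit`
#'   (mu, sigma, amplitude), `r_squared`, `poor_fit`, `n`.
#' @export
mesh_size_stats <- function(samples, bins = 40) {
  xi <- if (is.data.frame(samples)) samples$xi[!samples$capped] else as.numeric(samples)
  if (length(xi) < 100) stop("need at least 100 uncapped samples")
  if (stats::sd(xi) < 1e-12) stop("degenerate mesh samples: all values equal")
  h <- graphics::hist(xi, breaks = bins, plot = FALSE)
  x <- h$mids; y <- h$density
  start <- list(A = max(y), mu = mean(xi), s = stats::sd(xi))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-(x - mu)^2 / (2 * s^2)), start = start,
                      lower = c(0, min(x), 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("Gaussian fit failed; reporting sample moments")
    return(list(mean_xi = mean(xi), sem = stats::sd(xi) / sqrt(length(xi)),
                sd = stats::sd(xi), sample_mean = mean(xi), fit = NULL,
                r_squared = NA_real_, poor_fit = TRUE, n = length(xi)))
  }
  cf <- stats::coef(fit)
  resid <- y - stats::predict(fit)
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  if (r2 < 0.9) warning(sprintf("poor Gaussian fit to mesh distribution (R^2 = %.3f)", r2))
  se_mu <- tryCatch(summary(fit)$coefficients["mu", "Std. Error"],
                    error = function(e) NA_real_)
  list(mean_xi = unname(cf["mu"]), sem = unname(se_mu), sd = unname(cf["s"]),
       sample_mean = mean(xi),
       fit = list(amplitude = unname(cf["A"]), mu = unname(cf["mu"]), sigma = unname(cf["s"])),
       r_squared = r2, poor_fit = r2 < 0.9, n = length(xi))
}

#' Minimum-loop length statistics
#'
#' @param loops A `loop_set` (or list of them, one per configuration, in
#'   which case the s.e.m. of the mean is taken across configurations).
#' @return List: `p_lmin` (normalized distribution over l_min), `mean_lmin`,
#'   `sem`, `n_minloop`.
#' @export
loop_statistics <- function(loops) {
  sets <- if (inherits(loops, "loop_set")) list(loops) else loops
  all_l <- unlist(lapply(sets, function(s) s$l_min))
  n_tot <- length(all_l)
  if (n_tot == 0) {
    return(list(p_lmin = numeric(0), mean_lmin = NA_real_, sem = NA_real_,
                n_minloop = 0L))
  }
  tab <- table(all_l)
  p <- as.numeric(tab) / n_tot
  names(p) <- names(tab)
  means <- vapply(sets, function(s) if (s$n_minloop) mean(s$l_min) else NA_real_, numeric(1))
  means <- means[!is.na(means)]
  sem <- if (length(means) > 1) {
    stats::sd(means) / sqrt(length(means))
  } else {
    stats::sd(all_l) / sqrt(n_tot)
  }
  list(p_lmin = p, mean_lmin = mean(all_l), sem = sem, n_minloop = n_tot)
}

#' Branch-to-branch path statistics
#'
#' A chain is a maximal path joining two branching points (degree-3 nodes)
#' whose interior nodes all have degree <= 2; its length lambda is counted
#' in edges. Each chain is counted once; direct bonds between two branching
#' points give lambda = 1.
#'
#' @param graph A `network_graph`.
#' @return List: `lambda` (vector of chain lengths), `p_lambda`,
#'   `mean_lambda`, `n_chains`. Empty when fewer than two branching points.
#' @export
branch_path_statistics <- function(graph) {
  g <- as_igraph_network(graph)
  deg <- igraph::degree(g)
  hubs <- which(deg == 3)
  empty <- list(lambda = integer(0), p_lambda = numeric(0),
                mean_lambda = NA_real_, n_chains = 0L)
  if (length(hubs) < 2) return(empty)
  gs <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  adj <- igraph::as_adj_list(gs, mode = "all")
  adj <- lapply(adj, function(a) as.integer(a))
  lambdas <- integer(0)
  seen <- character(0)
  for (h in hubs) {
    for (nb in adj[[h]]) {
      # walk along the chain starting h -> nb until the next hub
      prev <- h; cur <- nb; len <- 1L
      repeat {
        if (cur %in% hubs) {
          key <- paste(min(h, cur), max(h, cur), min(prev, nb), max(prev, nb),
                       len, sep = "_")
          # canonical key: endpoints + first steps from both ends + length
          key2 <- chain_key(h, nb, cur, prev, len)
          if (!(key2 %in% seen)) {
            seen <- c(seen, key2)
            lambdas <- c(lambdas, len)
          }
          break
        }
        nxt <- setdiff(adj[[cur]], prev)
        if (length(nxt) != 1L) break  # dead end or isolated oddity
        prev <- cur; cur <- nxt; len <- len + 1L
      }
    }
  }
  if (!length(lambdas)) return(empty)
  tab <- table(lambdas)
  list(lambda = lambdas, p_lambda = stats::setNames(as.numeric(tab) / length(lambdas),
                                                    names(tab)),
       mean_lambda = mean(lambdas), n_chains = length(lambdas))
}

# a chain is identified by its two (hub, first-step) ends, orientation-free
chain_key <- function(h1, s1, h2, s2_prev, len) {
  e1 <- paste(h1, s1, sep = ":")
  e2 <- paste(h2, s2_prev, sep = ":")
  paste(sort(c(e1, e2)), collapse = "|")
}

#' Fractal dimension from shortest-path radius of gyration
#'
#' Samples random node pairs in the largest connected component, takes the
#' graph-shortest path between them, computes the 3-D radius of gyration of
#' each path from unwrapped node positions, and fits
#' `log Rg = nu * log n + c`. The fractal dimension is `d_f = 1/nu`.
#'
#' @param graph A `network_graph` with vertex coordinates.
#' @param config A `configuration` (for box unwrapping); optional if the
#'   graph has `x`, `y`, `z` and a box attribute.
#' @param n_paths Number of sampled paths.
#' @param seed RNG seed.
#' @param min_len Minimum path length (nodes) retained for the fit.
#' @return List: `nu`, `nu_se`, `d_f`, `fit` data (n, rg), `n_used`.
#' @export
fractal_dimension <- function(graph, config = NULL, n_paths = 200, seed = 1,
                              min_len = 3) {
  g <- as_igraph_network(graph)
  box <- if (!is.null(config)) config$box else attr(graph, "box")
  pos <- if (!is.null(config)) {
    config$centers
  } else {
    cbind(igraph::V(g)$x, igraph::V(g)$y, igraph::V(g)$z)
  }
  comp <- igraph::components(g)
  giant <- which.max(comp$csize)
  members <- which(comp$membership == giant)
  if (length(members) < 20) stop("largest connected component has fewer than 20 nodes")
  set.seed(seed)
  ns <- integer(0); rgs <- numeric(0)
  for (k in seq_len(n_paths)) {
    uv <- sample(members, 2)
    sp <- igraph::shortest_paths(g, from = uv[1], to = uv[2], output = "vpath")
    path <- as.integer(sp$vpath[[1]])
    if (length(path) < min_len) next
    # unwrap the path by minimum-image steps
    xyz <- matrix(0, length(path), 3)
    xyz[1, ] <- pos[path[1], ]
    for (i in 2:length(path)) {
      xyz[i, ] <- xyz[i - 1, ] + minimum_image(pos[path[i], ] - pos[path[i - 1], ], box)
    }
    cm <- colMeans(xyz)
    rg <- sqrt(mean(rowSums(sweep(xyz, 2, cm)^2)))
    if (rg > 0) { ns <- c(ns, length(path)); rgs <- c(rgs, rg) }
  }
  if (length(ns) < 10 || length(unique(ns)) < 3) {
    stop("too few usable paths for a fractal fit (", length(ns), " sampled)")
  }
  fit <- stats::lm(log(rgs) ~ log(ns))
  nu <- unname(stats::coef(fit)[2])
  nu_se <- summary(fit)$coefficients[2, 2]
  list(nu = nu, nu_se = nu_se, d_f = 1 / nu,
       fit = data.frame(n = ns, rg = rgs), n_used = length(ns))
}
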
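# Minimum loops, Gauss linking and the catenation census.

test_that("minimum loops: cycles, trees and the BFS contract", {
  box <- periodic_box(100)
  hexagon <- centers_configuration(cbind(10 + 3 * cos(2 * pi * (0:5) / 6),
                                         10 + 3 * sin(2 * pi * (0:5) / 6), 10), box)
  g <- build_bond_graph(hexagon, cycle_bonds(6))
  ls <- find_minimum_loops(g)
  expect_equal(ls$n_minloop, 1L)
  expect_equal(ls$l_min, 6L)
  # a tree has no loops
  tree <- centers_configuration(cbind(seq(5, 30, by = 5), 10, 10), box)
  gt <- build_bond_graph(tree, data.frame(i = 1:5, j = 2:6))
  expect_equal(find_minimum_loops(gt)$n_minloop, 0L)
})

test_that("minimum loops match a brute-force shortest-cycle oracle node-by-node", {
  d <- make_diamond_network(c(2, 2, 2), sublattices = 1, seed = 3)
  ls <- find_minimum_loops(d$graph)
  adj <- adj_list_of(d$graph)
  for (v in seq_along(adj)) {
    oracle <- brute_shortest_cycle_through(v, adj, max_len = 8)
    if (is.null(oracle)) {
      expect_true(is.na(ls$node_lmin[v]))
    } else {
      expect_equal(ls$node_lmin[v], length(oracle))
    }
  }
})

test_that("unwrap_loop records winding and closes contractible cycles", {
  box <- periodic_box(20)
  hexagon <- centers_configuration(cbind(19 + 3 * cos(2 * pi * (0:5) / 6),
                                         10 + 3 * sin(2 * pi * (0:5) / 6), 10) |>
                                     wrap_coords(box), box)
  p <- unwrap_loop(1:6, hexagon, box)
  expect_equal(p$winding, c(0L, 0L, 0L))
  expect_true(p$contractible)
  # chain winding once around x through the boundary
  ringx <- centers_configuration(cbind(seq(0, 17.5, by = 2.5), 10, 10), box)
  px <- unwrap_loop(1:8, ringx, box)
  expect_equal(px$winding, c(1L, 0L, 0L))
  expect_false(px$contractible)
})

test_that("Gauss linking number: Hopf, split and (2,2k) torus links", {
  # canonical Hopf pair as in the defining example
  t64 <- seq(0, 2 * pi, length.out = 65)[-65]
  A <- closed_polygon(cbind(cos(t64), sin(t64), 0))
  B <- closed_polygon(cbind(1 + cos(t64), 0, sin(t64)))
  expect_equal(abs(as.integer(gauss_linking_number(A, B))), 1L)
  far <- closed_polygon(cbind(10 + cos(t64), sin(t64), 0))
  expect_equal(as.integer(gauss_linking_number(A, far)), 0L)
  for (k in 0:5) {
    tl <- make_torus_link(k)
    expect_equal(abs(as.integer(gauss_linking_number(tl[[1]], tl[[2]]))), k)
    expect_equal(abs(crossing_sign_linking(tl[[1]], tl[[2]])), k)
  }
  # touching curves are rejected
  expect_error(gauss_linking_number(A, A), "touch")
})

test_that("Gauss sum and crossing-sign oracle agree on random smooth curves", {
  set.seed(42)
  n_pairs <- 200
  for (i in seq_len(n_pairs)) {
    a <- random_smooth_curve(); b <- random_smooth_curve()
    g <- try(gauss_linking_number(a, b), silent = TRUE)
    if (inherits(g, "try-error")) next
    expect_identical(as.integer(g), crossing_sign_linking(a, b))
  }
})

test_that("linking number is an isotopy invariant with the right symmetries", {
  tl <- make_torus_link(3)
  lk0 <- as.integer(gauss_linking_number(tl[[1]], tl[[2]]))
  rot <- quat_to_matrix(quat_from_axis_angle(c(1, 2, 3), 1.1))
  move <- function(p, f) closed_polygon(f(p$vertices))
  a2 <- move(tl[[1]], function(v) v %*% t(rot) + 5)
  b2 <- move(tl[[2]], function(v) v %*% t(rot) + 5)
  expect_equal(as.integer(gauss_linking_number(a2, b2)), lk0)
  # uniform scaling
  expect_equal(as.integer(gauss_linking_number(
    move(tl[[1]], function(v) 3 * v), move(tl[[2]], function(v) 3 * v))), lk0)
  # refinement: doubling vertices along each segment
  refine <- function(p) {
    v <- p$vertices; n <- nrow(v)
    mid <- (v + v[c(2:n, 1), ]) / 2
    out <- matrix(0, 2 * n, 3)
    out[seq(1, 2 * n, 2), ] <- v; out[seq(2, 2 * n, 2), ] <- mid
    closed_polygon(out)
  }
  expect_equal(as.integer(gauss_linking_number(refine(tl[[1]]), refine(tl[[2]]))), lk0)
  # mirror reflection negates Lk
  expect_equal(as.integer(gauss_linking_number(
    move(tl[[1]], function(v) v %*% diag(c(-1, 1, 1))),
    move(tl[[2]], function(v) v %*% diag(c(-1, 1, 1))))), -lk0)
})

test_that("the census aggregates totals, valence and percolation consistently", {
  d2 <- make_diamond_network(c(3, 3, 3), sublattices = 2, matching = "uniform",
                             seed = 1)
  ls <- find_minimum_loops(d2$graph, keep_all_comin = TRUE)
  cen <- link_census(ls, d2$config$box, config = d2$config)
  expect_equal(cen$linked_fraction, 1.0)
  expect_gte(cen$linking_valence, 1.0)
  expect_true(cen$percolates)
  # identity <Z> * N_minloop = L
  expect_equal(cen$linking_valence * cen$n_minloop, cen$total_linking)
  # single sublattice: no links at all
  d1 <- make_diamond_network(c(3, 3, 3), sublattices = 1, seed = 1)
  cen1 <- link_census(find_minimum_loops(d1$graph), d1$config$box, config = d1$config)
  expect_equal(cen1$total_linking, 0)
  expect_false(cen1$percolates)
  # a single loop can link nothing
  single <- link_census(list(make_torus_link(1)[[1]]), periodic_box(100))
  expect_equal(single$total_linking, 0)
  expect_equal(single$linking_valence, 0)
})

test_that("census totals are invariant under loop relabeling", {
  d2 <- make_diamond_network(c(2, 2, 2), sublattices = 2, matching = "uniform",
                             seed = 2)
  ls <- find_minimum_loops(d2$graph)
  polys <- lapply(ls$loops, unwrap_loop, config = d2$config, box = d2$config$box)
  polys <- polys[vapply(polys, function(p) p$contractible, logical(1))]
  cen_a <- link_census(polys, d2$config$box)
  set.seed(9)
  cen_b <- link_census(polys[sample(length(polys))], d2$config$box)
  expect_equal(cen_b$total_linking, cen_a$total_linking)
  expect_equal(cen_b$linked_fraction, cen_a$linked_fraction)
})

test_that("non-contractible loops are excluded from the census and counted", {
  box <- periodic_box(20)
  ringx <- centers_configuration(cbind(seq(0, 17.5, by = 2.5), 10, 10), box)
  px <- unwrap_loop(1:8, ringx, box)
  t64 <- seq(0, 2 * pi, length.out = 33)[-33]
  circ <- closed_polygon(cbind(10 + 3 * cos(t64), 3 + 3 * sin(t64), 10))
  cen <- link_census(list(px, circ), box)
  expect_equal(cen$n_noncontractible, 1L)
  expect_equal(cen$n_minloop, 1L)
  expect_equal(cen$total_linking, 0)
})
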
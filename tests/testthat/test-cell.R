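# cell domain: voxelization, membrane, partition, remodeling, shape

test_that("spherical initialization matches the volume oracle and is
           near-spherical", {
  fx <- ball_fixture()
  # oracle: direct enumeration over element centroids
  ctr <- expand.grid(x = seq(5, 95, 10), y = seq(5, 95, 10),
                     z = seq(5, 95, 10))
  n_oracle <- sum((ctr$x - 50)^2 + (ctr$y - 50)^2 + (ctr$z - 50)^2 <= 400)
  expect_equal(fx$cell$N, n_oracle)
  expect_equal(fx$cell$N, 32L)
  # count tracks the sphere volume at finer resolution too
  m5 <- hex_mesh(L = c(80, 80, 80), n = c(16, 16, 16), stiffness = 10)
  cl5 <- init_spherical_cell(m5, c(40, 40, 40), 20)
  expect_equal(cl5$N, 280L)
  expect_lt(abs(cl5$N - (4 / 3) * pi * 20^3 / 5^3) / cl5$N, 0.1)
  # centroid within half an edge; shape near-spherical
  expect_true(all(abs(cell_centroid(fx$mesh, fx$cell) - 50) <= 5))
  d <- principal_dimensions(fx$mesh, fx$cell)
  expect_lt(elongation(d[1], d[2], d[3]), 0.1)
  expect_true(all(abs(d - 40) <= 10))
})

test_that("degenerate and invalid initializations behave as documented", {
  mesh <- cube_mesh(n = 4, h = 10)
  # radius below half an edge falls back to the single containing element
  cl <- init_spherical_cell(mesh, c(20, 20, 20), 2)
  expect_equal(cl$N, 1L)
  expect_error(init_spherical_cell(mesh, c(5, 20, 20), 20), "fit")
})

test_that("membrane area counts exposed faces", {
  mesh <- cube_mesh(n = 4, h = 10)
  one <- structure(list(elems = taxisim:::elem_id(mesh, 1L, 1L, 1L),
                        N = 1L, r = 5), class = "cell_domain")
  expect_equal(membrane_nodes(mesh, one)$S, 6 * 100)
  two <- structure(list(elems = c(taxisim:::elem_id(mesh, 1L, 1L, 1L),
                                  taxisim:::elem_id(mesh, 2L, 1L, 1L)),
                        N = 2L, r = 5), class = "cell_domain")
  expect_equal(membrane_nodes(mesh, two)$S, 10 * 100)
  # voxelized ball: above the smooth sphere area but within 50%
  fx <- ball_fixture()
  mm <- membrane_nodes(fx$mesh, fx$cell)
  expect_equal(mm$S, 7200)  # frozen fixture value
  expect_gt(mm$S / (4 * pi * 20^2), 1)
  expect_lt(mm$S / (4 * pi * 20^2), 1.5)
  # tributary areas are a partition of S; area vectors close up
  expect_equal(sum(mm$area), mm$S)
  expect_equal(colSums(mm$avec), c(0, 0, 0))
})

test_that("front/rear partition signs and the tie break", {
  mesh <- cube_mesh(n = 3, h = 10)
  one <- structure(list(elems = taxisim:::elem_id(mesh, 1L, 1L, 1L),
                        N = 1L, r = 5), class = "cell_domain")
  part <- front_rear_partition(mesh, one, c(1, 0, 0))
  xs <- mesh$node_xyz[part$nodes, 1]
  expect_equal(sort(unique(part$delta)), c(-5, 5))
  expect_equal(part$delta, xs - 15)
  expect_equal(part$front, part$delta >= 0)
  # delta = 0 nodes are assigned to the front
  two <- structure(list(elems = c(taxisim:::elem_id(mesh, 0L, 1L, 1L),
                                  taxisim:::elem_id(mesh, 1L, 1L, 1L)),
                        N = 2L, r = 5), class = "cell_domain")
  p2 <- front_rear_partition(mesh, two, c(1, 0, 0))
  mid <- which(abs(p2$delta) < 1e-12)
  expect_gt(length(mid), 0)
  expect_true(all(p2$front[mid]))
  expect_error(front_rear_partition(mesh, one, c(0, 0, 0)), "degenerate")
})

test_that("swap selection advances the cell and respects constraints", {
  fx <- ball_fixture()
  e_pol <- c(1, 0, 0)
  part <- front_rear_partition(fx$mesh, fx$cell, e_pol)
  sel <- select_extension_retraction(fx$mesh, fx$cell, part, e_pol)
  expect_false(is.null(sel))
  expect_gt(fx$mesh$ecent[sel$e_ex, 1], fx$mesh$ecent[sel$e_re, 1])
  expect_false(sel$e_ex %in% fx$cell$elems)
  expect_true(sel$e_re %in% fx$cell$elems)
  # centroid update identity and conservation
  c0 <- cell_centroid(fx$mesh, fx$cell)
  cl2 <- remodel(fx$mesh, fx$cell, sel$e_ex, sel$e_re)
  expect_equal(cl2$N, fx$cell$N)
  expect_equal(cell_centroid(fx$mesh, cl2) - c0,
               (fx$mesh$ecent[sel$e_ex, ] - fx$mesh$ecent[sel$e_re, ]) /
                 fx$cell$N)
  expect_error(remodel(fx$mesh, fx$cell, sel$e_re, sel$e_re), "infeasible")
})

test_that("repeated +x swaps move the centroid monotonically and keep the
           domain connected, conserved and capped", {
  fx <- ball_fixture()
  cl <- fx$cell
  e_pol <- c(1, 0, 0)
  xs <- cell_centroid(fx$mesh, cl)[1]
  for (i in 1:12) {
    part <- front_rear_partition(fx$mesh, cl, e_pol)
    sel <- select_extension_retraction(fx$mesh, cl, part, e_pol)
    expect_false(is.null(sel))
    cl <- remodel(fx$mesh, cl, sel$e_ex, sel$e_re)
    xs <- c(xs, cell_centroid(fx$mesh, cl)[1])
    expect_equal(cl$N, 32L)
    expect_true(taxisim:::elements_connected(fx$mesh, cl$elems))
  }
  expect_true(all(diff(xs) > 0))
})

test_that("remodeling under random polarization preserves the invariants
           (property test)", {
  set.seed(33)
  fx <- ball_fixture()
  cl <- fx$cell
  cap <- ceiling(0.10 * cl$N)
  for (i in 1:40) {
    e_pol <- taxisim:::random_unit_vector()
    out <- displacement_matched_remodeling(fx$mesh, cl, v = 0.6, dt = 10,
                                           e_pol = e_pol, n_swap_max = 3L)
    cl <- out$cell
    expect_equal(cl$N, 32L)
    expect_true(taxisim:::elements_connected(fx$mesh, cl$elems))
    # the pseudopod budget: never exceeded by more than the transient
    # centroid-shift allowance of the admission rule
    expect_lte(taxisim:::pseudopod_count(fx$mesh, cl), cap + 2L)
  }
})

test_that("retraction never disconnects the domain (hinge case)", {
  mesh <- cube_mesh(n = 5, h = 10)
  # L-shaped tromino: removing the corner element disconnects it
  e1 <- taxisim:::elem_id(mesh, 1L, 1L, 1L)
  e2 <- taxisim:::elem_id(mesh, 2L, 1L, 1L)
  e3 <- taxisim:::elem_id(mesh, 2L, 2L, 1L)
  cl <- structure(list(elems = c(e1, e2, e3), N = 3L, r = 10),
                  class = "cell_domain")
  part <- front_rear_partition(mesh, cl, c(0, 1, 0))
  sel <- select_extension_retraction(mesh, cl, part, c(0, 1, 0))
  expect_false(is.null(sel))
  expect_true(sel$e_re != e2)  # the hinge stays
  rest <- setdiff(c(cl$elems, sel$e_ex), sel$e_re)
  expect_true(taxisim:::elements_connected(mesh, rest))
})

test_that("principal dimensions: boxes, rotation invariance, ball", {
  mesh <- cube_mesh(n = 6, h = 10)
  box <- function(ni, nj, nk) {
    idx <- as.matrix(expand.grid(i = seq_len(ni) - 1L, j = seq_len(nj) - 1L,
                                 k = seq_len(nk) - 1L))
    structure(list(elems = taxisim:::elem_id(mesh, idx[, 1], idx[, 2],
                                             idx[, 3]),
                   N = ni * nj * nk, r = 10), class = "cell_domain")
  }
  expect_equal(principal_dimensions(mesh, box(4, 2, 2)), c(40, 20, 20))
  # rotating the voxel set by 90 degrees leaves the sorted dims unchanged
  expect_equal(principal_dimensions(mesh, box(2, 4, 2)), c(40, 20, 20))
  expect_equal(principal_dimensions(mesh, box(2, 2, 4)), c(40, 20, 20))
  fx <- ball_fixture()
  expect_true(all(abs(principal_dimensions(fx$mesh, fx$cell) - 40) <= 10))
})

test_that("Corey shape factor: sphere, elongated box, scale invariance", {
  expect_equal(shape_factor(7, 7, 7), 1)
  expect_equal(shape_factor(40, 20, 20), 2^0.09)
  expect_equal(shape_factor(40, 20, 20), shape_factor(4, 2, 2))
  expect_error(shape_factor(1, 2, 3), "l_max")
  expect_error(shape_factor(3, 2, 0), "l_min")
  # f >= 1 whenever the ordering holds
  set.seed(8)
  for (i in 1:25) {
    l <- sort(runif(3, 0.1, 50), decreasing = TRUE)
    expect_gte(shape_factor(l[1], l[2], l[3]), 1)
  }
})
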
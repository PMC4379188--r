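# trilinear hexahedral elasticity: patch test, oracle equivalence,
# strain recovery, sensing loads and the sensing readout

test_that("patch test: uniform uniaxial traction gives Hooke's-law strain", {
  E <- 12; nu <- 0.3; sigma <- 0.5
  mesh <- cube_mesh(n = 4, h = 5, E = E, nu = nu)
  sol <- solve_elastic(mesh, uniaxial_face_loads(mesh, sigma))
  eps <- element_strains(sol, seq_len(mesh$ne))
  expect_equal(max(abs(eps[, "exx"] - sigma / E)) / (sigma / E), 0,
               tolerance = 1e-6)
  expect_equal(max(abs(eps[, "eyy"] + nu * sigma / E)) / (sigma / E), 0,
               tolerance = 1e-6)
  expect_lt(max(abs(eps[, "gxy"])), 1e-10)
})

test_that("solution is linear in loads and inversely linear in modulus", {
  mesh1 <- cube_mesh(n = 3, h = 5, E = 4)
  mesh2 <- cube_mesh(n = 3, h = 5, E = 8)
  loads <- uniaxial_face_loads(mesh1, 1)
  u1 <- solve_elastic(mesh1, loads)$u
  u2 <- solve_elastic(mesh2, loads)$u
  expect_equal(u1, 2 * u2, tolerance = 1e-9)
  expect_equal(solve_elastic(mesh1, 0 * loads)$u, numeric(mesh1$ndof))
})

test_that("sparse solve matches a dense direct solve on small meshes", {
  set.seed(21)
  for (n in c(2, 4)) {
    mesh <- hex_mesh(L = rep(n * 5, 3), n = rep(n, 3),
                     stiffness = function(x) 2 + x / 10)
    loads <- rnorm(mesh$ndof)
    # self-equilibrate so constraint reactions stay small
    loads <- loads - rep(colMeans(matrix(loads, ncol = 3, byrow = TRUE)),
                         mesh$nnod)
    K <- assemble_system(mesh)
    fixed <- taxisim:::constrained_dofs(mesh)
    free <- setdiff(seq_len(mesh$ndof), fixed)
    u_dense <- numeric(mesh$ndof)
    u_dense[free] <- solve(as.matrix(K[free, free]), loads[free])
    u_sparse <- solve_elastic(mesh, loads)$u
    expect_lt(max(abs(u_dense - u_sparse)) / max(abs(u_dense)), 1e-9)
  }
})

test_that("cached sensing solver reproduces the direct solve", {
  mesh <- hex_mesh(L = c(120, 60, 60), n = c(12, 6, 6), stiffness = c(1, 50))
  cell <- init_spherical_cell(mesh, c(30, 30, 30), 20)
  lw <- apply_sensing_loads(mesh, cell, 40)
  sv <- sensing_solver(mesh, E_cell = 4.8)
  u1 <- sv(cell$elems, lw$loads)$u
  E2 <- mesh$E_sub; E2[cell$elems] <- 4.8
  u2 <- solve_elastic(mesh, lw$loads, E_elem = E2)$u
  expect_lt(max(abs(u1 - u2)) / max(abs(u2)), 1e-6)
})

test_that("membrane strain tensor averages incident elements and is
           symmetric; directional strain is the quadratic form", {
  mesh <- cube_mesh(n = 3, h = 5, E = 10)
  # impose an exact affine displacement field u = A x
  A <- matrix(c(2e-3, 1e-4, 0, 1e-4, -1e-3, 0, 0, 0, 5e-4), 3, 3)
  u <- as.vector(t(mesh$node_xyz %*% t(A)))
  sol <- structure(list(u = u, mesh = mesh), class = "elastic_solution")
  eps_exact <- (A + t(A)) / 2
  Tn <- membrane_strain_tensor(sol, node = 32L)
  expect_equal(Tn, t(Tn))
  expect_equal(Tn, eps_exact, tolerance = 1e-12)
  e <- c(1, 0, 0)
  expect_equal(directional_strain(Tn, e), eps_exact[1, 1])
  expect_equal(directional_strain(diag(c(3e-3, 0, 0)), c(0, 1, 0)), 0)
  # hydrostatic tensor reads the same in any direction
  set.seed(5)
  ev <- taxisim:::random_unit_vector()
  expect_equal(directional_strain(diag(rep(2e-3, 3)), ev), 2e-3)
  expect_error(directional_strain(Tn, c(1, 1, 0)), "unit")
})

test_that("sensing loads point at the centroid and cancel by symmetry", {
  fx <- ball_fixture()
  lw <- apply_sensing_loads(fx$mesh, fx$cell, 2)
  L3 <- matrix(lw$loads, ncol = 3, byrow = TRUE)
  total <- colSums(L3)
  expect_lt(sqrt(sum(total^2)) / sum(sqrt(rowSums(L3^2))), 0.05)
  # each loaded node: force = F_sens * e_i
  i <- 7L
  nd <- lw$nodes[i]
  expect_equal(as.numeric(L3[nd, ]), as.numeric(lw$e_i[i, ]) * 2)
  expect_equal(apply_sensing_loads(fx$mesh, fx$cell, 0)$loads,
               numeric(fx$mesh$ndof))
})

test_that("stiffer substrate senses smaller deformation (monotone
           compliance) and contraction strains are negative", {
  probe <- function(E) {
    fx <- ball_fixture(E = E)
    pr <- net_traction_probe(fx$mesh, fx$cell, F_sens = 30)
    pr$eps
  }
  e_soft <- probe(2)
  e_stiff <- probe(20)
  expect_true(all(e_soft < 0))
  expect_true(all(e_stiff < 0))
  expect_lt(max(abs(e_stiff)), max(abs(e_soft)))
  # clearly monotone (the cell's own stiffness damps the contrast below
  # the bare 10x modulus ratio)
  expect_gt(median(e_soft) / median(e_stiff), 2)
})

test_that("mirror-symmetric loads give mirror-symmetric strain fields", {
  mesh <- cube_mesh(n = 4, h = 5, E = 10)
  # equal and opposite x-forces at two mirror-image nodes: the load is
  # invariant under reflection through the x = L/2 plane
  xyz <- mesh$node_xyz
  P <- which(xyz[, 1] == 5 & xyz[, 2] == 10 & xyz[, 3] == 10)
  Q <- which(xyz[, 1] == 15 & xyz[, 2] == 10 & xyz[, 3] == 10)
  loads <- numeric(mesh$ndof)
  loads[3 * P - 2] <- 1
  loads[3 * Q - 2] <- -1
  eps <- element_strains(solve_elastic(mesh, loads), seq_len(mesh$ne))
  # mirrored element pairing by flipping the x index
  m_of <- taxisim:::elem_id(mesh, mesh$n[1] - 1L - mesh$eijk[, 1],
                            mesh$eijk[, 2], mesh$eijk[, 3])
  scale <- max(abs(eps[, "exx"]))
  expect_lt(max(abs(eps[, "exx"] - eps[m_of, "exx"])) / scale, 1e-8)
  expect_lt(max(abs(eps[, "eyy"] - eps[m_of, "eyy"])) / scale, 1e-8)
})
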
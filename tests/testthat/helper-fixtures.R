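# fixtures are built in code; nothing is read from disk

# homogeneous cube mesh (n elements per edge, element edge h, modulus E kPa)
cube_mesh <- function(n = 4, h = 5, E = 10, nu = 0.3) {
  hex_mesh(L = rep(n * h, 3), n = rep(n, 3), stiffness = E, nu = nu)
}

# 10x10x10 box of 10 um elements with a centered r = 20 um cell
ball_fixture <- function(E = 10) {
  mesh <- hex_mesh(L = c(100, 100, 100), n = c(10, 10, 10), stiffness = E)
  list(mesh = mesh, cell = init_spherical_cell(mesh, c(50, 50, 50), 20))
}

# consistent nodal loads for a uniform normal traction sigma on the two
# x-faces of the box (tension positive): each boundary element face hands
# sigma * A_face / 4 to its four nodes
uniaxial_face_loads <- function(mesh, sigma) {
  loads <- numeric(mesh$ndof)
  Af <- mesh$h[2] * mesh$h[3]
  lo <- which(mesh$eijk[, 1] == 0L)
  hi <- which(mesh$eijk[, 1] == mesh$n[1] - 1L)
  lo_face <- c(1L, 4L, 8L, 5L)   # local nodes of the -x face
  hi_face <- c(2L, 3L, 7L, 6L)   # local nodes of the +x face
  for (e in lo) for (a in lo_face) {
    nd <- mesh$conn[e, a]
    loads[3 * nd - 2] <- loads[3 * nd - 2] - sigma * Af / 4
  }
  for (e in hi) for (a in hi_face) {
    nd <- mesh$conn[e, a]
    loads[3 * nd - 2] <- loads[3 * nd - 2] + sigma * Af / 4
  }
  loads
}

# net traction of a voxel cell on a mesh, using the simulator's readout
# (sensing solve -> substrate-side strains -> stress law -> tractions)
net_traction_probe <- function(mesh, cell, F_sens = 50,
                               params = cell_params(),
                               E_cell = params$K_pas + params$K_act) {
  mem <- membrane_nodes(mesh, cell)
  lw <- apply_sensing_loads(mesh, cell, F_sens)
  E_elem <- mesh$E_sub
  E_elem[cell$elems] <- E_cell
  sol <- solve_elastic(mesh, lw$loads, E_elem = E_elem)
  n_out <- -mem$avec / pmax(sqrt(rowSums(mem$avec^2)), 1e-12)
  eps <- sensing_strains(sol, cell, lw$nodes, lw$e_i, n_out = n_out)
  eps[is.na(eps)] <- params$eps_min
  sigma <- active_passive_stress(pmin(eps, 0), params)
  A_proj <- pmax(rowSums(mem$avec * lw$e_i), 0)
  tr <- (sigma * A_proj) * lw$e_i
  list(F_net = net_traction(tr), sum_abs = sum(sqrt(rowSums(tr^2))),
       eps = eps)
}

# tiny configuration for smoke tests (seconds, not minutes)
smoke_config <- function(n_steps = 5L, ...) {
  sim_config(L = c(120, 60, 60), n = c(12, 6, 6), n_steps = n_steps,
             cell_center = c(30, 30, 30), n_swap_max = 3L, ...)
}
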
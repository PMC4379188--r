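# Simulation orchestration: configuration presets, start-up calibrations,
# the per-step sensing -> stress -> force balance -> remodeling loop,
# multi-run campaigns and file output.

#' Build a validated simulation configuration
#'
#' Mesh presets: \code{"desk"} (400 x 100 x 100 um, 10 um elements; small
#' enough for test-suite campaigns), \code{"coarse"} (400 x 200 x 200 um,
#' 10 um elements) and \code{"paper"} (400 x 200 x 200 um, 5 um elements,
#' 128,000 elements). Any field can be overridden.
#'
#' @param preset mesh/size preset, see Details
#' @param L,n mesh box (um) and element counts (override the preset)
#' @param stiffness substrate stiffness end values \code{c(at_x0, at_xL)}
#'   in kPa, or a function of x
#' @param temperature,chemo optional gradient end values (deg C / M)
#' @param mu_ch,mu_th chemotactic / thermotactic effective factors
#'   (mechanotaxis gets the remainder)
#' @param ef_strength dcEF strength (mV/mm), NULL for no field
#' @param ef_direction,ef_polarity dcEF axis (anode to cathode) and the
#'   cell's attraction pole
#' @param eta_min,lambda viscosity model, see
#'   \code{\link{effective_viscosity}}
#' @param omega_satur,e_satur surface-charge saturation parameters
#' @param ef_gain electric-force scale in model units; NULL = calibrate at
#'   start-up so a 10 mV/mm reference field matches the initial net
#'   traction magnitude
#' @param ef_velocity_saturation clamp E * Omega(E) above saturation
#' @param params a \code{\link{cell_params}} object
#' @param cell_center initial cell center (um); default one radius plus
#'   one element from the soft wall, centered in y and z
#' @param n_steps number of time steps
#' @param dt minutes of real time per step
#' @param nu substrate Poisson ratio
#' @param F_sens per-node sensing force (nN); NULL = calibrate at start-up
#'   so the softest-substrate sensed strain reaches \code{eps_min}
#' @param E_cell modulus of cell-occupied elements during sensing (kPa);
#'   default \code{K_pas + K_act}
#' @param kappa fixed protrusion amplitude in [0, 1) (NULL = random draw
#'   each step)
#' @param v_ref reference migration speed (um/min) of a cell at the
#'   substrate midpoint, used to calibrate the velocity scale \code{c_v}
#'   at start-up so a crossing takes on the order of a hundred steps
#' @param c_v velocity calibration constant; NULL = calibrate from
#'   \code{v_ref}
#' @param n_swap_max maximum remodeling swap pairs per step; preset
#'   default is 3 at the coarse cell resolutions (one swap of a 32-element
#'   cell already moves the centroid by a tenth of an element edge, the
#'   displacement a paper-scale cell accumulates over ten swaps) and 10 at
#'   the fine "paper" resolution
#' @param cue_axis dominant-cue axis used for the alignment angle theta
#' @param vtk_every write a VTK snapshot every k steps (0 = never;
#'   requires \code{out_dir})
#' @param out_dir output directory for \code{\link{write_outputs}} /
#'   VTK snapshots
#' @return object of class \code{sim_config}
#' @export
sim_config <- function(preset = c("desk", "coarse", "paper"),
                       L = NULL, n = NULL,
                       stiffness = c(1, 100),
                       temperature = NULL, chemo = NULL,
                       mu_ch = 0, mu_th = 0,
                       ef_strength = NULL, ef_direction = c(1, 0, 0),
                       ef_polarity = "cathode",
                       eta_min = 1000, lambda = 0,
                       omega_satur = 1e-4, e_satur = 100,
                       ef_gain = NULL, ef_velocity_saturation = FALSE,
                       params = cell_params(),
                       cell_center = NULL,
                       n_steps = NULL, dt = 10, nu = 0.3,
                       F_sens = NULL, E_cell = NULL,
                       kappa = NULL, v_ref = 1, c_v = NULL,
                       n_swap_max = NULL,
                       cue_axis = c(1, 0, 0),
                       vtk_every = 0L, out_dir = NULL) {
  preset <- match.arg(preset)
  pdef <- switch(preset,
    desk   = list(L = c(400, 100, 100), n = c(40, 10, 10), n_steps = 300L,
                  n_swap_max = 3L),
    coarse = list(L = c(400, 200, 200), n = c(40, 20, 20), n_steps = 300L,
                  n_swap_max = 3L),
    paper  = list(L = c(400, 200, 200), n = c(80, 40, 40), n_steps = 600L,
                  n_swap_max = 10L))
  L <- L %||% pdef$L
  n <- n %||% pdef$n
  n_steps <- n_steps %||% pdef$n_steps
  n_swap_max <- n_swap_max %||% pdef$n_swap_max
  stopifnot(inherits(params, "cell_params"))
  w <- stimulus_weights(mu_ch = mu_ch, mu_th = mu_th)  # validates the sum
  field <- stimulus_field(Lx = L[1], stiffness = stiffness,
                          temperature = temperature, chemo = chemo,
                          ef_strength = ef_strength,
                          ef_direction = ef_direction,
                          ef_polarity = ef_polarity,
                          eta_min = eta_min, lambda = lambda,
                          omega_satur = omega_satur, e_satur = e_satur,
                          ef_gain = ef_gain,
                          ef_velocity_saturation = ef_velocity_saturation)
  cell_center <- cell_center %||% c(params$r + L[1] / n[1], L[2] / 2, L[3] / 2)
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (dt <= 0) stop("dt must be > 0")
  if (!is.null(kappa) && (kappa < 0 || kappa >= 1))
    stop("kappa must lie in [0, 1)")
  cue_axis <- unit_vector(cue_axis)
  if (is.null(cue_axis)) stop("cue_axis must be a non-zero vector")
  structure(list(preset = preset, L = L, n = n, nu = nu,
                 field = field, weights = w, params = params,
                 cell_center = cell_center, n_steps = as.integer(n_steps),
                 dt = dt, F_sens = F_sens,
                 E_cell = E_cell %||% (params$K_pas + params$K_act),
                 kappa = kappa, v_ref = v_ref, c_v = c_v,
                 n_swap_max = as.integer(n_swap_max),
                 cue_axis = cue_axis,
                 vtk_every = as.integer(vtk_every), out_dir = out_dir),
            class = "sim_config")
}

#' The stimulus conditions of the reference study design
#'
#' Six standard single-cell scenarios on the 1 to 100 kPa stiffness
#' gradient: pure mechanotaxis; added thermal gradient (36 to 39 deg C,
#' mu_th = 0.2); added chemoattractant gradient (0 to 5e-5 M) with
#' mu_ch = 0.35 or 0.4; and an added dcEF (cathode at the stiff end) of
#' 10 or 100 mV/mm.
#'
#' @param preset mesh preset passed to \code{\link{sim_config}}
#' @param ... further overrides passed to every \code{\link{sim_config}}
#' @return named list of \code{sim_config} objects
#' @export
default_scenarios <- function(preset = "desk", ...) {
  list(
    mechanotaxis = sim_config(preset, ...),
    thermotaxis  = sim_config(preset, temperature = c(36, 39), mu_th = 0.2, ...),
    chemotaxis_035 = sim_config(preset, chemo = c(0, 5e-5), mu_ch = 0.35, ...),
    chemotaxis_040 = sim_config(preset, chemo = c(0, 5e-5), mu_ch = 0.40, ...),
    ef_10  = sim_config(preset, ef_strength = 10, ...),
    ef_100 = sim_config(preset, ef_strength = 100, ...)
  )
}

# one-off probe: net traction of a cell placed at `center` on the real
# substrate (direct solve; used only during calibration)
probe_net_traction <- function(config, mesh, center) {
  params <- config$params
  cl <- init_spherical_cell(mesh, center, params$r)
  E_elem <- mesh$E_sub
  E_elem[cl$elems] <- config$E_cell
  lw <- apply_sensing_loads(mesh, cl, config$F_sens)
  sol <- solve_elastic(mesh, lw$loads, E_elem = E_elem)
  mem <- membrane_nodes(mesh, cl)
  n_out <- -mem$avec / pmax(sqrt(rowSums(mem$avec^2)), 1e-12)
  eps <- sensing_strains(sol, cl, lw$nodes, lw$e_i, n_out = n_out)
  eps[is.na(eps)] <- params$eps_min
  sigma <- active_passive_stress(pmin(eps, 0), params)
  S <- mem$S
  zeta <- adhesivity(params$k_f, params$n_f, params$psi)
  A_proj <- pmax(rowSums(mem$avec * lw$e_i), 0)
  tr <- (sigma * zeta * A_proj) * lw$e_i
  list(F_net = net_traction(tr), mean_nodal = mean(sqrt(rowSums(tr^2))),
       S = S)
}

# start-up calibrations (all deterministic, fixed before any RNG use):
#  - F_sens: per-node sensing force such that on a homogeneous substrate at
#    the minimum stiffness the most negative sensed directional strain
#    equals eps_min (the solve is linear in the load, so one unit solve and
#    a rescale replace an iterative search);
#  - F_hat: net traction magnitude of the initial cell at its starting
#    position (the largest traction-based force of a run; fallback to the
#    mean nodal traction for fully symmetric degenerate set-ups);
#  - c_v: maps the net traction of a probe cell at the domain center to
#    the reference speed v_ref, so the crossing happens on the order of a
#    hundred steps despite the decline of the traction with stiffness;
#  - ef_gain: a saturation-strength field on the initial membrane area
#    produces a force of magnitude F_hat (electrotaxis dominance at
#    saturation).
calibrate_run <- function(config, mesh, cell) {
  params <- config$params
  field <- config$field
  F_sens <- config$F_sens
  if (is.null(F_sens)) {
    Emin <- min(mesh$E_sub)
    E_hom <- rep(Emin, mesh$ne)
    E_hom[cell$elems] <- config$E_cell
    lw <- apply_sensing_loads(mesh, cell, 1)
    sol <- solve_elastic(mesh, lw$loads, E_elem = E_hom)
    eps1 <- sensing_strains(sol, cell, lw$nodes, lw$e_i)
    m <- min(eps1, na.rm = TRUE)
    if (!is.finite(m) || m >= 0)
      stop("sensing calibration failed: no contraction sensed")
    F_sens <- params$eps_min / m
  }
  cfg <- config
  cfg$F_sens <- F_sens
  p0 <- probe_net_traction(cfg, mesh, cell_centroid(mesh, cell))
  F_hat <- vnorm(p0$F_net)
  if (F_hat < 1e-9 * p0$mean_nodal || F_hat == 0) F_hat <- p0$mean_nodal
  c_v <- config$c_v
  if (is.null(c_v)) {
    mid <- c(mesh$L[1] / 2, mesh$L[2] / 2, mesh$L[3] / 2)
    pm <- probe_net_traction(cfg, mesh, mid)
    F_mid <- vnorm(pm$F_net)
    if (F_mid < 1e-9 * pm$mean_nodal || F_mid == 0) F_mid <- pm$mean_nodal
    eta_mid <- effective_viscosity(stiffness_at(field, mid[1]),
                                   field$eta_min, field$lambda)
    v_unit <- velocity_and_polarization(c(F_mid, 0, 0), 1, params$r,
                                        eta_mid, c_v = 1)$v
    c_v <- config$v_ref / v_unit
  }
  ef_gain <- field$ef_gain
  if (is.null(ef_gain) && !is.null(field$ef)) {
    # anchor: the saturation-strength field dominates the largest traction
    # force of a run, which a probe cell at the soft end of the substrate
    # generates (independent of where this run starts)
    soft_x <- if (is.function(field$stiffness)) 0 else
      if (field$stiffness[1] <= field$stiffness[2]) 0 else mesh$L[1]
    soft_ctr <- c(min(max(soft_x, params$r + mesh$h[1]),
                      mesh$L[1] - params$r - mesh$h[1]),
                  mesh$L[2] / 2, mesh$L[3] / 2)
    ps <- probe_net_traction(cfg, mesh, soft_ctr)
    F_soft <- vnorm(ps$F_net)
    if (F_soft < 1e-9 * ps$mean_nodal || F_soft == 0) F_soft <- ps$mean_nodal
    S_in <- membrane_nodes(mesh, cell)$S
    sat_nN <- field$e_satur *
      surface_charge(field$e_satur, field$omega_satur, field$e_satur) *
      S_in * 1e-3
    ef_gain <- F_soft / sat_nN
  }
  list(F_sens = F_sens, F_hat = F_hat, c_v = c_v, ef_gain = ef_gain)
}

#' Run one migration simulation
#'
#' Executes the per-step loop: mechano-sensing elastic solve, directional
#' membrane strains, active+passive stress, nodal tractions and net
#' traction, mechanotactic direction, cue vectors, effective force, random
#' protrusion force, electric force, drag closure, velocity/polarization,
#' and displacement-matched extension/retraction remodeling. Identical
#' \code{(config, seed)} pairs give identical output.
#'
#' @param config a \code{\link{sim_config}}
#' @param seed integer RNG seed for this run
#' @param verbose print a progress line every 25 steps
#' @return object of class \code{taxisim_run}: \code{trajectory}
#'   (one-row-per-step data frame), \code{metrics} (steady-state window,
#'   Random Index, equilibrium-plane tail mean, morphology maxima),
#'   \code{calibration}, \code{config} and \code{seed}
#' @export
run_simulation <- function(config, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  params <- config$params
  field <- config$field
  mesh <- hex_mesh(L = config$L, n = config$n, stiffness = field,
                   nu = config$nu)
  cell <- init_spherical_cell(mesh, config$cell_center, params$r)
  mem0 <- membrane_nodes(mesh, cell)
  S_in <- mem0$S
  cal <- calibrate_run(config, mesh, cell)
  F_sens <- cal$F_sens
  c_v <- cal$c_v
  ef_gain <- cal$ef_gain
  solver <- sensing_solver(mesh, config$E_cell)

  e_ch <- cue_unit_vector(field, "chemo")
  e_th <- cue_unit_vector(field, "temperature")
  w <- resolve_weights(config$weights, !is.null(e_ch), !is.null(e_th))

  zeta_f <- adhesivity(params$k_f, params$n_f, params$psi)
  zeta_b <- adhesivity(params$k_b, params$n_b, params$psi)

  e_mech_prev <- NULL
  e_pol_prev <- NULL
  ns <- config$n_steps
  rec <- vector("list", ns)

  for (step in seq_len(ns)) {
    ctr <- cell_centroid(mesh, cell)
    mem <- membrane_nodes(mesh, cell)
    lw <- apply_sensing_loads(mesh, cell, F_sens)
    sol <- solver(cell$elems, lw$loads)
    n_out <- -mem$avec / pmax(sqrt(rowSums(mem$avec^2)), 1e-12)
    eps_cell <- sensing_strains(sol, cell, lw$nodes, lw$e_i, n_out = n_out)
    # unanchored nodes (flat against a free box surface) meet no matrix
    # resistance: they sense the largest admissible contraction eps_min,
    # whose negative passive stress pushes the membrane off the surface
    eps_cell[is.na(eps_cell)] <- params$eps_min
    # the probing contraction compresses the cell, so sensed strains are
    # non-positive; positive readings are voxel artifacts of concave
    # membrane pockets and are clamped to zero
    sigma <- active_passive_stress(pmin(eps_cell, 0), params)
    nmem <- length(lw$nodes)
    S <- mem$S
    # front/rear adhesivity uses the previous polarization (equal defaults)
    zeta <- rep(zeta_f, nmem)
    if (!is.null(e_pol_prev) && zeta_f != zeta_b) {
      dlt <- sweep(mesh$node_xyz[lw$nodes, , drop = FALSE], 2, ctr) %*% e_pol_prev
      zeta[dlt < 0] <- zeta_b
    }
    # nodal traction toward the centroid, weighted by the tributary
    # membrane area projected on the pull direction; rear-facing membrane
    # patches (concave pockets) have no anchorage along the pull and
    # transmit nothing
    A_proj <- pmax(rowSums(mem$avec * lw$e_i), 0)
    tr <- (sigma * zeta * A_proj) * lw$e_i
    F_net <- net_traction(tr)
    Fmag <- vnorm(F_net)
    e_mech <- mechanotactic_direction(F_net)
    if (is.null(e_mech)) e_mech <- e_mech_prev %||% random_unit_vector()
    e_mech_prev <- e_mech

    F_eff <- effective_force(Fmag, e_mech, e_ch, e_th, w)
    F_prot <- protrusion_force(Fmag, kappa = config$kappa)
    F_EF <- if (is.null(field$ef)) c(0, 0, 0) else
      electric_force(field$ef$strength, S, field, gain = ef_gain)
    F_drag <- drag_force(F_eff, F_prot, F_EF)

    dims <- principal_dimensions(mesh, cell)
    f_shape <- shape_factor(dims[1], dims[2], dims[3])
    eta <- effective_viscosity(stiffness_at(field, ctr[1]),
                               field$eta_min, field$lambda)
    vp <- velocity_and_polarization(F_drag, f_shape, params$r, eta,
                                    c_v = c_v, prev_e_pol = e_pol_prev)
    e_pol <- vp$e_pol %||% e_mech
    e_pol_prev <- e_pol

    rem <- displacement_matched_remodeling(mesh, cell, vp$v, config$dt,
                                           e_pol, config$n_swap_max)
    cell <- rem$cell
    ctr_new <- cell_centroid(mesh, cell)
    S_new <- membrane_nodes(mesh, cell)$S
    dims_new <- principal_dimensions(mesh, cell)
    theta <- acos(max(-1, min(1, sum(e_pol * config$cue_axis))))

    rec[[step]] <- data.frame(
      step = step, x = ctr_new[1], y = ctr_new[2], z = ctr_new[3],
      v = vp$v, epol_x = e_pol[1], epol_y = e_pol[2], epol_z = e_pol[3],
      emech_x = e_mech[1], theta = theta,
      F_net = Fmag, F_eff = vnorm(F_eff), F_prot = vnorm(F_prot),
      F_EF = vnorm(F_EF), F_drag = vnorm(F_drag),
      S = S_new, CMI = cmi(S_new, S_in),
      elong = elongation(dims_new[1], dims_new[2], dims_new[3]),
      f_shape = f_shape, swaps = rem$swaps,
      displacement = rem$displacement, jammed = rem$jammed)

    if (config$vtk_every > 0 && !is.null(config$out_dir) &&
        step %% config$vtk_every == 0) {
      mask <- integer(mesh$ne)
      mask[cell$elems] <- 1L
      write_vtk_snapshot(mesh,
                         file.path(config$out_dir,
                                   sprintf("step_%04d.vtk", step)),
                         displacement = matrix(sol$u, ncol = 3, byrow = TRUE),
                         cell_mask = mask)
    }
    if (verbose && step %% 25 == 0)
      message(sprintf("step %d: x = %.1f um, v = %.3f um/min, CMI = %.2f",
                      step, ctr_new[1], vp$v, cmi(S_new, S_in)))
  }

  traj <- do.call(rbind, rec)
  rownames(traj) <- NULL
  win <- steady_window(traj$x, config$L[1])
  metrics <- list(
    S_in = S_in,
    steady_window = if (is.null(win)) NULL else range(win),
    RI = if (is.null(win)) NA_real_ else random_index(traj$theta[win]),
    iep = if (is.null(win)) NA_real_ else mean(traj$x[win]),
    max_elong = max(traj$elong), x_at_max_elong = traj$x[which.max(traj$elong)],
    max_cmi = max(traj$CMI), x_at_max_cmi = traj$x[which.max(traj$CMI)])
  structure(list(trajectory = traj, metrics = metrics,
                 calibration = cal,
                 config = config, seed = seed),
            class = "taxisim_run")
}

#' @export
print.taxisim_run <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("taxisim run (seed %d, %d steps)\n", x$seed,
              nrow(x$trajectory)))
  cat(sprintf("  final centroid x = %.1f um; IEP tail mean = %s um\n",
              x$trajectory$x[nrow(x$trajectory)],
              if (is.na(m$iep)) "no steady state" else sprintf("%.1f", m$iep)))
  cat(sprintf("  RI = %s, max elongation = %.3f, max CMI = %.3f\n",
              if (is.na(m$RI)) "NA" else sprintf("%.3f", m$RI),
              m$max_elong, m$max_cmi))
  invisible(x)
}

#' Run a campaign of repeated simulations over conditions
#'
#' Repeats each condition \code{n_runs} times with distinct derived seeds
#' and summarizes the equilibrium-plane position (mean and sd over runs),
#' mean Random Index and morphology maxima per condition. Failures are
#' reported per condition instead of aborting the whole campaign.
#'
#' @param configs a named list of \code{\link{sim_config}} objects (or a
#'   single config)
#' @param n_runs runs per condition
#' @param base_seed base seed; run j of condition i uses
#'   \code{base_seed + 1000 * i + j}
#' @param verbose print one line per finished run
#' @return list with a \code{summary} data frame (one row per condition)
#'   and the nested per-run results in \code{runs}
#' @export
run_campaign <- function(configs, n_runs = 10L, base_seed = 1L,
                         verbose = FALSE) {
  if (inherits(configs, "sim_config")) configs <- list(condition_1 = configs)
  if (length(configs) == 0L) stop("empty condition grid")
  if (is.null(names(configs)) || any(names(configs) == ""))
    names(configs) <- paste0("condition_", seq_along(configs))
  if (n_runs < 1) stop("n_runs must be >= 1")
  all_runs <- list()
  rows <- list()
  for (ci in seq_along(configs)) {
    cname <- names(configs)[ci]
    runs <- vector("list", n_runs)
    errs <- character(0)
    for (rj in seq_len(n_runs)) {
      sd_run <- base_seed + 1000L * ci + rj
      runs[[rj]] <- tryCatch(run_simulation(configs[[ci]], seed = sd_run),
                             error = function(e) e)
      if (inherits(runs[[rj]], "error")) {
        errs <- c(errs, conditionMessage(runs[[rj]]))
      } else if (verbose) {
        message(sprintf("%s run %d/%d: IEP tail %.1f um", cname, rj, n_runs,
                        runs[[rj]]$metrics$iep))
      }
    }
    ok <- runs[!vapply(runs, inherits, logical(1), "error")]
    all_runs[[cname]] <- runs
    if (length(ok) == 0L) {
      warning("condition '", cname, "' failed in all runs: ",
              paste(unique(errs), collapse = "; "))
      rows[[cname]] <- data.frame(condition = cname, n_ok = 0L,
                                  iep_mean = NA_real_, iep_sd = NA_real_,
                                  ri_mean = NA_real_,
                                  max_elong = NA_real_, max_cmi = NA_real_)
      next
    }
    iep <- tryCatch(
      suppressWarnings(iep_estimate(lapply(ok, function(r) r$trajectory$x),
                                    configs[[ci]]$L[1])),
      error = function(e) list(mean = NA_real_, sd = NA_real_))
    rows[[cname]] <- data.frame(
      condition = cname, n_ok = length(ok),
      iep_mean = iep$mean, iep_sd = iep$sd,
      ri_mean = mean(vapply(ok, function(r) r$metrics$RI, numeric(1)),
                     na.rm = TRUE),
      max_elong = mean(vapply(ok, function(r) r$metrics$max_elong, numeric(1))),
      max_cmi = mean(vapply(ok, function(r) r$metrics$max_cmi, numeric(1))))
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(summary = summary, runs = all_runs)
}

#' Write run outputs to a directory
#'
#' Writes \code{trajectory.csv} (one row per step, units documented in the
#' header comment of the file), \code{metrics.json} and a config echo
#' (\code{config.json}) for provenance.
#'
#' @param run a \code{taxisim_run}
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_outputs <- function(run, dir) {
  stopifnot(inherits(run, "taxisim_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(trajectory = file.path(dir, "trajectory.csv"),
             metrics = file.path(dir, "metrics.json"),
             config = file.path(dir, "config.json"))
  utils::write.csv(run$trajectory, paths["trajectory"], row.names = FALSE)
  jsonlite::write_json(run$metrics, paths["metrics"], auto_unbox = TRUE,
                       digits = NA, null = "null")
  jsonlite::write_json(config_echo(run$config), paths["config"],
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}

# serializable echo of a configuration (functions are labeled, not dumped)
config_echo <- function(config) {
  f <- config$field
  list(preset = config$preset, L = config$L, n = config$n, nu = config$nu,
       stiffness = if (is.function(f$stiffness)) "function" else f$stiffness,
       temperature = f$temperature, chemo = f$chemo,
       ef = f$ef, eta_min = f$eta_min, lambda = f$lambda,
       omega_satur = f$omega_satur, e_satur = f$e_satur,
       ef_velocity_saturation = f$ef_velocity_saturation,
       mu_mech = config$weights$mu_mech, mu_ch = config$weights$mu_ch,
       mu_th = config$weights$mu_th,
       cell_center = config$cell_center, r = config$params$r,
       n_steps = config$n_steps, dt = config$dt,
       F_sens = config$F_sens, E_cell = config$E_cell,
       kappa = config$kappa, v_ref = config$v_ref, c_v = config$c_v,
       n_swap_max = config$n_swap_max)
}
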
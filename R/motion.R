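# Per-step force balance and kinematics: random protrusion force,
# multi-cue effective force, electric force, Stokes drag with the Corey
# shape-factor correction, and the displacement-matched coupling between
# velocity and discrete remodeling.

#' Random protrusion force
#'
#' Actin-polymerization protrusions are modeled as a random force of
#' magnitude \code{kappa * F_net_mag} with \code{kappa ~ U[0, 1)} and an
#' isotropic random direction, redrawn every step. Consumes the current R
#' RNG stream; a seeded run is reproducible.
#'
#' @param F_net_mag magnitude of the net traction force
#' @param kappa optional fixed amplitude in [0, 1) overriding the random
#'   draw (used for deterministic runs); the random draws are still
#'   consumed so the RNG stream does not depend on this override
#' @return length-3 force vector
#' @export
protrusion_force <- function(F_net_mag, kappa = NULL) {
  if (F_net_mag < 0) stop("F_net_mag must be >= 0")
  k_draw <- stats::runif(1)
  e_rand <- random_unit_vector()
  k <- kappa %||% k_draw
  if (k < 0 || k >= 1) stop("kappa must lie in [0, 1)")
  k * F_net_mag * e_rand
}

#' Multi-cue effective force
#'
#' The net traction magnitude redistributed over the active guidance
#' directions: \code{F_eff = F_net_mag * (mu_mech e_mech + mu_ch e_ch +
#' mu_th e_th)}. Gradient cues reorient the traction but do not add force.
#'
#' @param F_net_mag magnitude of the net traction force
#' @param e_mech mechanotactic unit vector
#' @param e_ch,e_th chemotactic / thermotactic unit vectors (NULL when the
#'   cue is inactive; its weight must then be zero)
#' @param w a \code{\link{stimulus_weights}} object
#' @return length-3 force vector
#' @export
effective_force <- function(F_net_mag, e_mech, e_ch = NULL, e_th = NULL, w) {
  stopifnot(inherits(w, "stimulus_weights"))
  if (abs(w$mu_mech + w$mu_ch + w$mu_th - 1) > 1e-9)
    stop("effective factors must sum to 1")
  if (is.null(e_ch) && w$mu_ch != 0) stop("mu_ch > 0 but chemo cue inactive")
  if (is.null(e_th) && w$mu_th != 0) stop("mu_th > 0 but thermal cue inactive")
  dir <- w$mu_mech * e_mech
  if (!is.null(e_ch)) dir <- dir + w$mu_ch * e_ch
  if (!is.null(e_th)) dir <- dir + w$mu_th * e_th
  F_net_mag * dir
}

#' Drag force closing the force balance
#'
#' With inertia neglected the force balance on the cell body is
#' \code{F_drag + F_eff + F_prot + F_EF = 0}, so the drag is minus the sum
#' of the driving forces (exact by construction).
#'
#' @param F_eff,F_prot,F_EF driving force vectors
#' @return length-3 drag force vector
#' @export
drag_force <- function(F_eff, F_prot, F_EF) {
  -(F_eff + F_prot + F_EF)
}

#' Instantaneous velocity and polarization direction
#'
#' Stokes drag around a sphere of the nominal radius, corrected by the
#' Corey shape factor: \code{v = c_v * |F_drag| / (f_shape * 6 pi r eta)},
#' evaluated in um/min for drag in nN, radius in um and viscosity in Pa s
#' (with \code{c_v = 1} a 1 nN drag on a 20 um sphere in 1000 Pa s moves
#' at ~0.159 um/min). The calibration constant \code{c_v} rescales the
#' model's adhesivity-inflated force units to this physical scale (see the
#' package vignette); the polarization is the direction opposing the drag.
#'
#' @param F_drag drag force vector
#' @param f_shape Corey shape factor (>= 1)
#' @param r nominal cell radius (um)
#' @param eta local effective viscosity (Pa s)
#' @param c_v velocity calibration constant
#' @param prev_e_pol previous polarization, kept when the drag is
#'   degenerate
#' @param tol degeneracy tolerance on the drag norm
#' @return list with speed \code{v} (um/min) and unit \code{e_pol}
#' @export
velocity_and_polarization <- function(F_drag, f_shape, r, eta, c_v = 1,
                                      prev_e_pol = NULL, tol = 1e-12) {
  stopifnot(f_shape >= 1, r > 0, eta > 0)
  n <- vnorm(F_drag)
  if (!is.finite(n)) stop("non-finite drag force")
  if (n <= tol) {
    return(list(v = 0, e_pol = prev_e_pol))
  }
  # nN / (um * Pa s) -> um/min carries a factor 6e4
  v <- c_v * 6e4 * n / (f_shape * 6 * pi * r * eta)
  list(v = v, e_pol = -F_drag / n)
}

#' Displacement-matched extension/retraction remodeling
#'
#' Bridges the continuous kinematics to the discrete cell domain: swap
#' pairs are applied while the accumulated centroid displacement stays
#' below the kinematic target \code{v * dt}; the final, partial swap is
#' taken with probability (remaining displacement)/(swap displacement), so
#' the expected displacement matches the target without creating absorbing
#' frozen states. A hard cap of \code{n_swap_max} pairs per step applies.
#'
#' @param mesh a \code{\link{hex_mesh}}
#' @param cell a \code{cell_domain}
#' @param v speed (um/min)
#' @param dt step duration (min)
#' @param e_pol unit polarization vector
#' @param n_swap_max maximum swap pairs per step
#' @return list: updated \code{cell}, number of \code{swaps}, accumulated
#'   \code{displacement} (um), and \code{jammed} flag (no feasible swap)
#' @export
displacement_matched_remodeling <- function(mesh, cell, v, dt, e_pol,
                                            n_swap_max = 10L) {
  stopifnot(v >= 0, dt > 0)
  target <- v * dt
  acc <- 0
  swaps <- 0L
  jammed <- FALSE
  while (swaps < n_swap_max) {
    part <- front_rear_partition(mesh, cell, e_pol)
    sel <- select_extension_retraction(mesh, cell, part, e_pol)
    if (is.null(sel)) {
      jammed <- swaps == 0L
      break
    }
    d <- vnorm(mesh$ecent[sel$e_ex, ] - mesh$ecent[sel$e_re, ]) / cell$N
    if (acc + d > target) {
      # partial-swap rounding: unbiased in expectation
      if (stats::runif(1) >= (target - acc) / d) break
    }
    cell <- remodel(mesh, cell, sel$e_ex, sel$e_re)
    acc <- acc + d
    swaps <- swaps + 1L
  }
  list(cell = cell, swaps = swaps, displacement = acc, jammed = jammed)
}
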
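#' Active + passive contractile stress law
#'
#' Piecewise-linear stress transmitted by the cell as a function of the
#' directional internal strain sensed at a membrane node. Outside the
#' working range of the active machinery (\code{[eps_min, eps_max]}) only
#' the passive elements contribute (slope \code{K_pas}); inside, the active
#' acto-myosin stress is superposed, rising to \code{sigma_max} at
#' \code{eps_tilde = sigma_max / K_act} and vanishing at the strain bounds.
#' The law is continuous at all three breakpoints for any valid parameter
#' set.
#'
#' @param eps_cell directional strain(s), dimensionless (vectorized)
#' @param params a \code{\link{cell_params}} object
#' @return stress in kPa, same length as \code{eps_cell}
#' @export
#' @examples
#' p <- cell_params()
#' active_passive_stress(0, p)      # ~0.0643 kPa
#' active_passive_stress(0.12, p)   # passive only: 0.336 kPa
active_passive_stress <- function(eps_cell, params) {
  stopifnot(inherits(params, "cell_params"))
  if (!all(is.finite(eps_cell))) stop("eps_cell must be finite")
  K_pas <- params$K_pas; K_act <- params$K_act
  s_max <- params$sigma_max
  e_min <- params$eps_min; e_max <- params$eps_max; e_til <- params$eps_tilde
  sig <- K_pas * eps_cell                       # passive branch everywhere
  lo <- eps_cell >= e_min & eps_cell <= e_til   # rising active branch
  hi <- eps_cell > e_til & eps_cell <= e_max    # falling active branch
  sig[lo] <- K_act * s_max * (e_min - eps_cell[lo]) / (K_act * e_min - s_max) +
    K_pas * eps_cell[lo]
  sig[hi] <- K_act * s_max * (e_max - eps_cell[hi]) / (K_act * e_max - s_max) +
    K_pas * eps_cell[hi]
  sig
}

#' Adhesivity of the cell-substrate bond
#'
#' Dimensionless product of the integrin binding constant, the number of
#' available receptors and the ligand concentration. Callable separately
#' for the front (\code{k_f, n_f}) and rear (\code{k_b, n_b}) of the cell.
#'
#' @param k binding constant (mol^-1)
#' @param n_r number of available receptors
#' @param psi ligand concentration (mol)
#' @return dimensionless adhesivity
#' @export
adhesivity <- function(k, n_r, psi) {
  if (any(c(k, n_r, psi) < 0)) stop("adhesivity factors must be >= 0")
  k * n_r * psi
}

#' Nodal traction force
#'
#' Traction exerted on the substrate at one membrane node: the nodal stress
#' times the tributary membrane area times the adhesivity, directed along
#' the unit vector from the node towards the cell centroid (for positive
#' stress the node pulls itself inward). 1 kPa x um^2 = 1 nN, so with
#' stress in kPa and area in um^2 the result is in adhesivity-scaled nN.
#'
#' @param sigma_i nodal stress (kPa)
#' @param S_node tributary membrane area of the node (um^2)
#' @param zeta adhesivity (dimensionless, see \code{\link{adhesivity}})
#' @param e_i unit vector from node towards the cell centroid
#' @return length-3 force vector
#' @export
nodal_traction <- function(sigma_i, S_node, zeta, e_i) {
  if (S_node <= 0) stop("S_node must be > 0")
  n <- vnorm(e_i)
  if (n <= 1e-12) stop("e_i must be a non-zero unit vector")
  if (abs(n - 1) > 1e-6) stop("e_i must have unit norm")
  sigma_i * S_node * zeta * e_i
}

#' Net traction force on the whole cell
#'
#' Minus the sum of all nodal traction forces. Because nodes with smaller
#' internal deformation transmit larger stress, the net traction points
#' towards the direction of minimum cell internal deformation: up a
#' stiffness gradient, away from nearby free surfaces.
#'
#' @param tractions numeric matrix with one row per nodal traction (n x 3)
#' @return length-3 force vector
#' @export
net_traction <- function(tractions) {
  tractions <- rbind(tractions)
  if (nrow(tractions) == 0L) stop("need at least one nodal traction")
  -colSums(tractions)
}

#' Mechanotactic reorientation direction
#'
#' Unit vector of the net traction force. If the net traction is
#' (numerically) zero the polarization is degenerate and \code{NULL} is
#' returned; the caller is expected to keep the previous direction (or draw
#' a seeded random direction at the first step).
#'
#' @param F_net net traction force vector
#' @param tol degeneracy tolerance on the force norm
#' @return unit vector, or NULL when degenerate
#' @export
mechanotactic_direction <- function(F_net, tol = 1e-12) {
  unit_vector(F_net, tol = tol)
}
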